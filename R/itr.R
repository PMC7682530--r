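#' Fit an individualized treatment rule to a multi-arm trial
#'
#' Front door to the five ITR learners compared in this package. All return
#' an object inheriting from class `itr` whose `predict` method maps new
#' covariates to recommended arms.
#'
#' \describe{
#'   \item{`"pls-gl"`}{l1-penalized least squares on the basis
#'     `(1, X, A, XA)` with group-lasso selection at the factor level; the
#'     rule is the argmax of the `K` predicted conditional means.}
#'   \item{`"pls-hgl"`}{as above with the strong-hierarchy (hierarchical
#'     group lasso) penalty: an interaction can be selected only together
#'     with both of its parent main effects.}
#'   \item{`"acwl"`}{adaptive contrast weighted learning: doubly-robust AIPW
#'     arm means, adaptive contrasts, and a pruned weighted classification
#'     tree (default contrast `C2`, the most conservative bound).}
#'   \item{`"dlearn"`}{direct learning with linear pairwise decision
#'     functions aggregated over all arm pairs.}
#'   \item{`"bart"`}{Bayesian additive regression trees for `E(Y | X, A)`;
#'     the rule assigns the arm with the largest posterior mean.}
#' }
#'
#' Tuning parameters (penalty paths, tree complexity) are selected by
#' five-fold cross-validation by default. Ties in any argmax are broken
#' toward the smallest arm index (in the donor application arm 1 is the
#' longest, safest inter-donation interval).
#'
#' @param data a [trial_data] object.
#' @param method one of `"pls-gl"`, `"pls-hgl"`, `"acwl"`, `"dlearn"`,
#'   `"bart"`.
#' @param seed optional integer seed set before fitting (cross-validation
#'   folds, boosting, MCMC).
#' @param ... method-specific arguments: `cv_folds`, `nlambda`, `lambda`
#'   (pls); `contrast`, `regressor`, `nrounds`, `max_depth`, `eta`, `cp`,
#'   `minbucket` (acwl); `penalty` (dlearn); `ntree`, `nskip`, `ndpost`,
#'   `keepevery`, `k`, `power`, `base`, `nu`, `q`, `numcut` (bart).
#' @return An object of class `c("itr_<method>", "itr")`.
#' @export
itr <- function(data, method = c("pls-gl", "pls-hgl", "acwl", "dlearn",
                                 "bart"),
                seed = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "trial_data"))
  if (!is.null(seed)) set.seed(seed)
  fit <- switch(method,
    "pls-gl" = itr_pls_fit(data, hierarchy = FALSE, ...),
    "pls-hgl" = itr_pls_fit(data, hierarchy = TRUE, ...),
    "acwl" = itr_acwl_fit(data, ...),
    "dlearn" = itr_dlearn_fit(data, ...),
    "bart" = itr_bart_fit(data, ...))
  fit$n_train <- data$n
  fit
}

#' @export
print.itr <- function(x, ...) {
  lab <- switch(x$method,
    "pls-gl" = "l1-penalized least squares (group lasso)",
    "pls-hgl" = "l1-penalized least squares (hierarchical group lasso)",
    "acwl" = sprintf("adaptive contrast weighted learning (%s)",
                     x$contrast),
    "dlearn" = "direct learning (linear pairwise decision functions)",
    "bart" = "BART posterior-argmax rule",
    x$method)
  cat(sprintf("Individualized treatment rule: %s\n", lab))
  cat(sprintf("Arms: %d; training subjects: %s\n", x$K,
              if (is.null(x$n_train)) "?" else x$n_train))
  invisible(x)
}

#' @export
summary.itr <- function(object, ...) {
  print(object)
  if (inherits(object, "itr_pls")) {
    sel <- pls_interactions_selected(object)
    cat(sprintf("Selected arm-covariate interactions (lambda = %.4g): %s\n",
                object$lambda,
                if (any(sel)) paste(names(sel)[sel], collapse = ", ")
                else "none"))
  }
  if (inherits(object, "itr_acwl") && !is.null(object$tree)) {
    cat("Weighted classification tree:\n")
    print(object$tree)
  }
  if (inherits(object, "itr_bart"))
    cat(sprintf("Posterior draws kept: %d; mean residual sd: %.3f\n",
                object$forest$ndpost, mean(object$sigma)))
  invisible(object)
}
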