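# l1-penalized least squares on the basis (1, X, A, XA): the conditional
# mean E(Y | X, A) is fit with a rich linear model under a group-lasso
# penalty, and the rule is the argmax of the K predicted means. Two
# selection variants: GL (factor-level sparsity, no hierarchy constraint)
# and HGL (strong hierarchy: a selected interaction forces both of its
# parent main effects in), the latter via the overlapped-group
# (glinternet-style) formulation solved as an ordinary group lasso on a
# parent-augmented design.

itr_pls_fit <- function(data, hierarchy = FALSE, cv_folds = 5L,
                        nlambda = 50L, lambda_min_ratio = 1e-4,
                        lambda = NULL) {
  design <- build_design(data$X, data$A, data$K)
  if (hierarchy) {
    ex <- expand_hierarchy(design)
    pen <- vapply(ex$group_info, function(g) g$penalized, logical(1))
    cv <- cv_grplasso(ex$M, data$Y, ex$group, pen, nfolds = cv_folds,
                      lambda = lambda, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio)
    beta <- numeric(ex$n_basis)
    for (i in seq_along(ex$orig))
      beta[ex$orig[i]] <- beta[ex$orig[i]] + cv$beta[i]
    names(beta) <- colnames(design$matrix)
  } else {
    pen <- vapply(design$group_info, function(g) g$penalized, logical(1))
    cv <- cv_grplasso(design$matrix, data$Y, design$group, pen,
                      nfolds = cv_folds, lambda = lambda,
                      nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio)
    beta <- cv$beta
    names(beta) <- colnames(design$matrix)
  }
  structure(
    list(method = if (hierarchy) "pls-hgl" else "pls-gl",
         hierarchy = hierarchy, beta = beta, b0 = cv$b0,
         lambda = cv$lambda_min, cv = list(lambda = cv$lambda, mse = cv$cvm),
         design = design[c("group", "group_info", "hierarchy")],
         encoder = design$encoder, K = data$K),
    class = c("itr_pls", "itr"))
}

#' @export
predict.itr_pls <- function(object, newdata, type = c("arm", "mean"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "trial_data")) newdata <- newdata$X
  n <- nrow(newdata)
  mu <- matrix(NA_real_, n, object$K)
  for (a in seq_len(object$K)) {
    d <- design_matrix(object$encoder, newdata, rep(a, n), object$K)
    mu[, a] <- object$b0 + drop(d$M %*% object$beta)
  }
  if (type == "mean") return(mu)
  argmax_arm(mu)
}

#' @export
coef.itr_pls <- function(object, ...) c("(Intercept)" = object$b0,
                                        object$beta[-1])

# Per-basis-group l2 norms of the fitted coefficients.
pls_group_norms <- function(fit) {
  vapply(seq_along(fit$design$group_info), function(g)
    sqrt(sum(fit$beta[fit$design$group == g]^2)), numeric(1))
}

# Interaction-selection indicator per covariate (nonzero interaction block).
pls_interactions_selected <- function(fit, tol = 1e-10) {
  norms <- pls_group_norms(fit)
  info <- fit$design$group_info
  inter <- which(vapply(info, function(g) g$type == "inter", logical(1)))
  stats::setNames(norms[inter] > tol,
                  vapply(info[inter], function(g) g$cov, character(1)))
}

# Strong-hierarchy check: every selected interaction has both parents
# (covariate main effect and arm effect) selected.
strong_hierarchy_ok <- function(fit, tol = 1e-10) {
  norms <- pls_group_norms(fit)
  all(vapply(fit$design$hierarchy, function(h)
    norms[h$inter] <= tol ||
      (norms[h$main] > tol && norms[h$arm] > tol), logical(1)))
}

#' Selection percentages of arm-covariate interactions across repeated fits
#'
#' Given repeated `itr_pls` fits (e.g. across data splits), reports for each
#' covariate the percentage of fits in which its arm-interaction group was
#' selected (nonzero).
#'
#' @param fits list of at least two fitted `itr_pls` objects.
#' @return Data frame with columns `covariate` and `selected_pct`.
#' @export
selection_frequency <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "itr_pls")))
  sel <- vapply(fits, pls_interactions_selected,
                logical(length(pls_interactions_selected(fits[[1]]))))
  sel <- matrix(sel, ncol = length(fits))
  data.frame(covariate = names(pls_interactions_selected(fits[[1]])),
             selected_pct = 100 * rowMeans(sel))
}
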