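# BART-based ITR: sum-of-trees posterior for E(Y | X, A) with the arm
# supplied as one-hot dummy inputs, rule = per-subject argmax of posterior
# means over the K counterfactual arm settings.

# Numeric input matrix for the sampler: dummy-coded covariates + K one-hot
# arm indicator columns.
bart_input <- function(enc, X, A, K) {
  X <- as.data.frame(X)
  mains <- lapply(seq_along(enc$names), function(j)
    encode_covariate(enc$cols[[j]], X[[enc$names[j]]], enc$names[j]))
  arm <- vapply(1:K, function(a) as.numeric(A == a), numeric(nrow(X)))
  arm <- matrix(arm, ncol = K)
  colnames(arm) <- paste0("arm", 1:K)
  cbind(do.call(cbind, mains), arm)
}

itr_bart_fit <- function(data, ntree = 200L, nskip = 100L, ndpost = 1000L,
                         keepevery = 1L, k = 2, power = 2, base = 0.95,
                         nu = 3, q = 0.90, numcut = 100L) {
  enc <- make_encoder(data$X)
  M <- bart_input(enc, data$X, data$A, data$K)
  if (any(!is.finite(data$Y))) stop("BART requires finite outcomes")
  forest <- bart_mcmc(M, data$Y, as.integer(ntree), as.integer(nskip),
                      as.integer(ndpost), as.integer(keepevery),
                      k, power, base, nu, q, as.integer(numcut))
  structure(
    list(method = "bart", forest = forest, encoder = enc, K = data$K,
         settings = list(ntree = ntree, nskip = nskip, ndpost = ndpost,
                         keepevery = keepevery, k = k, power = power,
                         base = base, nu = nu, q = q, numcut = numcut),
         yhat_train_mean = forest$yhat_train_mean,
         sigma = forest$sigma),
    class = c("itr_bart", "itr"))
}

#' @export
predict.itr_bart <- function(object, newdata, type = c("arm", "mean"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "trial_data")) newdata <- newdata$X
  mu <- posterior_arm_means(object, newdata)
  if (type == "mean") return(mu)
  argmax_arm(mu)
}

# Posterior mean of E(Y | X, A = a) for each arm: n x K matrix.
posterior_arm_means <- function(object, X) {
  n <- nrow(X)
  mu <- matrix(NA_real_, n, object$K)
  for (a in seq_len(object$K)) {
    M <- bart_input(object$encoder, X, rep(a, n), object$K)
    mu[, a] <- drop(bart_eval(object$forest, M, FALSE))
  }
  mu
}

#' Posterior draws of the counterfactual arm means from a BART fit
#'
#' @param object a fitted `itr_bart` object (from [itr()] with
#'   `method = "bart"`).
#' @param X covariate data frame.
#' @return List of `K` matrices, each `ndpost x nrow(X)`: posterior draws of
#'   `E(Y | X, A = a)`.
#' @export
posterior_arm_draws <- function(object, X) {
  stopifnot(inherits(object, "itr_bart"))
  n <- nrow(X)
  lapply(seq_len(object$K), function(a) {
    M <- bart_input(object$encoder, X, rep(a, n), object$K)
    bart_eval(object$forest, M, TRUE)
  })
}

# Model-based ITR effect for one posterior draw: predicted outcome under the
# rule minus the predicted outcome averaged over the non-recommended arms
# (equal arm weights, matching uniform randomization), averaged over
# subjects. Monotone in the predicted outcome under the rule, so the
# per-draw argmax rule dominates every other rule draw by draw.
draw_effect <- function(draw_mat_list, arms) {
  K <- length(draw_mat_list)
  n <- length(arms)
  S <- nrow(draw_mat_list[[1]])
  under <- matrix(0, S, n)
  total <- matrix(0, S, n)
  for (a in seq_len(K)) {
    total <- total + draw_mat_list[[a]]
    sel <- arms == a
    if (any(sel)) under[, sel] <- draw_mat_list[[a]][, sel, drop = FALSE]
  }
  rowMeans(under - (total - under) / (K - 1))
}

#' Posterior distribution of the ITR effect of a rule
#'
#' For each posterior draw of the BART fit, computes the model-based ITR
#' effect of the rule: the predicted outcome under the recommended arm minus
#' the predicted outcome averaged over the remaining arms, averaged over
#' subjects. Summarized by the posterior mean and an equal-tail 95%
#' credible interval.
#'
#' @param object a fitted `itr_bart` object.
#' @param X covariate data frame on which to evaluate the rule.
#' @param rule anything accepted by [decide()] (e.g. the fitted object
#'   itself, or a [fixed_rule]).
#' @param level credible level (default 0.95, equal tails).
#' @return List with `mean`, `ci` (length 2) and the per-draw effects
#'   `draws`.
#' @export
posterior_itr_effect <- function(object, X, rule, level = 0.95) {
  stopifnot(inherits(object, "itr_bart"))
  if (inherits(X, "trial_data")) X <- X$X
  arms <- decide(rule, X)
  dr <- posterior_arm_draws(object, X)
  eff <- draw_effect(dr, arms)
  a <- (1 - level) / 2
  list(mean = mean(eff),
       ci = unname(stats::quantile(eff, c(a, 1 - a))),
       draws = eff)
}

#' Optimized-ITR reference: per-draw best-case effect distribution
#'
#' An idealized, non-achievable reference rule: within each MCMC draw every
#' subject is assigned to the arm maximizing that draw's predicted outcome,
#' so the rule varies across draws. Its per-draw effect bounds the BART ITR's
#' effect from above in every draw.
#'
#' @inheritParams posterior_itr_effect
#' @return List with `mean`, `ci`, per-draw effects `draws`, and
#'   `reference = "non-achievable"`.
#' @export
optimized_itr_reference <- function(object, X, level = 0.95) {
  stopifnot(inherits(object, "itr_bart"))
  if (inherits(X, "trial_data")) X <- X$X
  dr <- posterior_arm_draws(object, X)
  K <- object$K
  S <- nrow(dr[[1]])
  n <- ncol(dr[[1]])
  best <- dr[[1]]
  total <- dr[[1]]
  for (a in 2:K) {
    best <- pmax(best, dr[[a]])
    total <- total + dr[[a]]
  }
  eff <- rowMeans(best - (total - best) / (K - 1))
  a <- (1 - level) / 2
  list(mean = mean(eff),
       ci = unname(stats::quantile(eff, c(a, 1 - a))),
       draws = eff, reference = "non-achievable")
}
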