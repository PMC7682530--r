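# Adaptive contrast weighted learning: per-arm conditional means are
# estimated with a flexible outcome regression and corrected with the
# doubly-robust AIPW augmentation; per-subject arm-effect orderings give the
# adaptive contrasts C1 (best minus second best) and C2 (best minus worst),
# and the rule is a weighted classification tree predicting each subject's
# estimated best arm with contrast weights.

#' Doubly-robust per-arm conditional mean estimates
#'
#' Fits a regression of the outcome on covariates within each arm and forms
#' subject-level AIPW pseudo-estimates
#' \deqn{\hat\mu_a(X_i) = \tilde\mu_a(X_i) +
#'   \frac{I(A_i = a)}{\pi_a(X_i)}\,(Y_i - \tilde\mu_a(X_i))}
#' so a misspecified outcome model is corrected by the inverse-probability
#' weighted residual on the arm actually received.
#'
#' @param data a [trial_data] object.
#' @param regressor `"xgboost"` (gradient-boosted trees; default) or
#'   `"linear"` (per-arm least squares on the dummy-coded covariates).
#' @param nrounds,max_depth,eta boosting parameters for the default
#'   regressor.
#' @return List with `mu_hat` (`n x K` AIPW pseudo-estimates), `mu_tilde`
#'   (`n x K` regression predictions) and the fitted per-arm models.
#' @export
fit_arm_means <- function(data, regressor = c("xgboost", "linear"),
                          nrounds = 500L, max_depth = 3L, eta = 0.05) {
  regressor <- match.arg(regressor)
  stopifnot(inherits(data, "trial_data"))
  enc <- make_encoder(data$X)
  M <- dlearn_matrix(enc, data$X)[, -1, drop = FALSE]
  K <- data$K
  n <- data$n
  mu_tilde <- matrix(NA_real_, n, K)
  models <- vector("list", K)
  for (a in seq_len(K)) {
    sel <- data$A == a
    if (!any(sel)) stop(sprintf("arm %d is empty", a))
    if (regressor == "xgboost") {
      fit <- xgboost::xgboost(
        x = M[sel, , drop = FALSE], y = data$Y[sel],
        nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
        objective = "reg:squarederror", nthreads = 1L, verbosity = 0)
      mu_tilde[, a] <- stats::predict(fit, M)
    } else {
      fit <- stats::lm.fit(cbind(1, M[sel, , drop = FALSE]), data$Y[sel])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      mu_tilde[, a] <- drop(cbind(1, M) %*% cf)
    }
    models[[a]] <- fit
  }
  aug <- (outer(data$A, seq_len(K), "==") / data$propensity) *
    (data$Y - mu_tilde)
  list(mu_hat = mu_tilde + aug, mu_tilde = mu_tilde, models = models,
       regressor = regressor)
}

#' Treatment-effect orderings and adaptive contrasts
#'
#' For each subject orders the estimated arm means
#' \eqn{\hat\mu_{(1)} \le \dots \le \hat\mu_{(K)}}, records the ordering
#' labels \eqn{l_a} (ties broken by arm index, with the best label the
#' smallest tied arm), and forms the contrasts
#' \eqn{C_1 = \hat\mu_{(K)} - \hat\mu_{(K-1)}} and
#' \eqn{C_2 = \hat\mu_{(K)} - \hat\mu_{(1)}}.
#'
#' @param mu `n x K` matrix of per-subject arm mean estimates.
#' @return List with `l` (`n x K` ordering labels, last column the best
#'   arm), `best` (= `l[, K]`), `C1`, `C2`.
#' @export
contrast_set <- function(mu) {
  mu <- as.matrix(mu)
  if (any(!is.finite(mu))) {
    bad <- which(rowSums(!is.finite(mu)) > 0)[1]
    stop(sprintf("non-finite arm mean estimate for subject %d", bad))
  }
  n <- nrow(mu); K <- ncol(mu)
  if (K < 2) stop("need at least two arms")
  best <- max.col(mu, ties.method = "first")
  l <- t(vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(K), best[i])
    others <- others[order(mu[i, others], others)]
    c(others, best[i])
  }, integer(K)))
  mx <- mu[cbind(seq_len(n), best)]
  C1 <- mx - mu[cbind(seq_len(n), l[, K - 1L])]
  C2 <- mx - mu[cbind(seq_len(n), l[, 1L])]
  list(l = l, best = best, C1 = C1, C2 = C2)
}

itr_acwl_fit <- function(data, contrast = c("C2", "C1"),
                         regressor = c("xgboost", "linear"),
                         nrounds = 500L, max_depth = 3L, eta = 0.05,
                         cp = 1e-4, xval = 5L, minbucket = NULL) {
  contrast <- match.arg(contrast)
  regressor <- match.arg(regressor)
  am <- fit_arm_means(data, regressor, nrounds, max_depth, eta)
  cs <- contrast_set(am$mu_hat)
  w <- if (contrast == "C2") cs$C2 else cs$C1
  if (is.null(minbucket)) minbucket <- max(5L, round(data$n / 400))
  df <- data.frame(.label = factor(cs$best, levels = seq_len(data$K)),
                   data$X)
  if (all(w < 1e-10)) {  # numerically zero contrasts: no signal to classify
    warning("all contrast weights are zero; returning the majority label")
    maj <- as.integer(names(which.max(table(cs$best))))
    tree <- NULL
  } else {
    tree <- rpart::rpart(
      .label ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(cp = cp, xval = xval,
                                     minbucket = minbucket))
    # cost-complexity pruning, 1-SE rule
    ct <- tree$cptable
    if (nrow(ct) > 1) {
      i0 <- which.min(ct[, "xerror"])
      thr <- ct[i0, "xerror"] + ct[i0, "xstd"]
      cp_1se <- ct[min(which(ct[, "xerror"] <= thr)), "CP"]
      tree <- rpart::prune(tree, cp = cp_1se)
    }
    maj <- NULL
  }
  structure(
    list(method = "acwl", contrast = contrast, tree = tree, majority = maj,
         contrasts = cs[c("best", "C1", "C2")], regressor = regressor,
         K = data$K),
    class = c("itr_acwl", "itr"))
}

#' @export
predict.itr_acwl <- function(object, newdata, ...) {
  if (inherits(newdata, "trial_data")) newdata <- newdata$X
  if (is.null(object$tree)) return(rep(object$majority, nrow(newdata)))
  cl <- stats::predict(object$tree, newdata = as.data.frame(newdata),
                       type = "class")
  as.integer(as.character(cl))
}
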