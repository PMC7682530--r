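# Direct learning: for every unordered arm pair {a, i} a linear decision
# function f_ai is fit by weighted least squares on the transformed response
# 2*Y*A_ai (A_ai = +1 on arm a, -1 on arm i), weighted by the inverse arm
# propensity; the multi-arm rule is the argmax over arms of the summed
# pairwise functions, using f_ia = -f_ai.

# Linear model matrix (intercept + dummy-coded covariates), shared encoder.
dlearn_matrix <- function(enc, X) {
  X <- as.data.frame(X)
  mains <- lapply(seq_along(enc$names), function(j)
    encode_covariate(enc$cols[[j]], X[[enc$names[j]]], enc$names[j]))
  cbind("(Intercept)" = rep(1, nrow(X)), do.call(cbind, mains))
}

#' Pairwise direct-learning decision function
#'
#' Fits the linear decision function between arms `a` and `i` by weighted
#' least squares of `2 * Y * A_ai` on the covariates (with `A_ai = +1` for
#' arm `a`, `-1` for arm `i`), weighting each subject by the inverse of the
#' probability of the arm received. Optionally l1-penalized with
#' cross-validated lambda.
#'
#' @param data a [trial_data] object.
#' @param arms length-2 integer vector `c(a, i)`.
#' @param penalty `"none"` (default: ordinary weighted least squares) or
#'   `"l1"` (lasso via cross-validation).
#' @param cv_folds folds for the l1 path.
#' @return Named numeric coefficient vector (including intercept).
#' @export
fit_pair <- function(data, arms, penalty = c("none", "l1"), cv_folds = 5L) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(data, "trial_data"), length(arms) == 2L)
  a <- as.integer(arms[1]); i <- as.integer(arms[2])
  sel <- data$A %in% c(a, i)
  if (!any(data$A == a) || !any(data$A == i))
    stop("both arms of the pair must be present")
  enc <- make_encoder(data$X)
  M <- dlearn_matrix(enc, data$X[sel, , drop = FALSE])
  Aai <- ifelse(data$A[sel] == a, 1, -1)
  z <- 2 * data$Y[sel] * Aai
  w <- 1 / observed_propensity(data)[sel]
  if (penalty == "none") {
    fit <- stats::lm.wfit(M, z, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  } else {
    cv <- glmnet::cv.glmnet(M[, -1, drop = FALSE], z, weights = w,
                            nfolds = cv_folds)
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    beta <- stats::setNames(cf, colnames(M))
  }
  beta
}

itr_dlearn_fit <- function(data, penalty = c("none", "l1"), cv_folds = 5L) {
  penalty <- match.arg(penalty)
  K <- data$K
  enc <- make_encoder(data$X)
  pairs <- utils::combn(K, 2)
  coefs <- apply(pairs, 2, function(pr)
    fit_pair(data, pr, penalty = penalty, cv_folds = cv_folds))
  colnames(coefs) <- apply(pairs, 2, paste, collapse = "v")
  structure(
    list(method = "dlearn", coefs = coefs, pairs = pairs, penalty = penalty,
         encoder = enc, K = K),
    class = c("itr_dlearn", "itr"))
}

#' @export
predict.itr_dlearn <- function(object, newdata,
                               type = c("arm", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "trial_data")) newdata <- newdata$X
  M <- dlearn_matrix(object$encoder, newdata)
  K <- object$K
  score <- matrix(0, nrow(M), K)
  for (col in seq_len(ncol(object$pairs))) {
    a <- object$pairs[1, col]; i <- object$pairs[2, col]
    f <- drop(M %*% object$coefs[, col])
    score[, a] <- score[, a] + f     # f_ai
    score[, i] <- score[, i] - f     # f_ia = -f_ai
  }
  if (type == "score") return(score)
  argmax_arm(score)
}

#' @export
coef.itr_dlearn <- function(object, ...) object$coefs
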