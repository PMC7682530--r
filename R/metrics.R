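#' Inverse-probability-weighted value of a rule
#'
#' Plug-in IPW estimator of the value function
#' \deqn{\hat V(D) = \frac1n \sum_i \frac{I(A_i = D(X_i))}{P(A_i|X_i)} Y_i}
#' Under uniform three-arm randomization the weight is 3 for subjects whose
#' observed arm agrees with the rule. The Hajek variant divides by the sum of
#' the matched weights instead of `n`.
#'
#' @param data a [trial_data] object.
#' @param rule anything accepted by [decide()].
#' @param hajek logical; use the Hajek (self-normalized) form.
#' @return Estimated value (scalar).
#' @export
ipw_value <- function(data, rule, hajek = FALSE) {
  stopifnot(inherits(data, "trial_data"))
  pr <- observed_propensity(data)
  if (any(pr <= 0)) stop("positivity violated: zero propensity")
  arms <- decide(rule, data$X)
  agree <- data$A == arms
  contrib <- ifelse(agree, data$Y / pr, 0)
  if (hajek) {
    w <- ifelse(agree, 1 / pr, 0)
    if (sum(w) == 0) return(0)
    sum(contrib) / sum(w)
  } else {
    sum(contrib) / data$n
  }
}

#' Misclassification rate against a reference assignment
#'
#' Fraction of subjects whose predicted arm differs from the reference
#' (typically the true optimal arm of a simulation setting).
#'
#' @param predicted,truth integer arm vectors of equal length.
#' @return Rate in `[0, 1]`.
#' @export
misclassification <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  mean(as.integer(predicted) != as.integer(truth))
}

#' ITR effect of a rule on an outcome
#'
#' Difference in the mean outcome between subjects whose observed arm agrees
#' with the rule (concordant) and those whose arm differs (discordant):
#' \deqn{\hat\delta(D) = \bar Y_{A = D(X)} - \bar Y_{A \neq D(X)}}
#' For a [fixed_rule] this compares one arm against the pooled remaining
#' arms. If either group is empty the effect is undefined and `NA` is
#' returned with a warning.
#'
#' @param data a [trial_data] object.
#' @param rule anything accepted by [decide()].
#' @param outcome optional replacement outcome vector (defaults to
#'   `data$Y`); lets the same cohort be scored on benefit, risk and utility.
#' @return Scalar effect, or `NA_real_` if a group is empty.
#' @export
itr_effect <- function(data, rule, outcome = NULL) {
  stopifnot(inherits(data, "trial_data"))
  y <- if (is.null(outcome)) data$Y else as.numeric(outcome)
  stopifnot(length(y) == data$n)
  arms <- decide(rule, data$X)
  agree <- data$A == arms
  if (!any(agree) || all(agree)) {
    warning("ITR effect undefined: empty concordant or discordant group")
    return(NA_real_)
  }
  mean(y[agree]) - mean(y[!agree])
}

#' Benefit-risk utility
#'
#' \deqn{U = G - b \tilde R} where `G` is the benefit (units of blood
#' collected over two years), `Rtilde` the number of low-hemoglobin
#' deferrals, and `b >= 0` the trade-off parameter (equivalent benefit loss
#' per extra deferral).
#'
#' @param G benefit vector.
#' @param Rtilde deferral count vector (nonnegative).
#' @param b trade-off parameter (nonnegative scalar).
#' @return Utility vector.
#' @export
utility <- function(G, Rtilde, b) {
  if (length(b) != 1L || b < 0) stop("b must be a single nonnegative number")
  if (any(Rtilde < 0)) stop("deferral counts must be nonnegative")
  G - b * Rtilde
}

#' Variance-stabilizing transform of the deferral rate
#'
#' Maps a deferral rate `R` in `[0, 1]` to `asin(sqrt(1 - R))`: the arcsine
#' square-root transform of "1 - deferral rate", so that a larger transformed
#' outcome is better and maximizing it minimizes the deferral rate
#' (the transform is strictly decreasing in `R`).
#'
#' @param R deferral rate(s) in `[0, 1]`.
#' @return Transformed value(s) in `[0, pi/2]`.
#' @export
deferral_target_transform <- function(R) {
  if (any(R < 0 | R > 1)) stop("deferral rates must lie in [0, 1]")
  asin(sqrt(1 - R))
}

#' Proportions of subjects assigned to each arm by a rule
#'
#' @param rule anything accepted by [decide()].
#' @param X covariate data frame (or [trial_data]).
#' @param K number of arms.
#' @return Numeric vector of length `K` summing to 1.
#' @export
assignment_proportions <- function(rule, X, K = 3L) {
  if (inherits(X, "trial_data")) { K <- X$K; X <- X$X }
  if (nrow(X) == 0L) stop("empty covariate table")
  arms <- decide(rule, X)
  tabulate(arms, K) / length(arms)
}
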