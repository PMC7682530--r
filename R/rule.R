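#' Apply a treatment rule to covariates
#'
#' Generic dispatcher turning any supported rule representation into per-row
#' arm assignments. Supported representations: fitted `itr` objects (via
#' their `predict` method), [fixed_rule] objects, plain functions of the
#' covariate data frame, and precomputed integer assignment vectors.
#'
#' @param rule the rule.
#' @param X covariate data frame (or a [trial_data] object, whose `$X` is
#'   used).
#' @param ... passed to methods.
#' @return Integer vector of arms, one per row of `X`.
#' @export
decide <- function(rule, X, ...) UseMethod("decide")

#' @export
decide.itr <- function(rule, X, ...) {
  if (inherits(X, "trial_data")) X <- X$X
  predict(rule, X, ...)
}

#' @export
decide.function <- function(rule, X, ...) {
  if (inherits(X, "trial_data")) X <- X$X
  arms <- as.integer(rule(X))
  stopifnot(length(arms) == nrow(X))
  arms
}

#' @export
decide.default <- function(rule, X, ...) {
  if (inherits(X, "trial_data")) X <- X$X
  arms <- as.integer(rule)
  if (length(arms) == 1L) arms <- rep(arms, nrow(X))
  if (length(arms) != nrow(X))
    stop("assignment vector length does not match the data")
  arms
}

#' Non-personalized (fixed) rule
#'
#' The rule that assigns every subject to the same arm, used as the
#' one-size-fits-all baseline.
#'
#' @param arm arm index in `1..K`.
#' @param K number of arms (used only for validation).
#' @return An object of class `fixed_rule`.
#' @export
fixed_rule <- function(arm, K = 3L) {
  arm <- as.integer(arm)
  if (length(arm) != 1L || is.na(arm) || arm < 1L || arm > K)
    stop("arm must be a single integer in 1..K")
  structure(list(arm = arm, K = as.integer(K)), class = "fixed_rule")
}

#' @export
decide.fixed_rule <- function(rule, X, ...) {
  if (inherits(X, "trial_data")) X <- X$X
  rep(rule$arm, nrow(X))
}

#' @export
print.fixed_rule <- function(x, ...) {
  cat(sprintf("Fixed rule: assign every subject to arm %d (of %d)\n",
              x$arm, x$K))
  invisible(x)
}

# Shared tie-break: argmax over rows, ties to the smallest arm index (for the
# donor application arm 1 is the longest, safest inter-donation interval).
argmax_arm <- function(M) max.col(M, ties.method = "first")
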