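# Small in-code fixtures shared across test files.

# Tiny three-arm trial with hand-set values.
toy_trial <- function() {
  trial_data(
    X = data.frame(x1 = c(0.1, -0.4, 0.3, 0.9, -0.2, 0.5)),
    A = c(1, 1, 2, 2, 3, 3),
    Y = 1:6,
    K = 3, propensity = 1 / 3)
}

# Random three-arm trial with a linear signal, all-numeric covariates.
random_trial <- function(n = 200, p = 3, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * p, -1, 1), n, p))
  names(X) <- paste0("x", seq_len(p))
  A <- sample.int(3, n, replace = TRUE)
  Y <- X[[1]] + (A == 2) * X[[p]] + rnorm(n, 0, 0.5)
  trial_data(X, A, Y, K = 3, propensity = 1 / 3)
}

# Independent loop-based IPW value oracle: each subject's contribution is
# derived from scratch, then totalled.
ipw_loop <- function(data, arms) {
  contrib <- numeric(data$n)
  for (i in seq_len(data$n)) {
    if (data$A[i] == arms[i])
      contrib[i] <- data$Y[i] / data$propensity[i, data$A[i]]
  }
  sum(contrib) / data$n
}
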