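#' Benchmark simulation settings for three-arm ITR estimation
#'
#' Six data-generating processes with known true optimal rules, spanning
#' tree-type, linear and nonlinear arm-covariate interactions plus a setting
#' with discrete covariates and one with a trivial (single best arm) truth.
#' The outcome model is
#' \deqn{Y = m(X) + 0.5\,\Delta_{A}(X) + \epsilon,\qquad \epsilon \sim N(0,1)}
#' with main effect \eqn{m(X) = 1 + 0.5 X_4 + 0.3 X_5}, three arms sampled
#' uniformly, and the interaction functions \eqn{\Delta_a} listed below
#' (\eqn{\Delta_3 \equiv 0} throughout):
#'
#' \describe{
#'   \item{1 (tree)}{\eqn{\Delta_1 = 4 I(X_1 > 0.5) - 2};
#'     \eqn{\Delta_2 = 2 I(X_2 \ge 0.5) I(X_3 < 0.25) - 1}}
#'   \item{2 (linear)}{\eqn{\Delta_1 = 3X_1 - 2X_2};
#'     \eqn{\Delta_2 = 5X_3 - X_4 + X_5 - 1}}
#'   \item{3 (nonlinear)}{\eqn{\Delta_1 = 3X_1^2 - e^{X_2}};
#'     \eqn{\Delta_2 = X_3 X_4}}
#'   \item{4 (nonlinear)}{\eqn{\Delta_1 = 3X_1^2 - e^{X_2}};
#'     \eqn{\Delta_2 = X_3^3}}
#'   \item{5 (discrete)}{\eqn{X_1} discrete uniform on \{1..5\} (categorical),
#'     \eqn{X_2 \sim} Bernoulli(0.5);
#'     \eqn{\Delta_1 = 2\{I(X_1 = 1) + I(X_1 = 2)\}X_2 - 1};
#'     \eqn{\Delta_2 = 5 I(X_1 = 5) X_3 - 2}}
#'   \item{6 (trivial)}{\eqn{\Delta_1 = I(X_1 > 0.5) + 2};
#'     \eqn{\Delta_2 = 2 I(X_2 \ge 0.5) I(X_3 < 0.25) - 3}; arm 1 is optimal
#'     for every subject}
#' }
#'
#' Continuous covariates are independent U(-1, 1) unless stated otherwise.
#'
#' @param setting_id integer in 1..6.
#' @return An object of class `sim_setting`: list with the setting id, the
#'   main-effect function `m`, the list `delta` of three interaction
#'   functions (each taking the covariate data frame), the covariate sampler
#'   `draw_X(n)`, noise SD `sigma` and `K`.
#' @export
sim_setting <- function(setting_id) {
  setting_id <- as.integer(setting_id)
  if (length(setting_id) != 1L || is.na(setting_id) ||
      setting_id < 1L || setting_id > 6L)
    stop("setting_id must be a single integer in 1..6")

  draw_cont <- function(n) {
    X <- as.data.frame(matrix(stats::runif(5 * n, -1, 1), n, 5))
    names(X) <- paste0("X", 1:5)
    X
  }
  draw_disc <- function(n) {
    data.frame(
      X1 = factor(sample(1:5, n, replace = TRUE), levels = 1:5),
      X2 = stats::rbinom(n, 1, 0.5),
      X3 = stats::runif(n, -1, 1),
      X4 = stats::runif(n, -1, 1),
      X5 = stats::runif(n, -1, 1))
  }
  x1num <- function(X) if (is.factor(X$X1)) as.numeric(as.character(X$X1)) else X$X1

  d1 <- switch(setting_id,
    function(X) 4 * (X$X1 > 0.5) - 2,
    function(X) 3 * X$X1 - 2 * X$X2,
    function(X) 3 * X$X1^2 - exp(X$X2),
    function(X) 3 * X$X1^2 - exp(X$X2),
    function(X) { x1 <- x1num(X); 2 * ((x1 == 1) + (x1 == 2)) * X$X2 - 1 },
    function(X) (X$X1 > 0.5) + 2)
  d2 <- switch(setting_id,
    function(X) 2 * (X$X2 >= 0.5) * (X$X3 < 0.25) - 1,
    function(X) 5 * X$X3 - X$X4 + X$X5 - 1,
    function(X) X$X3 * X$X4,
    function(X) X$X3^3,
    function(X) { x1 <- x1num(X); 5 * (x1 == 5) * X$X3 - 2 },
    function(X) 2 * (X$X2 >= 0.5) * (X$X3 < 0.25) - 3)
  d3 <- function(X) rep(0, nrow(X))

  structure(
    list(setting_id = setting_id,
         m = function(X) 1 + 0.5 * X$X4 + 0.3 * X$X5,
         delta = list(d1, d2, d3),
         draw_X = if (setting_id == 5L) draw_disc else draw_cont,
         sigma = 1, K = 3L),
    class = "sim_setting")
}

# Interaction values as an n x K matrix.
delta_matrix <- function(setting, X) {
  vals <- lapply(setting$delta, function(f) f(X))
  matrix(unlist(vals), nrow = nrow(X), ncol = length(vals))
}

#' True optimal arm under a simulation setting
#'
#' Argmax over arms of the interaction functions, ties broken toward the
#' smallest arm index.
#'
#' @param setting a [sim_setting] object (or a setting id).
#' @param X covariate data frame drawn from the setting.
#' @return Integer vector of optimal arms.
#' @export
true_optimal_arm <- function(setting, X) {
  if (!inherits(setting, "sim_setting")) setting <- sim_setting(setting)
  D <- delta_matrix(setting, X)
  max.col(D, ties.method = "first")
}

#' Generate a trial dataset from a simulation setting
#'
#' @param setting_id integer 1..6 (or a [sim_setting] object).
#' @param n sample size (at least the number of arms).
#' @param seed integer seed; identical seeds reproduce identical datasets.
#' @return A [trial_data] object with the true optimal arms attached in
#'   `$optimal`.
#' @export
sim_trial <- function(setting_id, n, seed = NULL) {
  setting <- if (inherits(setting_id, "sim_setting")) setting_id
             else sim_setting(setting_id)
  n <- as.integer(n)
  if (n < setting$K) stop("n must be at least the number of arms")
  if (!is.null(seed)) set.seed(seed)
  X <- setting$draw_X(n)
  A <- sample.int(setting$K, n, replace = TRUE)
  D <- delta_matrix(setting, X)
  Y <- setting$m(X) + 0.5 * D[cbind(seq_len(n), A)] +
    stats::rnorm(n, 0, setting$sigma)
  trial_data(X, A, Y, K = setting$K, propensity = 1 / setting$K,
             optimal = max.col(D, ties.method = "first"))
}

#' Monte-Carlo oracle value of a rule under a simulation setting
#'
#' Evaluates \eqn{E\{m(X) + 0.5\,\Delta_{D(X)}(X)\}} over fresh covariate
#' draws: the exact population value of the rule (no outcome noise), used as
#' a diagnostic alongside the IPW estimator.
#'
#' @param setting_id setting id or [sim_setting].
#' @param rule anything accepted by [decide()]: a fitted `itr` object, a
#'   [fixed_rule], or a function mapping a covariate data frame to arms.
#' @param n_mc number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return Numeric value with the Monte-Carlo standard error in attribute
#'   `"se"`.
#' @export
oracle_value <- function(setting_id, rule, n_mc = 1e5, seed = NULL) {
  setting <- if (inherits(setting_id, "sim_setting")) setting_id
             else sim_setting(setting_id)
  if (!is.null(seed)) set.seed(seed)
  X <- setting$draw_X(n_mc)
  arms <- decide(rule, X)
  D <- delta_matrix(setting, X)
  v <- setting$m(X) + 0.5 * D[cbind(seq_len(n_mc), arms)]
  structure(mean(v), se = stats::sd(v) / sqrt(n_mc))
}
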