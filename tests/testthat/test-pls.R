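test_that("penalty limits bracket the group-lasso path", {
  d <- random_trial(300, p = 2, seed = 2)
  des <- build_design(d$X, d$A, d$K)
  pen <- vapply(des$group_info, function(g) g$penalized, logical(1))
  # enormous lambda: every penalized group zero
  hi <- itrlearn:::grplasso_path(des$matrix, d$Y, des$group, pen,
                                 lambda = 1e6)
  expect_true(all(abs(hi$beta[-1, 1]) < 1e-12))
  # lambda = 0 recovers ordinary least squares on the same basis
  lo <- itrlearn:::grplasso_path(des$matrix, d$Y, des$group, pen,
                                 lambda = 0, tol = 1e-13, maxit = 50000L)
  ols <- stats::lm.fit(des$matrix, d$Y)$coefficients
  fitted_pls <- lo$b0[1] + drop(des$matrix %*% lo$beta[, 1])
  fitted_ols <- drop(des$matrix %*% ifelse(is.na(ols), 0, ols))
  expect_equal(fitted_pls, fitted_ols, tolerance = 1e-6)
})

test_that("group-lasso coefficients are zero or retained jointly", {
  d <- random_trial(500, p = 4, seed = 3)
  fit <- itr(d, "pls-gl", seed = 5)
  norms <- itrlearn:::pls_group_norms(fit)
  for (g in seq_along(norms)) {
    cols <- fit$beta[fit$design$group == g]
    if (norms[g] == 0) expect_true(all(cols == 0))
  }
  expect_s3_class(fit, "itr_pls")
})

test_that("strong hierarchy holds on every HGL fit", {
  for (seed in 1:5) {
    d <- random_trial(400, p = 3, seed = seed)
    fit <- itr(d, "pls-hgl", seed = seed)
    expect_true(itrlearn:::strong_hierarchy_ok(fit))
  }
})

test_that("a strong single interaction is found and drives the rule", {
  # setting-2-like truth with one active interaction group (arm 2 x x1)
  set.seed(11)
  n <- 4000
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  A <- sample.int(3, n, TRUE)
  Y <- 0.5 * X$x2 + (A == 2) * 3 * X$x1 + rnorm(n)
  d <- trial_data(X, A, Y, K = 3, propensity = 1 / 3)
  fit <- itr(d, "pls-gl", seed = 1)
  sel <- itrlearn:::pls_interactions_selected(fit)
  expect_true(sel[["x1"]])
  # predicted best arm: 2 where x1 > 0, not 2 where x1 < 0
  arms <- decide(fit, data.frame(x1 = c(0.8, -0.8), x2 = c(0, 0)))
  expect_equal(arms[1], 2L)
  expect_false(arms[2] == 2L)
})

test_that("selection frequencies are percentages over fits", {
  fits <- lapply(1:3, function(s) itr(random_trial(300, seed = s),
                                      "pls-gl", seed = s))
  sf <- selection_frequency(fits)
  expect_true(all(sf$selected_pct >= 0 & sf$selected_pct <= 100))
  expect_setequal(sf$covariate, c("x1", "x2", "x3"))
  expect_error(selection_frequency(fits[1]), "2")
})

test_that("misclassification shrinks with the training size on linear truth", {
  test <- sim_trial(2, 4000, seed = 99)
  mc <- vapply(c(500, 2000, 20000), function(n) {
    mean(vapply(1:2, function(r) {
      f <- itr(sim_trial(2, n, seed = 1000 * r + n), "pls-gl", seed = r)
      misclassification(decide(f, test$X), test$optimal)
    }, numeric(1)))
  }, numeric(1))
  expect_true(mc[1] > mc[3])
  expect_true(mc[2] >= mc[3] - 0.005)
})
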