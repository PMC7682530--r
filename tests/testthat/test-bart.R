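test_that("a pure-noise outcome gives near-equal posterior arm means", {
  set.seed(1)
  n <- 600
  X <- data.frame(x = runif(n, -1, 1))
  A <- sample.int(3, n, TRUE)
  d <- trial_data(X, A, rnorm(n), K = 3, propensity = 1 / 3)
  fit <- itr(d, "bart", seed = 2, ntree = 50, nskip = 50, ndpost = 100)
  mu <- predict(fit, X, type = "mean")
  expect_lt(max(abs(mu[, 1] - mu[, 2])), 0.5)
  expect_lt(max(abs(mu[, 1] - mu[, 3])), 0.5)
})

test_that("a strong arm effect is detected for essentially all subjects", {
  set.seed(2)
  n <- 2000
  X <- data.frame(x = runif(n, -1, 1))
  A <- sample.int(3, n, TRUE)
  Y <- 2 * (A == 2) + rnorm(n)
  d <- trial_data(X, A, Y, K = 3, propensity = 1 / 3)
  fit <- itr(d, "bart", seed = 3, ntree = 50, nskip = 50, ndpost = 100)
  arms <- decide(fit, X)
  expect_gt(mean(arms == 2L), 0.99)
})

test_that("the posterior mean tracks the truth in the linear setting", {
  d <- sim_trial(2, 20000, seed = 31)
  st <- sim_setting(2)
  fit <- itr(d, "bart", seed = 4, ntree = 200, nskip = 100, ndpost = 100)
  mu <- predict(fit, d$X, type = "mean")
  D <- itrlearn:::delta_matrix(st, d$X)
  truth <- st$m(d$X) + 0.5 * D
  rmse <- sqrt(mean((mu - truth)^2))
  expect_lt(rmse, 0.15)
  # and the rule's accuracy sits at the published level for this setting
  te <- sim_trial(2, 5000, seed = 32)
  expect_lt(misclassification(decide(fit, te$X), te$optimal),
            0.056 + 3 * 0.004)
})

test_that("the optimized-ITR reference dominates the BART rule draw by draw", {
  d <- sim_trial(1, 1500, seed = 41)
  fit <- itr(d, "bart", seed = 5, ntree = 50, nskip = 50, ndpost = 80)
  eff_rule <- posterior_itr_effect(fit, d$X, fit)
  eff_opt <- optimized_itr_reference(fit, d$X)
  expect_true(all(eff_opt$draws >= eff_rule$draws - 1e-12))
  expect_identical(eff_opt$reference, "non-achievable")
  # fixed rules are also dominated
  eff_fixed <- posterior_itr_effect(fit, d$X, fixed_rule(1))
  expect_true(all(eff_opt$draws >= eff_fixed$draws - 1e-12))
})

test_that("a single posterior draw collapses the credible interval", {
  d <- random_trial(300, seed = 6)
  fit <- itr(d, "bart", seed = 6, ntree = 20, nskip = 20, ndpost = 1)
  eff <- posterior_itr_effect(fit, d$X, fixed_rule(2))
  expect_equal(eff$ci[1], eff$mean)
  expect_equal(eff$ci[2], eff$mean)
  # and the optimized reference coincides with the fitted rule's effect
  eff_rule <- posterior_itr_effect(fit, d$X, fit)
  eff_opt <- optimized_itr_reference(fit, d$X)
  expect_equal(eff_opt$mean, eff_rule$mean)
})

test_that("the rule survives arm-label permutation on the trivial setting", {
  d <- sim_trial(6, 2000, seed = 51)
  fit <- itr(d, "bart", seed = 7, ntree = 50, nskip = 50, ndpost = 100)
  perm <- c(2L, 3L, 1L)
  d2 <- trial_data(d$X, perm[d$A], d$Y, K = 3, propensity = 1 / 3)
  fit2 <- itr(d2, "bart", seed = 8, ntree = 50, nskip = 50, ndpost = 100)
  agree <- mean(perm[decide(fit, d$X)] == decide(fit2, d$X))
  expect_gt(agree, 0.99)
})

test_that("non-finite outcomes are rejected", {
  d <- random_trial(100, seed = 7)
  d$Y[1] <- NaN
  expect_error(itr(d, "bart", ntree = 10, nskip = 5, ndpost = 5), "finite")
})
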