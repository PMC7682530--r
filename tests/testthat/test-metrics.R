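test_that("IPW value reproduces hand computations on the toy trial", {
  toy <- toy_trial()
  # rule == arm 2 matches subjects 3 and 4: (1/6) * 3 * (3 + 4) = 3.5
  expect_equal(ipw_value(toy, fixed_rule(2)), 3.5)
  # a rule agreeing with nobody scores 0
  never <- c(2, 2, 3, 3, 1, 1)
  expect_equal(ipw_value(toy, never), 0)
  # constant outcome, uniform arms: estimator = 3 * n_a / n
  toy1 <- trial_data(toy$X, toy$A, rep(1, 6), K = 3, propensity = 1 / 3)
  expect_equal(ipw_value(toy1, fixed_rule(1)), 3 * 2 / 6)
})

test_that("IPW value equals the brute-force loop on small datasets", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:50, 1)
    X <- data.frame(x = rnorm(n))
    A <- c(1:3, sample.int(3, n - 3, TRUE))
    Y <- rnorm(n, 0, 3)
    d <- trial_data(X, A, Y, K = 3, propensity = 1 / 3)
    arms <- sample.int(3, n, TRUE)
    expect_equal(ipw_value(d, arms), ipw_loop(d, arms), tolerance = 0)
  }
})

test_that("Hajek variant self-normalizes", {
  toy <- toy_trial()
  expect_equal(ipw_value(toy, fixed_rule(2), hajek = TRUE), 3.5)  # (3+4)/2
  expect_equal(ipw_value(toy, c(2, 2, 3, 3, 1, 1), hajek = TRUE), 0)
})

test_that("misclassification counts disagreements", {
  expect_equal(misclassification(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(misclassification(c(1, 2), c(2, 1)), 1)
  expect_equal(misclassification(c(1, 2, 3, 1), c(1, 2, 1, 1)), 0.25)
  expect_error(misclassification(1:3, 1:4), "equal length")
})

test_that("ITR effect is the concordant-discordant mean difference", {
  d <- trial_data(data.frame(x = 1:4), c(1, 1, 2, 2), c(4, 2, 1, 1),
                  K = 2, propensity = 1 / 2)
  expect_equal(itr_effect(d, fixed_rule(1, 2)), 2)  # mean(4,2) - mean(1,1)
  expect_warning(eff <- itr_effect(d, d$A), "undefined")
  expect_true(is.na(eff))
})

test_that("fixed-rule ITR effect equals the arm-vs-rest mean contrast", {
  d <- random_trial(300, seed = 4)
  for (a in 1:3) {
    expected <- mean(d$Y[d$A == a]) - mean(d$Y[d$A != a])
    expect_equal(itr_effect(d, fixed_rule(a)), expected)
  }
})

test_that("utility and the deferral transform follow their definitions", {
  expect_equal(utility(10, 1, 2), 8)
  expect_equal(utility(10, 0, 5), 10)
  expect_equal(utility(10, 3, 0), 10)
  expect_error(utility(1, -1, 1), "nonnegative")
  expect_equal(deferral_target_transform(0), pi / 2)
  expect_equal(deferral_target_transform(1), 0)
  expect_equal(deferral_target_transform(0.75), pi / 6)
  expect_error(deferral_target_transform(1.2), "\\[0, 1\\]")
  # strictly decreasing in R
  r <- sort(runif(50))
  tv <- deferral_target_transform(r)
  expect_true(all(diff(tv) < 0))
})

test_that("assignment proportions sum to one and ignore row order", {
  X <- data.frame(x = 1:4)
  expect_equal(assignment_proportions(fixed_rule(1), X), c(1, 0, 0))
  expect_equal(assignment_proportions(c(1, 1, 2, 3), X),
               c(0.5, 0.25, 0.25))
  set.seed(1)
  arms <- sample.int(3, 100, TRUE)
  Xr <- data.frame(x = rnorm(100))
  perm <- sample(100)
  expect_equal(assignment_proportions(arms, Xr),
               assignment_proportions(arms[perm], Xr[perm, , drop = FALSE]))
  expect_equal(sum(assignment_proportions(arms, Xr)), 1)
})

test_that("fixed rules are validated and constant", {
  expect_error(fixed_rule(4, 3), "1..K")
  expect_equal(decide(fixed_rule(2), data.frame(x = 1:5)), rep(2L, 5))
  expect_equal(misclassification(decide(fixed_rule(2), data.frame(x = 1:5)),
                                 decide(fixed_rule(2), data.frame(x = 1:5))),
               0)
})

test_that("positivity is enforced", {
  expect_error(
    trial_data(data.frame(x = 1:3), 1:3, 1:3, K = 3,
               propensity = c(0, 0.5, 0.5)),
    "positivity")
})

test_that("IPW value is unbiased for a fixed rule", {
  # setting 2, fixed arm 2: compare the mean of the estimator across many
  # simulated trials against the population value from the oracle
  target <- as.numeric(oracle_value(2, fixed_rule(2), n_mc = 4e5, seed = 11))
  vals <- vapply(1:300, function(r)
    ipw_value(sim_trial(2, 2000, seed = 5000 + r), fixed_rule(2)),
    numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - target), 3 * se)
})
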