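test_that("interaction functions match the published setting definitions", {
  # setting 1: tree-type interactions
  s1 <- sim_setting(1)
  X <- data.frame(X1 = 0.6, X2 = 0, X3 = 0, X4 = 0, X5 = 0)
  expect_equal(s1$delta[[1]](X), 2)   # 4*I(0.6 > 0.5) - 2
  expect_equal(s1$delta[[2]](X), -1)
  expect_equal(s1$delta[[3]](X), 0)
  expect_equal(true_optimal_arm(s1, X), 1L)

  # setting 2: linear interactions
  s2 <- sim_setting(2)
  Xa <- data.frame(X1 = 1, X2 = 0, X3 = 0, X4 = 0, X5 = 0)
  Xb <- data.frame(X1 = 0, X2 = 0, X3 = 1, X4 = 0, X5 = 0)
  expect_equal(s2$delta[[1]](Xa), 3)
  expect_equal(s2$delta[[2]](Xa), -1)
  expect_equal(true_optimal_arm(s2, Xa), 1L)
  expect_equal(s2$delta[[2]](Xb), 4)
  expect_equal(true_optimal_arm(s2, Xb), 2L)

  # setting 6: arm 1 dominates everywhere
  s6 <- sim_setting(6)
  set.seed(1)
  X6 <- s6$draw_X(500)
  expect_true(all(true_optimal_arm(s6, X6) == 1L))
})

test_that("setting 5 uses a categorical, a binary and three continuous covariates", {
  s5 <- sim_setting(5)
  set.seed(2)
  X <- s5$draw_X(100)
  expect_s3_class(X$X1, "factor")
  expect_setequal(levels(X$X1), as.character(1:5))
  expect_true(all(X$X2 %in% 0:1))
  Xq <- data.frame(X1 = factor(5, levels = 1:5), X2 = 1, X3 = 0.8,
                   X4 = 0, X5 = 0)
  expect_equal(s5$delta[[2]](Xq), 2)   # 5*I(X1=5)*0.8 - 2
  expect_equal(s5$delta[[1]](Xq), -1)
})

test_that("generated outcomes follow m(X) + 0.5*Delta_A(X) + N(0,1)", {
  n <- 1e5
  for (s in c(1, 2, 5)) {
    st <- sim_setting(s)
    tr <- sim_trial(s, n, seed = 100 + s)
    D <- itrlearn:::delta_matrix(st, tr$X)
    resid <- tr$Y - st$m(tr$X) - 0.5 * D[cbind(seq_len(n), tr$A)]
    se_mean <- 1 / sqrt(n)
    expect_lt(abs(mean(resid)), 3 * se_mean)
    expect_lt(abs(var(resid) - 1), 3 * sqrt(2 / n))
  }
})

test_that("attached optimal arms agree with a brute-force argmax", {
  tr <- sim_trial(5, 1000, seed = 7)
  st <- sim_setting(5)
  brute <- integer(1000)
  for (i in seq_len(1000)) {
    vals <- vapply(1:3, function(a)
      st$delta[[a]](tr$X[i, , drop = FALSE]), numeric(1))
    brute[i] <- which(vals == max(vals))[1]  # smallest index on ties
  }
  expect_identical(tr$optimal, brute)
})

test_that("simulation draws are reproducible and validated", {
  expect_identical(sim_trial(3, 50, seed = 9), sim_trial(3, 50, seed = 9))
  expect_error(sim_setting(7), "1..6")
  expect_error(sim_trial(1, 2), "at least")
})

test_that("oracle value matches closed forms for the trivial setting", {
  # rule == arm 1: 1 + 0.5 * (P(X1 > 0.5) + 2) = 2.125
  v1 <- oracle_value(6, fixed_rule(1), n_mc = 2e5, seed = 3)
  expect_lt(abs(as.numeric(v1) - 2.125), 3 * attr(v1, "se"))
  # rule == arm 3: Delta_3 = 0, E m(X) = 1
  v3 <- oracle_value(6, fixed_rule(3), n_mc = 2e5, seed = 3)
  expect_lt(abs(as.numeric(v3) - 1), 3 * attr(v3, "se"))
  # determinism for identical rules and seed
  expect_identical(
    as.numeric(oracle_value(2, fixed_rule(2), 1e4, seed = 5)),
    as.numeric(oracle_value(2, fixed_rule(2), 1e4, seed = 5)))
})
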