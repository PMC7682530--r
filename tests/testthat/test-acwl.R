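test_that("AIPW pseudo-estimates follow the augmentation identity", {
  # 10-subject toy, linear regressor, hand-computed oracle
  set.seed(3)
  X <- data.frame(x = rnorm(10))
  A <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  Y <- rnorm(10)
  d <- trial_data(X, A, Y, K = 3, propensity = 1 / 3)
  am <- fit_arm_means(d, regressor = "linear")
  for (a in 1:3) {
    for (i in 1:10) {
      expected <- am$mu_tilde[i, a] +
        (A[i] == a) / (1 / 3) * (Y[i] - am$mu_tilde[i, a])
      expect_equal(am$mu_hat[i, a], expected)
    }
  }
  # subjects on a different arm carry no augmentation
  off <- A != 2
  expect_equal(am$mu_hat[off, 2], am$mu_tilde[off, 2])
  # the average pseudo-estimate is the IPW-augmented mean
  for (a in 1:3)
    expect_equal(mean(am$mu_hat[, a]),
                 mean(am$mu_tilde[, a]) +
                   mean((A == a) * 3 * (Y - am$mu_tilde[, a])))
})

test_that("contrast construction sorts, labels and bounds correctly", {
  cs <- contrast_set(matrix(c(1.0, 2.0, 0.5), 1))
  expect_equal(cs$l[1, ], c(3L, 1L, 2L))
  expect_equal(cs$best, 2L)
  expect_equal(cs$C1, 1.0)
  expect_equal(cs$C2, 1.5)
  cs_eq <- contrast_set(matrix(c(1, 1, 1), 1))
  expect_equal(cs_eq$C1, 0)
  expect_equal(cs_eq$C2, 0)
  cs2 <- contrast_set(matrix(c(0.3, 0.9), 1))
  expect_equal(cs2$C1, cs2$C2)
  expect_equal(cs2$C1, 0.6)
  expect_equal(cs2$best, 2L)
  expect_error(contrast_set(matrix(c(1, NA, 2), 1)), "non-finite")
})

test_that("contrast invariants hold on every subject of a fitted run", {
  d <- random_trial(600, seed = 5)
  fit <- itr(d, "acwl", seed = 5, nrounds = 50)
  cs <- fit$contrasts
  expect_true(all(cs$C1 >= 0))
  expect_true(all(cs$C2 >= cs$C1))
})

test_that("doubling all weights leaves the fitted rule unchanged", {
  set.seed(6)
  n <- 400
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  lab <- factor(ifelse(X$x1 > 0, 1, 2), levels = 1:3)
  w <- runif(n, 0.5, 2)
  t1 <- rpart::rpart(lab ~ ., data = X, weights = w, method = "class",
                     control = rpart::rpart.control(cp = 1e-4, xval = 0))
  t2 <- rpart::rpart(lab ~ ., data = X, weights = 2 * w, method = "class",
                     control = rpart::rpart.control(cp = 1e-4, xval = 0))
  expect_equal(predict(t1, X, type = "class"),
               predict(t2, X, type = "class"))
})

test_that("two arms reduce ACWL to one weighted classification", {
  d <- random_trial(300, seed = 9)
  d2 <- trial_data(d$X, ifelse(d$A == 3, 1, d$A), d$Y, K = 2,
                   propensity = 1 / 2)
  am <- fit_arm_means(d2, regressor = "linear")
  cs <- contrast_set(am$mu_hat)
  expect_equal(cs$C1, cs$C2)
  expect_equal(cs$C2, abs(am$mu_hat[, 2] - am$mu_hat[, 1]))
  expect_equal(cs$best, ifelse(am$mu_hat[, 2] > am$mu_hat[, 1], 2L, 1L))
})

test_that("all-zero weights yield the majority label with a warning", {
  d <- random_trial(200, seed = 10)
  am <- matrix(1, d$n, 3)  # equal means: C2 = 0 everywhere
  cs <- contrast_set(am)
  expect_true(all(cs$C2 == 0))
  # route through the fitting path with a degenerate outcome
  d0 <- trial_data(d$X, d$A, rep(5, d$n), K = 3, propensity = 1 / 3)
  expect_warning(fit <- itr(d0, "acwl", regressor = "linear", seed = 1),
                 "majority")
  expect_length(unique(decide(fit, d$X)), 1)
})

test_that("perfectly separating labels give a single-split tree", {
  set.seed(12)
  n <- 300
  X <- data.frame(z = runif(n, -1, 1), noise = runif(n))
  lab <- ifelse(X$z > 0, 2L, 1L)
  mu <- matrix(0, n, 3)
  mu[cbind(seq_len(n), lab)] <- 1
  cs <- contrast_set(mu)
  expect_true(all(cs$best == lab))
  df <- data.frame(.label = factor(lab, levels = 1:3), X)
  tree <- rpart::rpart(.label ~ ., data = df, weights = cs$C2,
                       method = "class",
                       control = rpart::rpart.control(cp = 1e-4, xval = 0))
  pred <- as.integer(as.character(predict(tree, X, type = "class")))
  expect_equal(pred, lab)
})
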