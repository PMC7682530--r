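test_that("the simulation study is deterministic and well-formed", {
  r1 <- run_simulation_study(settings = 6, methods = c("dlearn", "pls-gl"),
                             n_train = 600, n_test = 500, replicates = 2,
                             seed = 3)
  r2 <- run_simulation_study(settings = 6, methods = c("dlearn", "pls-gl"),
                             n_train = 600, n_test = 500, replicates = 2,
                             seed = 3)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$replicates, r2$replicates)
  expect_true(all(r1$summary$failures == 0))
  expect_true(all(r1$summary$misclassification_sd >= 0))
})

test_that("a single replicate reports zero spread by convention", {
  r <- run_simulation_study(settings = 6, methods = "dlearn",
                            n_train = 400, n_test = 300, replicates = 1,
                            seed = 4)
  expect_equal(r$summary$misclassification_sd, 0)
  expect_equal(r$summary$value_sd, 0)
})

test_that("the application summarizes splits, proportions and effects", {
  co <- suppressWarnings(gen_donor_cohort(1500, seed = 11))
  rep <- run_application(co, targets = c("donation", "utility"),
                         b_grid = c(1, 3), splits = 2, methods = "dlearn",
                         seed = 5)
  s <- rep$summary
  expect_true(all(abs(s$pct_12wk_mean + s$pct_10wk_mean +
                        s$pct_8wk_mean - 100) < 0.1))
  expect_setequal(unique(s$target), c("donation", "utility"))
  expect_equal(nrow(rep$fixed_rules), 3)
})

test_that("the utility identity holds exactly within each split", {
  co <- suppressWarnings(gen_donor_cohort(1200, seed = 12))
  rep <- run_application(co, targets = "utility", b_grid = c(2, 5),
                         splits = 2, methods = "dlearn", seed = 6)
  d <- rep$replicates
  expect_equal(d$effect_utility,
               d$effect_donation - d$b * d$effect_deferral_count)
})

test_that("fixed-rule utility effects are linear in b", {
  co <- suppressWarnings(gen_donor_cohort(1000, seed = 13))
  fr <- fixed_rule_effects(co, b_grid = 1:3)
  # utility effect at b is donation effect minus b times the count effect
  base <- donor_trial(co, "donation")
  for (a in 1:3) {
    dc <- itr_effect(base, fixed_rule(a), outcome = co$deferrals)
    for (b in 1:3)
      expect_equal(fr[[sprintf("effect_utility_b%g", b)]][a],
                   fr$effect_donation[a] - b * dc)
  }
})

test_that("reports round-trip through files", {
  r <- run_simulation_study(settings = 6, methods = "dlearn",
                            n_train = 400, n_test = 300, replicates = 2,
                            seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_report(r, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths["summary"])
  expect_equal(back$misclassification_mean, r$summary$misclassification_mean)
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$config$seed, 7)
})

test_that("trial datasets round-trip through CSV with a YAML sidecar", {
  d <- sim_trial(5, 80, seed = 14)  # includes a factor covariate
  file <- file.path(withr::local_tempdir(), "trial.csv")
  write_trial(d, file, seed = 14)
  back <- read_trial(file)
  expect_equal(back$Y, d$Y)
  expect_equal(back$A, d$A)
  expect_equal(back$X$X1, d$X$X1)
  expect_equal(back$K, d$K)
  expect_equal(back$propensity, d$propensity)
})
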