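# Orchestration of the two experiments: the six-setting simulation study
# (misclassification and IPW value on a fixed test set, across replicates)
# and the donor-cohort application (repeated 4:1 splits, three targets, a
# b-sweep for the utility target).

#' Simulation study across settings and methods
#'
#' For each setting a fixed test set is drawn once (from a seed derived from
#' the master seed) and reused across replicates; each replicate draws a
#' fresh training set, fits each method, and records the misclassification
#' rate against the true optimal rule on the test set and the IPW value of
#' the fitted rule there.
#'
#' @param settings integer vector of setting ids (subset of 1..6).
#' @param methods character vector of [itr()] methods.
#' @param n_train,n_test training and test sample sizes.
#' @param replicates number of replicates per setting.
#' @param seed master seed; replicate `r` of setting `s` uses seed
#'   `seed + 1000 s + r` and the test set of setting `s` uses
#'   `seed + 77000 + s`.
#' @param method_args named list (by method) of extra arguments passed to
#'   [itr()], e.g. `list(bart = list(ndpost = 200))`.
#' @return An object of class `itr_report`: list with `summary` (mean/SD per
#'   setting and method) and `replicates` (per-replicate records).
#' @export
run_simulation_study <- function(settings = 1:6,
                                 methods = c("pls-hgl", "pls-gl", "acwl",
                                             "dlearn", "bart"),
                                 n_train = 20000L, n_test = 10000L,
                                 replicates = 100L, seed = 1L,
                                 method_args = list()) {
  stopifnot(replicates >= 1)
  rows <- list()
  for (s in settings) {
    test <- sim_trial(s, n_test, seed = seed + 77000L + s)
    for (r in seq_len(replicates)) {
      train <- sim_trial(s, n_train, seed = seed + 1000L * s + r)
      for (m in methods) {
        args <- c(list(data = train, method = m,
                       seed = seed + 1000L * s + r),
                  method_args[[m]])
        rec <- tryCatch({
          fit <- do.call(itr, args)
          arms <- decide(fit, test$X)
          list(misclassification = misclassification(arms, test$optimal),
               value = ipw_value(test, arms), failed = FALSE)
        }, error = function(e) {
          warning(sprintf("setting %d, %s, replicate %d failed: %s",
                          s, m, r, conditionMessage(e)))
          list(misclassification = NA_real_, value = NA_real_,
               failed = TRUE)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          setting = s, method = m, replicate = r,
          misclassification = rec$misclassification, value = rec$value,
          failed = rec$failed)
      }
    }
  }
  reps <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(reps, reps[c("setting", "method")],
                                         drop = TRUE), function(d) {
    ok <- !d$failed
    data.frame(setting = d$setting[1], method = d$method[1],
               replicates = sum(ok), failures = sum(!ok),
               misclassification_mean = mean(d$misclassification[ok]),
               misclassification_sd = sd0(d$misclassification[ok]),
               value_mean = mean(d$value[ok]),
               value_sd = sd0(d$value[ok]))
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = reps,
                 config = list(settings = settings, methods = methods,
                               n_train = n_train, n_test = n_test,
                               replicates = replicates, seed = seed)),
            class = "itr_report")
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' @export
print.itr_report <- function(x, digits = 3, ...) {
  cat("ITR evaluation report\n")
  print(format(x$summary, digits = digits), ...)
  invisible(x)
}

#' Donor-cohort application with repeated 4:1 splits
#'
#' For each random 4:1 train/validation split and each analysis target
#' (donation; deferral via the variance-stabilizing transform; utility at
#' each trade-off parameter `b`), fits each method on the training part and
#' evaluates on the validation part: assignment proportions over the three
#' inter-donation intervals and empirical ITR effects on donation, deferral
#' rate, deferral count and utility.
#'
#' @param cohort a [gen_donor_cohort] result.
#' @param targets subset of `c("donation", "deferral", "utility")`.
#' @param b_grid utility trade-off values (used when `"utility"` is among
#'   the targets).
#' @param splits number of repeated splits.
#' @param split_ratio fraction of donors in the training part.
#' @param methods [itr()] methods to compare.
#' @param seed master seed; split `r` uses seed `seed + r`.
#' @param method_args named list of extra [itr()] arguments per method.
#' @return An object of class `itr_report` with per-split records, their
#'   summary, and fixed-rule baselines computed on the full cohort.
#' @export
run_application <- function(cohort,
                            targets = c("donation", "deferral", "utility"),
                            b_grid = 1:5, splits = 100L, split_ratio = 0.8,
                            methods = c("pls-hgl", "pls-gl", "acwl",
                                        "dlearn"),
                            seed = 1L, method_args = list()) {
  stopifnot(inherits(cohort, "donor_cohort"),
            split_ratio > 0, split_ratio < 1)
  targets <- match.arg(targets, several.ok = TRUE)
  tasks <- list()
  for (tg in targets) {
    bs <- if (tg == "utility") b_grid else NA_real_
    for (b in bs) tasks[[length(tasks) + 1L]] <- list(target = tg, b = b)
  }
  rows <- list()
  for (r in seq_len(splits)) {
    set.seed(seed + r)
    tr_idx <- sample.int(cohort$n, round(split_ratio * cohort$n))
    va_idx <- setdiff(seq_len(cohort$n), tr_idx)
    for (task in tasks) {
      train <- donor_trial(cohort, task$target, b = task$b, subset = tr_idx)
      valid <- donor_trial(cohort, task$target, b = task$b, subset = va_idx)
      for (m in methods) {
        args <- c(list(data = train, method = m, seed = seed + r),
                  method_args[[m]])
        rec <- tryCatch({
          fit <- do.call(itr, args)
          arms <- decide(fit, valid$X)
          pr <- assignment_proportions(arms, valid$X, K = 3L)
          eff_G <- itr_effect(valid, arms, outcome = cohort$G[va_idx])
          eff_R <- itr_effect(valid, arms, outcome = cohort$R[va_idx])
          eff_Rt <- itr_effect(valid, arms,
                               outcome = cohort$deferrals[va_idx])
          eff_U <- if (is.na(task$b)) NA_real_ else
            itr_effect(valid, arms,
                       outcome = utility(cohort$G[va_idx],
                                         cohort$deferrals[va_idx], task$b))
          list(pr = pr, eff_G = eff_G, eff_R = eff_R, eff_Rt = eff_Rt,
               eff_U = eff_U, failed = FALSE)
        }, error = function(e) {
          warning(sprintf("split %d, %s, target %s failed: %s",
                          r, m, task$target, conditionMessage(e)))
          list(pr = rep(NA_real_, 3), eff_G = NA_real_, eff_R = NA_real_,
               eff_Rt = NA_real_, eff_U = NA_real_, failed = TRUE)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          split = r, target = task$target, b = task$b, method = m,
          pct_12wk = 100 * rec$pr[1], pct_10wk = 100 * rec$pr[2],
          pct_8wk = 100 * rec$pr[3], effect_donation = rec$eff_G,
          effect_deferral = rec$eff_R, effect_deferral_count = rec$eff_Rt,
          effect_utility = rec$eff_U, failed = rec$failed)
      }
    }
  }
  reps <- do.call(rbind, rows)
  bkey <- ifelse(is.na(reps$b), "-", as.character(reps$b))
  summary <- do.call(rbind, lapply(
    split(reps, list(reps$target, bkey, reps$method), drop = TRUE),
    function(d) {
      ok <- !d$failed
      num <- c("pct_12wk", "pct_10wk", "pct_8wk", "effect_donation",
               "effect_deferral", "effect_deferral_count", "effect_utility")
      out <- data.frame(target = d$target[1], b = d$b[1],
                        method = d$method[1], splits = sum(ok),
                        failures = sum(!ok))
      for (cn in num) {
        out[[paste0(cn, "_mean")]] <- mean(d[[cn]][ok])
        out[[paste0(cn, "_sd")]] <- sd0(d[[cn]][ok])
      }
      out
    }))
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = reps,
                 fixed_rules = fixed_rule_effects(cohort, b_grid),
                 config = list(targets = targets, b_grid = b_grid,
                               splits = splits, split_ratio = split_ratio,
                               methods = methods, seed = seed)),
            class = "itr_report")
}

#' ITR effects of the three non-personalized rules on the full cohort
#'
#' @param cohort a [gen_donor_cohort] result.
#' @param b_grid utility trade-off values.
#' @return Data frame: per fixed arm, effects on donation and deferral rate
#'   and on utility at each `b`.
#' @export
fixed_rule_effects <- function(cohort, b_grid = 1:5) {
  base <- donor_trial(cohort, "donation")
  out <- lapply(1:3, function(a) {
    rule <- fixed_rule(a, 3L)
    row <- data.frame(arm = a,
                      interval = c("12wk", "10wk", "8wk")[a],
                      effect_donation = itr_effect(base, rule,
                                                  outcome = cohort$G),
                      effect_deferral = itr_effect(base, rule,
                                                   outcome = cohort$R))
    for (b in b_grid)
      row[[sprintf("effect_utility_b%g", b)]] <-
        itr_effect(base, rule,
                   outcome = utility(cohort$G, cohort$deferrals, b))
    row
  })
  do.call(rbind, out)
}

#' Write a report to CSV and JSON files
#'
#' @param report an `itr_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "itr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(dir, "summary.csv"),
             replicates = file.path(dir, "replicates.csv"),
             json = file.path(dir, "report.json"))
  utils::write.csv(report$summary, paths["summary"], row.names = FALSE)
  utils::write.csv(report$replicates, paths["replicates"],
                   row.names = FALSE)
  jsonlite::write_json(report[setdiff(names(report), "replicates")],
                       paths["json"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(paths)
}
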