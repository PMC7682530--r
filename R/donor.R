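# Synthetic blood-donor cohort for the three-arm inter-donation-interval
# study (arms 1/2/3 = 12/10/8-week intervals). The generator is a
# negative-binomial attendance process with, at each attendance, a Bernoulli
# low-hemoglobin deferral; a non-deferred attendance collects one unit of
# whole blood. So over two years G = attendances - deferrals, the deferral
# count never exceeds attendances, and shorter intervals raise both the
# collected units and the deferral count.

#' Configuration of the synthetic donor-cohort generator
#'
#' Defaults emulate the published three-arm male-donor cohort: mean
#' attendances over two years rising from about 5 (12-week arm) to 8
#' (8-week arm) and per-attendance low-Hb deferral probabilities rising from
#' about 2% to 5%, so that with purely quantitative arm-covariate
#' interactions every donor's benefit-optimal arm is the 8-week interval and
#' risk-optimal arm the 12-week interval.
#'
#' @param base_attendance mean attendances per arm (12/10/8 weeks).
#' @param attendance_dispersion negative-binomial size parameter.
#' @param base_deferral per-attendance deferral probability per arm at
#'   average covariates; may be 0 (no deferrals at all).
#' @param deferral_hb_slope logit-scale effect of one SD of baseline
#'   hemoglobin on the deferral probability (same for every arm).
#' @param quantitative_strength scale of the sign-preserving (quantitative)
#'   arm-covariate modification of the extra deferral risk of shorter
#'   intervals; 0 removes all arm-covariate interaction in the risk model.
#' @param qualitative_strength scale of a sign-flipping (qualitative)
#'   arm-covariate interaction on attendance: frail donors attend less under
#'   the 8-week interval, so their benefit-optimal arm is no longer 8 weeks.
#'   Default 0 (all interactions quantitative).
#' @param attendance_donation_slope log-scale effect of one SD of prior
#'   donation history on attendance.
#' @return An object of class `donor_config`.
#' @export
donor_config <- function(base_attendance = c(5.2, 6.3, 8.0),
                         attendance_dispersion = 12,
                         base_deferral = c(0.020, 0.033, 0.052),
                         deferral_hb_slope = -0.45,
                         quantitative_strength = 1,
                         qualitative_strength = 0,
                         attendance_donation_slope = 0.05) {
  stopifnot(length(base_attendance) == 3, length(base_deferral) == 3)
  if (any(base_attendance <= 0)) stop("mean attendances must be positive")
  if (attendance_dispersion <= 0) stop("dispersion must be positive")
  if (any(base_deferral < 0 | base_deferral >= 1))
    stop("deferral probabilities must lie in [0, 1)")
  structure(list(base_attendance = base_attendance,
                 attendance_dispersion = attendance_dispersion,
                 base_deferral = base_deferral,
                 deferral_hb_slope = deferral_hb_slope,
                 quantitative_strength = quantitative_strength,
                 qualitative_strength = qualitative_strength,
                 attendance_donation_slope = attendance_donation_slope),
            class = "donor_config")
}

donor_baseline <- function(n) {
  rtnorm <- function(n, m, s, lo, hi) pmin(pmax(stats::rnorm(n, m, s), lo), hi)
  cat_draw <- function(n, levels, prob)
    factor(sample(levels, n, TRUE, prob), levels = levels)
  data.frame(
    age = rtnorm(n, 43, 13, 18, 75),
    bmi = rtnorm(n, 26.5, 4, 16, 45),
    sf36_pcs = stats::rnorm(n, 54, 6),
    sf36_mcs = stats::rnorm(n, 52, 8),
    prior_donations = stats::rpois(n, 4),
    hb = stats::rnorm(n, 150, 10),
    wbc = rtnorm(n, 6.8, 1.6, 2, 15),
    rbc = stats::rnorm(n, 5.0, 0.35),
    mch = stats::rnorm(n, 29.5, 1.7),
    mcv = stats::rnorm(n, 90, 4),
    platelet = rtnorm(n, 250, 55, 80, 500),
    ethnicity = cat_draw(n, c("White", "Asian", "Black", "Mixed", "Other",
                              "Unknown"),
                         c(.93, .03, .01, .01, .01, .01)),
    blood_group = cat_draw(n, c("O+", "A+", "B+", "AB+", "O-", "A-", "B-",
                                "AB-"),
                           c(.37, .33, .08, .03, .07, .07, .02, .03)),
    iron_prescription = cat_draw(n, c("No", "Yes", "Unknown"),
                                 c(.97, .02, .01)),
    smoke_ever = cat_draw(n, c("No", "Yes", "Unknown"), c(.63, .35, .02)),
    smoke_current = cat_draw(n, c("No", "Yes", "Unknown"),
                             c(.90, .08, .02)),
    alcohol_ever = cat_draw(n, c("Yes", "No", "Unknown"), c(.93, .05, .02)),
    alcohol_current = cat_draw(n, c("Yes", "No", "Unknown"),
                               c(.85, .13, .02)),
    donor_status = cat_draw(n, c("Returning", "New"), c(.75, .25)))
}

# Frailty score in (0, 1): donors with low hemoglobin and little donation
# history are more susceptible to deferral under short intervals.
donor_frailty <- function(X) {
  z_hb <- (X$hb - 150) / 10
  z_don <- (X$prior_donations - 4) / 2
  stats::plogis(-(z_hb + 0.5 * z_don))
}

#' Generate a synthetic donor cohort
#'
#' @param n number of donors (the published male cohort has 20,574).
#' @param config a [donor_config].
#' @param seed integer seed.
#' @return An object of class `donor_cohort`: list with `baseline`
#'   (covariate data frame), `arm` (1 = 12-week, 2 = 10-week, 3 = 8-week),
#'   `attendances`, `G` (units collected), `deferrals` (low-Hb deferral
#'   count), `R` (deferral rate, 0 when a donor never attended) and the
#'   `config`.
#' @export
gen_donor_cohort <- function(n, config = donor_config(), seed = NULL) {
  stopifnot(inherits(config, "donor_config"))
  if (!is.null(seed)) set.seed(seed)
  X <- donor_baseline(n)
  arm <- sample.int(3L, n, replace = TRUE)
  z_hb <- (X$hb - 150) / 10
  z_don <- (X$prior_donations - 4) / 2
  frail <- donor_frailty(X)

  # attendance: NB with log-mean increasing in arm frequency; the
  # qualitative knob lets frail donors attend less under the 8-week arm
  log_mu <- log(config$base_attendance[arm]) +
    config$attendance_donation_slope * z_don -
    config$qualitative_strength * (arm == 3L) * pmax(frail - 0.35, 0)
  att <- stats::rnbinom(n, size = config$attendance_dispersion,
                        mu = exp(log_mu))

  # per-attendance deferral probability: base arm effect on the logit scale,
  # hemoglobin main effect, and a sign-preserving arm-step modification
  base <- config$base_deferral[arm]
  step <- pmin(pmax(config$quantitative_strength * 0.3 *
                      (frail - 0.5), -0.2), 0.3)
  eta <- stats::qlogis(base) + config$deferral_hb_slope * z_hb +
    (arm - 1L) * step
  pi_def <- ifelse(base == 0, 0, stats::plogis(eta))
  def <- stats::rbinom(n, att, pi_def)
  G <- att - def
  if (any(att == 0))
    warning(sprintf(
      "%d donor(s) with zero attendances; their deferral rate is set to 0",
      sum(att == 0)))
  R <- ifelse(att == 0, 0, def / att)
  structure(list(baseline = X, arm = arm, attendances = att, G = as.numeric(G),
                 deferrals = def, R = R, config = config, n = n),
            class = "donor_cohort")
}

#' @export
print.donor_cohort <- function(x, ...) {
  cat(sprintf("Synthetic donor cohort: %d donors, arms 12/10/8 weeks\n",
              x$n))
  cat(sprintf("Mean attendances by arm: %s\n",
              paste(sprintf("%.2f", tapply(x$attendances, x$arm, mean)),
                    collapse = " / ")))
  cat(sprintf("Mean units collected by arm: %s\n",
              paste(sprintf("%.2f", tapply(x$G, x$arm, mean)),
                    collapse = " / ")))
  cat(sprintf("Mean deferral rate by arm: %s\n",
              paste(sprintf("%.4f", tapply(x$R, x$arm, mean)),
                    collapse = " / ")))
  invisible(x)
}

#' Convert a donor cohort to a trial dataset for one analysis target
#'
#' @param cohort a [gen_donor_cohort] result.
#' @param target `"donation"` (outcome G), `"deferral"` (the
#'   variance-stabilized `asin(sqrt(1 - R))`, larger is better) or
#'   `"utility"` (`G - b * deferrals`).
#' @param b trade-off parameter for the utility target.
#' @param subset optional row indices.
#' @return A [trial_data] object.
#' @export
donor_trial <- function(cohort, target = c("donation", "deferral",
                                           "utility"),
                        b = 1, subset = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(cohort, "donor_cohort"))
  idx <- if (is.null(subset)) seq_len(cohort$n) else subset
  Y <- switch(target,
    donation = cohort$G[idx],
    deferral = deferral_target_transform(cohort$R[idx]),
    utility = utility(cohort$G[idx], cohort$deferrals[idx], b))
  trial_data(cohort$baseline[idx, , drop = FALSE], cohort$arm[idx], Y,
             K = 3L, propensity = 1 / 3)
}
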