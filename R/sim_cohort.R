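# Synthetic cohort tables with known trajectory parameters.
#
# Outcomes follow configurable polynomial age trajectories (optionally
# sex-specific) plus linear covariate effects and Gaussian noise; the
# generating parameters are returned alongside the table so trajectory
# estimators can be scored by parameter recovery.

default_trajectories <- function() {
  # coefficients are c(intercept, age, age^2, age^3); defaults emulate the
  # qualitative developmental picture: spindle density and fast-spindle
  # percent inverted-U, frequency rising, spindle and sigma power falling.
  # density stays well above zero across 5-22 y (outcomes are denominators
  # in percent-change analyses), peaking at 4.5/min at 15.2 y
  list(
    density      = c(0.3413, 0.5472, -0.018, 0), # vertex at 15.2 y
    frequency    = c(11.5, 0.05, 0, 0),
    power        = c(520, -17, 0, 0),
    fast_percent = c(6, 5.7, -0.15, 0),          # vertex at 19 y
    sigma_power  = c(60, -2, 0, 0)
  )
}

default_noise_sd <- function() {
  # residual SDs sized so each age trajectory explains roughly half the
  # outcome variance over ages 6-21 (R^2 ~ 0.4-0.5), the regime the study
  # population shows
  list(density = 0.4, frequency = 0.3, power = 80,
       fast_percent = 8, sigma_power = 10)
}

default_covariate_effects <- function() {
  # per-outcome multipliers applied to bmi (per percentile), ahi (per
  # event/h), disorder flag, and PSG system dummies; zero by default so the
  # null calibration of group contrasts holds unless effects are requested.
  list(bmi = 0, ahi = 0, disorder = 0, psg = 0)
}

#' Tanner-stage probabilities given age and sex
#'
#' Cumulative-logistic model over stages 1-5 with female cutpoints shifted
#' earlier; probabilities sum to one by construction.
#'
#' @param age Years.
#' @param sex `"male"` or `"female"`.
#' @param shift Years by which male maturation lags female.
#' @param scale Logistic scale, years.
#' @return Numeric vector of 5 probabilities.
#' @export
tanner_probabilities <- function(age, sex, shift = 1.5, scale = 0.8) {
  cuts <- c(10.5, 12, 13.5, 15) + if (sex == "male") shift else 0
  p_gt <- plogis((age - cuts) / scale)         # P(stage > k), k = 1..4
  c(1 - p_gt[1], -diff(p_gt), p_gt[4])
}

#' Configuration for the cohort simulator
#'
#' @param n_subjects Number of subjects (cross-sectional) or subject pairs
#'   (longitudinal).
#' @param age_range Age interval in years; must lie within \[5, 23\].
#' @param sex_ratio Fraction female.
#' @param trajectories Named list of per-outcome polynomial coefficients
#'   `c(b0, b1, b2, b3)`; an element may itself be
#'   `list(male = ..., female = ...)` for sex-specific trajectories.
#' @param covariate_effects List with `bmi`, `ahi`, `disorder`, `psg`
#'   scalar effects applied to every outcome.
#' @param noise_sd Named list of residual SDs per outcome (> 0).
#' @param subject_sd SD of a subject-level random intercept shared by the
#'   two longitudinal waves (within-subject correlation), expressed as a
#'   multiple of the outcome's `noise_sd`.
#' @param followup_interval_range Years between baseline and follow-up
#'   (longitudinal mode).
#' @param tanner_shift,tanner_scale Parameters of [tanner_probabilities()].
#' @param seed Integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 500,
                              age_range = c(6, 21),
                              sex_ratio = 0.48,
                              trajectories = default_trajectories(),
                              covariate_effects = default_covariate_effects(),
                              noise_sd = default_noise_sd(),
                              subject_sd = 1,
                              followup_interval_range = c(6, 13),
                              tanner_shift = 1.5,
                              tanner_scale = 0.8,
                              seed = 1L) {
  if (age_range[1] < 5 || age_range[2] > 23 || diff(age_range) <= 0) {
    stopf("age_range must be an interval within [5, 23] years")
  }
  if (any(unlist(noise_sd) < 0)) stopf("noise_sd must be >= 0")
  structure(
    list(n_subjects = n_subjects, age_range = age_range,
         sex_ratio = sex_ratio, trajectories = trajectories,
         covariate_effects = covariate_effects, noise_sd = noise_sd,
         subject_sd = subject_sd,
         followup_interval_range = followup_interval_range,
         tanner_shift = tanner_shift, tanner_scale = tanner_scale,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

traj_coef <- function(trajectories, outcome, sex) {
  co <- trajectories[[outcome]]
  if (is.list(co)) co <- co[[sex]]
  co
}

sim_covariates <- function(n, cfg, wave = c("baseline", "followup")) {
  wave <- match.arg(wave)
  systems <- if (wave == "baseline") c("B1", "B2") else "F"
  data.frame(
    race_ethnicity = sample(c("NH-white", "minority"), n, TRUE, c(0.75, 0.25)),
    bmi = pmin(99, pmax(1, rnorm(n, 60, 25))),
    ahi = rexp(n, rate = 2),
    disorder_flag = runif(n) < 0.15,
    psg_system = sample(systems, n, TRUE)
  )
}

outcome_value <- function(cfg, outcome, age, sex, cov, noise) {
  co <- vapply(seq_along(age),
               function(i) polyval_asc(traj_coef(cfg$trajectories, outcome,
                                                 sex[i]), age[i]),
               numeric(1))
  eff <- cfg$covariate_effects
  co + eff$bmi * cov$bmi + eff$ahi * cov$ahi +
    eff$disorder * cov$disorder_flag +
    eff$psg * (cov$psg_system != "B1") + noise
}

#' Simulate a cohort table with known trajectory parameters
#'
#' Cross-sectional mode yields one row per subject with ages drawn uniformly
#' over `age_range`. Longitudinal mode yields one row per subject carrying a
#' baseline assessment at ages 5-12 and a follow-up at ages 12-22, with the
#' follow-up interval drawn from `followup_interval_range` (clipped so the
#' follow-up age lands in 12-22); follow-up outcome columns keep the plain
#' outcome names, baseline values are prefixed `baseline_`.
#'
#' @param config A [cohort_sim_config()].
#' @param mode `"cross_sectional"` or `"longitudinal"`.
#' @return List: `table` (data.frame) and `truth` (generating parameters).
#' @export
simulate_cohort <- function(config,
                            mode = c("cross_sectional", "longitudinal")) {
  stopifnot(inherits(config, "cohort_sim_config"))
  mode <- match.arg(mode)
  n <- config$n_subjects
  outcomes <- names(config$trajectories)

  with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")

    if (mode == "cross_sectional") {
      age <- runif(n, config$age_range[1], config$age_range[2])
      cov <- sim_covariates(n, config, "baseline")
      tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                        age = age, sex = sex, cov)
      tanner <- vapply(seq_len(n), function(i) {
        sample.int(5L, 1L, prob = tanner_probabilities(
          age[i], sex[i], config$tanner_shift, config$tanner_scale))
      }, integer(1))
      tab$tanner <- tanner
      for (oc in outcomes) {
        tab[[oc]] <- outcome_value(config, oc, age, sex, cov,
                                   rnorm(n, 0, config$noise_sd[[oc]]))
      }
    } else {
      age_b <- runif(n, max(5, config$age_range[1]),
                     min(12, config$age_range[2]))
      lo <- pmax(config$followup_interval_range[1], 12 - age_b)
      hi <- pmin(config$followup_interval_range[2], 22 - age_b)
      interval <- runif(n, lo, hi)
      age_f <- age_b + interval
      cov <- sim_covariates(n, config, "baseline")
      subj <- rnorm(n)                       # shared z, scaled per outcome
      tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                        baseline_age = age_b, age = age_f,
                        followup_years = interval, sex = sex, cov)
      tab$tanner <- vapply(seq_len(n), function(i) {
        sample.int(5L, 1L, prob = tanner_probabilities(
          age_f[i], sex[i], config$tanner_shift, config$tanner_scale))
      }, integer(1))
      for (oc in outcomes) {
        sdo <- config$noise_sd[[oc]]
        u <- subj * config$subject_sd * sdo
        tab[[paste0("baseline_", oc)]] <-
          outcome_value(config, oc, age_b, sex, cov,
                        u + rnorm(n, 0, sdo))
        tab[[oc]] <-
          outcome_value(config, oc, age_f, sex, cov,
                        u + rnorm(n, 0, sdo))
      }
    }
    list(table = tab,
         truth = list(trajectories = config$trajectories,
                      covariate_effects = config$covariate_effects,
                      noise_sd = config$noise_sd, mode = mode))
  })
}
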