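# Maturational-trajectory statistics.
#
# Cross-sectional: covariate-adjusted polynomial age models where the
# highest-ordered significant (p < 0.05) age term fixes the final degree
# (lower-order terms always retained), predicted population mean curves
# with pointwise 95% CIs by marginal standardization over the observed
# covariate distribution, ages of extrema over 6-21 years, and standardized
# piece-wise slopes (outcome divided by its full-sample SD). Group
# contrasts (sex, Tanner 1-3 vs 4-5) use covariate-adjusted least-squares
# means. Longitudinal: percent change from baseline modeled per follow-up
# age group with the baseline value and follow-up length as additional
# covariates. Agreement between channel-reference dialects uses Lin's
# concordance correlation coefficient.

DEFAULT_COVARIATES <- c("sex", "race_ethnicity", "bmi", "ahi",
                        "disorder_flag", "psg_system")

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`; undefined (NA, with a warning)
#' where the baseline is zero.
#'
#' @param baseline,followup Numeric vectors, outcome units.
#' @return Percent change, %.
#' @export
percent_change <- function(baseline, followup) {
  out <- 100 * (followup - baseline) / baseline
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero)) {
    warning(sprintf("%d row(s) with zero baseline excluded (percent change undefined)",
                    sum(zero)), call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

# covariates that actually vary in `data`, as a formula string tail
covariate_terms <- function(data, covariates) {
  keep <- covariates[vapply(covariates, function(v) {
    v %in% names(data) && length(unique(data[[v]][!is.na(data[[v]])])) > 1L
  }, logical(1))]
  keep
}

age_poly_terms <- function(degree) {
  c("age", "I(age^2)", "I(age^3)")[seq_len(degree)]
}

#' Fit a covariate-adjusted polynomial age trajectory
#'
#' Fits the cubic model (with quadratic and linear terms retained), tests
#' the cubic term at `alpha`; if non-significant, refits the quadratic, then
#' the linear model. Ages are truncated to `age_range` before fitting.
#'
#' @param data Cohort data.frame (one row per subject).
#' @param outcome Outcome column name.
#' @param covariates Adjustment covariates (constant columns are dropped).
#' @param age_range Analysis age window, years.
#' @param alpha Significance level for the degree ladder.
#' @param max_degree Highest polynomial degree tried.
#' @return Object of class `trajectory_fit`: the final `lm` fit, selected
#'   degree, coefficient table, R^2, and the p-values of each tested
#'   highest-order term.
#' @export
fit_age_trajectory <- function(data, outcome,
                               covariates = DEFAULT_COVARIATES,
                               age_range = c(6, 21), alpha = 0.05,
                               max_degree = 3) {
  data <- data[data$age >= age_range[1] & data$age <= age_range[2], ,
               drop = FALSE]
  if (nrow(data) < 20L) stopf("need >= 20 rows within the age range")
  if (sd(data$age) == 0) stopf("no age variation in the data")
  covs <- covariate_terms(data, covariates)
  ladder_p <- numeric(0)
  for (degree in rev(seq_len(max_degree))) {
    rhs <- paste(c(age_poly_terms(degree), covs), collapse = " + ")
    fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = data)
    if (any(is.na(coef(fit)))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stopf("rank-deficient design; collinear terms: %s",
            paste(bad, collapse = ", "))
    }
    top <- age_poly_terms(degree)[degree]
    # a noiseless generator makes summary.lm warn about perfect fits; that
    # case is handled explicitly below
    sm <- suppressWarnings(summary(fit))
    p_top <- sm$coefficients[top, "Pr(>|t|)"]
    if (sm$sigma^2 < 1e-12 * var(data[[outcome]])) {
      # (near-)perfect fit: t statistics are numerical noise; judge the top
      # term by whether it contributes to the fitted values at all
      contrib <- abs(coef(fit)[top]) * sd(data$age^degree)
      p_top <- if (contrib > 1e-6 * sd(data[[outcome]])) 0 else 1
    }
    ladder_p[top] <- p_top
    if (degree == 1L || (!is.na(p_top) && p_top < alpha)) break
  }
  structure(
    list(fit = fit, outcome = outcome, degree = degree,
         covariates = covs, age_range = age_range,
         coefficients = summary(fit)$coefficients,
         r_squared = summary(fit)$r.squared,
         ladder_p = ladder_p, data = data),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s ~ age^%d (+%d covariates), R^2 = %.3f\n",
              x$outcome, x$degree, length(x$covariates), x$r_squared))
  invisible(x)
}

#' Predicted population mean curve with 95% CI
#'
#' Predicts the outcome at each requested age with covariates marginalized
#' over their observed distribution (each subject's covariates kept, age
#' replaced, predictions averaged). The pointwise CI uses the variance of
#' the predicted mean.
#'
#' @param tfit A [fit_age_trajectory()] result.
#' @param ages Ages at which to predict; must lie within the fit's age
#'   range (extrapolation is refused).
#' @param level Confidence level.
#' @return data.frame: `age`, `mean`, `lwr`, `upr`.
#' @export
predict_mean_curve <- function(tfit, ages = seq(tfit$age_range[1],
                                                tfit$age_range[2], by = 0.1),
                               level = 0.95) {
  if (any(ages < tfit$age_range[1] - 1e-9 | ages > tfit$age_range[2] + 1e-9)) {
    stopf("ages outside the fitted range [%g, %g]; extrapolation refused",
          tfit$age_range[1], tfit$age_range[2])
  }
  fit <- tfit$fit
  tt <- delete.response(terms(fit))
  V <- vcov(fit)
  tcrit <- qt(1 - (1 - level) / 2, fit$df.residual)
  out <- lapply(ages, function(a) {
    nd <- tfit$data
    nd$age <- a
    mm <- model.matrix(tt, nd)
    cvec <- colMeans(mm)
    m <- sum(cvec * coef(fit))
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(age = a, mean = m, lwr = m - tcrit * se, upr = m + tcrit * se)
  })
  do.call(rbind, out)
}

#' Ages of the trajectory's minimum and maximum
#'
#' Evaluates the fitted age polynomial's stationary points (derivative
#' roots) against the endpoints of the analysis window and reports the ages
#' of the minimum and maximum predicted values, rounded to 0.1 year.
#'
#' @param tfit A [fit_age_trajectory()] result.
#' @return List: `age_at_min`, `age_at_max` (years).
#' @export
locate_extrema <- function(tfit) {
  co <- coef(tfit$fit)
  b <- unname(c(co["age"],
                if (tfit$degree >= 2) co["I(age^2)"] else 0,
                if (tfit$degree >= 3) co["I(age^3)"] else 0))
  b[is.na(b)] <- 0
  lo <- tfit$age_range[1]; hi <- tfit$age_range[2]
  # stationary points of b1 a + b2 a^2 + b3 a^3
  crit <- numeric(0)
  if (b[3] != 0) {
    disc <- 4 * b[2]^2 - 12 * b[3] * b[1]
    if (disc >= 0) crit <- (-2 * b[2] + c(-1, 1) * sqrt(disc)) / (6 * b[3])
  } else if (b[2] != 0) {
    crit <- -b[1] / (2 * b[2])
  }
  cand <- c(lo, hi, crit[crit > lo & crit < hi])
  vals <- b[1] * cand + b[2] * cand^2 + b[3] * cand^3
  list(age_at_min = round(cand[which.min(vals)], 1),
       age_at_max = round(cand[which.max(vals)], 1))
}

# rows whose age falls in the closed whole-year segment [lo, hi], i.e.
# floor(age) in lo..hi
segment_rows <- function(data, segment) {
  data$age >= segment[1] & data$age < segment[2] + 1
}

#' Standardized piece-wise slopes
#'
#' Within each age segment, fits a covariate-adjusted linear model of the
#' outcome divided by its full-sample SD (so slopes are comparable across
#' segments) and returns the standardized age slope, its SE, and p-value.
#' Optionally also tests an age-by-group interaction within each segment.
#'
#' @param data Cohort data.frame.
#' @param outcome Outcome column name.
#' @param segments List of closed whole-year age intervals.
#' @param covariates Adjustment covariates.
#' @param interaction_var Optional column name; when given, the p-value of
#'   the `age:interaction_var` term is reported per segment.
#' @param min_rows Segments with fewer rows are omitted (with a message).
#' @return data.frame: `segment`, `n`, `beta_s`, `se`, `p_value`
#'   (+ `p_interaction`).
#' @export
piecewise_standardized_slopes <- function(data, outcome,
                                          segments = list(c(6, 10), c(11, 14),
                                                          c(15, 17), c(18, 21)),
                                          covariates = DEFAULT_COVARIATES,
                                          interaction_var = NULL,
                                          min_rows = 10L) {
  sd_full <- sd(data[[outcome]], na.rm = TRUE)
  if (!is.finite(sd_full) || sd_full == 0) stopf("outcome has zero variance")
  rows <- lapply(segments, function(seg) {
    sub <- data[segment_rows(data, seg), , drop = FALSE]
    if (nrow(sub) < min_rows) {
      message(sprintf("segment %d-%d omitted: %d row(s) < %d",
                      seg[1], seg[2], nrow(sub), min_rows))
      return(NULL)
    }
    sub$.y_std <- sub[[outcome]] / sd_full
    covs <- covariate_terms(sub, covariates)
    fit <- lm(stats::as.formula(paste(".y_std ~",
                                      paste(c("age", covs), collapse = " + "))),
              data = sub)
    sm <- summary(fit)$coefficients
    res <- data.frame(segment = sprintf("%d-%d", seg[1], seg[2]),
                      n = nrow(sub), beta_s = sm["age", "Estimate"],
                      se = sm["age", "Std. Error"],
                      p_value = sm["age", "Pr(>|t|)"])
    if (!is.null(interaction_var)) {
      fi <- lm(stats::as.formula(
        paste(".y_std ~ age *", interaction_var, "+",
              paste(setdiff(covs, interaction_var), collapse = " + "))),
        data = sub)
      smi <- summary(fi)$coefficients
      itr <- grep(paste0("^age:"), rownames(smi), value = TRUE)
      res$p_interaction <- if (length(itr)) smi[itr[1], "Pr(>|t|)"] else NA_real_
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted group means and contrast
#'
#' Least-squares means per stratum with the stratum contrast, computed by
#' marginal standardization over the observed covariate distribution
#' (emmeans with proportional weights). In longitudinal mode the covariate
#' set additionally includes the baseline value of the outcome and the
#' length of follow-up.
#'
#' @param data Cohort data.frame.
#' @param outcome Outcome column name (for longitudinal percent-change
#'   analyses, pass the percent-change column).
#' @param group Grouping column (two or more levels; rows with missing
#'   group are dropped).
#' @param age_group Optional closed whole-year age interval to restrict to.
#' @param covariates Adjustment covariates.
#' @param longitudinal When `TRUE`, adds `baseline_<outcome_base>` and
#'   `followup_years` to the covariates.
#' @param outcome_base Outcome whose baseline value adjusts longitudinal
#'   models (defaults to `outcome` stripped of a `pc_` prefix).
#' @param level Confidence level for the means' CIs.
#' @return List: `means` (data.frame stratum/mean/lwr/upr/n) and
#'   `contrast` (data.frame with estimate, SE, p; `NA` with a note when a
#'   single stratum is present).
#' @export
groupwise_adjusted_means <- function(data, outcome, group,
                                     age_group = NULL,
                                     covariates = DEFAULT_COVARIATES,
                                     longitudinal = FALSE,
                                     outcome_base = sub("^pc_", "", outcome),
                                     level = 0.95) {
  if (!is.null(age_group)) data <- data[segment_rows(data, age_group), ,
                                        drop = FALSE]
  data <- data[!is.na(data[[group]]) & !is.na(data[[outcome]]), , drop = FALSE]
  if (nrow(data) == 0L) stopf("no usable rows in the requested age group")
  data[[group]] <- factor(data[[group]])
  covs <- covariate_terms(data, setdiff(covariates, group))
  if (longitudinal) {
    extra <- c(paste0("baseline_", outcome_base), "followup_years")
    covs <- c(covs, intersect(extra, names(data)))
  }
  counts <- table(data[[group]])
  if (length(counts) < 2L) {
    m <- mean(data[[outcome]])
    return(list(
      means = data.frame(stratum = names(counts), mean = m,
                         lwr = NA_real_, upr = NA_real_,
                         n = as.integer(counts)),
      contrast = data.frame(estimate = NA_real_, se = NA_real_,
                            p_value = NA_real_,
                            note = "single stratum; contrast undefined")))
  }
  fit <- lm(stats::as.formula(
    paste(outcome, "~", paste(c(group, covs), collapse = " + "))), data = data)
  emm <- emmeans::emmeans(fit, specs = group, weights = "proportional",
                          level = level)
  ems <- as.data.frame(emm)
  cont <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  list(
    means = data.frame(stratum = as.character(ems[[1]]),
                       mean = ems$emmean, lwr = ems$lower.CL,
                       upr = ems$upper.CL,
                       n = as.integer(counts[as.character(ems[[1]])])),
    contrast = data.frame(estimate = cont$estimate, se = cont$SE,
                          p_value = cont$p.value,
                          note = as.character(cont$contrast))
  )
}

#' Pairwise Pearson correlation matrix
#'
#' @param data data.frame.
#' @param vars Columns to correlate; complete cases over these columns.
#' @return Correlation matrix; zero-variance columns give `NA` rows and
#'   columns.
#' @export
pearson_matrix <- function(data, vars) {
  sub <- data[vars]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  if (nrow(sub) < 3L) stopf("need >= 3 complete rows")
  const <- vapply(sub, function(x) sd(x) == 0, logical(1))
  m <- suppressWarnings(cor(sub))
  m[const, ] <- NA_real_
  m[, const] <- NA_real_
  m
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' moment (1/n) variances; the CI uses the Fisher z transform with Lin's
#' asymptotic variance. Penalizes location/scale shift as well as
#' decorrelation, so `rho_c <= |r|` always.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 3`.
#' @param conf_level Confidence level.
#' @return List of class `lin_ccc`: `estimate`, `lwr`, `upr`, `n`
#'   (`estimate = NA` when either input is constant).
#' @export
lin_concordance <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need >= 3 paired observations")
  out <- structure(list(estimate = NA_real_, lwr = NA_real_, upr = NA_real_,
                        n = n), class = "lin_ccc")
  sx <- var(x) * (n - 1) / n
  sy <- var(y) * (n - 1) / n
  if (sx == 0 || sy == 0) {
    out$note <- "constant input; concordance undefined"
    return(out)
  }
  sxy <- cov(x, y) * (n - 1) / n
  d <- mean(x) - mean(y)
  ccc <- 2 * sxy / (sx + sy + d^2)
  out$estimate <- ccc
  r <- sxy / sqrt(sx * sy)
  if (abs(ccc) < 1 && abs(r) > 0 && n > 2) {
    u <- d / (sx * sy)^(1 / 4)
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    hw <- qnorm(1 - (1 - conf_level) / 2) * sqrt(sz2)
    out$lwr <- tanh(z - hw)
    out$upr <- tanh(z + hw)
  } else if (ccc == 1) {
    out$lwr <- out$upr <- 1
  }
  out
}

#' @export
print.lin_ccc <- function(x, ...) {
  cat(sprintf("Lin's concordance: rho_c = %.4f [%.4f, %.4f], n = %d\n",
              x$estimate, x$lwr, x$upr, x$n))
  invisible(x)
}

#' Percent-change table for longitudinal cohorts
#'
#' Adds `pc_<outcome>` columns. Extreme values (beyond `iqr_mult` IQRs from
#' the median) are flagged; they are excluded only when
#' `exclude_outliers = TRUE`.
#'
#' @param data Longitudinal cohort data.frame with `baseline_<outcome>`
#'   columns.
#' @param outcomes Outcome names.
#' @param exclude_outliers Drop flagged values (set to `NA`)?
#' @param iqr_mult Flagging multiplier.
#' @return `data` with `pc_*` and `pc_*_outlier` columns.
#' @export
percent_change_table <- function(data, outcomes, exclude_outliers = FALSE,
                                 iqr_mult = 5) {
  for (oc in outcomes) {
    pc <- percent_change(data[[paste0("baseline_", oc)]], data[[oc]])
    iqr <- stats::IQR(pc, na.rm = TRUE)
    flag <- !is.na(pc) & abs(pc - median(pc, na.rm = TRUE)) > iqr_mult * iqr
    if (exclude_outliers) pc[flag] <- NA_real_
    data[[paste0("pc_", oc)]] <- pc
    data[[paste0("pc_", oc, "_outlier")]] <- flag
  }
  data
}

#' Tanner maturity grouping
#'
#' Collapses Tanner stages into the conventional less-mature (1-3) versus
#' more-mature (4-5) contrast; missing stages stay `NA` and are excluded
#' from Tanner contrasts only.
#'
#' @param tanner Integer vector of Tanner stages (1-5) with possible `NA`s.
#' @return Factor with levels `"1-3"`, `"4-5"`.
#' @export
tanner_group <- function(tanner) {
  factor(ifelse(is.na(tanner), NA_character_,
                ifelse(tanner <= 3, "1-3", "4-5")),
         levels = c("1-3", "4-5"))
}
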