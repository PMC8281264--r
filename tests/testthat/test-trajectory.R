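cross_cohort <- function(n = 300, seed = 1, ...) {
  simulate_cohort(cohort_sim_config(n_subjects = n, seed = seed, ...),
                  "cross_sectional")$table
}

test_that("percent change follows the published formula", {
  expect_equal(percent_change(4, 5), 25)
  expect_equal(percent_change(100, 50), -50)
  expect_equal(percent_change(7.3, 7.3), 0)
  expect_warning(out <- percent_change(c(2, 0), c(3, 3)), "zero baseline")
  expect_equal(out, c(50, NA))
})

test_that("a noiseless linear trajectory selects degree one and recovers the
           slope", {
  tab <- cross_cohort(100, seed = 4,
                      trajectories = list(density = c(2, 0.5, 0, 0)),
                      noise_sd = list(density = 0))
  fit <- fit_age_trajectory(tab, "density", covariates = character(0))
  expect_equal(fit$degree, 1L)
  expect_equal(unname(coef(fit$fit)["age"]), 0.5, tolerance = 1e-8)
})

test_that("degree selection finds the generating quadratic under noise", {
  picks <- replicate(25, {
    tab <- cross_cohort(500, seed = sample.int(1e6, 1))
    fit_age_trajectory(tab, "density")$degree
  })
  expect_gte(mean(picks == 2L), 0.9)
})

test_that("the predicted mean curve interpolates a noiseless generator and
           refuses extrapolation", {
  tab <- cross_cohort(100, seed = 5,
                      trajectories = list(density = c(1, 0.6, -0.02, 0)),
                      noise_sd = list(density = 0))
  fit <- fit_age_trajectory(tab, "density", covariates = character(0),
                            alpha = 0.9)  # degenerate p-values under 0 noise
  curve <- predict_mean_curve(fit, ages = c(8, 12, 16, 20))
  expect_equal(curve$mean, 1 + 0.6 * curve$age - 0.02 * curve$age^2,
               tolerance = 1e-6)
  expect_error(predict_mean_curve(fit, ages = c(3, 10)), "extrapolation")
})

test_that("curve CIs tighten as the sample grows", {
  w <- sapply(c(100, 1000), function(n) {
    tab <- cross_cohort(n, seed = 77)
    fit <- fit_age_trajectory(tab, "density")
    curve <- predict_mean_curve(fit, ages = 6:21)
    mean(curve$upr - curve$lwr)
  })
  expect_lt(w[2], w[1])
})

test_that("extrema ages come from the fitted polynomial over 6-21", {
  # concave quadratic with vertex at 15: max there, min at the far endpoint
  tab <- cross_cohort(200, seed = 6,
                      trajectories = list(density = c(-10, 3, -0.1, 0)),
                      noise_sd = list(density = 0.1))
  fit <- fit_age_trajectory(tab, "density", covariates = character(0))
  ex <- locate_extrema(fit)
  expect_equal(ex$age_at_max, 15, tolerance = 0.5)
  expect_equal(ex$age_at_min, 6)

  # increasing linear: endpoints
  tabl <- cross_cohort(200, seed = 7,
                       trajectories = list(density = c(0, 0.5, 0, 0)),
                       noise_sd = list(density = 0.1))
  exl <- locate_extrema(fit_age_trajectory(tabl, "density",
                                           covariates = character(0)))
  expect_equal(exl$age_at_min, 6)
  expect_equal(exl$age_at_max, 21)
})

test_that("generating quadratic vertex is recovered within +/- 0.8 years", {
  errs <- replicate(30, {
    tab <- cross_cohort(500, seed = sample.int(1e6, 1))
    fit <- fit_age_trajectory(tab, "density")
    abs(locate_extrema(fit)$age_at_max - 15.2)
  })
  expect_lte(median(errs), 0.8)
})

test_that("standardized slopes are invariant to outcome rescaling", {
  tab <- cross_cohort(400, seed = 8)
  b1 <- piecewise_standardized_slopes(tab, "density")
  tab$density <- tab$density * 37.5
  b2 <- piecewise_standardized_slopes(tab, "density")
  expect_equal(b1$beta_s, b2$beta_s, tolerance = 1e-10)
  expect_equal(b1$se, b2$se, tolerance = 1e-10)
})

test_that("a flat generator yields near-zero standardized slopes", {
  covered <- replicate(40, {
    tab <- cross_cohort(300, seed = sample.int(1e6, 1),
                        trajectories = list(density = c(2, 0, 0, 0)),
                        noise_sd = list(density = 0.5))
    b <- piecewise_standardized_slopes(tab, "density",
                                       segments = list(c(6, 21)))
    abs(b$beta_s) < 2 * b$se
  })
  expect_gte(mean(covered), 0.85)
})

test_that("adjusted means are equal with p ~ 1 when strata are identical", {
  tab <- cross_cohort(200, seed = 9)
  tab2 <- tab
  tab2$sex <- rep(c("male", "female"), 100)   # reassign strata arbitrarily
  tab2$density <- rep(tab$density[1:100], each = 2)  # identical by pair
  res <- groupwise_adjusted_means(tab2, "density", "sex",
                                  covariates = character(0))
  expect_equal(res$means$mean[1], res$means$mean[2], tolerance = 0.2)
  expect_gt(res$contrast$p_value, 0.5)
})

test_that("a true group effect in percent change is detected with covariate
           adjustment", {
  set.seed(123)
  found <- replicate(20, {
    cfg <- cohort_sim_config(n_subjects = 150, age_range = c(5, 22),
                             seed = sample.int(1e6, 1))
    tab <- simulate_cohort(cfg, "longitudinal")$table
    tab <- percent_change_table(tab, "density")
    # inject a +30 percentage-point male excess
    tab$pc_density <- tab$pc_density + ifelse(tab$sex == "male", 30, 0)
    res <- groupwise_adjusted_means(tab, "pc_density", "sex",
                                    longitudinal = TRUE)
    c(res$contrast$p_value < 0.05,
      abs(abs(res$contrast$estimate) - 30) < 15)
  })
  expect_gte(mean(found[1, ]), 0.8)           # power
  expect_gte(mean(found[2, ]), 0.8)           # magnitude recovery
})

test_that("single-stratum age groups report the contrast as undefined", {
  tab <- cross_cohort(100, seed = 10)
  tab$sex <- "female"
  res <- groupwise_adjusted_means(tab, "density", "sex",
                                  covariates = character(0))
  expect_true(is.na(res$contrast$p_value))
  expect_match(res$contrast$note, "single stratum")
})

test_that("pearson matrix handles exact linearity and zero variance", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1, z = -(1:20), c = 5)
  m <- pearson_matrix(d, c("x", "y", "z"))
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "z"], -1)
  m2 <- pearson_matrix(d, c("x", "c"))
  expect_true(is.na(m2["x", "c"]))
  set.seed(11)
  n <- 1e4; rho <- 0.5
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  m3 <- pearson_matrix(data.frame(x = x, y = y), c("x", "y"))
  expect_lt(abs(m3["x", "y"] - 0.5), 0.02)
})

test_that("Lin concordance: identity, shift penalty, and the closed-form
           value on a fixed vector", {
  x <- c(1, 2, 3, 4)
  expect_equal(lin_concordance(x, x)$estimate, 1)
  shifted <- lin_concordance(x, x + 2)
  expect_lt(shifted$estimate, 1)
  expect_equal(cor(x, x + 2), 1)

  y <- c(1.1, 2.0, 3.2, 3.9)
  n <- 4
  sx <- var(x) * (n - 1) / n; sy <- var(y) * (n - 1) / n
  sxy <- cov(x, y) * (n - 1) / n
  want <- 2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
  got <- lin_concordance(x, y)
  expect_equal(got$estimate, want, tolerance = 1e-12)
  expect_true(got$lwr < want && want < got$upr)

  expect_true(is.na(lin_concordance(c(1, 1, 1), c(1, 2, 3))$estimate))
})

test_that("rho_c never exceeds |r| and matches it only for equal moments", {
  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30, mean = runif(1, -1, 1))
    cc <- lin_concordance(x, y)$estimate
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
  }
  x <- rnorm(50); y <- x
  expect_equal(lin_concordance(x, y)$estimate, abs(cor(x, y)))
})

test_that("row order does not change any estimate", {
  tab <- cross_cohort(250, seed = 14)
  perm <- sample(nrow(tab))
  f1 <- fit_age_trajectory(tab, "density")
  f2 <- fit_age_trajectory(tab[perm, ], "density")
  expect_equal(sort(coef(f1$fit)), sort(coef(f2$fit)), tolerance = 1e-10)
  expect_equal(pearson_matrix(tab, c("density", "frequency")),
               pearson_matrix(tab[perm, ], c("density", "frequency")),
               tolerance = 1e-12)
})

test_that("percent-change outliers are flagged but kept unless excluded", {
  tab <- simulate_cohort(cohort_sim_config(n_subjects = 80,
                                           age_range = c(5, 22), seed = 15),
                         "longitudinal")$table
  tab$density[1] <- tab$baseline_density[1] * 500   # wild follow-up value
  t1 <- percent_change_table(tab, "density")
  expect_true(t1$pc_density_outlier[1])
  expect_false(is.na(t1$pc_density[1]))
  t2 <- percent_change_table(tab, "density", exclude_outliers = TRUE)
  expect_true(is.na(t2$pc_density[1]))
})

test_that("Tanner grouping collapses 1-3 vs 4-5 and keeps NA", {
  expect_equal(as.character(tanner_group(c(1, 3, 4, 5, NA))),
               c("1-3", "1-3", "4-5", "4-5", NA))
})
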