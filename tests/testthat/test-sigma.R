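tone_grid <- function(fs, seconds, stage = "N2") {
  n_ep <- seconds %/% 30
  data.frame(epoch_index = seq_len(n_ep) - 1L,
             start_s = (seq_len(n_ep) - 1L) * 30,
             end_s = seq_len(n_ep) * 30, stage = stage,
             artifact_flag = FALSE)
}

test_that("spectral resolution equals one over the window length", {
  fs <- 200
  x <- sin(2 * pi * 13 * seq(0, 60 - 1 / fs, by = 1 / fs))
  ps <- epoch_psd(x, tone_grid(fs, 60), fs)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.390625)
  ps2 <- epoch_psd(x, tone_grid(fs, 60), fs,
                   spectral_config(window_length = 2, window_step = 1))
  expect_equal(ps2$freqs[2] - ps2$freqs[1], 0.5)
})

test_that("exactly 22 half-overlapping 2.56-s windows tile a 30-s epoch", {
  expect_equal(spectral_config()$windows_per_epoch, 22L)
})

test_that("Parseval: a unit 13 Hz tone carries ~0.5 uV^2, all of it in the
           sigma band and none at 5 Hz", {
  for (fs in c(100, 200)) {
    t <- seq(0, 120 - 1 / fs, by = 1 / fs)
    grid <- tone_grid(fs, 120)
    ps <- epoch_psd(sin(2 * pi * 13 * t), grid, fs)
    total <- mean(rowSums(ps$power))
    expect_lt(abs(total - 0.5) / 0.5, 0.03)
    sig <- mean(sigma_band_power(ps$power, ps$freqs))
    expect_lt(abs(sig - 0.5) / 0.5, 0.03)

    ps5 <- epoch_psd(sin(2 * pi * 5 * t), grid, fs)
    expect_lt(mean(sigma_band_power(ps5$power, ps5$freqs)) /
                mean(rowSums(ps5$power)), 0.01)
  }
})

test_that("zero signal gives all-zero spectra; flat spectra count in-band
           bins", {
  fs <- 100
  ps <- epoch_psd(numeric(fs * 60), tone_grid(fs, 60), fs)
  expect_equal(max(ps$power), 0)
  freqs <- (0:128) * 0.390625
  expect_equal(sigma_band_power(rep(1, length(freqs)), freqs), 10)
})

test_that("power conservation: summed PSD matches band-limited time-domain
           variance for a stationary signal", {
  fs <- 100
  set.seed(6)
  x <- rnorm(fs * 120, 0, 10)
  xb <- butterworth_bandlimit_fft(x, fs)
  ps <- epoch_psd(xb, tone_grid(fs, 120), fs)
  expect_lt(abs(mean(rowSums(ps$power)) - var(xb)) / var(xb), 0.05)
})

test_that("injected high-amplitude transients reject exactly those epochs", {
  fs <- 100
  set.seed(3)
  x <- rnorm(fs * 100 * 30, 0, 15)           # 100 clean epochs
  grid <- tone_grid(fs, 100 * 30)
  bad <- c(4, 11, 23, 38, 40, 57, 66, 71, 88, 95)
  for (e in bad) x[e * 30 * fs + seq_len(fs)] <- 500
  acc <- flag_artifacts(x, grid, fs)
  expect_equal(which(!acc), bad + 1L)
})

test_that("annotated artifact intervals also reject their epochs", {
  fs <- 100
  x <- numeric(fs * 120)
  grid <- tone_grid(fs, 120)
  ann <- data.frame(onset_s = 35, offset_s = 36, label = "artifact")
  acc <- flag_artifacts(x, grid, fs, annotations = ann)
  expect_equal(which(!acc), 2L)
})

test_that("aggregation averages accepted NREM epochs only and across
           channels", {
  cfgs <- spectral_config()
  grid <- data.frame(epoch_index = 0:3, start_s = (0:3) * 30,
                     end_s = (1:4) * 30,
                     stage = c("N2", "N3", "W", "R"),
                     artifact_flag = FALSE)
  freqs <- (0:10) * 0.390625 + 11.33         # irrelevant placement
  spectra <- list(power = matrix(1, 4, 11), freqs = (0:10) * 0.390625,
                  epoch_index = 0:3)
  spectra$power[3, ] <- 100                   # W epoch: must not count
  spectra$power[4, ] <- 100                   # R epoch: must not count
  agg <- aggregate_sigma(spectra, grid, rep(TRUE, 4), cfgs)
  expect_equal(agg$n_epochs_total, 2L)
  base <- agg$sigma_power

  # rejecting one of two identical NREM epochs leaves the mean unchanged
  agg2 <- aggregate_sigma(spectra, grid, c(TRUE, FALSE, TRUE, TRUE), cfgs)
  expect_equal(agg2$sigma_power, base)
  expect_equal(agg2$percent_accepted, 50)

  # zero accepted NREM epochs: undefined and flagged
  agg0 <- aggregate_sigma(spectra, grid, c(FALSE, FALSE, TRUE, TRUE), cfgs)
  expect_true(is.na(agg0$sigma_power))
  expect_true(agg0$flagged)
})

test_that("the subject value is the mean of the two channel values", {
  fs <- 100
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rec <- sleep_recording(list(`C3-M2` = 2 * sin(2 * pi * 13 * t),
                              `C4-M1` = sqrt(8) * sin(2 * pi * 13 * t)),
                         fs)
  hyp <- as_hypnogram(rep("N2", 4))
  out <- sigma_power_analysis(rec, hyp, channels = c("C3-M2", "C4-M1"))
  # channel sigma powers ~2 and ~4 uV^2 -> average 3
  expect_equal(out$sigma_power_uv2[out$channel == "average"], 3,
               tolerance = 0.03)
})

test_that("epoch acceptance on realistic synthetic nights falls in a
           plausible 80-95% band", {
  sim <- simulate_sleep_eeg(eeg_sim_config(seed = 17))
  out <- sigma_power_analysis(sim$recording, sim$hypnogram, sim$annotations)
  pa <- out$percent_accepted[out$channel == "average"]
  expect_gt(pa, 75)
  expect_lt(pa, 99)
})
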