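make_track <- function(ratio, power = ratio, step = 0.2) {
  structure(
    data.frame(epoch_index = 0L, start_s = (seq_along(ratio) - 1) * step,
               power_s = power, ratio = ratio,
               alpha_ratio = rep(1, length(ratio)),
               beta_ratio = rep(1, length(ratio))),
    window_length = 1, window_step = step)
}

test_that("power S track: zero signal yields no defined windows, a
           stationary tone yields constant power with ratio one", {
  fs <- 100
  grid <- data.frame(epoch_index = 0:1, start_s = c(0, 30), end_s = c(30, 60),
                     stage = "N2", artifact_flag = FALSE)
  z <- compute_power_s_track(numeric(60 * fs), grid, fs)
  expect_equal(nrow(z), 0L)
  expect_equal(attr(z, "excluded_epochs"), 2L)

  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 13 * t)
  tr <- compute_power_s_track(tone, grid, fs)
  # five starts per second; the last four windows of the record extend past
  # the signal end and are dropped
  expect_equal(nrow(tr), 2 * 150 - 4)
  # stationary tone: power essentially constant (taper phase ripple only),
  # ratio = power / 30th percentile of a constant = 1
  expect_lt(diff(range(tr$power_s)) / mean(tr$power_s), 0.01)
  expect_equal(tr$ratio, rep(1, nrow(tr)), tolerance = 0.01)
})

test_that("a 13 Hz burst on faint background drives the ratio far above
           threshold inside the burst only", {
  fs <- 100
  set.seed(8)
  x <- rnorm(30 * fs, 0, 0.5)
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  idx <- (14 * fs + 1):(15 * fs)
  x[idx] <- x[idx] + 20 * sin(2 * pi * 13 * t)
  grid <- data.frame(epoch_index = 0L, start_s = 0, end_s = 30,
                     stage = "N2", artifact_flag = FALSE)
  tr <- compute_power_s_track(x, grid, fs)
  inside <- tr$start_s >= 13.6 & tr$start_s <= 14.4
  expect_true(all(tr$ratio[inside] > 3))
  outside <- tr$start_s < 12.5 | tr$start_s > 15.5
  expect_lt(mean(tr$ratio[outside]), 3)
})

test_that("candidate state machine follows the printed rules on hand-traced
           profiles", {
  # run of five supra windows then a clear drop: one candidate, offset at
  # the first window with ratio < 1.5 (power held high so only the ratio
  # criterion binds)
  tr <- make_track(c(0, 4, 4, 4, 4, 4, 0.5, 1, 1, 1), power = rep(10, 10))
  cand <- detect_candidates(tr)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$onset_idx, 2L)
  expect_equal(cand$offset_idx, 7L)
  expect_equal(cand$termination, "ratio")
  expect_equal(cand$onset_s, 0.2)
  expect_equal(cand$offset_s, 1.2 + 1)       # terminating window end

  # only four supra-threshold windows: below the minimum run
  expect_equal(nrow(detect_candidates(make_track(c(0, 4, 4, 4, 4, 0.5)))), 0L)

  # sustained elevation for 6 s never terminates within the 5-s horizon
  expect_equal(nrow(detect_candidates(make_track(rep(4, 32)))), 0L)

  # power-criterion termination: ratio stays high but power collapses below
  # 20% of the running peak
  ratio <- c(0, 4, 4, 4, 4, 4, 4, 4, 0)
  power <- c(1, 10, 50, 40, 30, 20, 9, 8, 1)
  cand2 <- detect_candidates(make_track(ratio, power))
  expect_equal(cand2$termination, "power")
  expect_equal(cand2$offset_idx, 7L)         # 9 < 0.2 * 50
})

test_that("detect_candidates matches the brute-force oracle on random
           tracks", {
  set.seed(99)
  cfg <- detector_config()
  for (rep in 1:200) {
    tr <- random_track(120)
    got <- detect_candidates(tr, cfg)
    want <- oracle_candidates(tr$start_s, tr$ratio, tr$power_s)
    # compare pre-merge structure through onset/offset windows
    expect_equal(got$onset_idx, want$onset_idx)
    expect_equal(got$offset_idx, want$offset_idx)
  }
})

test_that("raising the onset threshold never increases the event count", {
  set.seed(12)
  for (rep in 1:30) {
    tr <- random_track(150)
    counts <- sapply(c(2, 3, 4, 6), function(thr) {
      nrow(detect_candidates(tr, detector_config(onset_ratio_threshold = thr)))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("candidates overlapping arousals are deleted", {
  tr <- make_track(c(0, 4, 4, 4, 4, 4, 0.5, rep(1, 8)))
  grid <- data.frame(epoch_index = 0L, start_s = 0, end_s = 30,
                     stage = "N2", artifact_flag = FALSE)
  aro <- data.frame(onset_s = 0.5, offset_s = 2, label = "arousal")
  out <- reject_candidates(detect_candidates(tr), tr, aro, grid)
  expect_equal(out$rejected_reason, "arousal")
  none <- reject_candidates(detect_candidates(tr), tr,
                            data.frame(onset_s = 10, offset_s = 12,
                                       label = "arousal"), grid)
  expect_equal(none$rejected_reason, "")
})

test_that("alpha-dominated candidates are deleted, spindle-dominated kept", {
  base <- make_track(c(0, 5, 5, 5, 5, 5, 0.5, rep(1, 5)))
  grid <- data.frame(epoch_index = 0L, start_s = 0, end_s = 30,
                     stage = "N2", artifact_flag = FALSE)
  ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    label = character(0))
  kept <- reject_candidates(detect_candidates(base), base, ann, grid)
  expect_equal(kept$rejected_reason, "")
  alpha_heavy <- base
  alpha_heavy$alpha_ratio <- rep(10, nrow(base))
  gone <- reject_candidates(detect_candidates(alpha_heavy), alpha_heavy,
                            ann, grid)
  expect_equal(gone$rejected_reason, "alpha_beta")
})

test_that("a pure 9 Hz alpha burst leaking into the spindle sum is rejected
           by the alpha-ratio comparison", {
  fs <- 100
  set.seed(2)
  x <- rnorm(60 * fs, 0, 0.5)
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  burst <- 40 * sin(2 * pi * 9 * t) * spindletraj:::hann_window(length(t))
  idx <- (15 * fs + 1):(15 * fs + length(burst))
  x[idx] <- x[idx] + burst
  rec <- sleep_recording(list(`C3-M2` = x, `C4-M1` = x), fs)
  hyp <- as_hypnogram(rep("N2", 2))
  ev <- detect_spindles(rec, hyp, channels = "C3-M2")
  hit <- ev[ev$onset_s < 17 & ev$offset_s > 15, ]
  expect_true(nrow(hit) >= 1)
  expect_true(all(hit$rejected_reason == "alpha_beta"))
  # direct spectral confirmation: alpha ratio exceeds spindle ratio there
  grid <- epoch_grid(rec, hyp)
  tr <- compute_power_s_track(bandlimit(rec)$signals[[1]], grid, fs)
  inside <- tr$start_s >= 15 & tr$start_s <= 16.5
  expect_gt(mean(tr$alpha_ratio[inside]), mean(tr$ratio[inside]))
})

test_that("event characterization recovers frequency, fast class, and power
           scaling", {
  fs <- 100
  t <- seq(0, 1.5 - 1 / fs, by = 1 / fs)
  mk <- function(freq) {
    y <- numeric(30 * fs)
    idx <- (10 * fs + 1):(10 * fs + length(t))
    y[idx] <- 30 * sin(2 * pi * freq * t) * spindletraj:::hann_window(length(t))
    y
  }
  ch13 <- characterize_event(mk(13), fs, 10, 11.5)
  expect_lt(abs(ch13$peak_frequency - 13), 0.25 + 1e-9)
  expect_true(ch13$is_fast)
  expect_false(characterize_event(mk(11.5), fs, 10, 11.5)$is_fast)
  expect_true(characterize_event(mk(12), fs, 10, 11.5)$is_fast)
  ch2 <- characterize_event(2 * mk(13), fs, 10, 11.5)
  expect_equal(ch2$peak_power_s / ch13$peak_power_s, 4, tolerance = 1e-9)
})

test_that("metric arithmetic follows the definitions", {
  grid <- data.frame(epoch_index = 0:29, start_s = (0:29) * 30,
                     end_s = (1:30) * 30, stage = "N2",
                     artifact_flag = FALSE)
  ev <- data.frame(channel = "C3-M2", onset_s = seq_len(30), offset_s = 2 + seq_len(30),
                   duration_s = 2, peak_power_uv2 = 100,
                   peak_freq_hz = c(rep(13, 22), rep(11, 8)),
                   is_fast = c(rep(TRUE, 22), rep(FALSE, 8)),
                   epoch_index = 0L, rejected_reason = "")
  m <- summarize_metrics(ev, grid)
  avg <- m[m$channel == "average", ]
  expect_equal(avg$density, 30 / 15)
  expect_equal(avg$n2_minutes, 15)

  ev4 <- ev[1:4, ]
  ev4$is_fast <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(summarize_metrics(ev4, grid)$fast_percent[1], 75)

  # no N2 minutes: flagged, not silently zero
  gridw <- transform(grid, stage = "W")
  mw <- summarize_metrics(ev4, gridw)
  expect_true(all(mw$flagged))
  expect_true(all(is.na(mw$density)))
})

test_that("scaling the signal leaves density, frequency and fast percent
           unchanged and scales power quadratically", {
  sim <- simulate_sleep_eeg(n2_sim_config(minutes = 6, seed = 14))
  rec2 <- sim$recording
  rec2$signals <- lapply(rec2$signals, function(x) 3 * x)
  ev1 <- detect_spindles(sim$recording, sim$hypnogram, sim$annotations,
                         channels = "C3-M2")
  ev2 <- detect_spindles(rec2, sim$hypnogram, sim$annotations,
                         channels = "C3-M2")
  k1 <- ev1[ev1$rejected_reason == "", ]
  k2 <- ev2[ev2$rejected_reason == "", ]
  expect_equal(k1$onset_s, k2$onset_s)
  expect_equal(k1$peak_freq_hz, k2$peak_freq_hz)
  expect_equal(k1$is_fast, k2$is_fast)
  expect_equal(k2$peak_power_uv2, 9 * k1$peak_power_uv2, tolerance = 1e-6)
})

test_that("detected density tracks the embedded spindle rate at high SNR", {
  sim <- simulate_sleep_eeg(n2_sim_config(
    minutes = 10, seed = 31, arousal_rate = 0, artifact_rate = 0,
    alpha_contaminant_rate = 0))
  grid <- epoch_grid(sim$recording, sim$hypnogram, sim$annotations)
  ev <- detect_spindles(sim$recording, sim$hypnogram, sim$annotations,
                        channels = "C3-M2")
  m <- summarize_metrics(ev, grid, "C3-M2")
  truth_density <- sum(sim$events$kind == "spindle") / 10
  expect_lt(abs(m$density[1] - truth_density) / truth_density, 0.10)
})
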