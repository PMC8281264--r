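# N2 sleep-spindle detection.
#
# The detector slides a 1-s Hann-tapered FFT window in 0.2-s steps through
# each scored 30-s epoch (five window starts per second; windows do not
# straddle epochs because the ratio reference is defined per epoch). Power S
# is the summed spectral power over the spindle band (10-16 Hz); its ratio
# to the 30th percentile of power S over the windows of the containing epoch
# drives a run-length rule: a spindle candidate opens at the first window of
# a run of at least five consecutive windows with ratio > 3, and closes at
# the first later window where the ratio falls below 1.5 or power S falls
# below 20% of the running peak, provided that happens within 5 s of onset.
# Candidates overlapping arousals, dominated by alpha- or beta-band
# activity, or lying outside N2 are rejected.

#' Spindle-detector configuration
#'
#' All thresholds default to the published algorithm: spindle band
#' 10-16 Hz, fast band 12-16 Hz, 1-s windows advancing 0.2 s, ratio > 3 for
#' five consecutive windows against the 30th-percentile reference,
#' termination at ratio < 1.5 or power S < 20% of peak within 5 s. The
#' alpha and beta comparison bands are not pinned down by the published
#' description; they default to the flanking, non-overlapping intervals
#' \[7.5, 10) and (16, 25\] Hz and are configurable.
#'
#' @param spindle_band,fast_band,alpha_band,beta_band Hz intervals.
#' @param window_length,window_step Sliding-window geometry, s.
#' @param reference_percentile Percentile of power S per 30-s epoch used as
#'   the ratio reference.
#' @param onset_ratio_threshold Ratio that must be exceeded to open a run.
#' @param min_consecutive_windows Minimum run length.
#' @param offset_ratio_threshold Ratio below which a candidate terminates.
#' @param offset_power_fraction Fraction of the running peak power S below
#'   which a candidate terminates.
#' @param max_termination_horizon Seconds within which termination must
#'   occur, else the candidate is discarded.
#' @param merge_gap Candidates closer than this (s) are merged; defaults to
#'   one window step.
#' @param ratio_aggregate `"mean"` (default) or `"max"`: how the ratio
#'   "within the presumptive spindle" is aggregated for the alpha/beta
#'   rejection rule.
#' @param arousal_overlap `"any"` (default) or `"full"`: whether any overlap
#'   with an arousal, or only full containment, deletes a candidate.
#' @param zero_pad_factor Zero-padding factor for sub-bin peak-frequency
#'   estimation (4 gives 0.25-Hz bins from a 1-s window).
#' @param taper Analysis-window taper for the 1-s detection FFT:
#'   `"tukey"` (default, flat over the central 75% so short bursts near a
#'   window edge are not suppressed), `"hann"`, or `"rect"`.
#' @param taper_alpha Tukey edge fraction (ignored for other tapers).
#' @return List of class `detector_config`.
#' @export
detector_config <- function(spindle_band = c(10, 16),
                            fast_band = c(12, 16),
                            window_length = 1,
                            window_step = 0.2,
                            reference_percentile = 30,
                            onset_ratio_threshold = 3,
                            min_consecutive_windows = 5,
                            offset_ratio_threshold = 1.5,
                            offset_power_fraction = 0.2,
                            max_termination_horizon = 5,
                            alpha_band = c(7.5, 10),
                            beta_band = c(16, 25),
                            merge_gap = window_step,
                            ratio_aggregate = c("mean", "max"),
                            arousal_overlap = c("any", "full"),
                            zero_pad_factor = 4,
                            taper = c("tukey", "hann", "rect"),
                            taper_alpha = 0.25) {
  if (window_step <= 0 || window_step > window_length) {
    stopf("need 0 < window_step <= window_length")
  }
  thr <- c(onset_ratio_threshold, offset_ratio_threshold,
           offset_power_fraction, max_termination_horizon)
  if (any(thr <= 0)) stopf("detector thresholds must be > 0")
  for (b in list(spindle_band, fast_band, alpha_band, beta_band)) {
    if (diff(b) <= 0) stopf("frequency bands must be non-degenerate intervals")
  }
  structure(
    list(spindle_band = spindle_band, fast_band = fast_band,
         window_length = window_length, window_step = window_step,
         reference_percentile = reference_percentile,
         onset_ratio_threshold = onset_ratio_threshold,
         min_consecutive_windows = min_consecutive_windows,
         offset_ratio_threshold = offset_ratio_threshold,
         offset_power_fraction = offset_power_fraction,
         max_termination_horizon = max_termination_horizon,
         alpha_band = alpha_band, beta_band = beta_band,
         merge_gap = merge_gap,
         ratio_aggregate = match.arg(ratio_aggregate),
         arousal_overlap = match.arg(arousal_overlap),
         zero_pad_factor = zero_pad_factor,
         taper = match.arg(taper), taper_alpha = taper_alpha),
    class = "detector_config"
  )
}

detector_taper <- function(config, n) {
  switch(config$taper,
         hann = hann_window(n),
         rect = rep(1, n),
         tukey = tukey_window(n, config$taper_alpha))
}

# One-sided window power spectrum calibrated so a unit-amplitude in-band
# sinusoid sums to ~0.5 uV^2 across bins: P_k = c_k |X_k|^2 / (N * sum(w^2)).
window_power_matrix <- function(segmat, fs, w = hann_window(nrow(segmat))) {
  n <- nrow(segmat)
  X <- stats::mvfft(segmat * w)
  nb <- n %/% 2 + 1L
  P <- Mod(X[seq_len(nb), , drop = FALSE])^2 / (n * sum(w^2))
  coef <- rep(2, nb); coef[1] <- 1
  if (n %% 2 == 0) coef[nb] <- 1
  P * coef
}

band_bins <- function(freqs, band, lower_open = FALSE, upper_open = FALSE) {
  lo <- if (lower_open) freqs > band[1] else freqs >= band[1] - 1e-9
  hi <- if (upper_open) freqs < band[2] else freqs <= band[2] + 1e-9
  which(lo & hi)
}

#' Compute the sliding-window power S track
#'
#' @param x Band-limited channel signal, uV.
#' @param grid Epoch grid from [epoch_grid()].
#' @param fs Sampling rate, Hz.
#' @param config A [detector_config()].
#' @return data.frame with one row per window: `epoch_index`, `start_s`,
#'   `power_s` (uV^2), `ratio`, `alpha_ratio`, `beta_ratio`. Windows of
#'   epochs whose reference (30th-percentile) power is zero in any band are
#'   excluded; the count of such epochs is in `attr(, "excluded_epochs")`.
#' @export
compute_power_s_track <- function(x, grid, fs, config = detector_config()) {
  wl <- round(config$window_length * fs)
  step <- config$window_step
  n_starts <- round(30 / step)               # starts per epoch: 150 at 0.2 s
  freqs <- (seq_len(wl %/% 2 + 1L) - 1L) / config$window_length
  bins_s <- band_bins(freqs, config$spindle_band)
  bins_a <- band_bins(freqs, config$alpha_band, upper_open = TRUE)
  bins_b <- band_bins(freqs, config$beta_band, lower_open = TRUE)
  q <- config$reference_percentile / 100

  out <- vector("list", nrow(grid))
  excluded <- 0L
  for (e in seq_len(nrow(grid))) {
    ep_start <- grid$start_s[e]
    # windows advance continuously and may straddle the epoch boundary; a
    # window belongs to the epoch containing its start
    starts_s <- ep_start + (seq_len(n_starts) - 1L) * step
    idx0 <- round(starts_s * fs)
    fits <- idx0 + wl <= length(x)
    starts_s <- starts_s[fits]; idx0 <- idx0[fits]
    if (!length(idx0)) next
    segmat <- vapply(idx0, function(i) x[(i + 1L):(i + wl)], numeric(wl))
    segmat <- matrix(segmat, nrow = wl)
    P <- window_power_matrix(segmat, fs, detector_taper(config, wl))
    ps <- colSums(P[bins_s, , drop = FALSE])
    pa <- colSums(P[bins_a, , drop = FALSE])
    pb <- colSums(P[bins_b, , drop = FALSE])
    refs <- c(quantile(ps, q, names = FALSE),
              quantile(pa, q, names = FALSE),
              quantile(pb, q, names = FALSE))
    if (any(refs <= 0)) {                     # ratios undefined for epoch
      excluded <- excluded + 1L
      next
    }
    out[[e]] <- data.frame(
      epoch_index = grid$epoch_index[e], start_s = starts_s, power_s = ps,
      ratio = ps / refs[1], alpha_ratio = pa / refs[2],
      beta_ratio = pb / refs[3])
  }
  track <- do.call(rbind, out)
  if (is.null(track)) {
    track <- data.frame(epoch_index = integer(0), start_s = numeric(0),
                        power_s = numeric(0), ratio = numeric(0),
                        alpha_ratio = numeric(0), beta_ratio = numeric(0))
  }
  rownames(track) <- NULL
  attr(track, "excluded_epochs") <- excluded
  attr(track, "window_length") <- config$window_length
  attr(track, "window_step") <- step
  track
}

#' Detect provisional spindle candidates on a power S track
#'
#' Implements the run-length rule described at the top of this file.
#' Candidates start only at the first window of a maximal supra-threshold
#' run, so sustained elevation that fails to terminate within the horizon
#' yields no event. A break in window contiguity (epoch gap, end of track)
#' closes an open candidate at the last contiguous window. Candidates
#' separated by less than `merge_gap` are merged.
#'
#' @param track Output of [compute_power_s_track()].
#' @param config A [detector_config()].
#' @return data.frame: `onset_s`, `offset_s`, `onset_idx`, `offset_idx`
#'   (row indices into `track`), `termination` (`"ratio"`, `"power"`,
#'   `"both"`, or `"gap"`).
#' @export
detect_candidates <- function(track, config = detector_config()) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      onset_idx = integer(0), offset_idx = integer(0),
                      termination = character(0))
  n <- nrow(track)
  if (n == 0L) return(empty)
  step <- attr(track, "window_step") %||% config$window_step
  wl <- attr(track, "window_length") %||% config$window_length
  contig <- c(FALSE, abs(diff(track$start_s) - step) < 1e-6)

  above <- track$ratio > config$onset_ratio_threshold
  # maximal runs of supra-threshold, step-contiguous windows
  run_id <- cumsum(!(above & contig))
  runs <- which(above)
  if (!length(runs)) return(empty)
  run_list <- split(runs, run_id[runs])
  run_list <- run_list[vapply(run_list, length, integer(1)) >=
                         config$min_consecutive_windows]
  if (!length(run_list)) return(empty)

  cands <- empty
  last_offset <- 0L
  for (run in run_list) {
    i0 <- run[1]
    if (i0 <= last_offset) next
    peak <- track$power_s[i0]
    j <- i0 + 1L
    offset_idx <- NA_integer_
    term <- NA_character_
    while (j <= n) {
      if (!contig[j]) { offset_idx <- j - 1L; term <- "gap"; break }
      if (track$start_s[j] - track$start_s[i0] >
          config$max_termination_horizon) break
      peak <- max(peak, track$power_s[j])
      r_hit <- track$ratio[j] < config$offset_ratio_threshold
      p_hit <- track$power_s[j] < config$offset_power_fraction * peak
      if (r_hit || p_hit) {
        offset_idx <- j
        term <- if (r_hit && p_hit) "both" else if (r_hit) "ratio" else "power"
        break
      }
      j <- j + 1L
    }
    if (is.na(offset_idx) && j > n) { offset_idx <- n; term <- "gap" }
    if (is.na(offset_idx)) next               # horizon exceeded: discard
    cands <- rbind(cands, data.frame(
      onset_s = track$start_s[i0],
      offset_s = track$start_s[offset_idx] + wl,
      onset_idx = i0, offset_idx = offset_idx, termination = term))
    last_offset <- offset_idx
  }
  if (nrow(cands) < 2L) return(cands)

  # merge candidates re-triggering within one burst: gap measured between
  # the previous terminating window start and the next onset window start
  keep <- cands[1, ]
  for (k in 2:nrow(cands)) {
    m <- nrow(keep)
    gap <- cands$onset_s[k] - track$start_s[keep$offset_idx[m]]
    if (gap <= config$merge_gap + 1e-9) {
      keep$offset_s[m] <- cands$offset_s[k]
      keep$offset_idx[m] <- cands$offset_idx[k]
      keep$termination[m] <- cands$termination[k]
    } else {
      keep <- rbind(keep, cands[k, ])
    }
  }
  rownames(keep) <- NULL
  keep
}

#' Apply the rejection rules to spindle candidates
#'
#' A candidate is deleted if it overlaps an arousal, if its aggregated
#' power S ratio is less than the corresponding alpha- or beta-band ratio,
#' or if its midpoint lies outside N2 sleep.
#'
#' @param cands Output of [detect_candidates()].
#' @param track The power S track the candidates were detected on.
#' @param annotations Annotation data.frame (arousal intervals used).
#' @param grid Epoch grid (stage lookup).
#' @param config A [detector_config()].
#' @return `cands` with a `rejected_reason` column (`""` for survivors).
#' @export
reject_candidates <- function(cands, track, annotations, grid,
                              config = detector_config()) {
  if (nrow(cands) == 0L) {
    cands$rejected_reason <- character(0)
    return(cands)
  }
  agg <- if (config$ratio_aggregate == "mean") mean else max
  aro <- annotations[annotations$label == "arousal", , drop = FALSE]
  stage_by_epoch <- setNames(grid$stage, grid$epoch_index)
  reason <- character(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    on <- cands$onset_s[k]; off <- cands$offset_s[k]
    if (nrow(aro)) {
      ov <- interval_overlap(aro$onset_s, aro$offset_s, on, off)
      hit <- if (config$arousal_overlap == "any") any(ov > 0) else
        any(aro$onset_s <= on & aro$offset_s >= off)
      if (hit) { reason[k] <- "arousal"; next }
    }
    win <- cands$onset_idx[k]:cands$offset_idx[k]
    rs <- agg(track$ratio[win])
    if (rs < agg(track$alpha_ratio[win]) || rs < agg(track$beta_ratio[win])) {
      reason[k] <- "alpha_beta"; next
    }
    mid_ep <- epoch_of((on + off) / 2)
    st <- stage_by_epoch[as.character(mid_ep)]
    if (is.na(st) || st != "N2") reason[k] <- "not_n2"
  }
  cands$rejected_reason <- reason
  cands
}

#' Characterize a detected spindle
#'
#' Peak power S is the maximum 1-s window power S within the event; peak
#' frequency is the frequency of the maximal spectral bin of that peak
#' window over the spindle band, refined to sub-bin resolution by
#' zero-padding (x4 by default, 0.25-Hz bins). A spindle is fast when its
#' peak frequency lies in the fast band (12-16 Hz, lower edge inclusive).
#'
#' @param x Band-limited channel signal, uV.
#' @param fs Sampling rate, Hz.
#' @param onset_s,offset_s Event bounds, s.
#' @param config A [detector_config()].
#' @return List: `peak_power_s` (uV^2), `peak_frequency` (Hz), `is_fast`.
#' @export
characterize_event <- function(x, fs, onset_s, offset_s,
                               config = detector_config()) {
  wl <- round(config$window_length * fs)
  step <- config$window_step
  starts <- if (offset_s - config$window_length >= onset_s) {
    seq(onset_s, offset_s - config$window_length, by = step)
  } else onset_s
  idx0 <- round(starts * fs)
  idx0 <- idx0[idx0 + wl <= length(x)]
  segmat <- vapply(idx0, function(i) x[(i + 1L):(i + wl)], numeric(wl))
  segmat <- matrix(segmat, nrow = wl)
  freqs <- (seq_len(wl %/% 2 + 1L) - 1L) / config$window_length
  bins_s <- band_bins(freqs, config$spindle_band)
  w <- detector_taper(config, wl)
  ps <- colSums(window_power_matrix(segmat, fs, w)[bins_s, , drop = FALSE])
  kpk <- which.max(ps)

  seg <- segmat[, kpk] * w
  zp <- c(seg, numeric(wl * (config$zero_pad_factor - 1L)))
  fz <- (seq_along(zp) - 1L) / (config$window_length * config$zero_pad_factor)
  nb <- length(zp) %/% 2 + 1L
  spec <- Mod(fft(zp)[seq_len(nb)])^2
  bz <- band_bins(fz[seq_len(nb)], config$spindle_band)
  peak_freq <- fz[bz[which.max(spec[bz])]]

  list(peak_power_s = max(ps), peak_frequency = peak_freq,
       is_fast = peak_freq >= config$fast_band[1] &
         peak_freq <= config$fast_band[2] + 1e-9)
}

#' Detect spindles in a recording
#'
#' Runs the full chain (band-limit, power S track, candidate detection,
#' rejection, characterization) on the selected central channels.
#'
#' @param recording A [sleep_recording()] (raw; the 0.3-30 Hz band limit is
#'   applied internally).
#' @param hypnogram A `hypnogram`.
#' @param annotations Annotation data.frame.
#' @param config A [detector_config()].
#' @param channels Channel labels to analyze; default: the central pair
#'   chosen by [select_central_channels()].
#' @return data.frame of all candidates (kept and rejected): `channel`,
#'   `onset_s`, `offset_s`, `duration_s`, `peak_power_uv2`, `peak_freq_hz`,
#'   `is_fast`, `epoch_index`, `rejected_reason`.
#' @export
detect_spindles <- function(recording, hypnogram, annotations = NULL,
                            config = detector_config(), channels = NULL) {
  if (is.null(annotations)) annotations <- empty_annotations()
  if (is.null(channels)) {
    sel <- select_central_channels(recording)
    channels <- c(sel$left, sel$right)
  }
  rec <- bandlimit(recording)
  grid <- epoch_grid(rec, hypnogram, annotations)
  fs <- rec$sampling_rate
  res <- lapply(channels, function(ch) {
    x <- rec$signals[[ch]]
    track <- compute_power_s_track(x, grid, fs, config)
    cands <- detect_candidates(track, config)
    cands <- reject_candidates(cands, track, annotations, grid, config)
    if (nrow(cands) == 0L) {
      return(data.frame(channel = character(0), onset_s = numeric(0),
                        offset_s = numeric(0), duration_s = numeric(0),
                        peak_power_uv2 = numeric(0), peak_freq_hz = numeric(0),
                        is_fast = logical(0), epoch_index = integer(0),
                        rejected_reason = character(0)))
    }
    chr <- lapply(seq_len(nrow(cands)), function(k) {
      characterize_event(x, fs, cands$onset_s[k], cands$offset_s[k], config)
    })
    data.frame(
      channel = ch, onset_s = cands$onset_s, offset_s = cands$offset_s,
      duration_s = cands$offset_s - cands$onset_s,
      peak_power_uv2 = vapply(chr, `[[`, numeric(1), "peak_power_s"),
      peak_freq_hz = vapply(chr, `[[`, numeric(1), "peak_frequency"),
      is_fast = vapply(chr, `[[`, logical(1), "is_fast"),
      epoch_index = epoch_of((cands$onset_s + cands$offset_s) / 2),
      rejected_reason = cands$rejected_reason)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-subject spindle metrics
#'
#' Density (events per minute of N2), mean peak frequency, mean peak power,
#' and fast-spindle percent, per channel and averaged across channels.
#'
#' @param events Output of [detect_spindles()]; rejected rows are dropped
#'   here.
#' @param grid Epoch grid (N2 minutes).
#' @param channels Channels to summarize (a channel with no events still
#'   contributes a zero-density row); defaults to those present in `events`.
#' @return data.frame with one row per channel plus a `"average"` row:
#'   `channel`, `n_events`, `n2_minutes`, `density`, `mean_frequency`,
#'   `mean_power`, `fast_percent`, `flagged`.
#' @export
summarize_metrics <- function(events, grid, channels = NULL) {
  kept <- events[events$rejected_reason == "", , drop = FALSE]
  n2_min <- sum(grid$stage == "N2") * 30 / 60
  chans <- channels %||% unique(events$channel)
  if (!length(chans)) chans <- character(0)
  rows <- lapply(chans, function(ch) {
    ev <- kept[kept$channel == ch, , drop = FALSE]
    if (n2_min <= 0) {
      return(data.frame(channel = ch, n_events = nrow(ev), n2_minutes = 0,
                        density = NA_real_, mean_frequency = NA_real_,
                        mean_power = NA_real_, fast_percent = NA_real_,
                        flagged = TRUE))
    }
    data.frame(
      channel = ch, n_events = nrow(ev), n2_minutes = n2_min,
      density = nrow(ev) / n2_min,
      mean_frequency = if (nrow(ev)) mean(ev$peak_freq_hz) else NA_real_,
      mean_power = if (nrow(ev)) mean(ev$peak_power_uv2) else NA_real_,
      fast_percent = if (nrow(ev)) 100 * mean(ev$is_fast) else NA_real_,
      flagged = FALSE)
  })
  per_ch <- do.call(rbind, rows)
  if (is.null(per_ch) || nrow(per_ch) == 0L) {
    return(data.frame(channel = "average", n_events = 0L, n2_minutes = n2_min,
                      density = if (n2_min > 0) 0 else NA_real_,
                      mean_frequency = NA_real_, mean_power = NA_real_,
                      fast_percent = NA_real_, flagged = n2_min <= 0))
  }
  avg <- data.frame(
    channel = "average",
    n_events = mean(per_ch$n_events),
    n2_minutes = n2_min,
    density = mean(per_ch$density),
    mean_frequency = mean(per_ch$mean_frequency),
    mean_power = mean(per_ch$mean_power),
    fast_percent = mean(per_ch$fast_percent),
    flagged = any(per_ch$flagged))
  out <- rbind(per_ch, avg)
  rownames(out) <- NULL
  out
}
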