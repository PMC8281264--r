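# Synthetic staged sleep EEG with ground-truth spindle events.
#
# The generator emulates the signal content the detection pipeline assumes:
# a 1/f background, spindle bursts (sinusoid under a raised-cosine envelope,
# so their band power is analytically known), alpha-range contaminant
# bursts, scored arousals, and high-amplitude movement artifacts, laid over
# a user-specified stage sequence. Every embedded event is returned as exact
# ground truth so detector performance can be scored without human scoring.

default_stage_sequence <- function() {
  data.frame(stage = c("W", "N1", "N2", "N3", "N2", "R"),
             minutes = c(2, 3, 20, 15, 15, 5))
}

#' Configuration for the sleep-EEG simulator
#'
#' Defaults describe a plausible pediatric central-EEG night segment:
#' 10 uV RMS 1/f background (slope 1.5), 4 spindles per minute of N2 at
#' 11-15 Hz lasting 0.5-2 s with 30 uV peak envelope (3x the background
#' RMS), one alpha contaminant burst per minute of N2, 10 arousals and
#' 15 movement artifacts per hour.
#'
#' @param sampling_rate 100 or 200 Hz.
#' @param background_slope 1/f exponent of the background PSD.
#' @param background_rms Background RMS amplitude, uV.
#' @param spindle_rate Spindle events per minute of N2.
#' @param spindle_freq_range Spindle frequency interval, must lie in
#'   \[10, 16\] Hz.
#' @param spindle_duration_range Spindle duration interval, s.
#' @param spindle_amplitude Peak envelope amplitude, uV.
#' @param alpha_contaminant_rate Alpha-burst events per minute of N2.
#' @param alpha_freq_range Contaminant frequency interval, Hz.
#' @param arousal_rate Arousals per hour of recording.
#' @param artifact_rate Movement artifacts per hour of recording.
#' @param artifact_amplitude Artifact peak amplitude, uV.
#' @param stage_sequence data.frame (`stage`, `minutes`); total minutes set
#'   the recording duration.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return List of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(sampling_rate = 100,
                           background_slope = 1.5,
                           background_rms = 10,
                           spindle_rate = 4,
                           spindle_freq_range = c(11, 15),
                           spindle_duration_range = c(0.5, 2),
                           spindle_amplitude = 30,
                           alpha_contaminant_rate = 1,
                           alpha_freq_range = c(8, 9.5),
                           arousal_rate = 10,
                           artifact_rate = 15,
                           artifact_amplitude = 500,
                           stage_sequence = default_stage_sequence(),
                           seed = 1L) {
  if (!sampling_rate %in% c(100, 200)) {
    stopf("sampling_rate must be 100 or 200 Hz")
  }
  if (spindle_freq_range[1] < 10 || spindle_freq_range[2] > 16 ||
      diff(spindle_freq_range) < 0) {
    stopf("spindle_freq_range must be an interval within [10, 16] Hz")
  }
  if (any(spindle_duration_range <= 0)) stopf("spindle durations must be > 0")
  rates <- c(spindle_rate, alpha_contaminant_rate, arousal_rate, artifact_rate)
  if (any(rates < 0)) stopf("event rates must be >= 0")
  bad <- setdiff(unique(stage_sequence$stage), SLEEP_STAGES)
  if (length(bad)) {
    stopf("invalid stage label(s) in stage_sequence: %s",
          paste(sQuote(bad), collapse = ", "))
  }
  structure(
    list(sampling_rate = sampling_rate, background_slope = background_slope,
         background_rms = background_rms, spindle_rate = spindle_rate,
         spindle_freq_range = spindle_freq_range,
         spindle_duration_range = spindle_duration_range,
         spindle_amplitude = spindle_amplitude,
         alpha_contaminant_rate = alpha_contaminant_rate,
         alpha_freq_range = alpha_freq_range,
         arousal_rate = arousal_rate, artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude,
         stage_sequence = stage_sequence,
         duration = sum(stage_sequence$minutes) * 60,
         seed = as.integer(seed)),
    class = "eeg_sim_config"
  )
}

# 1/f background by spectral shaping of white noise; slope is exact on the
# PSD because amplitudes scale as f^(-slope/2). Shaping is flattened below
# 0.5 Hz to keep total variance finite; the band limit removes <0.3 Hz anyway.
sim_background <- function(n, fs, slope, rms) {
  if (rms <= 0) return(numeric(n))
  w <- rnorm(n)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  amp <- ifelse(f >= 0.5, f^(-slope / 2), 0.5^(-slope / 2))
  amp[1] <- 0                                # remove DC
  x <- Re(fft(fft(w) * amp, inverse = TRUE)) / n
  x / sd(x) * rms
}

# Sinusoidal burst under a raised-cosine (Hann) envelope.
burst_wave <- function(fs, duration, freq, amplitude, phase) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * sin(2 * pi * freq * t + phase) * hann_window(length(t))
}

# Poisson placement of events inside eligible epochs, rejecting overlaps
# with previously placed intervals.
place_events <- function(n_events, epochs, dur_range, busy) {
  placed <- data.frame(onset = numeric(0), offset = numeric(0))
  if (n_events == 0L || nrow(epochs) == 0L) return(placed)
  tries <- 0L
  while (nrow(placed) < n_events && tries < n_events * 50L) {
    tries <- tries + 1L
    dur <- runif(1, dur_range[1], dur_range[2])
    ep <- epochs[sample.int(nrow(epochs), 1L), ]
    if (ep$end_s - ep$start_s < dur) next
    onset <- runif(1, ep$start_s, ep$end_s - dur)
    offset <- onset + dur
    clash <- any(interval_overlap(busy$onset, busy$offset, onset, offset) > 0) ||
      any(interval_overlap(placed$onset, placed$offset, onset, offset) > 0)
    if (!clash) placed <- rbind(placed, data.frame(onset = onset, offset = offset))
  }
  placed[order(placed$onset), , drop = FALSE]
}

#' Simulate a staged sleep EEG recording with ground truth
#'
#' Produces a two-channel (C3-M2, C4-M1) recording in microvolts. Spindle
#' and contaminant bursts are added identically to both channels over
#' channel-independent 1/f backgrounds; the returned event list is the exact
#' ground truth.
#'
#' @param config An [eeg_sim_config()].
#' @return List: `recording` ([sleep_recording()]), `hypnogram`, `events`
#'   (data.frame `onset_s`, `offset_s`, `kind`, `frequency_hz`,
#'   `amplitude_uv`), and `annotations` (arousal/artifact intervals).
#' @export
simulate_sleep_eeg <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  fs <- config$sampling_rate
  n <- config$duration * fs
  stages <- rep(config$stage_sequence$stage,
                times = config$stage_sequence$minutes * 2)
  hyp <- as_hypnogram(stages)
  grid <- data.frame(epoch_index = seq_along(stages) - 1L,
                     start_s = (seq_along(stages) - 1L) * 30,
                     end_s = seq_along(stages) * 30,
                     stage = stages)
  n2 <- grid[grid$stage == "N2", , drop = FALSE]
  sleep_min_n2 <- nrow(n2) / 2
  hours <- config$duration / 3600

  with_seed(config$seed, {
    c3 <- sim_background(n, fs, config$background_slope, config$background_rms)
    c4 <- sim_background(n, fs, config$background_slope, config$background_rms)

    events <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                         kind = character(0), frequency_hz = numeric(0),
                         amplitude_uv = numeric(0))
    busy <- data.frame(onset = numeric(0), offset = numeric(0))
    add_bursts <- function(kind, count, epochs, dur_range, freq_range, amp) {
      pos <- place_events(count, epochs, dur_range, busy)
      for (i in seq_len(nrow(pos))) {
        freq <- runif(1, freq_range[1], freq_range[2])
        wave <- burst_wave(fs, pos$offset[i] - pos$onset[i], freq, amp,
                           runif(1, 0, 2 * pi))
        idx <- round(pos$onset[i] * fs) + seq_along(wave)
        c3[idx] <<- c3[idx] + wave
        c4[idx] <<- c4[idx] + wave
        events <<- rbind(events, data.frame(
          onset_s = pos$onset[i], offset_s = pos$offset[i], kind = kind,
          frequency_hz = freq, amplitude_uv = amp))
      }
      busy <<- rbind(busy, pos)
    }

    add_bursts("spindle", rpois(1, config$spindle_rate * sleep_min_n2),
               n2, config$spindle_duration_range, config$spindle_freq_range,
               config$spindle_amplitude)
    add_bursts("alpha_burst",
               rpois(1, config$alpha_contaminant_rate * sleep_min_n2),
               n2, c(0.8, 2), config$alpha_freq_range,
               config$spindle_amplitude)

    sleep_epochs <- grid[grid$stage != "W", , drop = FALSE]
    aro <- place_events(rpois(1, config$arousal_rate * hours),
                        sleep_epochs, c(3, 10), busy)
    if (nrow(aro)) {
      for (i in seq_len(nrow(aro))) {
        freq <- runif(1, 8, 12)
        wave <- burst_wave(fs, aro$offset[i] - aro$onset[i], freq,
                           config$background_rms * 1.5, runif(1, 0, 2 * pi))
        idx <- round(aro$onset[i] * fs) + seq_along(wave)
        c3[idx] <- c3[idx] + wave
        c4[idx] <- c4[idx] + wave
      }
      events <- rbind(events, data.frame(
        onset_s = aro$onset, offset_s = aro$offset, kind = "arousal",
        frequency_hz = NA_real_, amplitude_uv = NA_real_))
      busy <- rbind(busy, aro)
    }

    art <- place_events(rpois(1, config$artifact_rate * hours),
                        grid, c(0.5, 1.5), busy)
    if (nrow(art)) {
      for (i in seq_len(nrow(art))) {
        wave <- burst_wave(fs, art$offset[i] - art$onset[i], 2,
                           config$artifact_amplitude, runif(1, 0, 2 * pi))
        idx <- round(art$onset[i] * fs) + seq_along(wave)
        c3[idx] <- c3[idx] + wave
        c4[idx] <- c4[idx] + wave
      }
      events <- rbind(events, data.frame(
        onset_s = art$onset, offset_s = art$offset, kind = "artifact",
        frequency_hz = NA_real_, amplitude_uv = config$artifact_amplitude))
    }

    events <- events[order(events$onset_s), , drop = FALSE]
    rownames(events) <- NULL
    ann <- events[events$kind %in% c("arousal", "artifact"),
                  c("onset_s", "offset_s", "kind")]
    names(ann)[3] <- "label"
    rownames(ann) <- NULL

    list(
      recording = sleep_recording(list(`C3-M2` = c3, `C4-M1` = c4), fs),
      hypnogram = hyp,
      events = events,
      annotations = if (nrow(ann)) ann else empty_annotations()
    )
  })
}

#' Write a simulated recording to disk (EDF + sidecar tables)
#'
#' @param sim Result of [simulate_sleep_eeg()].
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used as the file stem.
#' @return Named character vector of written paths.
#' @export
write_simulated_recording <- function(sim, dir, id = "subject01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edf = file.path(dir, paste0(id, ".edf")),
    hypnogram = file.path(dir, paste0(id, "_hypnogram.tsv")),
    annotations = file.path(dir, paste0(id, "_annotations.tsv")),
    events = file.path(dir, paste0(id, "_events.tsv"))
  )
  write_edf(paths["edf"], sim$recording$signals, sim$recording$sampling_rate)
  write.table(
    data.frame(epoch_index = seq_along(sim$hypnogram) - 1L,
               stage = as.character(sim$hypnogram)),
    paths["hypnogram"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(sim$annotations, paths["annotations"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(sim$events, paths["events"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  paths
}
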