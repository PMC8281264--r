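# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the candidate-run oracle is a naive while-loop
# transcription of the detection rules, the envelope oracle thresholds the
# clean burst component directly, and spectral expectations come from
# Parseval / time-domain variance.

# Naive enumeration of spindle candidates on a ratio/power track.
# Rules: a candidate opens at the first window of a maximal contiguous run
# of >= min_run windows with ratio > onset_thr; scanning forward, it closes
# at the first window with ratio < offset_thr or power < frac * running
# peak, provided that window starts within horizon seconds of onset; a
# contiguity break closes it at the last contiguous window; no termination
# within the horizon discards the whole run; runs starting at or before the
# previous offset are skipped.
oracle_candidates <- function(start_s, ratio, power,
                              onset_thr = 3, min_run = 5,
                              offset_thr = 1.5, frac = 0.2, horizon = 5,
                              step = 0.2) {
  n <- length(ratio)
  out <- data.frame(onset_idx = integer(0), offset_idx = integer(0))
  contig <- c(FALSE, abs(diff(start_s) - step) < 1e-6)
  i <- 1L
  last_off <- 0L
  while (i <= n) {
    # maximal run start: above threshold, and previous window not part of
    # the same contiguous supra-threshold stretch
    if (ratio[i] > onset_thr &&
        (i == 1L || !contig[i] || ratio[i - 1L] <= onset_thr)) {
      len <- 1L
      while (i + len <= n && contig[i + len] && ratio[i + len] > onset_thr) {
        len <- len + 1L
      }
      if (len >= min_run && i > last_off) {
        peak <- power[i]
        j <- i + 1L
        off <- NA_integer_
        while (j <= n) {
          if (!contig[j]) { off <- j - 1L; break }
          if (start_s[j] - start_s[i] > horizon) break
          peak <- max(peak, power[j])
          if (ratio[j] < offset_thr || power[j] < frac * peak) { off <- j; break }
          j <- j + 1L
        }
        if (is.na(off) && j > n) off <- n
        if (!is.na(off)) {
          out <- rbind(out, data.frame(onset_idx = i, offset_idx = off))
          last_off <- off
        }
      }
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  out
}

# Random ratio/power tracks for the oracle-equivalence property. Power is
# tied to ratio through a positive per-epoch reference so both termination
# criteria are exercised.
random_track <- function(n = 200, step = 0.2) {
  ratio <- rexp(n, rate = 1 / 2)              # heavy enough tail to trigger
  ref <- rexp(1, 1) + 0.5
  structure(
    data.frame(epoch_index = 0L, start_s = (seq_len(n) - 1) * step,
               power_s = ratio * ref, ratio = ratio,
               alpha_ratio = rexp(n, 1), beta_ratio = rexp(n, 1)),
    window_length = 1, window_step = step)
}

# Interval events recovered from the clean burst-only component by direct
# envelope thresholding (rolling peak of |x| over half a cycle).
oracle_envelope_events <- function(x, fs, threshold, min_gap_s = 0.2) {
  above <- abs(x) > threshold
  # close sub-cycle zero-crossing gaps
  w <- round(fs * 0.06)
  above <- as.vector(stats::filter(as.numeric(above), rep(1, 2 * w + 1),
                                   sides = 2))
  above <- !is.na(above) & above > 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(onset = (starts[r$values] - 1) / fs,
                    offset = ends[r$values] / fs)
  if (nrow(seg) < 2L) return(seg)
  merged <- seg[1, ]
  for (k in 2:nrow(seg)) {
    if (seg$onset[k] - merged$offset[nrow(merged)] < min_gap_s) {
      merged$offset[nrow(merged)] <- seg$offset[k]
    } else {
      merged <- rbind(merged, seg[k, ])
    }
  }
  merged
}

# Event-level matching: overlap >= 50% of the shorter event, one-to-one.
match_events <- function(truth, detected) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(truth$offset_s[i], detected$offset_s) -
      pmax(truth$onset_s[i], detected$onset_s)
    shorter <- pmin(truth$offset_s[i] - truth$onset_s[i],
                    detected$offset_s - detected$onset_s)
    j <- which(ov >= 0.5 * shorter & !used)
    if (length(j)) { tp <- tp + 1L; used[j[1]] <- TRUE }
  }
  list(sensitivity = tp / nrow(truth), precision = sum(used) / nrow(detected))
}

# Short all-N2 simulation used by several tests.
n2_sim_config <- function(minutes = 10, seed = 1, ...) {
  eeg_sim_config(stage_sequence = data.frame(stage = "N2", minutes = minutes),
                 seed = seed, ...)
}
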