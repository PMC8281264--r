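# Recording containers, hypnogram/annotation I/O, epoching, channel policy,
# and the study-wide 0.3-30 Hz band limit.
#
# Conventions used throughout the package: time is seconds from recording
# start, intervals are half-open [onset, offset), epochs are 0-indexed 30-s
# windows. An event ending exactly on an epoch boundary belongs to the
# earlier epoch only.

SLEEP_STAGES <- c("W", "N1", "N2", "N3", "R")
ANNOTATION_LABELS <- c("arousal", "artifact")

#' Construct a sleep recording
#'
#' @param signals Named list of numeric vectors, microvolts. Channel labels
#'   are normalized so the A1/A2 mastoid-reference dialect maps onto M1/M2
#'   (e.g. `C3-A2` becomes `C3-M2`).
#' @param sampling_rate Hz, shared by all channels.
#' @param start_time Clock time string, informational.
#' @return Object of class `sleep_recording`.
#' @export
sleep_recording <- function(signals, sampling_rate, start_time = "00.00.00") {
  stopifnot(is.list(signals), length(signals) >= 1L)
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1L) stopf("channels must have equal length")
  names(signals) <- normalize_channel_label(names(signals))
  structure(
    list(signals = signals, sampling_rate = sampling_rate,
         start_time = start_time, duration = lens[[1]] / sampling_rate),
    class = "sleep_recording"
  )
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> %d channel(s) [%s], %g Hz, %.1f s\n",
              length(x$signals), paste(names(x$signals), collapse = ", "),
              x$sampling_rate, x$duration))
  invisible(x)
}

#' Normalize EEG channel labels across reference dialects
#'
#' Maps the older A1/A2 (ear) reference naming onto M1/M2 (mastoid) and
#' upper-cases, so `c3-a2` and `C3-M2` refer to the same derivation.
#'
#' @param labels Character vector of channel labels.
#' @return Normalized labels.
#' @export
normalize_channel_label <- function(labels) {
  out <- toupper(trimws(labels))
  sub("-A([12])$", "-M\\1", out)
}

#' Read a hypnogram table
#'
#' Expects a two-column table (`epoch_index`, `stage`) with 0-based epoch
#' indices over fixed 30-s epochs and stages in W/N1/N2/N3/R.
#'
#' @param path TSV file path.
#' @return Character vector of stages with class `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  stages <- toupper(trimws(tab$stage))
  as_hypnogram(stages)
}

#' @rdname read_hypnogram
#' @param stages Character vector of stage codes.
#' @export
as_hypnogram <- function(stages) {
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) {
    stopf("unknown sleep stage code(s): %s (expected %s)",
          paste(sQuote(bad), collapse = ", "),
          paste(SLEEP_STAGES, collapse = "/"))
  }
  structure(stages, class = "hypnogram", epoch_length = 30)
}

#' Read an annotation track (arousals and artifacts)
#'
#' @param path TSV with columns `onset_s`, `offset_s`, `label`
#'   (arousal/artifact). Intervals are half-open.
#' @return data.frame with those columns (empty if `path` is `NULL`).
#' @export
read_annotations <- function(path) {
  if (is.null(path)) return(empty_annotations())
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("numeric", "numeric", "character"))
  as_annotations(tab)
}

as_annotations <- function(tab) {
  if (nrow(tab) == 0L) return(empty_annotations())
  tab$label <- tolower(trimws(tab$label))
  bad <- setdiff(unique(tab$label), ANNOTATION_LABELS)
  if (length(bad)) stopf("unknown annotation label(s): %s",
                         paste(sQuote(bad), collapse = ", "))
  if (any(tab$onset_s >= tab$offset_s)) stopf("annotation onset must precede offset")
  tab[c("onset_s", "offset_s", "label")]
}

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             label = character(0))
}

#' Build the 30-s epoch grid
#'
#' Epochs partition the scored portion of the recording: the grid covers
#' `min(length(hypnogram), floor(duration / 30))` epochs, so trailing
#' unscored samples (or trailing hypnogram rows without signal) are dropped.
#'
#' @param recording A [sleep_recording()].
#' @param hypnogram A `hypnogram` vector.
#' @param annotations Annotation data.frame (artifact intervals set the
#'   per-epoch `artifact_flag`).
#' @return data.frame: `epoch_index` (0-based), `start_s`, `end_s`, `stage`,
#'   `artifact_flag`.
#' @export
epoch_grid <- function(recording, hypnogram, annotations = NULL) {
  n_fit <- floor(recording$duration / 30)
  n <- min(length(hypnogram), n_fit)
  grid <- data.frame(
    epoch_index = seq_len(n) - 1L,
    start_s = (seq_len(n) - 1L) * 30,
    end_s = seq_len(n) * 30,
    stage = as.character(hypnogram[seq_len(n)]),
    artifact_flag = FALSE
  )
  if (!is.null(annotations) && nrow(annotations)) {
    art <- annotations[annotations$label == "artifact", , drop = FALSE]
    for (i in seq_len(nrow(art))) {
      hit <- interval_overlap(grid$start_s, grid$end_s,
                              art$onset_s[i], art$offset_s[i]) > 0
      grid$artifact_flag <- grid$artifact_flag | hit
    }
  }
  grid
}

# epoch containing a time point (or an event assigned by its midpoint);
# a point exactly on a boundary belongs to the later epoch, so an event
# *ending* at a boundary (half-open) stays in the earlier one.
epoch_of <- function(time_s) as.integer(floor(time_s / 30))

#' Select the central derivation pair
#'
#' Prefers contralaterally referenced central channels (C3-M2, C4-M1); under
#' `prefer_contralateral` it falls back to the ipsilateral pair (C3-M1,
#' C4-M2) when the contralateral pair is absent, recording which reference
#' was used for downstream reporting.
#'
#' @param recording A [sleep_recording()].
#' @param policy `"prefer_contralateral"` or `"ipsilateral_only"`.
#' @return List: `left`, `right` (channel labels), `reference`.
#' @export
select_central_channels <- function(recording,
                                    policy = c("prefer_contralateral",
                                               "ipsilateral_only")) {
  policy <- match.arg(policy)
  have <- names(recording$signals)
  contra <- c(left = "C3-M2", right = "C4-M1")
  ipsi <- c(left = "C3-M1", right = "C4-M2")
  pick <- function(pair, ref) list(left = unname(pair["left"]),
                                   right = unname(pair["right"]),
                                   reference = ref)
  if (policy == "prefer_contralateral" && all(contra %in% have)) {
    return(pick(contra, "contralateral"))
  }
  if (all(ipsi %in% have)) return(pick(ipsi, "ipsilateral"))
  stopf("no usable central derivation pair (need %s or %s); available: %s",
        paste(contra, collapse = "/"), paste(ipsi, collapse = "/"),
        paste(have, collapse = ", "))
}

#' Apply the study-wide 0.3-30 Hz band limit
#'
#' Zero-phase (forward-backward) Butterworth band-pass, order 4 per pass,
#' applied to every channel. Removes DC and activity outside the common EEG
#' range so recordings from different acquisition systems are comparable.
#'
#' @param recording A [sleep_recording()].
#' @param band Pass band in Hz.
#' @param order Butterworth order per pass.
#' @return A band-limited `sleep_recording`.
#' @export
bandlimit <- function(recording, band = c(0.3, 30), order = 4) {
  fs <- recording$sampling_rate
  if (fs < 100) stopf("sampling rate %g Hz below supported minimum (100 Hz)", fs)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  recording$signals <- lapply(recording$signals, function(x) {
    as.numeric(signal::filtfilt(bf, x - mean(x)))
  })
  recording
}

#' Read a full recording: EDF + hypnogram + annotations
#'
#' @param edf_path EDF file.
#' @param hypnogram_path Hypnogram TSV (`epoch_index`, `stage`).
#' @param annotations_path Optional annotation TSV.
#' @return List: `recording`, `hypnogram`, `annotations`.
#' @export
read_recording <- function(edf_path, hypnogram_path, annotations_path = NULL) {
  edf <- read_edf(edf_path)
  rec <- sleep_recording(edf$signals, edf$sampling_rate, edf$start_time)
  central <- grepl("^C[34]", names(rec$signals))
  if (!any(central)) {
    stopf("no central EEG channel (C3/C4) in EDF; found: %s",
          paste(names(rec$signals), collapse = ", "))
  }
  list(recording = rec,
       hypnogram = read_hypnogram(hypnogram_path),
       annotations = read_annotations(annotations_path))
}
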