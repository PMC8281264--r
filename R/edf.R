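# Minimal European Data Format (EDF) I/O.
#
# EDF stores a fixed 256-byte ASCII header, one 256-byte ASCII block per
# signal, then data records of little-endian 16-bit integers. Only the
# features needed for single-rate polysomnography exports are implemented:
# all signals share one sampling rate, records last 1 s, and the physical
# dimension must be uV or mV (mV is converted to uV on read).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edf_pad(s, width)
}

#' Write signals to a 16-bit EDF file
#'
#' Signals are quantized to 16 bits over a symmetric physical range chosen
#' per channel from the data, so the worst-case round-trip error is
#' `max(abs(x)) / 32767` per channel.
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (one per channel, equal
#'   lengths), in microvolts.
#' @param sampling_rate Samples per second (integer); shared by all channels.
#' @param start_time Recording start clock time, `"hh.mm.ss"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, sampling_rate, start_time = "00.00.00") {
  stopifnot(is.list(signals), length(signals) >= 1L, !is.null(names(signals)))
  ns <- length(signals)
  nlen <- unique(vapply(signals, length, integer(1)))
  if (length(nlen) != 1L) stopf("all channels must have equal length")
  if (sampling_rate != round(sampling_rate)) {
    stopf("sampling_rate must be an integer number of Hz")
  }
  spr <- as.integer(sampling_rate)          # samples per 1-s record
  n_rec <- nlen %/% spr
  if (n_rec < 1L) stopf("recording shorter than one 1-s data record")

  phys_max <- vapply(signals, function(x) {
    m <- max(abs(x[seq_len(n_rec * spr)]), na.rm = TRUE)
    m <- if (!is.finite(m) || m == 0) 1 else m * 1.0001
    # quantize against the value the header actually stores
    as.numeric(trimws(edf_num(m, 8)))
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.01", 8), edf_pad(start_time, 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(
    hdr,
    field(names(signals), 16), field(rep("", ns), 80), field(rep("uV", ns), 8),
    paste(vapply(-phys_max, edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(rep(spr, ns), 8), field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  dig <- lapply(seq_len(ns), function(j) {
    # inverse of the EDF affine map over [-pm, pm] x [-32768, 32767]
    gain <- 2 * phys_max[j] / 65535
    offset <- phys_max[j] - gain * 32767
    d <- round((signals[[j]][seq_len(n_rec * spr)] - offset) / gain)
    as.integer(pmin(32767, pmax(-32768, d)))
  })
  # interleave by record: record r = channel 1 samples, channel 2 samples, ...
  out <- integer(n_rec * spr * ns)
  for (j in seq_len(ns)) {
    idx <- rep(seq_len(spr), n_rec) +
      spr * ns * rep(seq_len(n_rec) - 1L, each = spr) + spr * (j - 1L)
    out[idx] <- dig[[j]]
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

edf_parse_num <- function(raw, field) {
  x <- suppressWarnings(as.numeric(trimws(raw)))
  if (any(is.na(x))) {
    stopf("EDF header field '%s' is not numeric: '%s'", field,
          trimws(raw[is.na(x)][1]))
  }
  x
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors in uV),
#'   `sampling_rate` (Hz, common to all channels), `start_time`, and
#'   `n_records`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  take <- function(n) rawToChar(readBin(con, "raw", n))
  version <- trimws(take(8))
  if (version != "0") stopf("EDF header field 'version' invalid: '%s'", version)
  take(80); take(80); take(8)
  start_time <- trimws(take(8))
  header_bytes <- edf_parse_num(take(8), "header bytes")
  take(44)
  n_rec <- edf_parse_num(take(8), "number of data records")
  rec_dur <- edf_parse_num(take(8), "record duration")
  ns <- as.integer(edf_parse_num(take(4), "number of signals"))
  if (ns < 1L) stopf("EDF header field 'number of signals' invalid: %d", ns)
  if (header_bytes != 256L * (ns + 1L)) {
    stopf("EDF header field 'header bytes' inconsistent: %s", header_bytes)
  }
  fld <- function(width) vapply(seq_len(ns), function(i) trimws(take(width)), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  phys_min <- edf_parse_num(fld(8), "physical minimum")
  phys_max <- edf_parse_num(fld(8), "physical maximum")
  dig_min <- edf_parse_num(fld(8), "digital minimum")
  dig_max <- edf_parse_num(fld(8), "digital maximum")
  fld(80)
  spr <- as.integer(edf_parse_num(fld(8), "samples per record"))
  fld(32)

  scale_unit <- ifelse(dims %in% c("uV", "µV"), 1,
                       ifelse(dims == "mV", 1000, NA_real_))
  if (any(is.na(scale_unit))) {
    stopf("unsupported physical dimension '%s' (need uV or mV)",
          dims[is.na(scale_unit)][1])
  }
  if (length(unique(spr / rec_dur)) != 1L) {
    stopf("channels have differing sampling rates; harmonization not supported")
  }

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr)) stopf("EDF data section truncated")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max
  signals <- vector("list", ns)
  names(signals) <- labels
  rec_len <- sum(spr)
  starts <- cumsum(c(0L, spr[-ns]))
  for (j in seq_len(ns)) {
    idx <- rep(seq_len(spr[j]), n_rec) + starts[j] +
      rec_len * rep(seq_len(n_rec) - 1L, each = spr[j])
    signals[[j]] <- (raw[idx] * gain[j] + offset[j]) * scale_unit[j]
  }
  list(signals = signals, sampling_rate = spr[1] / rec_dur,
       start_time = start_time, n_records = n_rec)
}
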