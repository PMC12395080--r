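# Minimal EDF (European Data Format) I/O: 16-bit integer samples, ASCII
# header. Covers the plain-EDF subset needed to interchange clinical-style
# multichannel recordings; EDF+ annotation signals are dropped on read.

edf_field <- function(con, nchars, name) {
  raw <- readChar(con, nchars, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < nchars) {
    stop(sprintf("malformed EDF header: truncated field '%s'", name), call. = FALSE)
  }
  trimws(raw)
}

edf_num <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("malformed EDF header: field '%s' is not numeric ('%s')",
                             name, x), call. = FALSE)
  v
}

#' Normalize an EDF channel label to a bare 10--20 name
#'
#' Strips common dialect decorations such as the `"EEG "` prefix and
#' `"-Ref"`/`"-REF"`/`"-A1"` reference suffixes; unrecognized labels pass
#' through verbatim.
#'
#' @param label character vector of raw EDF labels.
#' @return Character vector of cleaned labels.
#' @export
normalize_channel_label <- function(label) {
  out <- trimws(label)
  out <- sub("^EEG[ _]+", "", out, ignore.case = TRUE)
  out <- sub("[-_](Ref|REF|ref|LE|A1|A2|AVG)$", "", out)
  trimws(out)
}

#' Read an EDF file as a continuous recording
#'
#' Supports plain EDF with 16-bit samples. All retained signals must share
#' one sampling rate; mixed rates raise an error rather than resampling
#' implicitly. EDF+ annotation signals are dropped. Labels are normalized
#' via [normalize_channel_label()].
#'
#' @param path path to an EDF file.
#' @return A [continuous_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) < 256) {
    stop("malformed EDF header: file shorter than the 256-byte fixed header",
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8, "version")
  if (version != "0") stop("malformed EDF header: field 'version' must be '0'", call. = FALSE)
  edf_field(con, 80, "patient_id"); edf_field(con, 80, "recording_id")
  edf_field(con, 8, "startdate"); edf_field(con, 8, "starttime")
  header_bytes <- edf_num(edf_field(con, 8, "header_bytes"), "header_bytes")
  edf_field(con, 44, "reserved")
  n_records <- edf_num(edf_field(con, 8, "n_data_records"), "n_data_records")
  rec_dur <- edf_num(edf_field(con, 8, "record_duration"), "record_duration")
  ns <- edf_num(edf_field(con, 4, "n_signals"), "n_signals")
  if (ns < 1) stop("malformed EDF header: field 'n_signals' must be >= 1", call. = FALSE)
  rdfield <- function(nchars, name) {
    vapply(seq_len(ns), function(i) edf_field(con, nchars, sprintf("%s[%d]", name, i)),
           character(1))
  }
  labels <- rdfield(16, "label")
  rdfield(80, "transducer"); rdfield(8, "phys_dim")
  phys_min <- as.numeric(rdfield(8, "phys_min"))
  phys_max <- as.numeric(rdfield(8, "phys_max"))
  dig_min <- as.numeric(rdfield(8, "dig_min"))
  dig_max <- as.numeric(rdfield(8, "dig_max"))
  rdfield(80, "prefiltering")
  spr <- as.numeric(rdfield(8, "samples_per_record"))
  rdfield(32, "signal_reserved")
  if (any(is.na(phys_min) | is.na(phys_max) | is.na(dig_min) | is.na(dig_max) | is.na(spr))) {
    stop("malformed EDF header: non-numeric signal scaling field", call. = FALSE)
  }
  expected_header <- 256 + 256 * ns
  if (header_bytes != expected_header) {
    stop(sprintf("malformed EDF header: field 'header_bytes' is %d, expected %d",
                 header_bytes, expected_header), call. = FALSE)
  }
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop("EDF file contains no data signals", call. = FALSE)
  if (length(unique(spr[keep])) > 1L) {
    stop("unsupported input: signals have mixed sampling rates (no implicit resampling)",
         call. = FALSE)
  }
  fs <- spr[keep][1] / rec_dur
  data <- vector("list", ns)
  for (i in which(keep)) data[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                      endian = "little")
      if (length(vals) < spr[i]) {
        stop(sprintf("malformed EDF data: record %d of signal %d truncated", r, i),
             call. = FALSE)
      }
      if (keep[i]) data[[i]][[r]] <- vals
    }
  }
  kept <- which(keep)
  samples <- do.call(rbind, lapply(kept, function(i) {
    dig <- unlist(data[[i]], use.names = FALSE)
    (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i]) +
      phys_min[i]
  }))
  continuous_recording(samples, fs, normalize_channel_label(labels[kept]))
}

#' Write a recording to an EDF file
#'
#' 16-bit plain EDF, one-second data records. Epoched recordings are
#' concatenated in epoch order. Amplitudes are scaled per channel to the
#' full digital range, so the round-trip error is bounded by the 16-bit
#' quantization step.
#'
#' @param rec a [continuous_recording()] or [epoched_recording()].
#' @param path output path.
#' @param patient_id,recording_id free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "qeegmeta") {
  if (inherits(rec, "epoched_recording")) {
    samples <- do.call(cbind, rec$epochs)
  } else if (inherits(rec, "continuous_recording")) {
    samples <- rec$samples
  } else stop("unsupported recording class", call. = FALSE)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nch <- nrow(samples)
  n_records <- floor(ncol(samples) / fs)
  if (n_records < 1) stop("recording shorter than one 1-s data record", call. = FALSE)
  samples <- samples[, seq_len(n_records * fs), drop = FALSE]
  pmax_ <- apply(abs(samples), 1L, max)
  pmax_[pmax_ == 0] <- 1
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768; dig_max <- 32767
  fmt <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")
  fmtn <- function(x, w) {
    s <- formatC(x, width = w, format = "g", digits = 6)
    if (nchar(s) > w) s <- substr(s, 1, w)
    formatC(s, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    fmt("0", 8), fmt(patient_id, 80), fmt(recording_id, 80),
    fmt("01.01.00", 8), fmt("00.00.00", 8),
    fmt(as.character(256 + 256 * nch), 8), fmt("", 44),
    fmt(as.character(n_records), 8), fmt("1", 8), fmt(as.character(nch), 4)
  ), con, eos = NULL)
  field_block <- function(vals, w) {
    writeChar(paste(vapply(vals, fmt, character(1), w = w), collapse = ""),
              con, eos = NULL)
  }
  field_block(rec$channel_labels, 16)
  field_block(rep("", nch), 80)            # transducer
  field_block(rep("uV", nch), 8)           # physical dimension
  writeChar(paste(vapply(phys_min, fmtn, character(1), w = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_max, fmtn, character(1), w = 8), collapse = ""), con, eos = NULL)
  field_block(rep(as.character(dig_min), nch), 8)
  field_block(rep(as.character(dig_max), nch), 8)
  field_block(rep("", nch), 80)            # prefiltering
  field_block(rep(as.character(fs), nch), 8)
  field_block(rep("", nch), 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((samples[ch, cols] - phys_min[ch]) * scale[ch] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
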