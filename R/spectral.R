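#' Per-channel power spectrum of one epoch
#'
#' Single rectangular-window FFT of the full epoch (no taper by default,
#' matching a bare FFT analysis; set `taper = "hann"` to apply a Hann window
#' first). Power is returned on the one-sided grid k / epoch_len for
#' k = 0 .. N/2; the DC bin is retained here but excluded from every band
#' computation downstream.
#'
#' @param epoch channels x timepoints numeric matrix (finite).
#' @param fs sampling rate in Hz.
#' @param taper `"none"` (default) or `"hann"`.
#' @return A list of class `power_spectrum`: `freqs` (Hz), `power` (bins x
#'   channels, >= 0), `resolution` (Hz, = 1 / epoch length).
#' @export
epoch_spectrum <- function(epoch, fs, taper = c("none", "hann")) {
  taper <- match.arg(taper)
  stopifnot(is.matrix(epoch), is.numeric(epoch))
  if (!all(is.finite(epoch))) stop("epoch contains non-finite samples", call. = FALSE)
  n <- ncol(epoch)
  if (n < 2) stop("epoch must have at least 2 samples", call. = FALSE)
  x <- t(epoch)  # timepoints x channels for mvfft
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w
  }
  X <- stats::mvfft(x)
  nkeep <- floor(n / 2) + 1L
  power <- Mod(X[seq_len(nkeep), , drop = FALSE])^2 / n
  freqs <- (seq_len(nkeep) - 1) * fs / n
  structure(list(freqs = freqs, power = power, resolution = fs / n),
            class = "power_spectrum")
}

# band power per channel for one power_spectrum: 4 x channels matrix
band_power_matrix <- function(spec) {
  bands <- canonical_bands()
  out <- matrix(NA_real_, nrow = nrow(bands), ncol = ncol(spec$power),
                dimnames = list(bands$band, NULL))
  for (i in seq_len(nrow(bands))) {
    bins <- band_bins(spec$freqs, bands$f_lo[i], bands$f_hi[i],
                      closed_hi = bands$band[i] == "beta")
    out[i, ] <- colSums(spec$power[bins, , drop = FALSE])
  }
  out
}

#' Relative band power of a subject recording
#'
#' For every epoch and channel, band power is the sum of spectral power over
#' the band's bins; relative power is the band's share of the summed power
#' over delta + theta + alpha + beta (0.5--20 Hz). Values are averaged first
#' across channels within each epoch and then across epochs, yielding one
#' value per band per subject.
#'
#' @param rec an [epoched_recording()], already average-referenced.
#' @param taper passed to [epoch_spectrum()].
#' @return Named numeric vector (delta, theta, alpha, beta) summing to 1.
#' @export
relative_band_power <- function(rec, taper = "none") {
  stopifnot(inherits(rec, "epoched_recording"))
  specs <- lapply(rec$epochs, epoch_spectrum, fs = rec$fs, taper = taper)
  rel_power_from_spectra(specs)
}

rel_power_from_spectra <- function(specs) {
  per_epoch <- vapply(specs, function(spec) {
    bp <- band_power_matrix(spec)
    tot <- colSums(bp)
    if (any(tot <= 0)) {
      stop("degenerate signal: zero total band power in a channel-epoch", call. = FALSE)
    }
    rel <- sweep(bp, 2L, tot, "/")
    rowMeans(rel)  # average over channels first
  }, numeric(4))
  rowMeans(per_epoch)  # then over epochs
}

#' Peak frequency of the dominant rhythm
#'
#' For each channel, the power spectra of all epochs are averaged and the
#' peak is the frequency of the maximum bin within 4--13 Hz (ties broken
#' toward the lower frequency). The subject value is the mean over channels.
#'
#' @param rec an [epoched_recording()], already average-referenced.
#' @param f_lo,f_hi closed search range in Hz (default 4--13).
#' @param taper passed to [epoch_spectrum()].
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(rec, f_lo = 4, f_hi = 13, taper = "none") {
  stopifnot(inherits(rec, "epoched_recording"))
  specs <- lapply(rec$epochs, epoch_spectrum, fs = rec$fs, taper = taper)
  peak_from_spectra(specs, f_lo = f_lo, f_hi = f_hi)
}

peak_from_spectra <- function(specs, f_lo = 4, f_hi = 13) {
  avg <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  freqs <- specs[[1]]$freqs
  bins <- which(freqs >= f_lo & freqs <= f_hi)
  if (!length(bins)) stop("no spectral bins inside the search range", call. = FALSE)
  peaks <- apply(avg[bins, , drop = FALSE], 2L, function(p) freqs[bins][which.max(p)])
  mean(peaks)
}

#' Extract the full qEEG feature set for one subject
#'
#' Bundles relative band power, peak frequency, and the mean phase lag index
#' per band into one row: the per-subject feature vector on which all group
#' statistics operate.
#'
#' @param rec an [epoched_recording()], preprocessed (channels excluded,
#'   average-referenced).
#' @param edge_trim_s seconds trimmed from each end of the phase series
#'   before the PLI (Hilbert edge suppression); see [mean_pli()].
#' @return One-row data frame: subject_id, peak_frequency, rel_delta,
#'   rel_theta, rel_alpha, rel_beta, pli_delta, pli_theta, pli_alpha,
#'   pli_beta.
#' @export
extract_features <- function(rec, edge_trim_s = 0.5) {
  stopifnot(inherits(rec, "epoched_recording"))
  # one spectrum per epoch, shared between relative power and peak frequency
  specs <- lapply(rec$epochs, epoch_spectrum, fs = rec$fs)
  rel <- rel_power_from_spectra(specs)
  pk <- peak_from_spectra(specs)
  bands <- canonical_bands()
  band_list <- lapply(seq_len(nrow(bands)), function(i) {
    list(f_lo = bands$f_lo[i], f_hi = bands$f_hi[i], name = bands$band[i])
  })
  mats <- pli_matrices(rec, band_list, edge_trim_s = edge_trim_s)
  pli <- vapply(mats, function(M) mean(M[upper.tri(M)]), numeric(1))
  names(pli) <- bands$band
  data.frame(
    subject_id = if (!is.null(rec$meta$subject_id)) rec$meta$subject_id else NA_character_,
    peak_frequency = pk,
    rel_delta = rel[["delta"]], rel_theta = rel[["theta"]],
    rel_alpha = rel[["alpha"]], rel_beta = rel[["beta"]],
    pli_delta = pli[["delta"]], pli_theta = pli[["theta"]],
    pli_alpha = pli[["alpha"]], pli_beta = pli[["beta"]],
    stringsAsFactors = FALSE
  )
}

#' Names of the nine subject-level qEEG features
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("peak_frequency", "rel_delta", "rel_theta", "rel_alpha", "rel_beta",
    "pli_delta", "pli_theta", "pli_alpha", "pli_beta")
}
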