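#' Construct an epoched multichannel recording
#'
#' The unit on which all qEEG features are computed: a stack of fixed-length
#' epochs, each a channels x timepoints matrix, with channel labels, sampling
#' rate and optional subject metadata (site, etiology, delirium status).
#'
#' @param epochs list of numeric matrices, each channels x timepoints; all
#'   must share dimensions and contain only finite values.
#' @param channel_labels character vector of unique 10--20 channel names, one
#'   per row of each epoch.
#' @param fs sampling rate in Hz.
#' @param meta optional named list of subject metadata.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(epochs, channel_labels, fs, meta = list()) {
  stopifnot(is.list(epochs), length(epochs) >= 1L)
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  dims <- dim(epochs[[1]])
  for (e in epochs) {
    if (!is.matrix(e) || !is.numeric(e)) stop("each epoch must be a numeric matrix", call. = FALSE)
    if (!identical(dim(e), dims)) stop("all epochs must share the same dimensions", call. = FALSE)
    if (!all(is.finite(e))) stop("epochs contain non-finite samples", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dims[1]) {
    stop("channel_labels length must equal the number of epoch rows", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique", call. = FALSE)
  structure(
    list(epochs = epochs, channel_labels = channel_labels, fs = fs, meta = meta),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf(
    "<epoched_recording> %d epoch(s), %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
    length(x$epochs), d[1], d[2], x$fs, d[2] / x$fs
  ))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
n_epochs <- function(rec) UseMethod("n_epochs")

#' @export
n_epochs.epoched_recording <- function(rec) length(rec$epochs)

#' Construct a continuous multichannel recording
#'
#' @param samples numeric matrix, channels x timepoints.
#' @param fs sampling rate in Hz.
#' @param channel_labels unique channel names.
#' @param annotations optional data frame with columns `start_s`, `end_s`,
#'   `label` marking artifact spans or eyes-state intervals.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, fs, channel_labels,
                                 annotations = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop("one label per channel row required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("start_s", "end_s", "label") %in% names(annotations)))
  }
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         annotations = annotations),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.4g s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.null(x$annotations) && nrow(x$annotations)) {
    cat(sprintf("  %d annotation(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' Drop channels from a recording
#'
#' Removes the given channels, preserving the order of the remainder. No
#' interpolation of dropped channels is performed. Labels not present in the
#' recording are ignored with a warning.
#'
#' @param rec an `epoched_recording` or `continuous_recording`.
#' @param labels_to_drop character vector of channel labels to remove;
#'   defaults to the systematically excluded set A1, A2, Fp1, Fp2.
#' @return A recording of the same class with the remaining channels.
#' @export
exclude_channels <- function(rec, labels_to_drop = c("A1", "A2", "Fp1", "Fp2")) {
  labels_to_drop <- as.character(labels_to_drop)
  unknown <- setdiff(labels_to_drop, rec$channel_labels)
  if (length(unknown)) {
    warning("ignoring unknown channel label(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  keep <- !(rec$channel_labels %in% labels_to_drop)
  if (!any(keep)) stop("cannot drop every channel", call. = FALSE)
  if (all(keep)) return(rec)
  if (inherits(rec, "epoched_recording")) {
    rec$epochs <- lapply(rec$epochs, function(e) e[keep, , drop = FALSE])
  } else {
    rec$samples <- rec$samples[keep, , drop = FALSE]
  }
  rec$channel_labels <- rec$channel_labels[keep]
  rec
}

#' Re-reference to the average montage
#'
#' Subtracts, at every timepoint, the instantaneous mean over the retained
#' channels from each channel. Applied after channel exclusion: the reference
#' is computed over the analysis channel set only.
#'
#' @param rec an `epoched_recording` or `continuous_recording` with at least
#'   two channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  avg_ref_mat <- function(m) {
    if (nrow(m) < 2L) stop("average reference requires >= 2 channels", call. = FALSE)
    sweep(m, 2L, colMeans(m), "-")
  }
  if (inherits(rec, "epoched_recording")) {
    rec$epochs <- lapply(rec$epochs, avg_ref_mat)
  } else if (inherits(rec, "continuous_recording")) {
    rec$samples <- avg_ref_mat(rec$samples)
  } else {
    stop("unsupported recording class", call. = FALSE)
  }
  rec
}

#' Epoch selection policy
#'
#' Sites A and B select 10 epochs at random from all available clean epochs
#' (`random_among_clean`); site C takes the first 4 clean epochs in temporal
#' order (`first_clean`).
#'
#' @param n_epochs number of epochs to select (>= 1).
#' @param epoch_len epoch length in seconds.
#' @param selection `"random_among_clean"` or `"first_clean"`.
#' @param seed RNG seed used by the random policy.
#' @return An object of class `epoch_policy`.
#' @export
epoch_policy <- function(n_epochs, epoch_len = 8,
                         selection = c("random_among_clean", "first_clean"),
                         seed = NULL) {
  selection <- match.arg(selection)
  stopifnot(n_epochs >= 1, epoch_len > 0)
  if (selection == "random_among_clean" && is.null(seed)) {
    stop("the random epoch-selection policy requires a seed", call. = FALSE)
  }
  structure(list(n_epochs = as.integer(n_epochs), epoch_len = epoch_len,
                 selection = selection, seed = seed),
            class = "epoch_policy")
}

#' Select analysis epochs under a policy
#'
#' Continuous input is segmented into non-overlapping `epoch_len` windows
#' starting at t = 0 (a trailing partial window is dropped). A window is
#' clean if it does not overlap any annotation labelled `"artifact"`; if
#' eyes-state annotations are present, the window must additionally lie
#' inside an `"eyes-closed"` span. Epoched input is treated as all clean.
#'
#' @param rec a `continuous_recording` or `epoched_recording`.
#' @param policy an [epoch_policy()].
#' @return An `epoched_recording` with exactly `policy$n_epochs` epochs.
#' @export
select_epochs <- function(rec, policy) {
  stopifnot(inherits(policy, "epoch_policy"))
  if (inherits(rec, "continuous_recording")) {
    npts <- round(policy$epoch_len * rec$fs)
    if (npts < 2) stop("epoch length too short for sampling rate", call. = FALSE)
    n_avail <- floor(ncol(rec$samples) / npts)
    starts <- (seq_len(n_avail) - 1L) * npts + 1L
    clean <- vapply(starts, function(s) {
      t0 <- (s - 1) / rec$fs; t1 <- t0 + policy$epoch_len
      ann <- rec$annotations
      if (is.null(ann) || !nrow(ann)) return(TRUE)
      art <- ann[ann$label == "artifact", , drop = FALSE]
      if (nrow(art) && any(art$start_s < t1 & art$end_s > t0)) return(FALSE)
      eyes <- ann[ann$label %in% c("eyes-closed", "eyes-open"), , drop = FALSE]
      if (nrow(eyes)) {
        closed <- eyes[eyes$label == "eyes-closed", , drop = FALSE]
        return(nrow(closed) > 0 && any(closed$start_s <= t0 & closed$end_s >= t1))
      }
      TRUE
    }, logical(1))
    avail_idx <- which(clean)
    epochs_all <- lapply(starts, function(s) {
      rec$samples[, s:(s + npts - 1L), drop = FALSE]
    })
    labels <- rec$channel_labels
    fs <- rec$fs
    meta <- list()
  } else if (inherits(rec, "epoched_recording")) {
    avail_idx <- seq_along(rec$epochs)
    epochs_all <- rec$epochs
    labels <- rec$channel_labels
    fs <- rec$fs
    meta <- rec$meta
  } else {
    stop("unsupported recording class", call. = FALSE)
  }
  if (length(avail_idx) < policy$n_epochs) {
    stop(sprintf("insufficient clean epochs: %d available, %d requested",
                 length(avail_idx), policy$n_epochs), call. = FALSE)
  }
  sel <- switch(policy$selection,
    first_clean = avail_idx[seq_len(policy$n_epochs)],
    random_among_clean = sort(with_seed(
      policy$seed, sample(avail_idx, policy$n_epochs)
    ))
  )
  epoched_recording(epochs_all[sel], labels, fs, meta)
}

#' Flag high-amplitude epoch windows
#'
#' A simple automatic artifact screen: flags every epoch-length window whose
#' peak absolute amplitude on any channel exceeds `threshold`. Intended as a
#' coarse stand-in for manual visual rejection.
#'
#' @param rec a `continuous_recording` or `epoched_recording`.
#' @param threshold positive amplitude threshold (signal units).
#' @param epoch_len window length in seconds (continuous input only).
#' @return A data frame of annotations (`start_s`, `end_s`, `label`), one row
#'   per flagged window, with label `"artifact"`.
#' @export
amplitude_artifact_screen <- function(rec, threshold, epoch_len = 8) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stop("'threshold' must be a single positive number (Inf allowed)", call. = FALSE)
  }
  if (inherits(rec, "epoched_recording")) {
    npts <- ncol(rec$epochs[[1]])
    peaks <- vapply(rec$epochs, function(e) max(abs(e)), numeric(1))
    starts_s <- (seq_along(peaks) - 1) * npts / rec$fs
    len_s <- npts / rec$fs
  } else {
    npts <- round(epoch_len * rec$fs)
    n_win <- floor(ncol(rec$samples) / npts)
    peaks <- vapply(seq_len(n_win), function(i) {
      max(abs(rec$samples[, ((i - 1L) * npts + 1L):(i * npts), drop = FALSE]))
    }, numeric(1))
    starts_s <- (seq_len(n_win) - 1) * epoch_len
    len_s <- epoch_len
  }
  hit <- which(peaks > threshold)
  data.frame(start_s = starts_s[hit], end_s = starts_s[hit] + len_s,
             label = rep("artifact", length(hit)), stringsAsFactors = FALSE)
}
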