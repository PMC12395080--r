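#' Canonical frequency band definitions
#'
#' The four analysis bands: delta 0.5--4 Hz, theta 4--8 Hz, alpha 8--13 Hz and
#' lower beta 13--20 Hz. Bands are half-open `[lo, hi)` except beta, whose
#' upper edge (20 Hz) is closed; the half-open convention prevents shared
#' edges from being counted twice, which would break the sum-to-one property
#' of relative power. Only lower beta is analyzed, to limit muscle-activity
#' contamination.
#'
#' @return A data frame with columns `band`, `f_lo`, `f_hi`.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta"),
    f_lo = c(0.5, 4, 8, 13),
    f_hi = c(4, 8, 13, 20),
    stringsAsFactors = FALSE
  )
}

#' Assign a frequency to its analysis band
#'
#' Half-open assignment `[f_lo, f_hi)`; 20 Hz belongs to beta; frequencies
#' outside 0.5--20 Hz map to `NA`.
#'
#' @param freq numeric vector of frequencies in Hz, `>= 0`.
#' @return Character vector of band names (`NA` where unassigned).
#' @export
#' @examples
#' band_of(c(1, 5, 10, 15, 20, 25))
band_of <- function(freq) {
  stopifnot(is.numeric(freq), all(freq >= 0, na.rm = TRUE))
  bands <- canonical_bands()
  out <- rep(NA_character_, length(freq))
  for (i in seq_len(nrow(bands))) {
    hit <- freq >= bands$f_lo[i] & freq < bands$f_hi[i]
    out[hit] <- bands$band[i]
  }
  out[freq == 20] <- "beta"
  out
}

band_bins <- function(freqs, f_lo, f_hi, closed_hi = FALSE) {
  # DC bin never participates in band computations
  if (closed_hi) {
    which(freqs >= f_lo & freqs <= f_hi & freqs > 0)
  } else {
    which(freqs >= f_lo & freqs < f_hi & freqs > 0)
  }
}
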