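#' Oscillator specification
#'
#' One narrowband component of the synthetic EEG signal model. The oscillator
#' is rendered by shaping white Gaussian noise with a Gaussian spectral
#' amplitude envelope centred at `center_freq` with full width at half
#' maximum `bandwidth`, so spectra have realistic width and a well-defined
#' maximum (a pure tone would make peak detection degenerate; a flat
#' brick-wall band would make it uniform over the band). A fraction
#' `coupling_strength` of the oscillator's power is a component common to
#' all channels, injected with per-channel phase offsets spread evenly over
#' `[0, coupling_lag]`; the remainder is independent per channel. Spreading
#' the offsets keeps every channel pair at a strictly positive lag no larger
#' than `coupling_lag`, so full coupling at lag pi/2 drives the phase lag
#' index toward 1 on every pair while zero lag leaves it blind, as it
#' should be.
#'
#' @param center_freq oscillator centre frequency in Hz, inside (0, Nyquist).
#' @param rel_amplitude relative RMS amplitude, >= 0.
#' @param bandwidth spectral FWHM in Hz (frequency jitter), > 0.
#' @param coupling_lag cross-channel phase offset span in radians.
#' @param coupling_strength fraction in [0, 1] of power shared across channels.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(center_freq, rel_amplitude = 1, bandwidth = 1,
                            coupling_lag = pi / 2, coupling_strength = 0) {
  stop_if_not_scalar_number(center_freq, "center_freq")
  stop_if_not_scalar_number(rel_amplitude, "rel_amplitude")
  stop_if_not_scalar_number(bandwidth, "bandwidth")
  stop_if_not_scalar_number(coupling_strength, "coupling_strength")
  if (center_freq <= 0) stop("'center_freq' must be positive", call. = FALSE)
  if (rel_amplitude < 0) stop("'rel_amplitude' must be >= 0", call. = FALSE)
  if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("'coupling_strength' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(center_freq = center_freq, rel_amplitude = rel_amplitude,
                 bandwidth = bandwidth, coupling_lag = coupling_lag,
                 coupling_strength = coupling_strength),
            class = "oscillator_spec")
}

#' The 17 scalp channels retained for analysis
#'
#' The 10--20 montage's 21 channels minus the systematically excluded A1, A2
#' (earlobes) and Fp1, Fp2 (frontopolar, dominated by eye movement).
#'
#' @return Character vector of 17 channel labels.
#' @export
analysis_channels <- function() {
  c("F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Per-subject simulation parameters
#'
#' @param subject_id subject identifier.
#' @param site study site, one of `"A"`, `"B"`, `"C"`.
#' @param etiology delirium etiology stratum.
#' @param delirium logical delirium status.
#' @param age age in years.
#' @param oscillators list of [oscillator_spec()] objects.
#' @param one_over_f_exponent exponent chi of the 1/f^chi background.
#' @param noise_scale RMS amplitude of the background noise.
#' @param n_epochs number of epochs to simulate (>= 1).
#' @param epoch_len epoch length in seconds; `epoch_len * fs` must be integer.
#' @param fs sampling rate in Hz.
#' @param channels channel labels (unique).
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, site = "A", etiology = "medical",
                           delirium = FALSE, age = 70,
                           oscillators = list(oscillator_spec(10)),
                           one_over_f_exponent = 1, noise_scale = 1,
                           n_epochs = 10, epoch_len = 8, fs = 512,
                           channels = analysis_channels()) {
  stopifnot(n_epochs >= 1, epoch_len > 0, fs > 0)
  npts <- epoch_len * fs
  if (abs(npts - round(npts)) > 1e-9) {
    stop("epoch_len * fs must be an integer number of samples", call. = FALSE)
  }
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  for (o in oscillators) {
    if (!inherits(o, "oscillator_spec")) stop("oscillators must be oscillator_spec objects", call. = FALSE)
    if (o$center_freq >= fs / 2) {
      stop(sprintf("oscillator at %g Hz is at or above Nyquist (%g Hz)",
                   o$center_freq, fs / 2), call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), site = site,
                 etiology = etiology, delirium = isTRUE(delirium), age = age,
                 oscillators = oscillators,
                 one_over_f_exponent = one_over_f_exponent,
                 noise_scale = noise_scale, n_epochs = as.integer(n_epochs),
                 epoch_len = epoch_len, fs = fs, channels = channels),
            class = "subject_params")
}

# Noise shaped in the frequency domain: a white complex Gaussian spectrum
# multiplied by an amplitude envelope, inverse-transformed; each channel
# (column) is scaled to unit RMS. With analytic = TRUE negative frequencies
# are dropped and the complex analytic signal returned (used for the
# phase-lagged common component, nch = 1).
shaped_noise <- function(n, nch, env, analytic = FALSE) {
  spec <- matrix(complex(real = stats::rnorm(n * nch),
                         imaginary = stats::rnorm(n * nch)), n, nch) * env
  if (analytic) {
    x <- stats::mvfft(spec, inverse = TRUE) / n
    rms <- sqrt(colMeans(Re(x)^2))
  } else {
    x <- Re(stats::mvfft(spec, inverse = TRUE) / n)
    rms <- sqrt(colMeans(x^2))
  }
  rms[rms == 0] <- 1
  sweep(x, 2L, rms, "/")
}

# Gaussian spectral amplitude envelope (FWHM = bandwidth) centred at f0.
narrowband_envelope <- function(n, fs, f0, bandwidth, analytic = FALSE) {
  freqs <- (seq_len(n) - 1) * fs / n
  freqs_signed <- ifelse(freqs > fs / 2, freqs - fs, freqs)
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))
  env <- exp(-((abs(freqs_signed) - f0)^2) / (2 * sigma^2))
  env[1] <- 0  # no DC
  if (analytic) env[freqs_signed < 0] <- 0
  env
}

# 1/f^chi amplitude envelope.
one_over_f_envelope <- function(n, fs, exponent) {
  freqs <- (seq_len(n) - 1) * fs / n
  freqs_signed <- ifelse(freqs > fs / 2, freqs - fs, freqs)
  c(0, abs(freqs_signed[-1])^(-exponent / 2))
}

#' Simulate one epoch of multichannel EEG
#'
#' Realizes the signal model: independent 1/f^chi background noise per
#' channel plus each oscillator rendered as a narrowband signal. Per
#' oscillator, a fraction `coupling_strength` of the power is a common
#' analytic component injected into every channel with an evenly spread
#' per-channel phase offset in `[0, coupling_lag]`; the remaining fraction is
#' an independent narrowband realization per channel.
#'
#' @param params a [subject_params()] object.
#' @param epoch_index epoch number (enters the RNG substream derivation).
#' @param seed integer seed for this epoch's substream.
#' @return A channels x timepoints numeric matrix.
#' @export
simulate_epoch <- function(params, epoch_index = 1L, seed) {
  stopifnot(inherits(params, "subject_params"))
  if (missing(seed)) stop("a seed is required: simulation must be reproducible", call. = FALSE)
  n <- as.integer(round(params$epoch_len * params$fs))
  nch <- length(params$channels)
  with_seed(derive_seed(seed, "epoch", epoch_index), {
    out <- matrix(0, nrow = n, ncol = nch)  # timepoints x channels internally
    if (params$noise_scale > 0) {
      env <- one_over_f_envelope(n, params$fs, params$one_over_f_exponent)
      out <- out + params$noise_scale * shaped_noise(n, nch, env)
    }
    for (osc in params$oscillators) {
      if (osc$center_freq >= params$fs / 2) {
        stop("oscillator frequency at or above Nyquist", call. = FALSE)
      }
      if (osc$rel_amplitude == 0) next
      c_frac <- osc$coupling_strength
      comp <- matrix(0, n, nch)
      if (c_frac > 0) {
        env_a <- narrowband_envelope(n, params$fs, osc$center_freq,
                                     osc$bandwidth, analytic = TRUE)
        z <- shaped_noise(n, 1L, env_a, analytic = TRUE)[, 1]
        # per-channel lags spread over [0, coupling_lag]: every pair gets a
        # strictly positive lag <= coupling_lag
        lags <- if (nch > 1) osc$coupling_lag * (seq_len(nch) - 1) / (nch - 1) else 0
        common <- Re(outer(z, exp(-1i * lags)))
        rms <- sqrt(colMeans(common^2)); rms[rms == 0] <- 1
        comp <- comp + sqrt(c_frac) * sweep(common, 2L, rms, "/")
      }
      if (c_frac < 1) {
        env <- narrowband_envelope(n, params$fs, osc$center_freq, osc$bandwidth)
        comp <- comp + sqrt(1 - c_frac) * shaped_noise(n, nch, env)
      }
      out <- out + osc$rel_amplitude * comp
    }
    t(out)
  })
}

#' Simulate all epochs for one subject
#'
#' @param params a [subject_params()] object.
#' @param seed integer seed; each epoch draws from a derived substream.
#' @return An [epoched_recording()] carrying the subject metadata.
#' @export
simulate_subject <- function(params, seed) {
  if (missing(seed)) stop("a seed is required: simulation must be reproducible", call. = FALSE)
  epochs <- lapply(seq_len(params$n_epochs), function(i) {
    simulate_epoch(params, epoch_index = i, seed = seed)
  })
  epoched_recording(
    epochs, params$channels, params$fs,
    meta = list(subject_id = params$subject_id, site = params$site,
                etiology = params$etiology, delirium = params$delirium,
                age = params$age)
  )
}

#' Default effect profile of delirium on the signal model
#'
#' Emulates global EEG slowing: oscillator power shifts toward delta (delta
#' and theta amplitudes up, alpha and beta down), the dominant-rhythm centre
#' frequency drops by `peak_shift_hz`, and band-wise phase coupling changes
#' slightly (up in the slow bands, down in the fast bands). Magnitudes are
#' chosen to produce moderate-to-large standardized mean differences of the
#' kind reported in clinical delirium qEEG studies.
#'
#' @param peak_shift_hz reduction of the dominant-rhythm centre frequency, Hz.
#' @param delta_gain,theta_gain,alpha_gain,beta_gain multiplicative amplitude
#'   changes per band oscillator.
#' @param coupling_delta named numeric: additive change of coupling_strength
#'   per band (clamped to [0, 1]).
#' @return A named list, class `effect_profile`.
#' @export
delirium_effect_profile <- function(peak_shift_hz = 1.5,
                                    delta_gain = 1.9, theta_gain = 1.25,
                                    alpha_gain = 0.85, beta_gain = 0.55,
                                    coupling_delta = c(delta = 0.02, theta = 0.03,
                                                       alpha = -0.03, beta = -0.08)) {
  structure(list(peak_shift_hz = peak_shift_hz,
                 gains = c(delta = delta_gain, theta = theta_gain,
                           alpha = alpha_gain, beta = beta_gain),
                 coupling_delta = coupling_delta),
            class = "effect_profile")
}

#' Null (zero-magnitude) delirium effect profile
#' @return An `effect_profile` with no group difference.
#' @export
null_effect_profile <- function() {
  delirium_effect_profile(peak_shift_hz = 0, delta_gain = 1, theta_gain = 1,
                          alpha_gain = 1, beta_gain = 1,
                          coupling_delta = c(delta = 0, theta = 0, alpha = 0, beta = 0))
}

#' Full parameterization of a synthetic multicenter cohort
#'
#' Defaults mirror the study layout: five etiology-by-site subgroups with
#' delirious/non-delirious counts 38/70 (site A post-stroke), 41/41 (site A
#' medical), 44/43 (site B post-stroke), 26/27 (site B medical) and 24/23
#' (site C postoperative); 10 epochs per subject at sites A and B, 4 at
#' site C; 8-s epochs at 512 Hz on the 17 analysis channels. Ages are drawn
#' from normal distributions truncated to [40, 100] with delirious mean 79.2
#' (SD 9.2) and non-delirious mean 72.9 (SD 13.1). Site profiles carry small
#' non-zero offsets so between-study heterogeneity (tau^2 > 0, I^2 > 0) is
#' present by default.
#'
#' @param subgroups data frame with columns `site`, `etiology`, `n_del`,
#'   `n_ctrl`, `n_epochs`.
#' @param effect an `effect_profile` applied to delirious subjects.
#' @param site_profiles named list (per site) of multiplicative amplitude
#'   offsets (`amp_gain`), additive dominant-frequency offsets in Hz
#'   (`peak_offset_hz`), noise scaling (`noise_gain`) and additive coupling
#'   offsets (`coupling_offset`).
#' @param subject_sd named list of between-subject variabilities: `log_amp`
#'   (SD of log amplitude), `center_freq` (SD in Hz of the dominant-rhythm
#'   centre), `coupling` (SD of coupling_strength).
#' @param age_del,age_ctrl `c(mean, sd)` of the truncated-normal age
#'   distributions.
#' @param epoch_len,fs epoch length (s) and sampling rate (Hz).
#' @param channels analysis channel labels.
#' @param baseline list of baseline [oscillator_spec()]s per band for a
#'   non-delirious subject.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(subgroups,
                        effect = delirium_effect_profile(),
                        site_profiles = default_site_profiles(),
                        subject_sd = list(log_amp = 0.35, center_freq = 0.75,
                                          coupling = 0.04),
                        age_del = c(79.2, 9.2), age_ctrl = c(72.9, 13.1),
                        epoch_len = 8, fs = 512,
                        channels = analysis_channels(),
                        baseline = default_baseline_oscillators()) {
  stopifnot(is.data.frame(subgroups),
            all(c("site", "etiology", "n_del", "n_ctrl", "n_epochs") %in% names(subgroups)))
  if (any(subgroups$n_del < 2) || any(subgroups$n_ctrl < 2)) {
    stop("every subgroup arm needs at least 2 subjects", call. = FALSE)
  }
  structure(list(subgroups = subgroups, effect = effect,
                 site_profiles = site_profiles, subject_sd = subject_sd,
                 age_del = age_del, age_ctrl = age_ctrl,
                 epoch_len = epoch_len, fs = fs, channels = channels,
                 baseline = baseline),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_baseline_oscillators <- function() {
  list(
    delta = oscillator_spec(2.0, rel_amplitude = 0.6, bandwidth = 1.5,
                            coupling_strength = 0.20),
    theta = oscillator_spec(6.0, rel_amplitude = 0.5, bandwidth = 1.0,
                            coupling_strength = 0.20),
    alpha = oscillator_spec(10.0, rel_amplitude = 1.0, bandwidth = 1.0,
                            coupling_strength = 0.25),
    beta  = oscillator_spec(16.0, rel_amplitude = 0.4, bandwidth = 2.0,
                            coupling_strength = 0.15)
  )
}

#' @rdname cohort_spec
#' @export
default_site_profiles <- function() {
  list(
    A = list(amp_gain = c(delta = 1.00, theta = 1.00, alpha = 1.00, beta = 1.00),
             peak_offset_hz = 0.0, noise_gain = 1.00,
             coupling_offset = c(delta = 0, theta = 0, alpha = 0, beta = 0)),
    B = list(amp_gain = c(delta = 1.15, theta = 1.05, alpha = 0.95, beta = 1.10),
             peak_offset_hz = 0.3, noise_gain = 1.10,
             coupling_offset = c(delta = 0.02, theta = 0.01, alpha = -0.02, beta = 0.02)),
    C = list(amp_gain = c(delta = 0.90, theta = 0.95, alpha = 1.10, beta = 0.85),
             peak_offset_hz = -0.3, noise_gain = 0.90,
             coupling_offset = c(delta = -0.02, theta = -0.01, alpha = 0.02, beta = -0.02))
  )
}

#' Default multicenter cohort specification
#'
#' @return A [cohort_spec()] with the study's five subgroups: 173 delirious
#'   and 204 non-delirious subjects in total.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' sum(spec$subgroups$n_del)   # 173
#' sum(spec$subgroups$n_ctrl)  # 204
default_cohort_spec <- function() {
  subgroups <- data.frame(
    site = c("A", "A", "B", "B", "C"),
    etiology = c("post-stroke", "medical", "post-stroke", "medical", "postoperative"),
    n_del = c(38L, 41L, 44L, 26L, 24L),
    n_ctrl = c(70L, 41L, 43L, 27L, 23L),
    n_epochs = c(10L, 10L, 10L, 10L, 4L),
    stringsAsFactors = FALSE
  )
  cohort_spec(subgroups)
}

rtruncnorm1 <- function(mean, sd, lo = 40, hi = 100) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Build subject_params for one subject from the cohort spec.
subject_from_spec <- function(spec, subject_id, site, etiology, delirium,
                              age, n_epochs, subj_seed) {
  prof <- spec$site_profiles[[site]]
  eff <- if (delirium) spec$effect else null_effect_profile()
  with_seed(derive_seed(subj_seed, "params"), {
    oscillators <- lapply(names(spec$baseline), function(band) {
      base <- spec$baseline[[band]]
      amp <- base$rel_amplitude * prof$amp_gain[[band]] * eff$gains[[band]] *
        exp(stats::rnorm(1, 0, spec$subject_sd$log_amp))
      f0 <- base$center_freq + if (band == "alpha") {
        prof$peak_offset_hz - eff$peak_shift_hz +
          stats::rnorm(1, 0, spec$subject_sd$center_freq)
      } else {
        stats::rnorm(1, 0, spec$subject_sd$center_freq / 2)
      }
      f0 <- max(0.5, min(f0, spec$fs / 2 - 1))
      coup <- clamp01(base$coupling_strength + prof$coupling_offset[[band]] +
                        eff$coupling_delta[[band]] +
                        stats::rnorm(1, 0, spec$subject_sd$coupling))
      oscillator_spec(f0, rel_amplitude = amp, bandwidth = base$bandwidth,
                      coupling_lag = base$coupling_lag, coupling_strength = coup)
    })
    subject_params(subject_id, site = site, etiology = etiology,
                   delirium = delirium, age = age, oscillators = oscillators,
                   one_over_f_exponent = 1,
                   noise_scale = 1.0 * prof$noise_gain,
                   n_epochs = n_epochs, epoch_len = spec$epoch_len,
                   fs = spec$fs, channels = spec$channels)
  })
}

#' Build the cohort table for a spec
#'
#' Draws subject identities, ages and per-subject signal parameters without
#' simulating any EEG. Used by [simulate_cohort()] and by streaming pipeline
#' runs that simulate one subject at a time.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed (required).
#' @return A list with `table` (one row per subject: subject_id, site,
#'   etiology, delirium, age, n_epochs) and `params` (named list of
#'   [subject_params()]).
#' @export
cohort_plan <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed)) {
    stop("a master seed is required: cohort simulation must be reproducible",
         call. = FALSE)
  }
  rows <- list(); params <- list()
  sid <- 0L
  for (i in seq_len(nrow(spec$subgroups))) {
    sg <- spec$subgroups[i, ]
    for (delirium in c(TRUE, FALSE)) {
      n <- if (delirium) sg$n_del else sg$n_ctrl
      agepar <- if (delirium) spec$age_del else spec$age_ctrl
      for (j in seq_len(n)) {
        sid <- sid + 1L
        subject_id <- sprintf("S%03d", sid)
        subj_seed <- derive_seed(seed, "subject", subject_id)
        age <- with_seed(derive_seed(subj_seed, "age"),
                         rtruncnorm1(agepar[1], agepar[2]))
        p <- subject_from_spec(spec, subject_id, sg$site, sg$etiology,
                               delirium, age, sg$n_epochs, subj_seed)
        rows[[sid]] <- data.frame(
          subject_id = subject_id, site = sg$site, etiology = sg$etiology,
          delirium = delirium, age = age, n_epochs = sg$n_epochs,
          seed = subj_seed, stringsAsFactors = FALSE
        )
        params[[subject_id]] <- p
      }
    }
  }
  list(table = do.call(rbind, rows), params = params)
}

#' Simulate a full multicenter cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed (required).
#' @return A list with `cohort` (the subject table) and `recordings` (named
#'   list of [epoched_recording()], keyed by subject id). For large cohorts
#'   all recordings are held in memory; pipeline runs instead stream subject
#'   by subject via [cohort_plan()].
#' @export
simulate_cohort <- function(spec, seed) {
  plan <- cohort_plan(spec, seed)
  recordings <- lapply(plan$table$subject_id, function(id) {
    simulate_subject(plan$params[[id]],
                     seed = plan$table$seed[plan$table$subject_id == id])
  })
  names(recordings) <- plan$table$subject_id
  list(cohort = plan$table, recordings = recordings)
}
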