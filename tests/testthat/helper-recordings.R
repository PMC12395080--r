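# Builders shared across test files. Test recordings use reduced sampling
# rates and epoch lengths so the suite stays fast; the spectral and PLI code
# paths are identical at any fs.

# multichannel recording where every channel is the same set of sinusoids
# (amplitude, freq, phase) plus optional per-channel phase shifts
make_sine_recording <- function(freqs, amps = rep(1, length(freqs)),
                                nch = 2, n_epochs = 1, fs = 256,
                                epoch_len = 4, phases = NULL,
                                labels = paste0("ch", seq_len(nch))) {
  n <- fs * epoch_len
  t <- (seq_len(n) - 1) / fs
  if (is.null(phases)) phases <- matrix(0, nch, length(freqs))
  epochs <- lapply(seq_len(n_epochs), function(e) {
    do.call(rbind, lapply(seq_len(nch), function(ch) {
      rowSums(vapply(seq_along(freqs), function(i) {
        amps[i] * cos(2 * pi * freqs[i] * t + phases[ch, i])
      }, numeric(n)))
    }))
  })
  epoched_recording(epochs, labels, fs)
}

# small cohort specification for fast end-to-end runs
tiny_cohort_spec <- function(n_del = 4, n_ctrl = 4, n_epochs = 2,
                             effect = delirium_effect_profile(peak_shift_hz = 2),
                             nch = 6, fs = 128, epoch_len = 4) {
  spec <- default_cohort_spec()
  spec$subgroups$n_del <- rep(as.integer(n_del), 5)
  spec$subgroups$n_ctrl <- rep(as.integer(n_ctrl), 5)
  spec$subgroups$n_epochs <- rep(as.integer(n_epochs), 5)
  spec$effect <- effect
  spec$fs <- fs
  spec$epoch_len <- epoch_len
  spec$channels <- analysis_channels()[seq_len(nch)]
  spec
}

# one simulated, preprocessed subject from a spec-like parameter set
quick_subject <- function(seed = 1, n_epochs = 2, nch = 4, fs = 128,
                          epoch_len = 4, coupling = 0.2, noise = 1) {
  osc <- lapply(default_baseline_oscillators(), function(o) {
    o$coupling_strength <- coupling
    o
  })
  p <- subject_params("T1", oscillators = osc, noise_scale = noise,
                      n_epochs = n_epochs, epoch_len = epoch_len, fs = fs,
                      channels = paste0("ch", seq_len(nch)))
  average_reference(simulate_subject(p, seed = seed))
}
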