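---
title: "Methods: synthetic multicenter qEEG cohorts and subgroup meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multicenter qEEG cohorts and subgroup meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

Delirium — an acute disturbance of attention and cognition precipitated by
another medical condition — is accompanied by measurable changes in the
resting EEG, most consistently a *global slowing*: power shifts from the
alpha and beta bands toward delta and theta, and the dominant occipital
rhythm slows. Whether these signatures, and phase-based functional
connectivity, behave the same way across delirium etiologies (post-stroke,
medical, postoperative) is a multicenter question: recordings come from
different sites with different hardware, epoch budgets and recruitment, so a
naive pooled t-test would confound site with etiology.

`qeegmeta` implements the resulting two-layer analysis as a reusable,
fully testable pipeline:

1. **Feature layer.** From per-subject epoched EEG (8-s eyes-closed epochs,
   21-channel 10–20 montage at 512 Hz, channels A1/A2/Fp1/Fp2 excluded,
   average reference) compute nine features per subject: relative spectral
   power in delta (0.5–4 Hz), theta (4–8 Hz), alpha (8–13 Hz) and lower beta
   (13–20 Hz); the peak frequency in 4–13 Hz; and the mean phase lag index
   (PLI) per band.
2. **Statistics layer.** Within each of five etiology-by-site subgroups,
   contrast delirious vs non-delirious subjects with Hedges' *g*; pool the
   subgroup effects with an inverse-variance random-effects model whose
   between-study variance τ² is estimated by REML; quantify heterogeneity
   with Cochran's Q and I²; and complement this with bootstrap descriptive
   CIs, status-stratified heterogeneity, an age-adjusted regression and a
   leave-site-out sensitivity analysis.

Because no patient recordings are distributed, the canonical input is the
package's own synthetic cohort generator, which reproduces the study layout
(five subgroups with delirious/non-delirious counts 38/70, 41/41, 44/43,
26/27, 24/23 — 173 vs 204 subjects; 10 epochs per subject at two sites and
4 at the third) with *known* ground-truth effects, so every downstream stage
can be validated end to end.

## The signal model

Real EEG is not simulated physiologically (no neural mass models, no
artifacts beyond an optional amplitude-spike injector). The generator uses
the *minimal* model that exposes every measured quantity:

$$x_c(t) \;=\; \sigma\,\eta_c(t) \;+\; \sum_k a_k
  \Big( \sqrt{c_k}\, s_k(t; \phi_c) + \sqrt{1 - c_k}\, w_{k,c}(t) \Big)$$

per channel $c$, where $\eta_c$ is $1/f^{\chi}$ background noise
(independent per channel, $\chi = 1$ by default), and each oscillator $k$
is a narrowband process with centre frequency $f_k$, relative amplitude
$a_k$ and coupling fraction $c_k \in [0,1]$.

Three choices deserve comment:

* **Narrowband rendering.** Oscillators are white Gaussian noise shaped in
  the frequency domain by a Gaussian amplitude envelope whose full width at
  half maximum is the `bandwidth` parameter (default 1 Hz; 1.5 Hz for delta
  and 2 Hz for beta, which are broader in practice). A pure sinusoid would
  make peak detection degenerate, and a flat brick-wall band would make the
  spectral argmax uniform over the band; the Gaussian envelope gives spectra
  realistic width *and* a well-defined expected maximum at $f_k$.
* **Phase-lagged coupling.** A fraction $c_k$ of each oscillator's power is
  one common complex (analytic) realization injected into every channel;
  channel $c$ receives it rotated by a phase offset spread evenly over
  $[0, \lambda_k]$ with $\lambda_k$ the `coupling_lag` (default $\pi/2$).
  Spreading the offsets keeps every channel pair at a strictly positive lag
  no greater than $\lambda_k$: at $c_k = 1$ the PLI of every pair
  approaches 1, while equal offsets (zero pairwise lag) would be invisible
  to the PLI by construction. $\pi/2$ maximizes the index's sensitivity and
  avoids both of its blind spots (0 and $\pi$).
* **Group and site effects.** Delirium is injected as a slowing profile:
  multiplicative amplitude gains per band (defaults 1.9 delta, 1.25 theta,
  0.85 alpha, 0.55 beta), a reduction of the dominant-rhythm centre
  frequency (default 1.5 Hz) and small per-band changes of the coupling
  fraction (+0.02 delta, +0.03 theta, −0.03 alpha, −0.08 beta). Sites carry
  small non-zero offsets in amplitude, dominant frequency, noise level and
  coupling, so between-study heterogeneity (τ² > 0, I² > 0) is present by
  default, as in real multicenter data. Between-subject variability
  (log-normal amplitudes with SD 0.35 on the log scale, dominant frequency
  SD 0.75 Hz, coupling SD 0.04) sets the within-subgroup variance and hence
  realistic effect-size magnitudes of order |g| ≈ 1. Ages are drawn from
  normal distributions truncated to [40, 100] years with means 79.2
  (SD 9.2) and 72.9 (SD 13.1) for delirious and non-delirious subjects,
  so the age-covariate analysis is exercisable. These defaults were fixed
  once, before any recovery experiments, as values a clinical
  neurophysiologist would call plausible for this kind of cohort.

What the generator deliberately does *not* emulate: ocular/muscle/movement
artifacts and their manual rejection, electrode impedance drift, volume
conduction (beyond the zero-lag component that the PLI is designed to
ignore), non-stationarity within an epoch, medication effects, and absolute
amplitude calibration (all implemented measures are scale-invariant, so
units are arbitrary). Passing recovery tests therefore shows the *pipeline*
is correct and well calibrated, not that real delirium EEG behaves like the
model.

## Preprocessing contract

The stage order is fixed and tested: **exclude channels → select epochs →
average reference**. The average reference is computed over the retained
channels only — re-referencing over dropped channels would be impossible
from the retained data. No channel interpolation is performed. Continuous
input is segmented into non-overlapping 8-s windows starting at $t = 0$
(no overlap is the conservative reading when none is specified). An epoch
is *clean* if it overlaps no artifact annotation and, when eyes-state
annotations exist, lies inside an eyes-closed span; synthetic data are all
eyes-closed by construction. Two selection policies cover the sites'
practice: 10 epochs chosen uniformly at random among clean epochs (sites
A/B; seeded, so reproducible), or the first 4 clean epochs in temporal
order (site C). An amplitude-threshold screen can stand in for manual
rejection when reading real EDF files.

## Feature definitions and numerical choices

* **Spectra** are single rectangular-window FFTs of each full 8-s epoch
  (resolution 1/8 Hz). No taper is applied by default — matching a bare FFT
  analysis — though a Hann option exists. The DC bin is excluded from every
  band computation.
* **Band edges** are half-open $[f_{lo}, f_{hi})$ with 20 Hz closed at the
  top. Shared edges must not be counted twice or the four relative powers
  would not sum to 1; the half-open convention makes the sum exact by
  construction. 0.5 Hz belongs to delta. Only lower beta (13–20 Hz) is
  analyzed, limiting muscle-artifact contamination.
* **Relative power** is computed per epoch and channel, normalized by the
  summed power over the four bands, averaged across channels within an
  epoch and then across epochs ("first for each channel, then across
  channels"). With complete data this equals the epoch-then-channel order
  exactly — a tested identity.
* **Peak frequency** is the argmax of the epoch-averaged per-channel
  spectrum on the closed range [4, 13] Hz, averaged over channels.
  Epoch-averaging before the argmax is more stable than averaging
  per-epoch argmaxes; ties break toward the lower frequency so the result
  is deterministic.
* **Band-limited phase** uses a frequency-domain brick-wall filter (bins
  outside the band zeroed, zero phase, idempotent) followed by the analytic
  signal; this keeps the toolchain FFT-centric and avoids FIR order/ripple
  choices. The first and last 0.5 s of each epoch's phase series are
  discarded to suppress Hilbert edge artifacts, leaving ≥ 7 s effective.
* **PLI** between two channels is $|\,\mathrm{mean}_t\,
  \mathrm{sign}(\sin \Delta\phi(t))\,|$; the sine maps the wrapped phase
  difference consistently and sends both 0 and π to zero, so zero-lag
  common signals (volume conduction) contribute nothing. The subject value
  averages all $\binom{n}{2}$ unordered pairs per epoch, then epochs. The
  production path computes the per-sample sign from the unnormalized
  analytic signal in a small compiled kernel — the sign is
  amplitude-invariant — and is tested to 1e−12 against a literal
  per-sample, phase-based loop.

One behaviour of the model worth knowing: with a 1-Hz-wide oscillator
dominating a band, the phase *difference* of two independent channels
decorrelates on the ~1 s scale, so a finite epoch contains only a handful
of effectively independent sign samples and the *null* mean PLI sits well
above zero (≈ 0.15–0.25 for 4 × 8-s epochs, by Monte-Carlo under this
model). Tests therefore compare against Monte-Carlo null levels rather
than assuming the null is near zero. Likewise the average reference mixes
the common component across channels and attenuates mid-range coupling;
the coupling-fidelity property (PLI monotone in coupling strength) is
validated on the raw simulated channels.

## Statistical layer

For one feature and one subgroup with delirious and control arms
$(n_1, n_2)$:

$$d = \frac{\bar x_{del} - \bar x_{ctrl}}{s_p}, \qquad
  J = 1 - \frac{3}{4(n_1 + n_2 - 2) - 1}, \qquad g = J\,d,$$

$$\widehat{\mathrm{Var}}(g) = J^2 \left[ \frac{n_1 + n_2}{n_1 n_2} +
  \frac{d^2}{2(n_1 + n_2)} \right],$$

with $s_p$ the pooled SD. Negative $g$ means lower values in delirium. The
$J$ above is the standard small-sample approximation; the exact
gamma-function correction (as used by `metafor`) differs by ~1e−4 at these
sample sizes, and the test suite cross-checks against it at that tolerance.

Subgroup effects are pooled with random-effects weights
$w_i^* = 1/(v_i + \tau^2)$, where τ² maximizes the restricted likelihood of
$g_i \sim N(\mu, v_i + \tau^2)$. REML uses Fisher scoring from a
DerSimonian–Laird start, τ² floored at 0, convergence |Δτ²| < 1e−8, at most
200 iterations; it is verified against a 1e−4-step grid search of the
restricted likelihood and against `metafor`. Cochran's Q is computed with
*fixed-effect* weights (the standard definition) even though pooling is
random-effects, and $I^2 = \max(0, (Q - \mathrm{df})/Q) \times 100$.
Note `metafor` reports a τ²-based I²; the Q-based definition used here can
differ by a few points.

Choices where the methodology left room:

* **CIs** for $g$ and the pooled effect are normal-quantile (Wald)
  intervals; a Knapp–Hartung option was considered and left out to keep
  the default the simplest standard reading.
* **Descriptive CIs** are percentile bootstrap (1000 iterations, seeded),
  not BCa — the simplest nonparametric interval, used because the feature
  distributions are skewed.
* **Status-stratified heterogeneity** (is the variability in the delirious
  or the control arm?) meta-analyzes the *raw subgroup means* of one status
  arm with variance $s_i^2/n_i$: within a single arm there is no contrast
  to standardize, so SMDs are not available. This construction is
  documented as the package's own.
* **Age adjustment** is an ordinary least-squares fit
  `feature ~ status + age` per feature, with t-based two-sided p-values.
* **Sensitivity analysis** re-pools each feature after dropping all
  subgroups of one site (by default the 4-epoch site C), re-estimating τ².
* Subgroups with fewer than two subjects in either arm are dropped with a
  warning, never imputed; pooling requires at least two remaining
  subgroups.

## Reproducibility

Every run derives all randomness from one master seed through labelled
substreams (`hash(master, stage, unit)`), so subject simulation, epoch
selection and every bootstrap are independent of execution order, and two
runs with the same config and seed produce byte-identical result tables.
`run_study()` streams subjects (simulate → featurize → discard), so the
full 377-subject cohort never needs to be held in memory at once.

## Problem sizes used by the tests

The unit and property tests run on reduced instances — typically 128 Hz
sampling, 4-s epochs, 3–6 channels and a handful of subjects per arm —
chosen so the suite exercises every code path at identical numerics while
staying quick to run; the spectral and PLI code is rate-agnostic. The
calibration checks use the study's real subgroup sizes (38/70, 41/41,
44/43, 26/27, 24/23) at the feature level, and the direction-recovery check
runs the full pipeline twenty times on a five-subgroup cohort of 8 subjects
per subgroup. The acceptance script runs the complete default cohort (377
subjects at 512 Hz, 8-s epochs, 17 channels) from scratch.

## Known limitations

* The generator's effect sizes are plausible but arbitrary; pooled SMD
  magnitudes from synthetic runs are not estimates of any clinical
  quantity — only their signs and the calibration of the inferential
  machinery are meaningful.
* PLI group differences produced through the pipeline arise from both
  injected coupling changes and band-power changes (a narrowband-dominance
  effect on the null level); disentangling the two is out of scope.
* The EDF reader covers plain 16-bit EDF with one sampling rate across
  signals; EDF+ annotations are dropped, and mixed-rate files are rejected
  rather than resampled.
* Heterogeneity statistics with five subgroups have low power; I² is
  reported but its sampling error at k = 5 is large.
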