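---
title: "Predicting neonatal cognitive outcome from quantitative EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting neonatal cognitive outcome from quantitative EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoqeeg)
```

## The problem and the model

Neonatal hypoxic-ischemic encephalopathy (HIE) carries a high risk of
later cognitive impairment. The premise of this package is that the
functional organisation of the newborn brain, read from multichannel
resting-state EEG in the first week of life, carries predictive
information about composite cognitive scores assessed around age two
(BSITD-III scale: population mean 100, SD 15; observed cohort range
74–145). Two feature families operationalise that premise:

* **phase-coupling structure** between electrodes, summarised as a
  weighted graph and reduced to global topology metrics, and
* **signal complexity** per electrode, summarised by entropy measures.

Both are computed *within narrowband components* obtained by a fully
adaptive decomposition rather than fixed filter banks, because fixed band
edges are a poor fit for neonatal EEG, whose oscillations do not sit at
adult textbook frequencies.

## Pipeline stages and their assumptions

### Preprocessing

Channels are declared bad when their SD (after a 0.5–45 Hz zero-phase
band-pass) falls below a flatness floor or exceeds the cross-channel
median by more than 3 robust z-units. The robust scale (MAD) is floored
at 10% of the median SD so that a homogeneous montage cannot generate
spurious flags from a near-zero scale estimate. The remaining channels
are re-referenced to their common average, cut into non-overlapping 2-s
epochs (EEG is only quasi-stationary over short windows), and any epoch
whose peak absolute amplitude strictly exceeds 55 µV is rejected — an
epoch peaking at exactly the threshold is retained. ICA (FastICA,
symmetric fixed-point with a tanh contrast, written in-package) estimates
as many components as channels on the concatenated epochs; components
flagged by a pluggable rule are zeroed before reconstruction
`x' = W⁻¹u'`. The default rule is pass-through; a template-topography
rule (`topography_rule()`) flags components whose scalp projection
correlates with a frontal-weighted template above 0.8, targeting ocular
sources. Finally every subject is truncated to their first
`n_keep_epochs` clean epochs so the cohort is balanced.

Filtering is performed in the Fourier domain (out-of-band coefficients
zeroed), which is exactly zero-phase and numerically robust at very low
normalized cut-offs (0.5 Hz at 512–1000 Hz), where IIR designs are
fragile.

### NA-MEMD

For each channel, the clean epochs of *all* subjects are stacked into one
matrix (rows ordered subject-major, epoch-minor), so a single multivariate
decomposition yields the same number of modes, at matched scales, for
every subject and epoch — mode alignment by construction. White-noise
variates (default two, at 10% of the pooled signal SD, seeded) are
appended before sifting; their dyadic filter-bank behaviour stabilises
the scale structure, and their modes are discarded afterwards.

Sifting details, where the method leaves room for choices:

* **Direction sampling.** K unit vectors from a Hammersley
  low-discrepancy sequence mapped to the hypersphere through exact
  inverse-CDF transforms of the hyperspherical angles (default K = 64;
  at least twice the composite dimensionality is recommended).
* **Envelopes.** For each direction, the signal is projected and the
  multivariate values at the projection *maxima and minima* are
  interpolated by natural cubic splines; using both extrema families
  makes the direction set act as if closed under negation, which removes
  the envelope-mean bias a one-sided treatment would incur with a
  non-antipodal direction set. Extremum instants are refined to
  sub-sample precision by local parabolic interpolation — this cuts the
  envelope-mean error on pure tones by three orders of magnitude and is
  what keeps clean oscillations intact across sifting iterations.
  Boundaries mirror the two nearest extrema.
* **Stoppage.** Sifting of a mode stops when the local ratio of the
  envelope-mean norm to the envelope amplitude exceeds the tolerance
  (default 0.075) on fewer than that fraction of samples and nowhere
  exceeds ten times it, or after `max_sift_iterations` (default 10).
  This amplitude-normalized criterion sifts noisy details hard while
  leaving already-symmetric oscillations untouched. An energy-ratio
  criterion was evaluated first and rejected: it under-sifts noisy modes
  and over-sifts tonal ones, which splits single tones across adjacent
  modes.
* **Mode consolidation.** After sifting, adjacent modes whose pooled
  spectral centroids differ by less than a factor of 1.5 are summed.
  Genuine neighbours of a dyadic cascade differ by a factor of about 2,
  so consolidation only repairs over-decomposition (one oscillation
  leaking across two spectrally indistinguishable modes) and leaves the
  cascade intact. Completeness (`sum of modes + residue = input`) and
  alignment are unaffected.
* **Global stop.** Extraction ends when the remainder is monotonic on
  every variate (applied jointly, not per variate) or no projection
  retains two extrema.

Mode selection mirrors the retain-the-middle logic of a ten-mode
decomposition (drop the first three noisy modes and the residue-like
last mode) and, for reduced synthetic profiles whose mode counts are
smaller, a band rule keeps the modes whose pooled spectral centroid falls
in a requested band.

### Connectivity and graph metrics

Instantaneous phases come from the FFT-based analytic signal. Per epoch,
the first and last 5% of analytic samples are discarded (transform edge
taper), then WPLI is computed for every channel pair with the expectation
taken over the epoch's samples; matrices are averaged over epochs. The
cross-spectrum convention `X = Z₁·conj(Z₂)` versus `conj(Z₁)·Z₂` only
flips the sign of Im X, which the outer absolute value absorbs, so the
choice is immaterial. A cross-spectrum that is identically real gives
WPLI = 0, the volume-conduction null.

Graphs are complete weighted networks — no proportional thresholding.
Path-based metrics run on lengths = 1/weight (zero weight = unreachable):
characteristic path length is the mean finite off-diagonal shortest-path
distance (igraph's Dijkstra), global efficiency the mean reciprocal
distance with unreachable pairs contributing zero, and radius/diameter
the extremes of the eccentricity. Weighted transitivity is the
cube-root-intensity triangle sum over connected triples. Note that
epoch-averaged WPLI carries a positive small-sample bias of order
1/sqrt(effective samples per epoch); narrowband nulls therefore sit well
above zero, and averaging more epochs does not remove this (only longer
epochs or debiased estimators would, the latter deliberately out of
scope).

### Complexity measures

* **Sample entropy** `-ln(A/B)` with Chebyshev distance, self-matches
  excluded, tolerance `r` expressed as a fraction of the epoch SD
  (default 0.2, recommended range 0.1–0.25), embedding dimension default
  3, optional template delay. When A or B is zero the upper-bound value
  `ln((N−m−1)(N−m))` is returned and flagged.
* **Permutation entropy** over ordinal patterns of order 3 at delay 1 by
  default; ties break by temporal order. The normalizer is `ln(n!)` (the
  actual maximum ordinal entropy) with plain `ln(n)` available — the
  choice is a constant factor and cannot affect downstream correlations.
* **Spectral entropy** of the periodogram restricted to 0.5–45 Hz
  (clipped to the Nyquist frequency on low-rate profiles), in nats.

Features are computed per epoch and arithmetically averaged, giving
3 measures × channels columns per retained mode.

### Screening and regression

Each feature is screened by Pearson correlation with the outcome scores;
p-values come from `t = r√(n−2)/√(1−r²)` on n−2 degrees of freedom,
two-tailed, and significance is *inclusive* at p ≤ 0.05 (a feature at
exactly 0.05 counts). No multiple-testing correction is applied — this
reproduces the analysis as practised and is flagged as a caveat in the
README. Significant features feed bagged and boosted regression-tree
ensembles (30 learners, boosting rate 0.1, minimum leaf 8 — the common
regression-learner defaults, recorded in every report), evaluated by
leave-one-subject-out cross-validation. RMSE, MAE and R² are pooled over
the held-out predictions, R² against the constant baseline at the grand
mean of the actual scores; per-fold errors are kept in the fold log.
With 19 training subjects and minimum leaf 8, individual trees are
effectively stumps; held-out R² of roughly 0.1–0.3 is the realistic
ceiling for a single planted predictor at r ≈ 0.6 and n = 20.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes:
labelled 10–20 montages at clinical sampling rates, planted narrowband
oscillations with random phases, planted band-limited phase coupling
(partner channel = phase-shifted copy mixed with independent same-band
noise in proportion 1 − strength), planted artifacts (flat and
high-variance channels, supra-threshold epochs, low-frequency
frontal-weighted ocular transients with a known time course), and a
per-subject complexity gradient: one channel's delta component trades a
pure tone for flat-spectrum narrowband noise along a mixing schedule.
Scores follow `baseline + slope·z(gradient) + N(0, residual SD)`, clipped
to 74–145; with the gradient standardized, the planted population
correlation is `slope/√(slope² + residual²)`, and the clipping fraction
is recorded in the ground truth because clipping attenuates it.

Two constructions keep the planted effect size faithful at small n.
First, the irregular part of the gradient is built block-wise at the
downstream epoch length with unit magnitude at every in-band DFT bin
(random phases only, the tone bin excluded), so each epoch's in-band
spectrum is exactly as flat as the mixing ratio dictates — realization
variance would otherwise blur a correlation that the recovery experiment
must resolve against its theoretical power limit. Second, in the
demonstration cohort the non-gradient channels carry delta tones at
*distinct* DFT-grid frequencies and RMS-matched amplitudes, so the common
average reference neither interferes with the gradient channel's tone
bin nor unbalances channel SDs (which would trip bad-channel detection).

What the generator does *not* emulate: realistic neonatal EEG morphology
(burst suppression, sleep states, 1/f background), volume conduction, or
electrode-specific noise spectra. Passing tests therefore establish that
the implementation recovers structure it is designed to detect under its
own assumptions — not clinical validity on real recordings.

## Problem sizes used in validation

The full study layout (20 subjects × 12 channels × 30 epochs of 1024
samples at 512 Hz, K = 64) is supported but deliberately not exercised in
the routine validation, which runs reduced profiles chosen to keep the
whole suite in the minutes range while preserving every structural
property:

* tone separation: 3 variates × 1024 samples at 256 Hz, 2 vs 20 Hz,
  K = 16, 50 noise-realization seeds;
* end-to-end recovery: 20 subjects × 4 channels × 5 retained 4-s epochs
  of 512 samples at 128 Hz, K = 16, 100 seeds (4-s epochs keep ≥ 10
  cycles of the 2.5 Hz gradient per epoch, which the decomposition needs
  to keep the delta mode coherent at this reduced rate);
* screening calibration: 500 all-null cohorts of 20 subjects × 12
  entropy features from 128-sample noise epochs.

## Numerical and degenerate-input conventions

Constant series have undefined phases (analytic signal imaginary part
zero, warning); WPLI returns 0 when the denominator vanishes; an all-zero
multivariate input decomposes into zero modes and a zero residue;
`p_from_r(±1, n)` returns exactly 0; constant features screen as `NA` and
never significant; constant scores make every LOSOCV prediction equal
that constant with RMSE 0 and undefined R². Seeds propagate from a single
run seed to every stochastic stage (cohort generation, noise subspace,
ICA initialisation, bootstrap resampling) through a deterministic
integer-stream derivation, so identical configurations reproduce
bit-identical outputs.

## Known limitations

* Epoch-averaged WPLI is biased upward on narrowband signals (debiased
  WPLI is out of scope); compare values against matched nulls, not zero.
* The correlation screen's family-wise error rate is uncontrolled by
  design.
* EDF I/O is not implemented; recordings travel in a documented
  TSV + JSON array container (`write_fixture()`/`read_recording()`), and
  EDF paths are refused with a pointer to that container.
* The decomposition's mode count on short, noisy records is variable;
  the band selection rule plus mode consolidation handle this, but
  centroid-based selection can return more than one mode per canonical
  band (`entropy_feature_table(combine_modes = TRUE)` then sums them).
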