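---
title: "Decoding self-paced reaching direction from pre-movement slow cortical potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding self-paced reaching direction from pre-movement slow cortical potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpdecode)
```

## The problem

When a person decides to reach toward a target without an external go cue,
the EEG over fronto-parietal cortex shows slow build-ups of activity —
slow cortical potentials (SCPs), below about 1 Hz — that begin hundreds of
milliseconds before the arm moves. `scpdecode` asks, on a single-trial
basis: *can the direction of the upcoming reach (up / down / left / right)
be read out from these pre-movement potentials, and how early?* The answer
matters for neuroprosthetics and stroke rehabilitation, where decoding the
intended movement before it happens lets an assistive device act in
register with the user's own motor plan.

The package implements the complete analysis chain as reusable, tested
functions, together with a synthetic-data generator that emulates the
self-paced center-out protocol, so the entire pipeline can be validated
end to end without access to patient recordings.

## The decoding model

Trials come from a self-paced center-out task: a cue marks the target, the
subject waits at least 2 s (earlier starts are discarded as cued
reactions), then moves at will. Analysis is aligned to *movement onset*
(t = 0). The chain is:

1. **Channel subset and reference.** Analysis uses a configurable subset
   (default 34 of 64 extended-10/20 electrodes, excluding the outer ring
   and frontopolar rows most affected by ocular artifacts), re-referenced
   to the common average.
2. **Filtering and resampling.** A zero-phase (forward-backward)
   Butterworth low-pass at 120 Hz, decimation to 128 Hz, then the analysis
   band: SCP 0.1–1 Hz by default; delta, theta as amplitude bands; alpha
   through low-gamma as Hilbert-envelope bands; and instantaneous-phase
   variants of the fast bands.
3. **Sliding windows.** 250 ms windows sliding every 62.5 ms over the
   intention period \[-2, 1\] s around onset. Windows are labeled by their
   *endpoint*; the default grid runs from -1.75 to +1 s (45 windows).
   Within each window the band signal is subsampled to 16 Hz (4 time
   points per channel), anchored at the window end.
4. **Channel selection by CVA.** Canonical variate analysis solves the
   between- vs within-class scatter eigenproblem `B v = λ W v` over the
   window's channels × points features; the per-channel *discriminant
   power* (eigenvalue-weighted squared canonical coefficients, summed over
   a channel's columns) ranks channels and the top 10 are kept — giving a
   40-dimensional feature vector.
5. **Classification by LDA.** A four-class linear discriminant with one
   pooled covariance: posteriors are prior × shared-covariance Gaussian
   density, normalized by Bayes' rule; the argmax class is predicted.
6. **Chronological cross-validation.** 5 folds that keep recording order
   (contiguous blocks), a more honest estimate than shuffled splits under
   slow nonstationarity. Decoding accuracy (DA) is the confusion-matrix
   trace over the number of test trials; chance for the balanced 4-class
   task is 0.25.
7. **Chance level by permutation.** 10 repetitions of the 5-fold scheme
   with training labels permuted (selection re-run per permutation),
   scored against intact test labels.
8. **Early detection.** Per window, the five fold DAs are compared with
   the 50 permuted DAs by a one-sided Wilcoxon rank-sum test; detection is
   the endpoint of the first run of five consecutive windows with
   p < 0.05 beginning at or before onset.
9. **Selected classifier.** The pre-onset window with the highest mean DA
   is frozen (per-fold standardization, channels, LDA) and re-applied
   across all windows of the intention period (sensitivity) and of the
   idle period \[-1, 2\] s around the *cue* (specificity, which should stay
   at chance).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_len` / `window_step` | 0.25 / 0.0625 | s | temporal resolution of the decoding curve |
| `analysis_span` | \[-2, 1\] | s vs onset | covers intention and early execution |
| `idle_span` | \[-1, 2\] | s vs cue | specificity control period |
| `feature_rate` | 16 | Hz | 4 points per window; dimensionality control |
| `n_select_channels` | 10 | – | 40 features, tractable for LDA at ~200 trials |
| `n_folds` | 5 | – | chronological blocks of ~46 trials |
| `n_permutation_reps` | 10 | – | 50 chance draws per window |
| `alpha`, `consecutive_windows` | 0.05, 5 | – | detection rule |
| `shrinkage` (LDA) | 0.05 | – | stabilizes the 40×40 pooled covariance |
| `cva_ridge` | 1e-6 | – | numerical floor for the within-class scatter |

Filter orders are deliberately low: order 2 (single pass) for the narrow
bands — at 0.1–1 Hz on 128 Hz data higher orders are numerically fragile —
and order 4 for the 120 Hz low-pass. Forward-backward application squares
each magnitude response.

## Numerical choices

- **Zero-phase filtering** uses odd (anti-symmetric) reflection padding of
  `max(6 × order, 1 s)` samples per edge; SCP-band edge transients last
  seconds and would otherwise contaminate epochs. The band-pass is the
  direct 4-pole design (verified stable at 0.1–1 Hz / 128 Hz against the
  cascaded high-pass + low-pass, which is kept as an automatic fallback).
- **Envelope definition**: the modulus of the FFT-based analytic signal,
  computed on the continuous recording *before* epoching so epoch edges
  carry no Hilbert distortion. A `rectified` option gives the literal
  absolute value of the band-passed signal instead.
- **CVA regularization.** The within-class scatter gets a scaled-identity
  ridge `eps × trace(W)/p`, escalated tenfold until the Cholesky
  factorization is well conditioned. When the scatter is *structurally*
  rank-deficient — fewer within-class degrees of freedom than features, as
  with 96 training trials × 136 features — the ridge jumps directly to one
  average eigenvalue (`eps = 1`). This is the standard
  regularized-discriminant-analysis shrinkage; with an infinitesimal ridge
  the data-free null-space directions acquire enormous eigenvalues and the
  discriminant-power ranking degenerates into noise (we observed planted
  channel recovery collapsing from ~100% to ~50% without it).
- **LDA shrinkage** 0.05 toward scaled identity; `0` reproduces the plain
  pooled covariance when conditioning allows. Priors are empirical class
  frequencies (for the balanced design this is indistinguishable from
  uniform priors).
- **Ties.** Channel-selection ties break by montage order; posterior ties
  by fixed class order; best-window ties by the endpoint closest to onset.
- **Degenerate inputs.** Zero pooled covariance falls back to identity
  with a warning (posteriors then reduce to priors where means coincide);
  orphan onsets, shuffled fold inputs, spans outside the recording, and
  channel mismatches between a frozen classifier and new epochs are
  errors.
- **Phase features** enter the classifier as (cos φ, sin φ) pairs by
  default, removing the circular discontinuity at ±π; `raw_angle`
  reproduces the literal encoding. Phase is extracted on the continuous
  signal, so features are invariant to global amplitude scaling.
- **Permutation policy.** One fresh permutation per repetition × fold,
  shared across windows; permutations re-run CVA selection by default so
  the chance level includes selection optimism (`refit` mode reuses the
  real selection and is cheaper).

## What the synthetic generator emulates — and what it does not

`generate_recording()` produces one continuous session: ~240 trials in
chronological order with jittered 2–4 s inter-trial gaps, cue and onset
events (cue-to-onset latency 2 s + Gamma(2, 0.5), i.e. mean 3 s, matching
the order of magnitude of real self-paced onset times), a configurable
fraction (~4%) of early starts that violate the 2 s rule, and per-channel
background noise of 1/f^α-shaped plus white components (default 10 µV and
2 µV RMS) — so ~230 trials survive the early-start rule, as in real use.

The direction code is a slow component added on eight fronto-parietal
channels with two orthogonal, unit-norm spatial gradients
(anterior–posterior for up/down, lateral for left/right). The per-trial
waveform needs care: *any* monophasic "ramp then plateau" pulse has most
of its spectral mass below 0.1 Hz, and a zero-phase band-pass converts
that out-of-band mass into seconds-long acausal tails — the planted
direction information would then be decodable long before its nominal
onset, making the generator's own ground truth false. The component is
therefore a Hann-windowed slow sine (two cycles over 3 s, carrier 2/3 Hz,
zero net area, envelope skewed toward the movement) whose rising limb
spans \[-0.5, 0\] s: in-band by construction, so the analysis filter is
nearly idempotent on it and its information genuinely begins at the
configured effect onset. The SNR parameter is the planted component's RMS
(on a unit-gain channel, over the pre-onset-to-movement interval) divided
by the background RMS inside the effect band.

An optional phase-locked carrier (same amplitude in every direction,
direction-specific phase at onset) exercises the phase pipeline: envelope
decoding is blind to it, phase decoding is not.

Passing tests on this generator show that the pipeline recovers *planted*
spatio-temporal direction codes at the stated operating points; they do
not show that real EEG carries such codes, nor do they model eye/muscle
artifacts, electrode drift, inter-subject variability, or stroke-lesion
topographies. Results on real recordings remain the domain of the EDF/BDF
readers plus the user's own data.

## Problem sizes used in the validation suite

The shipped tests run the full chain at reduced scale, chosen to keep the
suite comfortably interactive: 120-trial sessions at 128 Hz and a
34-channel montage for the parameter-recovery and specificity studies
(20 seeds each), a 240-trial session at 256 Hz for the chance-level check,
and 5-window grids where the full 45-window curve is not the point of the
test. The acceptance script regenerates the chance-level analysis from
scratch at the full 240-trial size.

## Known limitations

- The 34-name default subset is a documented stand-in: the montage minus
  outer ring and frontopolar rows. Real studies derive their exclusion
  from EOG correlations; supply your own subset via
  `pipeline_config(channel_subset = ...)`.
- Zero-phase filtering is non-causal: detection times reflect offline
  analysis and would shift in a causal, online implementation.
- With a 0.9 Hz-wide SCP band the temporal resolution of the decoding
  curve is ~0.3 s; detection times within one window step of a true onset
  are not distinguishable.
- The Wilcoxon detection rule applies no multiple-comparison correction
  across windows (by design, replicating the standard rule); occasional
  false runs are expected at α = 0.05 and long grids.
- At very low planted SNR (≲ 0.5 under the unit-norm pattern convention)
  the accuracy gain over chance is smaller than the run-to-run noise of a
  ~120-trial cross-validated estimate, so accuracy-versus-SNR curves are
  flat to within noise at the bottom and only resolve from SNR ≈ 1
  upward.
- EDF/BDF reading supports equal-rate signal layouts and sidecar event
  tables; embedded annotation streams are not parsed.

## A worked example

```{r example, eval = FALSE}
library(scpdecode)

# a synthetic session: 240 self-paced center-out trials, direction-coded
# SCPs planted at snr 2 from 0.5 s before movement onset
gen <- generate_recording(synth_config(snr = 2, rng_seed = 42))
rec <- discard_early_starts(gen$recording)

cfg <- pipeline_config()
res <- decode_directions(rec, cfg)
res
```

The printout reports the permutation chance level (~0.25), the peak
pre-onset decoding accuracy and its window, the early-detection time, and
the idle-period (specificity) accuracy. `res$time_specific$da_mean` holds
the full decoding curve over the 45 window endpoints.
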