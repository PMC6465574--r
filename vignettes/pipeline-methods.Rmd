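---
title: "Methods: from raw fNIRS light intensity to decoded positive emotions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw fNIRS light intensity to decoded positive emotions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirsemotion` implements a complete analysis chain for film-clip emotion
studies recorded with continuous-wave, tri-wavelength functional
near-infrared spectroscopy (fNIRS) over the frontal cortex, together
with a synthetic-data generator that emulates such a study (13
participants, 37 film clips — 30 positive, 6 negative, 1 neutral — and a
24-channel montage sampled at 50 Hz). This vignette explains the models
and procedures, the parameters that matter, and the design choices made
where the design was genuinely open.

## 1. Optics: the modified Beer-Lambert law

A continuous-wave fNIRS channel measures light intensity $I(\lambda, t)$
at wavelengths $\lambda_1 = 785$, $\lambda_2 = 808$, $\lambda_3 = 850$
nm. The change in optical density relative to a reference intensity is

$$\Delta OD^{\lambda_i}(t) = \ln\frac{I_{\mathrm{ref}}^{\lambda_i}}{I^{\lambda_i}(t)},$$

and the modified Beer-Lambert law relates it linearly to concentration
changes of oxy- and deoxy-hemoglobin:

$$\Delta OD^{\lambda_i} = \left(\varepsilon_{HbO}^{\lambda_i}\,\Delta C_{HbO}
 + \varepsilon_{HbR}^{\lambda_i}\,\Delta C_{HbR}\right)\cdot r \cdot DPF^{\lambda_i},$$

with $\varepsilon$ the specific extinction coefficients
(mm$^{-1}\,\mu M^{-1}$), $r$ the source-detector separation (30 mm) and
$DPF$ the differential path-length factor converting geometric to
effective photon path length. With three wavelengths and two
chromophores the system is overdetermined; `invert_mbll()` solves it per
channel and time point by least squares through the normal equations
(the Moore-Penrose reading of the non-square matrix inverse, the only
mathematically coherent one).

**Extinction table.** The coefficients and DPFs are instrument
calibration constants. The shipped defaults
(`inst/extdata/extinction_defaults.csv`) use published compiled
hemoglobin spectra interpolated to the three wavelengths and typical
adult-forehead DPFs (6.38, 6.14, 5.86). Every value is overridable via
`read_extinction()` on a CSV config. Because the true device constants
are unknowable from outside, recovered absolute concentration scales are
arbitrary — all downstream classification and correlation results are
invariant to that scale. The simulator and the inverter share one table,
which is why forward-then-inverse round trips are exact (tested to
relative error below $10^{-10}$).

**Intensity reference.** $I_{\mathrm{ref}}$ defaults to the
whole-recording per-channel mean ("mean" policy); a pre-stimulus window
("prestim") is selectable. The choice shifts each $\Delta OD$ trace by a
constant that the later per-clip baseline correction removes, so it does
not affect results.

## 2. Preprocessing

* **Band-pass 0.01–0.2 Hz, zero-phase.** The filter is a 4th-order
  Butterworth band-pass (a 2nd-order analog prototype; band-pass
  transformation doubles the order) applied forward and backward with
  `filtfilt`, giving zero phase shift and the squared magnitude
  response. At 50 Hz the normalized band edges are tiny; the 2nd-order
  prototype is the highest that remains numerically stable in
  transfer-function form, and it meets the response targets: gain 0.98
  at 0.1 Hz, $10^{-3}$ at the 1.2 Hz cardiac band. Respiratory
  (~0.25 Hz) and cardiac oscillations are rejected; Mayer waves
  (~0.1 Hz) are inside the band and are *not* removed — they are part of
  the noise the decoder must live with. The filter is applied to raw
  intensity (as the fluctuation about the channel mean, so intensities
  stay positive for the log), matching the stated processing order of
  the emulated study; because $\Delta OD$ is the log of a near-unity
  ratio, this equals filtering the optical density to first order. The
  0.01-Hz high-pass edge transient has a time constant of roughly 16 s,
  which is why property tests of the frequency response use long series
  and evaluate the steady-state midsection.
* **No artifact rejection.** Deliberate: the emulated protocol applied
  none beyond the band-pass.
* **Baseline.** Each clip's response is corrected by subtracting the
  per-channel mean over the 10 s before clip onset.
* **Epoching.** The last 30 s of each clip (where the induced emotion is
  maximal) are cut into three non-overlapping 10-s windows — half-open
  intervals $[\mathrm{offset}-30, \mathrm{offset}-20)$, etc., indexed
  1..3 — each exactly 500 samples at 50 Hz. Clips shorter than 30 s are
  an error; partial windows are never produced.
* **Features.** Each window is reduced to its per-channel time mean: a
  24-dimensional spatial pattern per chromophore. Six clips per category
  yield $3 \times 6 = 18$ samples per class.

## 3. Behavioral analytics

Ratings are participants × clips × items Likert scores (1–7) on 14
items: 10 positive emotions plus arousal, valence, familiarity, liking.

* **Reliability.** `icc_per_item()` computes ICC(2,k) — two-way random
  effects, absolute agreement, average measures across the k = 13
  raters — from the two-way mean squares. The form is selectable
  (`ICC2_1`, `ICC3k`) because the average-measures form, while right
  for "how reliable is the group mean rating", is violently unstable
  under the null: Spearman-Brown amplification maps a single-measures
  ICC of $-0.03$ to roughly $-0.6$. Property tests of the null
  distribution therefore use the single-measures form, and parameter
  recovery is verified against the closed form
  $\sigma^2_c / (\sigma^2_c + \sigma^2_e/k)$ at 500 clips.
* **Manipulation checks.** Per target emotion: one-way repeated-measures
  ANOVA (no sphericity correction by default; the protocol being
  emulated reported none) over the 10 positive items on participant
  means of the clip group, then paired t-tests of the target item
  against the other nine with Benjamini-Hochberg correction. Items are
  labelled `target` / `lower` / `not-different`; a significantly
  *higher* non-target item keeps the `not-different` label (the signed
  t statistic carries the direction), mirroring the three-colour
  reporting convention of such checks.
* **Correlation structure and MDS.** Pearson correlations between items
  are computed across the 30 positive clips on cross-participant mean
  ratings. The 10 positive emotions are embedded by nonmetric (Kruskal)
  MDS on the dissimilarity $1 - r$, with classical-scaling
  initialisation so the solution is deterministic; badness of fit is
  Stress-1. Nonmetric scaling uses only the rank order of
  dissimilarities, so any monotone transform of $1 - r$ gives the same
  embedding. On the package's default target correlation structure the
  embedding separates three groups — {amusement, interest, joy},
  {awe, gratitude, hope, inspiration, pride}, {love, serenity} — and
  hierarchical clustering on the embedding with silhouette-chosen k
  recovers exactly that partition (`suggest_clusters()`). The strictest
  reading of "mutual nearest neighbours" for the playfulness trio does
  not survive the 2-D projection (one between-cluster distance lands
  0.016 closer), which is why the qualitative tests check
  nearest-neighbour membership and the 3-cluster partition instead.
* **Cluster scores and stimulus selection.** A clip's cluster score is
  the mean of its ratings on the cluster's member emotions (ratings 1,
  2, 2 on the playfulness items give 1.67). Cluster membership is
  explicit configuration (`default_clusters()`), never inferred
  silently. `select_top_clips()` picks the six highest-scoring positive
  clips per cluster, breaking ties by ascending clip id and reporting
  the tie. For cluster-vs-cluster contrasts the two top-6 sets can
  overlap (a clip can score high on both); `contrast_clips()` assigns a
  shared clip to the cluster scoring it higher and refills the other
  side from its next-best clips until the sets are disjoint.

## 4. Decoding

Per participant, chromophore and contrast: 36 balanced samples (18 + 18),
a linear-kernel SVM with C = 1 on z-scored features (scaler fitted on
training folds only; C is configurable — the emulated protocol states no
tuning, so the standard default is used), sixfold cross-validation with
six test samples per fold, accuracy = pooled fraction of correct
held-out predictions in percent.

**Fold construction is clip-grouped**: each fold holds one clip from
each class, so the three windows of a clip never straddle the
train/test boundary — within-clip autocorrelation cannot leak. The
literal alternative (random samples into folds) is available as
`fold_mode = "sample"` for comparison.

**Chance levels** come from permutation: the 36 labels are shuffled
uniformly 100 times, the full fold-wise training/testing is re-run per
shuffle, and the mean of the 100 shuffle accuracies is the chance level.
The ± spread reported alongside group chance levels is the SD pooled
over all shuffle accuracies (matching the ~13-point magnitudes such
protocols print); the across-participant SD of per-participant chance
means is also computable from the same results.

## 5. Correlation topographies

Per participant, the per-clip response (mean over the extracted 30 s,
per channel) is correlated across the 30 positive clips with each
cluster score and with valence, giving 24-channel r maps per
chromophore. The per-clip mean (rather than per-10-s-sample)
observations are the default — 30 paired observations per correlation —
with the alternative exposed in code. Group maps average r channel-wise;
inference is a one-sample t-test per channel on Fisher-z transformed r
(toggleable), BH-corrected across the 24 channels. Zero-variance
channels yield `NA` with a warning rather than an error.

## 6. The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions being emulated, and they are not tuned per analysis.

* **Schedule.** 37 clips: 1 neutral first, then 6 negative, then 30
  positive (order randomized within the last two blocks per
  participant). Clip durations are clip properties, drawn once per
  design from $30 + 99\,\mathrm{Beta}(2, 2.95)$ s — range 30–129 s, mean
  ≈ 70 s. Rests are 45 s plus uniform jitter up to 15 s; the recording
  starts with a 60-s lead-in so every clip has its 10-s baseline.
* **Ratings.** Each clip draws a latent 14-item profile from a Gaussian
  whose correlation matrix is the package's default target structure
  (projected to the nearest positive-definite matrix if needed). A
  deterministic elevation of 2.2 latent SD is added to the clip's
  target emotion and 1.4 to the target's cluster siblings — a clip
  built to elicit awe also elicits gratitude and inspiration — and
  negative clips depress the positive items and valence. Participants
  add a rater bias (SD 0.15) and independent noise (SD 0.6); values are
  discretised to 1–7 by equal-probability thresholds. These magnitudes
  were chosen so that manipulation checks pass decisively and top-6
  stimulus selection is mostly (not perfectly) cluster-pure, as in real
  materials; the latent-correlation recovery test evaluates the
  pre-shift profiles, since the elevation is deterministic and would
  otherwise distort the comparison.
* **Hemodynamics.** True concentration changes are cluster-specific
  spatial patterns (encouragement: medial HbO increase; playfulness:
  global HbR decrease; harmony: left-lateral; negative: right-lateral —
  caricatures on the montage's region grid, not measured quantities)
  times a boxcar with 5-s half-cosine ramps, scaled by a peak amplitude
  of 0.4 µM HbO, a per-participant log-normal factor (SD 0.2) and a
  per-clip gain (SD 0.25). Noise adds cardiac (1.2 Hz, 0.75 µM),
  respiratory (0.25 Hz, 0.4 µM) and Mayer (0.1 Hz, 0.3 µM) oscillations
  with small frequency jitter and random phase, a random-walk drift
  (1 µM), band-limited 0.01–0.2 Hz background (0.3 µM RMS — the
  component that actually survives filtering and windowing, hence the
  effective noise floor for decoding), and white noise (0.15 µM). HbR
  receives the same structure scaled by 0.35 with its own draws. The
  true series go through the *forward* Beer-Lambert model to optical
  density and to intensity $I = I_0 e^{-\Delta OD}$ with 0.05%
  multiplicative measurement noise.
* **What it does not emulate.** Motion artifacts, optode-coupling
  drifts, superficial/systemic physiology shared across channels,
  habituation across the session, and any real anatomical channel
  geometry. Passing tests therefore demonstrate the pipeline's
  correctness and statistical calibration, not field performance on
  real recordings.

## 7. Numerical choices and degenerate inputs

* Least-squares inversion via the normal equations (3×2 system, condition
  is excellent for realistic extinction tables); rank deficiency is an
  error at table construction and at inversion.
* Non-positive intensities abort OD conversion with channel, wavelength
  and time index named.
* Zero-variance features abort decoding; zero-variance channels in
  correlation maps yield flagged `NA`s; zero between-clip variance makes
  the ICC undefined (`NA` with warning); zero-variance post hoc pairs
  are flagged, not fatal.
* Ties in top-clip selection break by ascending clip id and are
  reported.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; equal (design, seed) pairs are bit-identical.

## 8. Problem sizes used by the test suite

The suite exercises reduced designs chosen to keep each property's
Monte-Carlo error well inside its assertion margin: single-participant
cohorts with one clip per emotion for recording-level loops (16 seeds
for null calibration, 12 for the 3×-noise power check), 500 virtual
feature-level participants for the decoding null, 3000 clips for latent
correlation recovery, 500 clips for ICC recovery, and the full
13-participant design for the end-to-end chance-level check (100
shuffles per classifier, 1300 shuffle accuracies in total). The
acceptance script runs the full-design chance-level computation from
scratch.

## 9. Known limitations

* The decoder is a single linear SVM per contrast; no feature selection,
  no nonlinear kernels, no slope/skewness/kurtosis features.
* Group-level inference on topographies assumes exchangeable
  participants and uses the Fisher-z t approximation, whose deep tail at
  13 participants is slightly anticonservative (visible in the
  global-null familywise calibration test).
* The SNIRF/HDF5 dialect is not implemented; long-format CSV is the
  supported interchange format.
* Absolute concentration units depend on the extinction/DPF table and
  are therefore nominal µM.
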