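---
title: "Recognizing preterm delivery from EHG signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing preterm delivery from EHG signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The electrohysterogram (EHG) records the electrical activity of the uterine
muscle from the abdominal surface. Its statistical character changes as
pregnancy progresses, and recordings made weeks before delivery carry
information about whether the pregnancy will end preterm (before 37
completed weeks). `ehgforest` implements a complete, reproducible analysis
for this question on cohorts shaped like the open term–preterm EHG
database: 3 bipolar channels, 20 Hz, 30-minute recordings, with gestational
age at recording and at delivery known per subject.

Subjects are stratified by *when* they were recorded: before gestational
week 26 ("early": groups PE = preterm, TE = term) or at/after it ("late":
PL, TL). A recording week of exactly 26.0 is late, and a delivery week of
exactly 37.0 is term; gestational ages given as weeks + days are converted
to fractional weeks (`weeks + days/7`). The two strata are analysed
independently.

## The pipeline

1. **Record I/O** — WFDB-style header/signal pairs (format 16, gestational
   metadata in `#Rectime`/`#Gestation` header comments) or a plain CSV
   dialect; a tab-separated cohort manifest ties records together.
2. **Preprocessing** — the third channel (electrode pair E4–E3) is the
   analysis channel; signals are band-limited to 0.08–4 Hz and the first
   and last 5 minutes are discarded, leaving 24,000 analysis samples of a
   30-minute record.
3. **Features** — 31 per record (below).
4. **Group statistics** — per-feature medians and quartiles per group and
   two-sided Mann–Whitney U tests for PE vs TE and PL vs TL at
   per-feature α = 0.05.
5. **Class balancing** — ADASYN oversampling of the preterm minority in
   feature space.
6. **Classification** — a random forest (89 trees, depth ≤ 20, up to 29
   candidate features per split) under stratified six-fold
   cross-validation, reporting accuracy, sensitivity (preterm detection
   rate), specificity, ROC/AUC and out-of-bag permutation feature
   importance.

## Preprocessing choices

The public database distributes band-passed signals, so by default a
record whose `prefiltered_band` metadata covers the requested band is
trimmed but not re-filtered; `force_filter = TRUE` applies the filter to
raw inputs. The filter is a cascade of 4th-order Butterworth high-pass
(0.08 Hz) and low-pass (4 Hz) sections, each applied forward–backward.
Zero-phase filtering keeps the trim boundaries aligned in time. A cascade
was chosen over a single band-pass design because a band design with a
normalized lower edge of 0.008 is numerically ill-conditioned at this
order; the cascade comfortably meets the targets verified in the test
suite (≥ 20 dB attenuation at half the lower edge and at twice the upper
edge, ≤ 1 dB ripple mid-band). No claim is made that the output is
waveform-identical to the database's own (unspecified) filter.

## The 31 features

*Time domain.* RMS amplitude; the lag (seconds) of the first zero
crossing of the biased, mean-removed autocorrelation, linearly
interpolated between samples (a constant or never-crossing signal yields
a flagged maximum-lag sentinel).

*Frequency domain.* From a plain untapered periodogram of the
mean-removed signal (resolution fs/N): peak frequency (lowest bin on
ties), median frequency (first bin where cumulative power reaches half
the total) and mean (centroid) frequency.

*Wavelet subbands.* A 6-level periodized symlet-5 decomposition; detail
levels 3–6 are reported as subbands W2–W5. Per subband: energy SE (sum of
squared coefficients), maximum SM (largest absolute coefficient),
singular value SS (largest singular value of the coefficient vector
arranged as a 20-row Hankel matrix) and variance SV. The periodized
transform is orthonormal, so subband energies add up to the signal energy
(exactly, for lengths divisible by 2^6; odd lengths are zero-padded per
level). The Hankel construction behind SS is a design choice — "singular
values of a coefficient vector" requires some matrix arrangement, and a
short-window Hankel (trajectory) matrix is the standard one in singular
spectrum analysis; the row count is configurable.

*Autoregressive model.* Yule–Walker AR(5) coefficients (convention
`x_m = a_1 x_(m-1) + ... + a_5 x_(m-5) + eps`) and the innovation-variance
estimate `e`. Yule–Walker with biased autocovariances is guaranteed
stable and is the convention under which white noise gives coefficients
near zero and `e` near the sample variance.

*Nonlinear.* Time reversibility `Tr = mean((x_m - x_(m-tau))^3)` with
`tau = 1`; the largest Lyapunov exponent by Rosenstein-style
nearest-neighbour divergence tracking on a (2, 1) delay embedding
(temporal exclusion window 10 samples, slope fitted over divergence steps
1–8); sample entropy with `m = 2`, `r = 0.1·SD`, Chebyshev distance,
self-matches excluded; and the Grassberger–Procaccia correlation
dimension, i.e. the least-squares slope of `log C(t)` vs `log t` over a
log-spaced grid of 16 thresholds spanning the 5th–50th percentile of
pairwise distances, computed on the scalar (dimension-1) embedding and on
`M - 1` of the `M` trimmed samples, matching the published pair-loop
convention. Scalar embedding also matches the small magnitudes the
original analysis reports (≈ 0.1–0.3).

Numerical notes: sample entropy with no matched template pairs, spectra
of constant signals, and similar degenerate cases return flagged `NaN`
sentinels rather than errors, and `extract_all()` never drops a feature.
The Lyapunov estimator caps the number of reference trajectories at 2,000
evenly strided points (neighbours are still searched over all points);
this stabilizes runtime at full record length with no measurable effect
on the map benchmarks in the test suite. For the correlation dimension,
the distance quantiles that place the scaling region are estimated from a
1,500-point strided subsample; the correlation sums themselves are exact
(a sorted two-pointer count in the scalar case, verified against a
double-loop oracle).

An optional short-window mode (`window_samples = 600`) computes RMS and
the spectral features per non-overlapping 30-s window and averages them,
since window-based amplitude/frequency estimates are common for EMG-like
signals; all other features always use the full trimmed record. The
full-record mode is the default everywhere.

## Group comparison

Medians with 25th/75th percentiles (linear-interpolation quantiles) per
feature and group; two-sided Mann–Whitney U tests, exact when the smaller
group has ≤ 8 observations without ties (irrelevant at the cohort sizes
here, where 19 vs 143 always takes the corrected normal approximation),
with tie and continuity corrections otherwise. No multiplicity correction
by default — the analysis convention is per-feature α = 0.05 — but a
Benjamini–Hochberg option is exposed. A mean ± SD summary mode is also
available.

## ADASYN

Synthetic preterm rows are generated as
`s = x_i + lambda (x_z - x_i)`, `lambda ~ U(0,1)`, where `x_i` is a
recorded minority row and `x_z` one of its `k = 5` nearest minority
neighbours. The number of offspring per minority point is proportional to
the fraction of majority points among its `k` nearest neighbours in the
full dataset, normalized, with largest-remainder rounding so the total is
exactly `G = round((n_maj - n_min)·beta)`; `beta = 1` balances the
classes (19 vs 143 gives exactly 124 synthetics). Neighbourhoods are
computed on z-scored features because the raw features span many orders
of magnitude; interpolation happens in the original space, so every
synthetic lies in the per-dimension bounding box of its two parents. If
every minority neighbourhood is purely minority (fully separated
classes), allocation falls back to uniform with a warning. `k` and `beta`
follow the original ADASYN publication; the source analysis states
neither, and its reported post-balancing totals (135 and 111) are not
reproducible from the counting rule for any single `beta`, so exact
replication of those totals is not claimed.

## Classification and evaluation

The forest replicates the published setting exactly: 89 trees, depth
limit 20, and up to 29 candidate features per split — kept although it
nearly disables split-level feature subsampling, as a fidelity-over-
convention choice. Scores are vote fractions; PRETERM is the positive
class. Folds are stratified (the source says only "randomly
partitioned"; stratification keeps both classes in every test fold at
19-minority cohort sizes). By default ADASYN runs *inside* each training
fold, so no synthetic row is ever evaluated; a `pre_split` mode
reproduces the published ordering (balancing described before
cross-validation) and is flagged as leakage-prone in the report. The ROC
is built from pooled out-of-fold scores with trapezoidal AUC, and the
mean of per-fold AUCs is reported alongside (the published AUC lying
below its accuracy suggests a non-pooled construction; both variants are
therefore emitted). Importance is out-of-bag permutation importance
(accuracy drop on permuted out-of-bag samples), clipped at zero,
averaged over folds, and normalized to percentages summing to 100 —
whether the original ranking was impurity- or permutation-based is not
stated; permutation importance is the less biased default.

## The synthetic-cohort generator

Real cohorts require an external download, so the generator emulates the
database's structure: per-record 3 channels at 20 Hz for 30 minutes,
cohort counts 19/143 (early) and 19/119 (late), gestational metadata
drawn consistently with each group's definition. The analysis channel is
an AR(5)-filtered Gaussian background (default coefficients 0.55, −0.25,
0.15, −0.08, 0.04; innovation SD 3 µV) plus Gaussian-windowed sinusoidal
bursts (Poisson rate 4 per recording, carriers 0.1–0.4 Hz, widths 20–60
s) that emulate contraction-like activity inside the analysis band.
Channels 1–2 are independent backgrounds plus the shared bursts.

Class structure enters through two interpretable dials chosen to
reproduce the direction and relative strength of the two strongest
published contrasts:

* **Amplitude** (`amplitude_ratio = 1.5`): early-stratum preterm records
  are scaled up, matching the reported ~1.6× preterm/term RMS ratio in
  the early stratum. A per-record log-normal amplitude factor
  (`amplitude_cv_log = 0.35`) reproduces the broad between-subject
  overlap the published quartiles show — without it, amplitude features
  would separate the classes perfectly, which the real data do not.
* **Regularity** (`regularity_shift = 6`): the "regular" class's channel
  is mixed with a two-component deterministic oscillation,
  `(1-w)·stochastic + w·sd·sqrt(2)·det` with `w = shift/(1+shift)`, with
  the carrier frequency and phases jittered per record so the class is
  recognizable by its low irregularity rather than by a fixed spectral
  line. The preterm class is the regular one in the early stratum and
  the term class in the late stratum, matching the opposite sample-
  entropy directions reported for the two strata. The default produces
  a roughly 2.5× sample-entropy contrast — strong and clearly separated,
  without attempting to match absolute published medians.

Setting `amplitude_ratio = 1` and `regularity_shift = 0` gives an exact
null: the class label then has no influence on the signal distribution.
What passing tests on this generator shows is that the *pipeline*
behaves correctly (calibrated nulls, recoverable effects, reproducible
reports); it does not show that real EHG recordings are this easy, and
the generator makes no attempt at electrode geometry, signal
propagation, or the artifact structure of clinical recordings.

## Problem sizes used in tests and the acceptance script

Full-scale (24,000-sample) records are used wherever the check concerns
full-scale arithmetic (feature arity, trimming, the pair-loop count,
closed-form estimator benchmarks). The simulation studies — null-AUC
calibration, strong-effect accuracy, importance ranking, pipeline
determinism — run on cohorts of 4-minute records trimmed by 0.5 minutes
(3,600 analysis samples) with the full early-stratum group sizes
(19/143), and balanced 60/60 cohorts for the null; these sizes were
chosen as the smallest at which the quantities of interest are stable,
and they are stated here so results can be read at the scale they were
computed.

## Known limitations

* The published headline numbers (accuracies, importance percentages,
  Table-style medians) were computed on the external clinical database
  and are not reproduced here; the pipeline supports running on it once
  downloaded, but all machine-checked results are property-based.
* The SS (singular value) feature depends on an undocumented matrix
  construction; a different arrangement would change its scale.
* The Lyapunov and correlation-dimension estimators are reported as
  descriptive features, with map-based benchmarks as accuracy checks;
  no claim of attractor reconstruction for stochastic EHG signals is
  intended.
* WFDB support covers the header/format-16 subset the cohort dialect
  needs, not the full specification.
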