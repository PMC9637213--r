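---
title: "Methods: CSP and Laplacian-mask features for two-group EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP and Laplacian-mask features for two-group EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease (PD) alters the cortical response to auditory stimuli
before motor symptoms allow a clinical diagnosis. Given multi-channel EEG
recorded under an auditory oddball paradigm (frequent *Standard* tones,
rare *Novelty*/*Target* sounds), the task is to decide from one recording
whether the subject belongs to the PD group or the healthy-control group.
`eegcsp` implements a complete pipeline for this two-group problem:
zero-phase band-pass filtering, onset-centered epoching, pooled group
averaging, Common Spatial Patterns (CSP) for feature extraction and channel
selection, surface-Laplacian mask features, a classical per-band baseline
feature set, and a fixed-split classifier harness. Because the clinical
recordings themselves are not redistributable, the package ships a
synthetic cohort generator that reproduces the statistical structure the
pipeline assumes, so every stage is testable end to end.

## The pipeline and its assumptions

### Preprocessing

Records are band-pass filtered per channel with a zero-phase (two-way)
least-squares FIR filter. The low edge is fixed at 0.1 Hz; the upper edge
is a grid parameter in {4, 13, 20, 30} Hz. The filter is linear-phase
(type I, odd length, default 1651 taps at 500 Hz ≈ 3.3 s) and is applied
forward and backward in one pass by convolving with its autocorrelation.
Two numerical choices matter:

* **Transition bands are pinned, not "don't care".** With a 0.05 Hz
  transition at the 0.1 Hz edge and a short filter, the classical firls
  formulation with unconstrained transition regions develops huge spurious
  lobes inside the transitions (we measured in-transition gains above 30;
  `scipy.signal.firls` reproduces the same pathology for the same
  specification). The design therefore covers all of [0, fs/2] with
  explicit linear ramps across the transitions. The pass band stays within
  about 1% of unity and stop-band rejection exceeds 20 dB (both asserted in
  tests).
* **Records shorter than three filter lengths refuse to filter** rather
  than returning transient-dominated output.

Epochs are 4 s (2000 samples at 500 Hz) with the task onset centered at
0-based index 1000; events whose window would cross a record edge are
skipped with a warning. Analysis intervals are half-open sample ranges
`[onset + start, onset + start + length)` with lengths 250/500/1000 ms and
start offsets `{0, 100, 200}` ms by convention (the start offset has little
effect and is treated as a free grid parameter).

### Pooled group averages

CSP is fitted not on single trials but on one averaged interval per group
and task: every interval of every record in the group is summed and divided
by the total interval count `z_tot`. Records with more intervals therefore
weigh more — this is deliberate and distinct from the "average of
per-record averages" construction, which is also implemented
(`method = "of_averages"`) but not the default. A two-record example (one
record with a single all-zero interval, one with three all-4 intervals)
distinguishes the two: the pooled average is 3, the average of averages 2.

### Common Spatial Patterns

For class covariances we use trace-normalized scatter matrices
`C = E Eᵀ / tr(E Eᵀ)`. The fit is the standard two-step CSP:

1. eigendecompose the composite `C_c = C_control + C_pd = U Λ Uᵀ` and
   whiten with `P = Λ^{-1/2} Uᵀ`;
2. diagonalize the whitened PD covariance `P C_pd Pᵀ = B D Bᵀ` and set
   `W = Bᵀ P`, ordered by `D` descending.

The published description of the algorithm compresses step 2 (it states
that the whitened class matrices "share common eigenvectors" without
spelling out the second diagonalization); the stated properties only hold
with the explicit second step, so the full standard algorithm is
implemented. `diag(D)` are the per-component PD-variance fractions
`λ_pd`; `λ_pd + λ_control = 1` by construction. The first three components
(`MxPMnC1..3`) maximize PD variance, the last three (`MnPMxC1..3`)
minimize it. Rows of `W` are spatial *filters*; columns of `W⁻¹` are
spatial *patterns* — the scalp projection of each component and the thing a
topographic plot shows.

Numerical choices: whitening uses `P = Λ^{-1/2} Uᵀ` (the orientation the
source text leaves ambiguous; both orientations whiten); eigenvalue order
is LAPACK's stable descending order; each component's sign is fixed so its
largest-magnitude pattern weight is positive; a numerically rank-deficient
composite receives a Tikhonov load of `1e-10 × tr(C_c)` with a warning.
Features are the natural log of the population variance (divide by *n*) of
the component signal over the interval, computed by default on the
record's averaged interval (`avg_then_map`); mapping each interval and
averaging the projections (`map_then_avg`) is also available and agrees to
float tolerance because both operations are linear.

**A caveat the tests make explicit:** the class covariances are estimated
from one averaged interval (60 channels × 250–500 samples of smooth,
band-limited signal), so their effective rank is far below the channel
count. Directions spanned by one class's residual noise but not the
other's then reach variance ratios near 1 and can outrank genuinely
discriminative components — the ratio is scale-invariant, so no SNR
improvement removes this. This is inherent to average-interval CSP at this
channel/sample ratio and is plausibly why the source analysis found its
best features in the *second and third* components rather than the first.
Filter/pattern *recovery* is therefore assessed on covariances estimated
from full 60-s records, where the sample support is three orders of
magnitude larger.

### Informative-channel ranking

The source analysis selected Laplacian mask centers by visually reading
the six extreme pattern maps. The package quantifies that reading: per
channel and component, `score = |weight| + mean |weight − neighbor
weight|` over the four grid neighbors, on raw pattern weights; the channel
score is the maximum over the six extreme components, rescaled to [0, 1].
Raw (not per-component-normalized) weights are used deliberately: patterns
equal `C_c Wᵀ` columns, so components carrying more signal variance have
proportionally larger patterns and dominate the score, which is what makes
the ranking meaningful when only a few components are informative. The
score is a documented quantification of a visual procedure, not a claim of
equivalence to it.

### Surface-Laplacian masks

Electrodes are placed on a rectangular row/column grid (rows Fp…O, columns
7,5,3,1,z,2,4,6,8). The mask output is
`y(n) = x_center(n) − ¼ Σ x_neighbor(n)` with neighbors at grid distance
d = 1 (small mask) or d = 2 (large mask); a center without all four
neighbors is infeasible and reported by name. The per-record feature is
the *mean* of the mask output over the averaged task interval — one number
per mask. Because the operator is linear, computing it on the average
interval equals averaging per-interval outputs (asserted at 1e-10). The
default candidate centers are F3, Fz, F4, FC3, FCz, FC4, C3, CPz plus C4
for left/right symmetry.

The exact clinical montage is not published with the recordings this
package targets; the default 60-channel layout is a conventional 10-10
grid arranged so that all nine candidate centers admit small masks and
F3/F4/C3/C4 admit large masks, and it is a configuration input
(`build_grid()`, `read_layout()`) so any cap can be described. Channels
with no natural grid position are declared off-grid rather than
force-fitted.

### Baseline features

The comparison feature set computes sample entropy (m = 2,
r = 0.2 × SD, the standard convention), RMS, median frequency and peak
frequency per interval in five bands (delta 0.1–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–100 Hz — the names are conventional, the edges are
configurable) for all three tasks and all channels, then averages over
intervals: 4 × 5 × 3 × 60 = 3600 features per 60-channel record. Median
frequency uses a midpoint-cumulative convention on the Hann periodogram
(each bin's power centered on its frequency) so that a single on-bin
spectral line returns its own frequency exactly and two equal lines return
their midpoint; peak-frequency ties break to the lowest frequency. Band
filters use 1 Hz interior transitions so adjacent-band powers add to the
broadband power within 5% on white noise.

### Classification

The cohort is split once, stratified by group, 60% learning / 40%
validation (25+25 subjects → 15+15 learning, 10+10 validation), persisted
to JSON with a hash so the split cannot silently change. PD is the
positive class: sensitivity = TP/(TP+FN) over PD records, specificity =
TN/(TN+FP) over controls. Six classifier kinds are provided: SVM with
polynomial (degree 3) and RBF kernels (C = 1, `gamma = 1/(p·var)`, an SMO
implementation — no SVM library is assumed), Gaussian naive Bayes, LDA and
QDA (via MASS), and a deterministic CART tree. SVM features are z-scored
with learning-set statistics; the other classifiers consume raw features.
The grid runner fits `W` and any feature scaling on learning records only
and applies them unchanged to validation records. On the split size used
here (20 validation records) accuracies are multiples of 5% — exactly the
granularity of the published figures.

The note on the source data's split: the publication states 15+15 learning
records out of 25+25 subjects but "12 from the patients … and 12 from the
controls" for validation. Only 10+10 validation is consistent with the
sizes and with the printed metric triples (85/70/100 and 90/80/100 are
the unique 10+10 confusion realizations); the package defaults to 15+15 /
10+10 and documents the discrepancy.

## The synthetic cohort: what it emulates and what it does not

A cohort is 25 control + 25 PD records (one per subject), 60 channels at
500 Hz, 60 s each, with 10 Standard / 2 Novelty / 2 Target events at ≥ 4 s
inter-onset gaps. Each record is

* background noise: per-channel 1/f-shaped (exponent 1) unit-variance
  series scaled by `noise_sigma` (default 10 µV) and mixed through a
  full-rank spatially smooth matrix (Gaussian kernel over grid distance,
  unit row norms), emulating volume conduction;
* optionally a group-specific background source along a planted unit-norm
  spatial direction (Gaussian profile centered on Fz);
* an onset-locked ERP template per event: spatial profile × time course ×
  group/task amplitude, with 10% lognormal per-record amplitude jitter.

The default time course is a **unipolar half-sine bump** (300 ms, peak 1),
resembling a P3-like slow positivity. An earlier design used a 10 Hz
damped cosine; that was abandoned because a zero-mean oscillation carries
almost no *mean* amplitude, making the Laplacian feature (an interval
mean) blind to any planted amplitude difference — the generator would then
be unable to exercise the mask-feature pathway it exists to test. The
damped cosine remains available (`erp_shape = "damped_cosine"`).

Two reference worlds are exported. `planted_cohort_config()` is the
high-SNR recovery world: a PD-only background source of 10 µV against 1 µV
spatially *white* noise (noise at one tenth of the planted source's
standard deviation) plus a doubled PD Standard-task ERP, both along the
Fz-centered direction. White noise is essential to the *filter*-recovery
claim: with spatially correlated noise the filter must decorrelate the
background and only the *pattern* can align with the planted direction —
the tests assert both cosines at full size, fitting the recovery model on
the whole cohort's raw records (recovery is a generator/CSP property with
no train/validation leakage concern; the classification grid still fits
`W` on learning records only). `null_cohort_config()` is the
same world with every group difference removed; on it, the best
grid-search validation accuracy must stay inside a Bonferroni-adjusted
binomial band around 50% (the adjustment accounts for selecting the
maximum over grid cells; Bonferroni is conservative for correlated cells,
which widens the band — the safe direction for a null check).

What the generator does **not** emulate: eye-blink/EMG artifacts (the
pipeline assumes artifact-cleaned input), realistic forward head
modelling, per-subject montage variation, medication on/off session
structure, or session-to-session nonstationarity. A green pipeline test on
synthetic data therefore establishes algorithmic correctness and
statistical sanity — not clinical performance on real recordings, whose
headline accuracies are not reproduced here.

## Known limitations

* Average-interval CSP is ill-posed at 60 channels × ≤ 500 samples (see
  above); component selection, not more data per interval, is the lever.
* The SMO SVM is a compact implementation adequate for tens of records;
  it is not tuned for large problems.
* The EDF importer handles the common case (uniform rate, 16-bit EDF/EDF+
  with an annotation channel); it is not a general EDF library.
* `sample_entropy` is O(n²); intended for interval-length series.
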