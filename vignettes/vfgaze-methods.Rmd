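---
title: "Detecting visual field defects from free-viewing gaze: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting visual field defects from free-viewing gaze: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vfgaze)
```

## The problem

Standard automated perimetry (SAP) demands prolonged fixation and explicit
button presses, which many patients find taxing. Free viewing of short video
clips is an attractive alternative signal: an observer with a visual field
defect (VFD), such as a glaucomatous scotoma, receives degraded bottom-up
input from the damaged region and — absent compensatory strategies — should
saccade toward salient events there less often, and agree less with where
healthy observers look at the same moment of the same clip. `vfgaze`
implements the full analysis chain needed to test this idea: per-trial event
features, directional saccade-amplitude rank profiles, the viewing-priority
statistic, visual-field maps with cohort rank comparison, kernel-PCA group
separation with naive-Bayes cross-validation, and integrated-visual-field
(IVF) scoring — plus a simulator that generates control and patient cohorts
with known ground truth.

## Coordinate conventions

Tracker files use a top-left pixel origin with y running downward. Everything
inside the package is screen-centered degrees, x right-positive and y
up-positive, converted per axis with true tangent geometry
(`px_to_deg()` / `deg_to_px()`): on a 50 × 35 cm screen at 60 cm the full
subtense is 45.2° × 32.5°, wide enough that a single deg/px scale factor
would be measurably wrong off-axis. The conversion is exactly invertible.
Whether the original analyses used linear or trigonometric conversion is not
documented anywhere we could find; the trigonometric choice is ours and is
exact.

Gaze-relative ("visual field") coordinates re-center on the current
fixation: each next fixation becomes a vector with leftward and downward
components negative (`to_vf_vectors()`).

## Events and basic features

`detect_events()` classifies raw samples with the standard velocity
(30 deg/s) and acceleration (8,000 deg/s²) thresholds, requiring the
excursion to be sustained over at least two samples. Velocity comes from a
3-sample central difference with no extra smoothing — the simplest
reproducible stand-in for a tracker's proprietary parser; consequently event
boundaries on smooth velocity profiles carry a few milliseconds of threshold-
crossing bias, which is irrelevant for duration/amplitude statistics at the
studied scales. Fixation fragments shorter than 40 ms (a default we chose to
absorb detection jitter; not externally specified) are merged into the
adjacent saccade. Events, together with flagged gaps, exactly tile the
sampled span.

`basic_features()` pools a participant's trials and reports median fixation
duration, fixation count, median saccade amplitude and median peak velocity.
Means are also returned: the methods sections of the source analyses say
"mean" while their results report medians, so the median is our default
reporting path. Group comparisons use the two-sample Wilcoxon-Mann-Whitney
rank-sum test (`compare_groups()`); the phrase "signed-rank" sometimes
attached to this test in the literature is a conflation — group sizes are
unequal, so only the rank-sum form applies. The z statistic uses the
tie-corrected normal approximation; Bonferroni-corrected alphas are rounded
to three decimals as conventionally reported (4 comparisons → 0.013,
3 → 0.017).

## Directional saccade-amplitude rank profiles

Saccades are binned into 18 half-open 20° direction sectors
(`directional_profile()`). A patient's per-bin median and maximum amplitude
is ranked within the control cohort with mid-rank tie handling
(`normalized_rank_profile()`); mid-ranks keep the rank uniform on [0, 1]
under exchangeability, which the 2.5%/97.5% tail flags presuppose. With *n*
controls the discrete flag probability is 2/(n+1), so calibration checks use
41 controls (≈ 4.9%). Controls are always ranked leave-one-out against the
remaining controls to avoid self-ranking bias.

`control_extent()` turns the cohort's directional envelope (per-bin group
median + 2 SD) into rectangular grid half-angles, assigning bins whose
centers lie within 45° of the horizontal axis to the horizontal extent — 18
sectors do not reduce to one horizontal and one vertical number by
themselves, so this split is our definition — and snapping up to whole bins.

## Viewing priority

The viewing priority (VP) of a fixation expresses how closely it matches
where a reference cohort looked at the same moment of the same clip, while
discounting where that cohort looks regardless of content (center bias,
screen layout). The verbal contract we implement: *reference* fixations are
cohort fixations on the same clip whose intervals overlap a ±500 ms window
around the scored fixation's onset; *random* fixations are the cohort's
fixations in the same window on other clips; the scored observer is always
excluded; reference and random sets always come from the control cohort.

The concrete statistic is a cluster-priority construction built on fuzzy
c-means (FCM):

1. Fit C = 5 FCM clusters (fuzzifier m = 2) to the reference set and,
   separately, to the random set; pool the 2C centers.
2. Give every center a priority
   `A_k / (A_k + B_k · n_ref / n_rand)`, where `A_k` and `B_k` are the
   summed FCM memberships of the reference and random points under center k
   (the rebalancing factor makes exchangeable sets score 0.5 regardless of
   set sizes).
3. Score the fixation as its membership-weighted mean priority, clamped to
   [0, 1].

An all-reference neighborhood scores → 1, an all-random neighborhood → 0,
exchangeable sets ≈ 0.5, and the statistic is invariant under rigid motions
of the whole configuration. When the random set is empty the construction
falls back to a uniform baseline (one reference-set's worth of mass spread
evenly over the centers) and logs it. FCM is implemented in-package (15
lines of vectorized alternating updates) because scoring out-of-sample
points and deterministic seeded initialization are both needed; the test
suite cross-checks it against `e1071::cmeans`. Window half-width, C, m,
tolerance (1e-4 on memberships), iteration cap and seed are all exposed in
`vp_params()`.

For whole cohorts, `vp_cohort()` groups fixations into 500-ms windows per
clip, fits each window's clusters once on the full control cohort, and
applies the leave-one-out exclusion *exactly* on the mass counts by
subtracting the scored control's own memberships before priorities are
formed. This makes the cohort computation roughly two orders of magnitude
cheaper than per-fixation refits while changing only the temporal
quantization of the window (onset-quantized rather than onset-centered); the
per-fixation contract remains available as `assemble_sets()` +
`compute_vp()` and is what the unit tests pin down.

Whether VP should be rescaled per clip or globally is not externally
specified; we emit raw per-fixation values and leave any recalibration to
the caller (`summarize_vp()` averages per trial, then per participant, and
correlates the result with MD and IVF-score covariates).

## Visual-field maps

* `fixation_heatmap()` — each fixation is an isotropic Gaussian with
  σ = 1° (≈ tracker accuracy and foveal extent). Bins store exact Gaussian
  *mass* (per-axis normal CDF differences), so maps are additive and total
  mass equals the fixation count up to edge losses; dividing a VP-weighted
  heat map by the unweighted one yields `average_vp_map()`, masked where the
  fixation mass is below 1e-3 (the continuous VP surface is undefined where
  nobody looked; the threshold is ours).
* `count_map()` — plain bin counts on a 2° grid, normalized by the maximum
  (fixation maps used for kernels) or by the sum (endpoint proportion maps).
* `saccade_map()` — the 12 × 10° half-angle endpoint-proportion grid with
  the four central bins excluded (116 scored bins); the companion
  fixation-distribution variant keeps the central bins.
* `relative_rank_map()` — per-participant z-normalization over unmasked bins
  followed by per-bin mid-ranking of the patient among the controls; 0.5
  means typical.
* `binned_map_vs_sensitivity()` — 6° cells centered on the true HFA 24-2 or
  30-2 test locations (not an arbitrary square tiling), paired with the dB
  thresholds and correlated with `pearson_r()`; blind-spot locations at
  (15, ±3)° are excluded. The 24-2 lattice is the 6°-spaced grid offset 3°
  from the meridians with |x|+|y| ≤ 30 plus the two nasal points (54
  locations, 52 scored); 30-2 is the analogous 76-point grid, and "the
  central 30°" is read as the ±30° HFA layout.

## Kernel PCA and classification

Per-clip fixation maps on the control-derived grid feed two kernels between
participants i and j: the all-clips kernel
`exp(-0.5 ((meanDist + maxDist)/σ)²)` on the mean and maximum of the
per-clip Euclidean map distances (σ = 2 for fixation/VP maps, σ = 0.2 for
saccade maps, whose values have far smaller variance; both exposed in
`kernel_spec()`), and the per-clip kernel `exp(-Dist)`. These kernels are
not guaranteed positive semidefinite, so `kpca_project()` double-centers,
eigendecomposes, drops negative eigenvalues (reporting their mass), scales
eigenvectors by the square roots of their eigenvalues, and fixes each
component's sign by its largest-magnitude loading. Explained-variance
fractions are over the retained positive spectrum. The first five components
feed a Gaussian naive-Bayes classifier (`e1071::naiveBayes`) evaluated with
stratified 10-fold cross-validation (`nb_crossval()`; stratification is our
choice — plain folds can produce single-class training sets at these sample
sizes, and any such fold is redrawn and logged). Accuracy is reported as
"mean% (min – max%)".

## Perimetry

`merge_ivf()` is the best-location binocular merge: after left-eye fields
are mirrored into right-eye orientation on read, the integrated field is the
positionwise maximum. `ivf_score()` sums 0/1/2 penalties over the 52 scored
locations (≥ 20 dB → 0; [10, 20) → 1; < 10 → 2; the middle class is made
half-open so the three classes tile the dB axis — the printed "between 10
and 19 dB" would otherwise leave (19, 20) unassigned). `md_summaries()`
signs the between-eye MD difference as open minus covered, so positive means
the better eye was tested. A bundled example table of 19 patients
(`inst/extdata/patient_clinical_summary.csv`: MD of tested and covered eye,
IVF score) supports worked examples and tests.

## The synthetic cohort

`make_cohort()` generates everything the pipeline consumes, with ground
truth. Design:

* **Salience track** (`make_track()`) — a single salient target per clip,
  piecewise constant, jumping at Poisson times (0.5 jumps/s by default) to
  uniform positions in an inset screen box. This stands in for video
  content: it produces the shared, time-locked gaze consistency that VP
  rewards, and its jumps elicit the long saccades that distinguish the
  groups. It does not model photometric saliency, semantics or storylines.
* **Sensitivity fields** (`make_field()`) — 30 dB age-normal baseline, 1 dB
  measurement noise, archetype regions (peripheral loss, nasal arc, tunnel
  vision, central loss, blind) attenuated toward 0 dB by a severity in
  [0, 1]. MD is the mean departure from baseline.
* **Observer** (`simulate_trial()`) — log-normal fixation durations (median
  280 ms, σ_log 0.4); after each fixation the target is detected with
  probability `plogis(0.237 · (dB − 13.6))` (≈ 0.98 at 30 dB, ≈ 0.3 at
  10 dB), where dB is the field sensitivity at the target's gaze-relative
  location; a detected target farther than 2° is followed with p = 0.8 plus
  1° landing noise; otherwise the observer makes a small exploratory saccade
  pulled 30% toward screen center with 2.5° step noise — keeping exploration
  center-clustered and small, so a defect removes the long target-driven
  saccades without adding artifactual large relocations. An optional
  compensation probability redirects unfollowed saccades into the damaged
  field instead. Peak velocity is filled from the main sequence
  `500 · (1 − exp(−amplitude/5))` deg/s. These defaults were chosen once to
  reproduce the order of magnitude of real control statistics (≈ 3
  fixations/s, median amplitudes of a few degrees) and are not fitted to any
  outcome.
* **Regimes** — monocular simulates through the tested eye's field (severe
  by default; the fellow eye mild at severity 0.2, i.e. asymmetric disease),
  binocular through the best-location IVF. With asymmetric fields the IVF is
  nearly intact, so binocular group differences shrink — the central
  monocular-vs-binocular contrast the pipeline is designed to exhibit.

All randomness derives from one master seed through a documented splitting
scheme; identical configs give byte-identical event tables.

**What passing tests do and do not show.** The simulator captures the two
causal mechanisms of interest (bottom-up loss, top-down compensation),
center bias, and the main sequence. It does not capture semantic gaze
guidance, smooth pursuit, blinks, tracker noise spectra, clip-to-clip
content variability, or adaptation over time. Recovery of the defect signal
from synthetic cohorts therefore validates the *pipeline's statistical
machinery*, not the clinical effect size in real patients.

## Problem sizes used in the checks

The bundled checks run the study-sized synthetic cohort — 20 controls and 20
patients (mixed archetypes at full severity, no compensation), 10 clips of
60 s — over 20 master seeds for the viewing-priority and direction-resolved
mechanism checks, 10 seeds for the classifier (with a matched defects-off
null), and 8 controls / 8 patients × 3 clips × 30 s × 20 seeds per regime
for the monocular-vs-binocular contrast; rank-calibration checks use 200
resamples of a 41-observer homogeneous pool. These sizes are the package's
reference conditions and are stated here so the reported numbers are
interpretable.

## Known limitations

* ASC support is limited to EFIX/ESACC/MSG lines; proprietary EDF binaries
  are out of scope, as are calibration and live tracker control.
* The VP construction satisfies the verbal contract of the original
  statistic but is our concrete instantiation; absolute VP levels are not
  comparable across implementations (medians here run lower than the ≈ 0.9
  reported for real control cohorts, whose reference sets are denser in
  time).
* Event detection boundary accuracy is limited by threshold crossing on
  smooth profiles (a few ms), and no blink reconstruction, microsaccade or
  smooth-pursuit classification is attempted.
* Rank-map and rank-profile inference is descriptive (flags, not tests), by
  design.
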