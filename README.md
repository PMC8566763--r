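# vfgaze

Detecting and localizing visual field defects from free-viewing eye
movements.

## The problem

Glaucomatous visual field defects (VFDs) are normally mapped with standard
automated perimetry (SAP), a demanding test requiring sustained fixation and
button presses. Free viewing of video clips is a candidate low-burden
alternative: a patient whose visual field is damaged receives less bottom-up
input from the damaged region and — without compensatory strategies — should
saccade toward salient events there less often, and should agree less with
where healthy observers look at the same moment of the same clip. `vfgaze`
implements the analysis pipeline needed to test and apply this idea, plus a
scotoma-conditioned scanpath simulator that generates cohorts with known
ground truth for calibration and power checks.

## What it computes

For trials of fixations/saccades (CSV event tables, EyeLink ASC event lines,
or raw gaze samples via built-in event detection):

* **Basic features** — per-participant median fixation duration, fixation
  count, saccade amplitude and peak velocity; group comparison by the
  two-sample Wilcoxon–Mann–Whitney rank-sum test with Bonferroni-corrected
  alphas.
* **Directional rank profiles** — median/maximum saccade amplitude in 18
  direction bins of 20°, ranked against a control cohort
  (rank = (#smaller + ties/2)/n, flagged outside [0.025, 0.975]).
* **Viewing priority (VP)** — a per-fixation statistic in [0, 1] expressing
  how closely the fixation matches where a reference cohort looked during
  the same ±500 ms of the same clip, discounted by where that cohort looks
  regardless of content. Built on fuzzy c-means cluster priorities:
  clusters fitted to the time-matched *reference* set (same clip) and
  *random* set (other clips) receive priorities
  `A_k / (A_k + B_k · n_ref/n_rand)` from the two sets' membership masses,
  and a fixation scores its membership-weighted priority.
* **Visual-field maps** — gaze-relative Gaussian heat maps (σ = 1°, exact
  per-bin mass), average-VP maps, count/proportion maps on 2° grids sized
  from the control cohort's saccade envelope, z-normalized relative-rank
  maps against controls, 12×10°-half-angle saccade-endpoint maps with the
  central four bins excluded, and HFA 24-2/30-2-aligned 6° binning
  correlated against SAP dB sensitivities.
* **Group separation** — kernel PCA on map distances
  (`exp(-0.5((meanDist+maxDist)/σ)²)` over all clips, `exp(-Dist)` per
  clip), first five components classified by Gaussian naive Bayes under
  stratified 10-fold cross-validation.
* **Perimetry** — best-location binocular merge (integrated visual field),
  the 0–104 IVF score over 52 locations (≥20 dB → 0, [10, 20) → 1,
  <10 dB → 2), and signed between-eye MD differences.

See `vignettes/vfgaze-methods.Rmd` for the models, parameter defaults and
their rationale, and known limitations.

## Worked example

Simulate a small monocular cohort (8 controls, 8 patients with full-severity
defects, 3 clips × 30 s), then run the three core analyses:

```r
library(vfgaze)

coh <- make_cohort(cohort_config(n_controls = 8, n_patients = 8,
                                 n_clips = 3, clip_duration_s = 30, seed = 42))
parts <- vapply(coh$trials, `[[`, "", "participant")
ids <- unique(parts)
is_ctl <- ids %in% coh$control_ids

# 1. basic features: patients make shorter saccades
feat <- do.call(rbind, lapply(ids, function(id)
  basic_features(coh$trials[parts == id])))
compare_groups(feat$sacc_amplitude_deg[is_ctl],
               feat$sacc_amplitude_deg[!is_ctl], n_comparisons = 4)
#> rank-sum: medians 4.872 vs 4.305, U = 64, z = 3.361, p = 0.0001554 (alpha = 0.013) *

# 2. viewing priority: patients agree less with the control cohort
vp <- vp_cohort(coh$trials, coh$control_ids, vp_params(seed = 42))
sm <- summarize_vp(vp)
vps <- sm$overall$mean_vp[match(ids, sm$overall$participant)]
compare_groups(vps[is_ctl], vps[!is_ctl], n_comparisons = 4)
#> rank-sum: medians 0.7957 vs 0.6589, U = 64, z = 3.361, p = 0.0001554 (alpha = 0.013) *

# 3. kernel PCA + naive Bayes on fixation maps
fm <- cohort_fixation_maps(coh$trials, coh$control_ids)
emb <- kpca_project(kernel_matrix(fm$maps, kernel_spec("all_clips", 2)))
nb <- nb_crossval(emb$projections,
                  ifelse(ids %in% coh$control_ids, "control", "patient"),
                  classifier_config(seed = 42))
nb$formatted
#> "68.8% (50.0 - 100.0%)"

# perimetry: a full-severity tunnel field and its IVF score
tun <- make_field("tunnel", severity = 1, seed = 7)
tun
#> sensitivity_field: hfa24_2, right eye, 54 locations (52 scored), MD = -22.57793 dB
ivf_score(merge_ivf(tun, tun))
#> [1] 80
```

The rank-sum lines read: control vs patient group medians (saccade
amplitude 4.87° vs 4.31°; mean VP 0.80 vs 0.66), the Mann–Whitney U and z
statistics, the two-sided p, and the Bonferroni-corrected alpha for four
comparisons; the `*` marks significance. The tunnel field attenuates all
24-2 locations beyond 10° eccentricity to 0 dB, so its 40 damaged scored
locations each contribute 2 points: IVF score 80 of a possible 104.

`run_pipeline(run_config(out_dir, ...))` chains all stages (features,
directional profiles, VP, maps, classification, IVF) and writes CSV tables,
map files and a JSON summary; configs can also be read from YAML with
`read_run_config()`.

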