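---
title: "Degree centrality and treatment-response prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree centrality and treatment-response prediction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcpredict)
```

This vignette documents the models implemented in `dcpredict`, the
parameters that matter, the synthetic-cohort generator that stands in for
restricted patient data, and the design decisions taken where the
procedure admitted more than one reasonable reading.

## The pipeline

The package analyses resting-state BOLD fMRI of a two-group (patient /
control), two-session (pre- / post-treatment) cohort in five stages:

1. **Temporal preprocessing.** Drop the first 10 volumes (magnetization
   equilibrium), compute frame-wise displacement (FD) from the six
   realignment parameters, exclude any session whose parameters exceed
   2 mm translation or 2 degrees rotation, regress out the Friston-24
   motion expansion plus the global signal, and band-pass filter to
   0.01–0.08 Hz. Spatial steps (realignment estimation, normalization)
   are assumed done upstream; the pipeline takes already-aligned volumes
   on a common 3 mm grid.
2. **Degree centrality (DC).** Pearson-correlate every pair of in-mask
   voxel time courses; an edge exists where r strictly exceeds 0.25;
   DC is the per-voxel edge count (binary, default) or the sum of
   suprathreshold correlations (weighted option). The map is z-scored
   over the mask and smoothed with a 6 mm FWHM Gaussian.
3. **Group inference.** Voxelwise GLMs: a two-sample contrast (patients
   vs controls at baseline) and a paired contrast (baseline vs
   follow-up), both adjusted for age, gender, education, and mean FD,
   with Benjamini–Hochberg FDR at q = 0.05. The binarized paired
   difference is the classifier's feature mask.
4. **Response classification.** Patients are labeled responders when
   their PANSS total falls by strictly more than 50%. Baseline smoothed
   DC z values inside the feature mask feed a linear soft-margin SVM
   (C = 1) under leave-one-out cross-validation; significance comes from
   a permutation test (1000 label permutations by default); the primal
   weight vector is back-projected into the volume and regions ranked by
   their percentage of the total absolute weight.
5. **Symptom correlation.** Per region and PANSS subscale, Pearson
   correlation between the mean DC change (baseline minus follow-up) and
   the symptom change (same direction, so improvement is positive), with
   one BH-FDR pass over the whole region-by-subscale family.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `n_discard` | 10 volumes | equilibration volumes dropped |
| head radius | 50 mm | converts rotations to mm in FD |
| exclusion | 2 mm / 2° | max absolute realignment parameter |
| band | 0.01–0.08 Hz | pass band (bin-inclusive, ideal filter) |
| `r_threshold` | 0.25 | edge threshold on signed r, strict |
| `fwhm_mm` | 6 mm | smoothing kernel FWHM |
| `q` | 0.05 | FDR level |
| `C` | 1 | SVM soft-margin parameter (never tuned) |
| `n_permutations` | 1000 | label permutations |
| `responder_threshold` | 0.5 | fractional PANSS-total reduction |

## Design decisions

- **FD definition.** The mean FD covariate uses the Power-style formula:
  sum of absolute translation differences plus 50 mm times the sum of
  absolute rotation differences between consecutive volumes. The
  exclusion rule is read as a cap on the absolute realignment parameters
  themselves (2 mm, 2°), the conventional reading of that phrasing, not
  as an FD threshold.
- **Filter.** A discrete-Fourier ideal band-pass with bin-inclusive
  edges, applied to demeaned series. Pure in-band sinusoids pass within
  1%; out-of-band sinusoids are attenuated by over 99%. The filter is
  linear and idempotent on its pass band.
- **Order of operations.** Discard, then FD (on the post-discard motion
  rows), then confound regression, then band-pass. Regressing before
  filtering follows the processing order the pipeline is modeled on;
  the confound matrix is not itself band-limited.
- **Binary vs weighted DC.** The defining equation of DC uses 0/1
  adjacency, while the surrounding text of the method this implements
  speaks of a weighted map; the package defaults to the printed equation
  (binary) and offers `binary_degree = FALSE` for the weighted reading.
  Both are tested against a naive all-pairs oracle.
- **Threshold on signed r.** Edges require r > 0.25, strictly;
  anticorrelated voxels are never connected. Zero-variance voxels
  contribute no edges (with a warning) rather than aborting the map.
- **z-scoring** uses the in-mask sample SD (n − 1); the resulting map is
  affine-invariant to the raw degree scale. Smoothing is applied after
  z-scoring.
- **Two-sided p values, BH FDR.** Sidedness is not otherwise specified;
  two-sided is the imaging convention. "FDR" is Benjamini–Hochberg, the
  neuroimaging default; no cluster-extent thresholding is applied.
- **Paired covariates.** Whether covariates enter the paired test is
  ambiguous in the procedure modeled here; both are supported
  (`paired_covariates`), and the covariates are mean-centered so the
  intercept remains the adjusted mean paired difference.
- **Feature-mask circularity.** The feature mask derives from the
  patients' own baseline-vs-follow-up contrast, which includes the
  subjects later classified. This mirrors the modeled procedure and is
  flagged here: mask selection is not nested inside the LOOCV loop, so
  the accuracy estimates inherit that optimism in real applications.
  On the synthetic cohorts the planted responder signature is
  mean-balanced, so the univariate mask selection is not informed by the
  labels.
- **PANSS reduction** is computed on raw totals,
  (baseline − followup)/baseline, with a strict > 50% rule; the
  floor-corrected variant (baseline − 30) is deliberately not used.
- **Feature standardization.** Features are standardized per column with
  mean and SD estimated on the training fold only, avoiding leakage into
  the held-out subject. This choice is configurable
  (`standardize = FALSE` gives raw-scale kernels).
- **Permutation p** uses the add-one estimator
  (1 + #{null ≥ observed})/(1 + B): conservative, never zero, and exactly
  reproducible under a seed.
- **AUC** is the Mann–Whitney probability computed from the pooled
  held-out decision values across LOOCV folds, ties counted one half.
- **Region labels** come from an integer atlas volume supplied by the
  caller; the synthetic generator emits its own ground-truth atlas
  (region 1 = planted hub region, remaining mask split into octants).
  Peak coordinates are reported in voxel indices, plus affine-mapped mm
  when an affine is available.
- **ΔPANSS direction** is baseline − follow-up, so improvement is
  positive and a negative DC–symptom correlation means a larger DC
  decrease accompanies a smaller symptom improvement. The FDR family for
  the correlation stage is all regions × all four subscales in one pass.

## The synthetic cohort

Real cohorts of this kind are restricted, so the generator is a
first-class, tested module whose ground truth the downstream stages must
recover.

**Signal model.** Every in-mask voxel is a weighted sum of K shared
latent signals plus independent noise, all stationary Gaussian AR(1).
Non-hub voxels load on exactly one latent with weight 1, partitioning the
background into K functional communities whose members correlate at
1/(1 + σ²). Hub voxels load on *every* latent with per-latent weight
`hub_loading` in a fixed, balanced random-sign pattern, which connects
them to all communities at once — genuinely higher graph degree, the
defining property of a hub. Two features of this construction matter:

- *Sign balance.* A hub that loaded uniformly on all latents would be
  nearly collinear with the global mean signal, and global-signal
  regression would annihilate it. Balanced ± patterns keep hub signals
  near-orthogonal to the global mean, so hub degree survives the
  pipeline's own preprocessing.
- *Slow latents, broadband noise.* Latents default to AR 0.8 (power
  concentrated at low frequencies, as hemodynamic fluctuations are) and
  the voxel noise to AR 0.3 (broadband). The 0.01–0.08 Hz band then
  retains most of the signal and rejects most of the noise — the reason
  that band is used on real data, reproduced in miniature.

**The loading–DC response curve.** The measured hub z-DC is a saturating
function of `hub_loading`: below about 0.25 hubs blend into the
background, between about 0.25 and 0.7 the curve is steep
(roughly 3–4 z units per loading unit at the bottom, flattening above),
and past 0.9 the hub–community correlation saturates near its ceiling
1/sqrt(K(1 + σ_eff²)). All planted effects are placed on the responsive
part of this curve.

**Planted effects.**

- *Diagnosis effect*: patients at baseline carry hub loading
  `hub_loading + effect_delta`; at follow-up it renormalizes to
  `hub_loading`, the controls' level — the restoration phenomenon the
  paired contrast should find.
- *Response signature*: every patient carries an antisymmetric
  redistribution of baseline hub loading over two blocks (a quarter of
  the hub region each) at opposite ends of the region, of magnitude
  `responder_effect`; its **sign** encodes response. Group and region
  means are untouched, so univariate contrasts stay homogeneous while
  the multivariate classifier has a genuine spatial pattern to learn —
  the regime multivariate pattern analysis is meant for. The blocks sit
  at opposite ends of the region so that 6 mm smoothing cannot cancel
  the pattern.
- *Symptom coupling*: a per-subject latent u drives both the baseline
  hub-loading increment (`loading_sd`·u) and the positive-score
  improvement (correlation `symptom_coupling`), so the planted
  ΔDC–ΔPANSS correlation is known. In coupling mode the baseline
  positive score is drawn with a narrower spread so the planted
  improvement rarely collides with the subscale floor of 7, which would
  otherwise attenuate the recovered correlation.

**PANSS trajectories.** Baseline subscales are drawn near the printed
first-episode ranges (positive 7–31, negative 7–34, general 30–64;
total constrained to 63–124); follow-up totals are set so the strict
50% rule matches the planted responder flag exactly, including after
integer rounding. Demographics (age, gender, education) are drawn from
distributions matching the published group summaries so the
covariate-adjusted GLM path is exercised realistically.

**Defaults as study conditions.** 38 subjects per group, responder
fraction 0.5 (a 19/19 split), TR 2 s, 120 retained volumes on a
12×12×12 grid of 3 mm voxels with an ellipsoid mask (912 voxels, 46
hubs), K = 6 latents, `hub_loading` 0.25, `effect_delta` 0.4,
`responder_effect` 0.2, `loading_sd` 0.1, noise SD 1, motion-step SD
0.02 mm.

**What the generator does not emulate.** No hemodynamic response
function, no anatomy, no spatial noise correlations beyond the planted
smoothing, no scanner drift or physiological artifacts, no
susceptibility dropout. Passing tests therefore demonstrate that the
pipeline's statistics are calibrated and that planted connectivity
effects of realistic magnitude are recovered — not that the pipeline is
robust to every artifact of real scanners.

## Calibration checks and the problem sizes used

The acceptance suite verifies, at sizes chosen to keep a laptop-scale
run:

- *Printed-table reproduction*: the education and age group comparisons
  recompute to t = −2.7 and −0.2 from summary statistics, and the
  balanced gender table to χ² = 0; the unique 19/19 confusion matrix
  (TP 15, FN 4, TN 17, FP 2) yields 84.2% / 78.9% / 89.5%.
- *Oracle equivalence*: block-wise degree equals the naive all-pairs
  computation exactly on 50 random instances up to V = 500, T = 50,
  both binary and weighted, at thresholds 0.1 / 0.25 / 0.5.
- *Null calibration*: 500 null voxel sets give an FDR-significant
  fraction far below q + 0.01; 50 pure-noise LOOCV runs at n = 38
  average within 0.5 ± 0.1; 100 permutation tests on noise (n = 26,
  99 permutations each) give p values consistent with uniformity
  (Kolmogorov–Smirnov at α = 0.01 — the add-one estimator on a discrete
  accuracy is slightly conservative by construction, visible as a mean
  p just above 0.5, within the test's tolerance at this size).
- *Effect recovery*: with a strong planted effect (`hub_loading` 0.25,
  `effect_delta` 0.42, `responder_effect` 0.36 — the widest usable span
  of the response curve), a 10-vs-10 cohort recovers ≥ 80% of hub
  voxels in both FDR-corrected t maps, and a 10-responder vs
  10-nonresponder cohort reaches LOOCV accuracy ≥ 0.9 with the planted
  region ranked first. Each contrast is tested at 10 subjects per
  group of that contrast; at 5-vs-5 the linear SVM over a ~150-voxel
  mask is unstable for any effect size (a small-sample property of
  MVPA, not of the planted signal — a single region-contrast feature
  classifies those cohorts perfectly).
- *Coupling recovery*: planted ρ ∈ {−0.5, 0, 0.5} between hub ΔDC and
  positive-score improvement is recovered within ±0.15, averaged over
  50 replicates of n = 38 patients (8³ grid, 150 volumes,
  `loading_sd` 0.35; DC computed on the generated series directly,
  since the coupling property concerns the DC and correlation stages).
  The residual gap (≈0.43 recovered for 0.5 planted) is honest
  attenuation: finite-T degree estimation noise and integer PANSS
  scores.
- *Determinism*: identical configs and seeds reproduce cohorts
  bit for bit and pipeline reports exactly.

## Numerical notes

- Correlations are computed blockwise from standardized columns
  (`crossprod`), never materializing the V×V matrix beyond
  V × `chunk_size`; the strict r > threshold comparison is applied to
  the same floating-point quantity the naive oracle computes, and exact
  agreement is asserted in tests.
- The Gaussian kernel uses σ = FWHM/(2·sqrt(2·ln 2)·voxel size) per
  axis, a radius of 4σ, unit-sum normalization, and mirror (reflect)
  boundaries, so constant volumes are preserved to 1e−12.
- GLM t maps solve the normal equations once per design and reuse the
  factorization across voxels; rank-deficient designs are an error that
  names the collinear columns rather than a silent drop.
- Degenerate cases are policy, not crashes: zero-variance voxels lose
  their edges with a warning; zero-variance correlation pairs are
  flagged undefined and excluded from the FDR family; an empty feature
  mask skips the classifier stage and reports it.

## Known limitations

- No spatial preprocessing: volumes must already be aligned and
  normalized; no slice-timing correction.
- The feature-selection circularity noted above is reproduced by
  design, not fixed.
- Permutation tests refit the full LOOCV per permutation; at study
  sizes this is minutes of compute, and the analysis scripts use 1000
  permutations only where the result is reported.
- The synthetic generator's ground truth is a low-dimensional latent
  model; effect sizes quoted for it do not translate directly to real
  scanners.
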