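# dcpredict

Graph-based degree centrality from resting-state fMRI, and its use to
predict antipsychotic treatment response in first-episode schizophrenia.

Not all patients with schizophrenia respond to antipsychotic medication,
and group-level fMRI differences do not by themselves help the individual
patient. This package implements, end to end, a pipeline that (i) maps
voxelwise **degree centrality** (DC) — how many other voxels a voxel's BOLD
time course correlates with — before and after treatment, (ii) tests where
patients differ from controls and where treatment renormalizes DC, (iii)
trains a linear support-vector machine on baseline DC to classify
responders (patients whose PANSS total score falls by more than 50%) from
nonresponders, and (iv) correlates regional DC change with symptom change.
Because clinical rs-fMRI cohorts of this kind are access-restricted, the
package ships a synthetic-cohort generator with known ground truth (planted
hub regions, planted response signatures, planted symptom coupling) so that
every stage can be tested and calibrated.

## The statistic at the core

For the in-mask voxels of a preprocessed BOLD series, compute all pairwise
Pearson correlations r_ij and form an undirected graph with

    a_ij = 1  if r_ij > 0.25,   a_ij = 0 otherwise

(the threshold removes weak, noise-driven correlations; anticorrelations
never form edges). The degree centrality of voxel i is

    DC_i = sum_j a_ij            (binary; a weighted variant sums the r_ij)

DC maps are z-scored over the mask and smoothed with a 6 mm FWHM Gaussian.
Group inference uses voxelwise GLMs (two-sample and paired t, with age,
gender, education, and mean frame-wise displacement as covariates) at
P < 0.05 after Benjamini–Hochberg FDR correction. The binarized
baseline-vs-follow-up difference is the feature mask for a linear SVM
(C = 1) evaluated by leave-one-out cross-validation with a 1000-permutation
significance test; the primal weight map ranks regions by their share of
the total absolute weight.

## Worked example

The numbered scripts under `analysis/` run the full study on the synthetic
cohort (38 patients with two sessions, 38 controls, 12x12x12 voxel grid at
3 mm, 120 retained volumes at TR 2 s):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess_and_dc.R
Rscript analysis/03_group_inference.R
Rscript analysis/04_classify_response.R
Rscript analysis/05_symptom_correlation.R
```

Output of the first two stages:

```
Simulated 114 subject-sessions on a 12x12x12 grid (912 in-mask voxels,
46 planted hub voxels). Patients: 19 responders / 19 nonresponders.
Simulated demographics: age t = 0.1 (p = 0.94), education t = -3.0 (p = 0.004), gender chi2 = 0.48.
...
Preprocessed 114 sessions; 0 excluded for head motion (mean FD 0.096 mm).
Mean hub-region z by condition: patients baseline 0.97, patients follow-up -0.26, controls -0.30
```

The planted effect is visible directly: the hub region's mean z-scored DC
is elevated at baseline in patients (0.97) and renormalizes to the control
level (about -0.3) after treatment. Stage 3 then reports how many of the
planted hub voxels the FDR-corrected t maps recover, stage 4 prints the
LOOCV accuracy/sensitivity/specificity/AUC and the permutation p for
responder classification plus the region weight ranking (the planted hub
region should rank first), and stage 5 the FDR-corrected region-by-subscale
correlation table. Tables land in `results/`.

The same machinery is available programmatically:

```r
library(dcpredict)
report <- run_pipeline(pipeline_config(
  seed = 1, n_permutations = 200,
  cohort = list(n_per_group = 10, grid_dims = c(10, 10, 10),
                n_timepoints = 120)))
report$metrics
```

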