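# auriclass

Morphological classification of the human external ear from 3D surface
meshes, for forensic identification work. The package builds *classification
criterion images* (CCIs) — prototype ear shapes derived by a two-stage
principal component analysis of homologous ear models — and classifies ear
meshes against them by minimum *distance between vertices* (DBV), with the
upper auricle and the lobule treated as separate regions.

## What it computes

Given a cohort of triangle meshes in dense vertex-wise correspondence
(every subject shares the template's vertex order), the pipeline is:

1. **Dense correspondence** (`fit_template`): similarity Procrustes on 18
   anatomical landmarks, a thin-plate-spline warp, nearest-point surface
   projection, optional Laplacian relaxation.
2. **Alignment** (`generalized_procrustes`): size and posture standardised
   against the evolving mean shape.
3. **Shape PCA** (`fit_shape_pca`): for aligned shapes
   `x_i = x̄ + Σ_k s_ik φ_k`, eigenvalues `λ_k` (population convention, so a
   component's SD is `√λ_k`), contribution ratios `CR_k = 100 λ_k / Σ λ`,
   and per-specimen scores. Component counts are chosen by scree elbow,
   eigenvalue-magnitude threshold and the slope of the per-component DBV of
   the `±3 SD` shape pair.
4. **Composite images** (`make_composite_images`): `2k + 4·C(k,2)` meshes
   synthesized at `±amplitude` on single PCs and on all sign pairs of PC
   pairs (50 for k = 5, 72 for k = 6).
5. **Criterion images** (`second_stage_pca`, `derive_ccis`): a second PCA
   over the composite images, then `2·n_pcs` prototypes at `±amplitude` on
   its leading components (10 upper-auricle, 12 lobule at the reference
   settings).
6. **Classification** (`classify_one`, `classify_cohort`): assign each mesh
   to the CCI with minimum mean DBV
   `DBV(a, b) = mean_i ‖a_i − b_i‖` when under a calibrated threshold;
   report under/over-threshold rates, multi-match rates and left/right
   asymmetry.

Because no real CT cohort ships with the package, a first-class synthetic
generator (`make_template`, `make_modes`, `sample_population`) produces
ear-like cohorts with known latent deformation modes, ages, left/right
structure and noise, so every stage is testable with ground truth.

## Worked example

```r
library(auriclass)

template <- make_template(resolution = 0, seed = 1)   # 600-vertex ear sheet
spec <- population_spec(
  n_subjects = 40, side_plan = c(both = 20, left = 12, right = 8),
  n_modes = 4, mode_sd = c(6, 4, 3, 2), seed = 1,
  correspondence_jitter = "resample")                 # 60 meshes, no shared order
cfg <- pipeline_config(population = spec, k_upper = 4, k_lobule = 4,
                       cci_pcs_upper = 4, cci_pcs_lobule = 4, seed = 1)
run <- run_pipeline(cfg)

run$per_region$upper_auricle$model
#> <shape_model> 60 specimens, 460 vertices, 24 displayed PCs (CR >= 1%)

tidy(run$per_region$upper_auricle$model, ages = run$cohort_manifest$age,
     rounded = TRUE)
#> # A tibble: 24 × 5
#>      pc    ev    cr   ccr     r
#>   <int> <dbl> <dbl> <dbl> <dbl>
#> 1     1 12.4   18.8  18.8  0.12
#> 2     2  7.83  11.8  30.7  0.29
#> 3     3  4.65   7    37.7 -0.25
#> 4     4  3.33   5    42.7  0.09
#> # ...

run$built$upper_auricle$ccis
#> <cci_set> 8 criterion images (upper_auricle), threshold 4.23 mm

glance(run$classification)
#> # A tibble: 2 × 5
#>   region        n_total pct_under pct_multi pct_asymmetric
#> 1 upper_auricle      60        90      56.7             65
#> 2 lobule             60        90      50               80
```

Reading the output: the upper-auricle PCA keeps 24 components above the 1%
contribution-ratio display cutoff; PC1 carries 18.8% of the total shape
variance and no component correlates strongly with age (column `r`). Eight
criterion images were derived (two per kept second-stage component) and the
classification threshold was calibrated to the 90th percentile of the
cohort's minimum DBVs, so 90% of meshes classify; 56.7% match more than one
prototype within the threshold, and 65% of bilateral subjects get different
left and right assignments.

`autoplot(model)` draws the scree curve, `plot_dbv_slope()` the per-PC DBV
of the `±3 SD` pairs, and `plot_assignment_frequencies()` the per-CCI
assignment shares.

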