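# piradsflow

Semi-automated, size-rule PI-RADS v2.1 scoring of prostate lesions on
multiparametric MRI (mpMRI), for imaging scientists who want an
objective, reproducible counterpart to qualitative radiologist scoring.
PI-RADS assessment suffers from substantial inter-reader variability;
the measurable part of the standard — the lesion size rule — can be
computed. This package implements that computable core as a tested
pipeline, exercised end-to-end on synthetic phantoms with analytic
ground truth.

Given DWI (high b-value), ADC and T2W volumes plus manually marked
lesion ROIs (the one remaining manual step), the pipeline:

1. segments the whole gland on DWI with a **Chan–Vese active contour**
   minimizing the two-phase energy
   `E(C, c1, c2) = ∫_in (u − c1)² dV + ∫_out (u − c2)² dV`
   inside a rectangular shape prior, refined by morphological opening;
2. registers T2W to the DWI frame with a **12-DoF affine transform**
   maximizing **mutual information** `H(A) + H(B) − H(A,B)`, so the
   DWI-space masks serve both sequences;
3. splits the gland into peripheral and transition zones with a
   **probabilistic atlas** thresholded at p = 0.5, resolving leftover
   partial-volume voxels by a three-term belongingness cost
   (normalized intensity difference, probability, distance);
4. measures each lesion by **direct least-squares ellipse fitting** of
   the conic `ax² + bxy + cy² + dx + ey + f = 0` (constraint
   `4ac − b² = 1`) per ROI slice: maximum diameter = major axis of the
   best-fit ellipse, volume = slice profile × Σ per-slice areas;
5. assigns a **PI-RADS score (2–5)** from diameter cut-points
   (score 5 at ≥ 1.5 cm) with a clinical-significance flag
   (volume > 0.5 cc), and evaluates scoring with LDA / linear SVM /
   Gaussian SVM under stratified 5-fold cross-validation
   (sensitivity, specificity, accuracy, ROC-AUC, Pearson r).

A phantom generator (`generate_phantom()`) provides ellipsoidal-gland
mpMRI volumes with posterior-crescent PZ, controlled elliptical
lesions and Gaussian/Rician noise, plus analytic truth for every
downstream quantity.

## Worked example

```r
library(piradsflow)

sp <- phantom_spec(lesions = list(
  lesion_spec(center = c(48, 60, 6), in_plane_semiaxes = c(0.85, 0.4)),
  lesion_spec(center = c(38, 58, 5), in_plane_semiaxes = c(0.3, 0.2),
              n_slices = 2)),
  seed = 42)
ph <- generate_phantom(sp)
ph
#> phantom_output: 96x96x12 grid, 2 lesion(s), noise sigma 0
#>   lesion diameter_cm volume_cc
#> 1      1         1.7 0.6408849
#> 2      2         0.6 0.2261947

gland <- segment_gland(ph$volumes$dwi)
dice(gland, ph$gland_truth)
#> [1] 0.9998

measurements <- lapply(ph$lesion_truth, measure_lesion)
measurements[[1]]
#> lesion_measurement: max diameter 1.702 cm, volume 0.625 cc over 1 slice(s) (profile 0.6 cm)

score_cohort(measurements)$scores
#>   lesion max_diameter_cm volume_cc score clinically_significant
#> 1      1       1.7017928 0.6249763     5                   TRUE
#> 2      2       0.5886698 0.2391359     3                  FALSE
```

The 1.7 cm lesion crosses the 1.5 cm cutoff and scores 5 (clinically
significant); the 0.6 cm lesion falls in the score-3 band and, at
0.24 cc, below the 0.5 cc significance bound. Measured diameters agree
with the analytic truth to well under one in-plane voxel (0.8 mm).

`run_pipeline()` chains all stages (segment → register → zones →
measure → score) and writes NIfTI/CSV/JSON intermediates; a
command-line wrapper with per-stage subcommands ships in
`inst/cli/piradsflow.R`:

```sh
Rscript inst/cli/piradsflow.R simulate --out phantom/ --seed 4
Rscript inst/cli/piradsflow.R pipeline --dwi phantom/dwi.nii.gz \
    --roi phantom/lesions_truth.nii.gz --out results/
```

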