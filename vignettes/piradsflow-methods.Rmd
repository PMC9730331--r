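---
title: "Methods: semi-automated size-rule PI-RADS v2.1 scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated size-rule PI-RADS v2.1 scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piradsflow)
```

# Overview

`piradsflow` implements a semi-automated pipeline for size-based
PI-RADS v2.1 assessment of peripheral-zone prostate lesions on
multiparametric MRI. The pipeline is *semi*-automated in one specific
sense: lesion regions of interest are user input (marked slice-by-slice
on high b-value DWI, as in clinical practice), while everything else —
gland segmentation, T2W-to-DWI registration, zonal segmentation, lesion
measurement and score assignment — is computed.

The stages, in execution order:

1. **Gland segmentation** on high b-value DWI by a two-phase
   region-based active contour inside a rectangular shape prior
   (`segment_gland()`).
2. **Registration** of the T2W gland region to the DWI frame with a
   12-parameter affine transform maximizing mutual information
   (`register_t2w_to_dwi()`), so DWI-space masks can be reused on T2W.
3. **Zonal segmentation** into peripheral zone (PZ) and transition zone
   (TZ) by a probabilistic atlas thresholded at probability 0.5,
   followed by a partial-volume correction that assigns the leftover
   voxels (`segment_zones()`).
4. **Lesion measurement** by direct least-squares ellipse fitting per
   ROI slice (`measure_lesion()`).
5. **Score assignment** from maximum diameter and volume
   (`assign_score()`), and **evaluation** of scoring agreement and
   classifier-based diagnostic performance (`cross_validate()`,
   `agreement()`).

Because clinical prostate MRI cannot ship with a package, every stage
is exercised on synthetic phantoms with analytic ground truth
(`generate_phantom()`); the phantom generator is first-class, tested
code.

# Gland segmentation

The active contour minimizes the two-phase piecewise-constant energy

$$E(C, c_1, c_2) = \int_{\text{inside}(C)} (u - c_1)^2 \, dV +
  \int_{\text{outside}(C)} (u - c_2)^2 \, dV,$$

where $u$ is the image and $c_1, c_2$ are the mean intensities of the
two regions the contour $C$ partitions the domain into; for a fixed
contour the region means minimize the energy exactly
(`optimal_means()`). The level set is evolved slice-by-slice inside a
rectangular shape prior that is reused on every slice; the prior is
either supplied (`init_rect`) or derived automatically as the
bounding box of the Otsu foreground dilated by 20%, which keeps the
pipeline runnable unattended on phantoms.

Numerical choices:

* The pure data energy above is ill-posed on noisy images, so the flow
  includes a curvature-regularization term with a small weight `mu`
  (default 0.1 on min-max-normalized intensities); `mu = 0` reproduces
  the pure two-phase functional.
* Iterations: at most `max_iterations` (default 100) per slice, stopping
  early when fewer than 0.1% of domain voxels change label between
  iterations. Update steps that would increase the data energy (beyond a
  small curvature slack) are rejected with a halved time step, so the
  energy is non-increasing over accepted iterations.
* The level set is initialized from the Otsu foreground inside the
  prior; a degenerate (constant) domain raises an error rather than
  returning an arbitrary contour.
* Refinement: morphological opening with a disc structuring element of
  radius 2 removes speckle, then the largest connected component is
  kept. Opening is idempotent, so re-running refinement changes
  nothing.

# Registration

The transform family is the full 12-parameter affine map
$x' = A(x - c) + t + c$ in voxel coordinates, pivoted on the grid
centre so scales and rotations do not induce large spurious
translations. The similarity measure is mutual information,
$MI = H(A) + H(B) - H(A,B)$, from a 32-bin joint histogram.

For the *optimization objective* the joint histogram is built with
partial-volume interpolation: each fixed voxel distributes its unit
mass over the eight moving-image neighbours of its inverse-mapped
position with trilinear weights. Resample-then-histogram MI is
piecewise constant in the transform and its interpolation blur can
displace the optimum on piecewise-constant images; the partial-volume
histogram varies smoothly instead. Its known artifact — spurious sharp
maxima wherever the sampling is grid-commensurate, most prominently at
the identity — is handled structurally: candidate transforms are
generated by staged Nelder-Mead searches (translation-only on a
half-resolution grid, translation from the centre-of-mass start, and a
multi-start search over isotropic scale at $s \in \{0.9, 1, 1.1\}$),
each candidate gets a short full-resolution refine over translation
plus per-axis scales, and only then is a winner selected by
full-resolution MI and polished over all 12 parameters. If the final
transform does not improve on the identity's MI, the identity is
returned with a warning.

Registration operates on gland-ROI-masked intensities, not whole
images and not binary masks; masked intensities retain the boundary
structure MI needs while excluding background anatomy. Parameter
recovery is verified on phantoms: translations to within a small
fraction of a voxel, and a 1.1 isotropic scale to within about 1% per
axis. The scale test uses a thin-slice (1.5 mm spacing, 30 slices)
phantom rendered with `supersample = 3`: at a 6 mm slice profile a
binary-rendered gland carries almost no through-plane scale
information, whereas fractional boundary coverage — like the partial
volume averaging of real MRI — makes sub-voxel geometry recoverable.

# Zonal segmentation

The probabilistic atlas is built from training subjects aligned to the
target grid: the statistical atlas is the voxelwise mean intensity and
the per-zone probability is the fraction of training masks containing
the voxel (`build_atlas()`). Zone masks are obtained by thresholding at
probability 0.5 with a *strict* inequality: voxels at or below 0.5 for
both zones form the partial-volume (PV) set. The PV correction then
assigns each PV voxel $v$ to the zone $z \in \{PZ, TZ\}$ minimizing

$$\text{cost}(v, z) = w_{int}\,\lvert \hat I(v) - \hat\mu_z \rvert +
  w_{prob}\,(1 - p_z(v)) + w_{dist}\,\hat d(v, z),$$

with $\hat I$ the min-max-normalized intensity, $\hat\mu_z$ the zone's
normalized intensity mean over the subject's thresholded zone voxels,
$p_z$ the atlas probability, and $\hat d$ the Euclidean distance (mm)
to the nearest voxel of the zone, normalized by the gland bounding-box
diagonal. Design choices that were genuinely open:

* The three cost terms have no canonical scaling; each is normalized
  to $[0, 1]$ so the equal default weights ($1/3$ each) are
  meaningful. Weights are configurable (`pv_cost_params()`).
* "Distance from the zone" is implemented as nearest-voxel distance
  (computed against the zone boundary); centroid distance was the
  alternative and would penalize elongated zones.
* Exact cost ties are assigned to PZ, the zone under analysis in a
  PZ-lesion pipeline, so ambiguous boundary voxels err toward the zone
  being scored. Configurable via `pv_cost_params(tie =)`.

After correction, PZ and TZ partition the gland exactly — zero
unassigned and zero doubly-assigned voxels — and this is asserted
voxelwise in the tests over a leave-one-out phantom atlas family.

# Lesion measurement

Each ROI slice is measured by fitting the conic
$a x^2 + b x y + c y^2 + d x + e y + f = 0$ to the ROI boundary by
least squares under the ellipse-specific constraint $4ac - b^2 = 1$
(numerically stable block decomposition, centroid-centred
coordinates). Unconstrained conic least squares can return a
hyperbola; the constrained variant cannot. Boundary points are the
0.5-level contour of the mask (marching-squares), in centimetres;
fitting the filled region instead would bias the axes.

* **Maximum diameter** = twice the largest per-slice semi-major axis
  (measurement is two-dimensional, per slice, and one diameter is
  reported per lesion).
* **Volume** = slice profile (slice thickness + gap) × sum of
  per-slice areas. Areas come from the fitted ellipse
  ($\pi a b$) by default; raw pixel-count area is available via
  `area_method = "pixel"`.

All centimetre/cc conversions happen inside the measurement code —
voxel indices everywhere else — so there is a single conversion site.
Ellipse fitting on short boundary arcs has a known curvature bias; no
correction is applied, and measurements on small ROIs inherit it.

# Score assignment

The size ladder is right-closed at three diameter cut-points:
score 2 below `t23`, 3 from `t23`, 4 from `t34`, 5 from `t45`
($d \ge t$ promotes, matching the "$\ge$ 1.5 cm" convention at the 4/5
boundary). Only two constants of the mapping are fixed by the PI-RADS
size rule: the 4/5 cutoff `t45 = 1.5` cm and the clinical-significance
volume bound `v_sig = 0.5` cc (strict: a lesion is flagged when volume
*exceeds* 0.5 cc, or when its score is 4 or 5). The lower cut-points
default to midpoints between adjacent per-score mean diameters of the
reference measurement table bundled as the generator's class
parameters (`(0.47 + 0.67)/2 = 0.57` and `(0.67 + 0.96)/2 = 0.815`,
rounded to 0.82); they are explicit, documented arguments of
`score_rule()` and must be reviewed for any other cohort. Volume does
not enter the 2–5 ladder by default; an optional, off-by-default
`volume_override` promotes a score-3 lesion above `v_sig` to 4.

# Evaluation

Diagnostic performance is evaluated with linear discriminant analysis
(`MASS::lda`), a linear SVM and a Gaussian-kernel SVM (`e1071::svm`),
under stratified k-fold cross-validation (default 5). Fixed defaults:
SVM cost 1; the Gaussian kernel is
$\exp(-\lVert x - y\rVert^2 / (2\sigma^2))$ with $\sigma$ set by the
median pairwise-distance heuristic on the training features. The
feature vector is (maximum diameter, volume) — the two quantities the
measurement stage produces.

* Folds are seed-derived after a canonical row sort, so results are
  invariant to input row order; per-fold class proportions stay within
  one sample of the global proportions.
* Multi-class sensitivity and specificity are macro-averaged
  one-vs-rest; accuracy, sensitivity and specificity are reported as
  mean ± SD *across folds* (the SD is labelled as such).
* ROC curves use rank-based tie handling, so the trapezoidal AUC
  equals the normalized Mann-Whitney statistic exactly; the test suite
  asserts this identity on random instances. Multi-class AUC is the
  macro-average of one-vs-rest areas computed from pooled out-of-fold
  decision scores (LDA posteriors; per-class one-vs-rest SVM decision
  values).
* The two-class task maps scores 2–3 to "low" and 4–5 to "high"
  (`binarize_scores()`).
* Agreement with a reference assessment uses the Pearson
  product-moment correlation plus a confusion matrix and per-class
  detection rates.

# The phantom generator

`generate_phantom()` emulates the geometry and contrast structure of a
midgland prostate mpMRI study: an ellipsoidal gland on a dark
background, a posterior-crescent PZ and anterior TZ (the crescent
depth is the `zone_split` fraction of the per-slice gland extent),
elliptical lesions spanning 1–5 slices that are DWI-hyperintense and
ADC-hypointense, and additive Gaussian or Rician noise. The
through-plane grid spacing equals slice thickness + gap (6 mm with the
3 mm + 3 mm defaults), so the voxel grid and the slice-profile volume
formula are consistent by construction. Ground-truth lesion
measurements are analytic: diameter $= 2\max_s a_s$ and volume
$= (\text{profile}) \sum_s \pi a_s b_s$, exact to numerical precision.

Channel contrasts are free parameters: no claim is made that the
default intensity ratios match any cohort, only that they provide
two-phase structure for segmentation and multimodal contrast for
registration. `generate_feature_table()` draws labelled
(diameter, volume) pairs per score class from truncated-at-zero
normal distributions; its default class parameters are the per-score
ellipse-fit means ± SDs of the reference measurement table
(0.47 ± 0.06 cm / 0.13 ± 0.03 cc for score 2 up to 1.45 ± 0.15 cm /
0.99 ± 0.25 cc for score 5).

What the phantom deliberately does **not** model: MR physics (no bias
fields, no motion, no susceptibility artifacts), anatomical
variability beyond ellipsoids and crescents, a DCE channel, and
realistic inter-tissue texture. Passing tests therefore demonstrate
the correctness of the algorithms under controlled conditions, not
clinical performance on real data.

By default voxels are rendered binary from centre membership, which
makes noise-free phantoms exactly piecewise constant (and region means
exact). `supersample = k` instead averages membership over $k^3$
sub-voxel offsets, giving boundary voxels fractional intensities like
real partial-volume averaging; this is used where sub-voxel geometry
matters (registration scale recovery).

# Problem sizes and runtime choices

The shipped tests run phantoms at 48³–96² × 8–30 voxel grids, a
59-lesion end-to-end cohort (16/10/18/15 per score), 200
random-ellipse fits, 20 rasterized measurement recoveries, a
leave-one-out atlas family of four subjects, and classifier checks at
n = 100–400. These sizes were chosen so the full suite and the
acceptance script each run on a single CPU in a few minutes while
keeping every estimate's sampling error far from its acceptance
margin.

# Known limitations

* Gland segmentation is slice-wise 2D with a shared rectangular prior;
  a fully 3D level set or a learned shape prior is out of scope.
* The registration optimizer is derivative-free and multi-start; it is
  robust on gland-ROI inputs but, like all MI registration, can fail
  on inputs with little mutual structure (it then returns the identity
  with a warning).
* Only the PZ crescent / TZ remainder zonal model is generated and
  scored; central zone and anterior stroma are not subdivided, and no
  TZ scoring ladder is implemented.
* Appearance-based PI-RADS criteria (ADC hypointensity grading, T2W
  texture, DCE upgrade) are outside the size-rule scope of this
  package.
* Ellipse fitting on partial arcs carries curvature bias; small or
  crescent-shaped ROIs are measured less accurately than convex ones.
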