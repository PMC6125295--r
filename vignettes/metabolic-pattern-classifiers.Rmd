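---
title: "Metabolic pattern classifiers: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic pattern classifiers: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgpattern)
```

# The problem

FDG-PET measures regional glucose metabolism. Alzheimer's disease produces
a reproducible spatial signature — hypometabolism in posterior midline,
temporo-parietal and medial frontal cortex with relative sparing (and
hence, after global normalization, apparent hypermetabolism) of
sensorimotor cortex, basal ganglia and cerebellum. `fdgpattern` learns this
signature from a labeled two-group cohort of spatially normalized volumes
and quantifies its expression in new scans. Everything downstream of
spatial normalization is in scope; warping to a template and smoothing of
real scans are not performed here and are assumed done upstream.

# Common preprocessing

**Mask.** The analysis mask keeps voxels whose value in the mean training
image is at least a fraction (default 0.25) of that image's maximum. The
mean image, rather than any single scan, defines the maximum: this makes
the mask deterministic and insensitive to single-scan artifacts. Inside
cross-validation the mask is rebuilt from each training fold so that no
information about held-out subjects leaks into feature selection; for
prospective application the training mask travels with the stored model.

**Proportional scaling.** Each scan is divided by its own in-mask mean, so
scaled values are ratios to the subject's global uptake. This removes
dose/metabolism offsets but, being a ratio, makes regional decreases appear
partly as relative increases elsewhere — which is why "hypermetabolism" in
these patterns is always relative.

**Voxel order.** In-mask voxels are vectorized in the grid's column-major
(Fortran) order, i.e. `which(mask$include)`. The order is part of the model
contract; pattern vectors, group-mean profiles and masks are stored
together so stored models are portable.

# The five machines

**GLM.** Per voxel, uptake is regressed on a 0/1 group dummy
(disease = 1, control = 0, so larger scores mean more disease-like). With
this coding the fitted slope is exactly the group mean difference, which is
how it is computed; a generic least-squares oracle verifies the identity in
the tests. The intercept map is not stored: it shifts every subject score
equally and z-scoring absorbs it.

**SSM/PCA.** The scaled subprofile model works in log space: after the log
transform, subtracting each subject's mean removes residual global scaling
exactly (a multiplicative factor becomes an additive constant), and
subtracting each voxel's mean across subjects (the group mean profile,
GMP) leaves a doubly centered residual matrix. Its top right singular
vectors are covariance patterns; subject scores are projections. SSM/PCA1
keeps the single PC with the largest two-sample |t| on subject scores
(ties break to the lowest index); SSM/PCA2 runs stepwise linear regression
of the 0/1 label on the PC scores — forward entry at p < 0.05, backward
removal at p ≥ 0.10 — and combines the retained PCs with their regression
weights. The label regression is linear, not logistic: with a 0/1 response
the coefficient t-tests are the classical stepwise criteria and the
procedure is deterministic. Patterns are oriented so the disease group's
mean score is positive. Prospective scoring log-transforms a new scan,
removes its row mean, subtracts the *training* GMP and projects onto the
pattern, which reproduces training scores exactly and is invariant to any
positive rescaling of the scan.

With n subjects and p voxels (p >> n), the decomposition runs through the
n-by-n Gram matrix, so cost is O(n^2 p), not O(p^2).

**Linear SVM.** Both solvers maximize the soft-margin dual with the linear
kernel `K(x, z) = x.z / scale^2 + offset` and box constraint C (default 1;
a configuration knob, as the reference settings leave it at its default).

* *ISDA* drops the equality constraint and absorbs the bias into a kernel
  offset of 0.1; it sweeps subject indices in ascending order, each step
  being the exact single-coordinate maximizer clipped to [0, C]. Its
  nominal gradient tolerance of 0 is interpreted as a machine-precision
  floor: `max(1e-12 * max(1, |g|_max), 64 eps |f|_max)`. The second term
  matters because the cached decision values accumulate rounding
  proportional to their magnitude — and on proportionally scaled images the
  Gram diagonal is of order the voxel count, so demanding an absolute
  1e-12 would never terminate. Even so, on realistic image Grams (which are
  dominated by one near-constant component and hence extremely
  ill-conditioned) ISDA routinely runs to its 1,000,000-iteration cap; this
  mirrors its reference configuration (tolerance zero with the same cap)
  and the partially converged machine is returned with a warning flag.
* *SMO* keeps the equality constraint with an explicit bias. The working
  pair is the maximal KKT violator on the "up" side plus the low-side
  partner with the largest second-order gain `(v_i - v_j)^2 / (2 eta)`;
  if that partner cannot move, the maximal violating pair is used, which
  always can. Alphas within 1e-12 C of a bound are snapped onto it —
  without the snap, an alpha at `C - 1e-16` passes the strict bound test
  and deadlocks pair selection. Convergence is the Keerthi gap falling
  below the gradient tolerance (default 0.001).

Both solvers are verified against generic convex-QP solutions (an
interior-point solver for the equality-constrained dual, box-constrained
quasi-Newton for the unconstrained one) to 1e-4 on decision values.

*Robust learning.* Assuming a 5% mislabeling rate in training data, after
convergence the `ceiling(0.05 n)` subjects with the largest hinge slack are
removed and the solver refits once. The exact robust procedure behind the
reference implementation is unpublished; this one-pass remove-and-refit is
our reconstruction and is recorded as such in each model's extras.

# Scoring, thresholds, evaluation

Subject scores are always dot products with the pattern (plus bias).
GLM/SSM scores are z-scored to the mean and n−1 standard deviation of the
training controls, and designation uses the z-threshold that maximizes
sensitivity × specificity on the training ROC; candidate thresholds sit
midway between adjacent distinct scores, and ties break toward higher
specificity (fewer false positives). SVM designation is the sign of the
raw decision value — no ROC threshold — though z-scores are still reported
for plotting.

The AUC is the trapezoidal area under the empirical ROC, computed by mean
ranks, which is exactly the Mann-Whitney pair-count statistic with ties
worth 1/2. Cross-validation is stratified (class counts per fold differ by
at most one, seeded permutation), k = 10 by default, and pools held-out
scores across folds rather than averaging per-fold metrics; everything
data-dependent (mask, pattern, z-threshold, outlier removal) derives from
the training fold only.

**Topographic similarity.** Two pattern maps are compared by voxel-wise
Pearson correlation. Because smoothed brain maps are spatially
autocorrelated, the null uses surrogate maps built by Fourier phase
randomization of one map inside the mask's bounding box (random phases
taken from the FFT of white noise, which preserves Hermitian symmetry and
hence realness, and the full amplitude spectrum), re-masked before
correlating. The p-value is `(1 + #{|r_surr| >= |r|}) / (1 + n_surr)` with
an optional Bonferroni factor for comparison tables. The published method
this emulates corrects for autocorrelation by an approach whose details
are not in our sources; phase randomization is a standard, calibrated
stand-in (empirical type-I error 0.05 at alpha = 0.05 in the test suite),
not a reimplementation of that method.

# The synthetic phantom

Real clinical cohorts of this kind are access-restricted, so validation
runs on phantoms with known ground truth:

```
volume_i = scale_i * template * exp(expr_i * pattern) + noise_i
```

* `template`: a sum of Gaussian blobs, strictly positive on its support,
  caricaturing a brain (default grid 32^3 at 4 mm — about 7,600 mask
  voxels; a configuration path allows full-resolution stress tests).
* `pattern`: Gaussian-weighted log multiplicative factors — regional
  hypometabolism (factors 0.85–0.90) in posterior/temporal/frontal blobs
  and mild relative hypermetabolism (1.05–1.08) in sensorimotor/cerebellar
  blobs, matching the magnitudes seen in moderate disease.
* `expr_i`: pattern expression, Normal(0, 1) in controls and Normal(d, 1)
  in patients, so `d` is the planted Cohen's d (default 1.5). Controls
  additionally gain 0.06 expression units per year of age, making the
  control-group age correlation of subject scores ≈ 0.35, the magnitude
  reported in real normal cohorts. An `expression_sd` knob (default 1)
  exists so degenerate no-variance cohorts can be produced.
* `scale_i`: log-normal global scaling (sd 0.2) — the nuisance that
  proportional scaling and SSM row-centering must remove.
* `noise_i`: white noise smoothed with the same 8 mm FWHM kernel a PET
  pipeline applies, scaled to 5% of the in-support template mean. Matching
  the smoothing kernel makes the similarity-test calibration honest, since
  surrogate nulls then face realistic autocorrelation.

The pattern is planted multiplicatively in log space — exactly SSM's
generative assumption — so SSM recovery is a fair test; GLM and SVM see
the same data without that advantage. Identical spec and seed give
bit-identical cohorts (and byte-identical NIfTI files).

**What the phantom does not model:** real anatomy (no atlas), scanner
point-spread and attenuation artifacts, structured inter-subject anatomical
variability, multi-site effects, longitudinal change. Passing phantom tests
therefore demonstrates correctness of the machinery, not clinical
performance.

# An honest ceiling on phantom AUC

With unit within-group expression spread and mean shift d, the latent
expression is the sufficient statistic for group membership, so no
classifier can beat `AUC = Phi(d / sqrt(2))` — about 0.856 at the default
d = 1.5. Measured pooled CV AUCs (~0.80 for GLM/SSM, lower for the SVMs,
which overfit in the n << p regime exactly as their cross-validated scores
suggest on real data) should be read against that ceiling, not against 1.
The acceptance suite keeps an aspirational AUC ≥ 0.9 check at these very
conditions; it fails by construction and is retained deliberately as a
documented red rather than silently weakened.

# Numerical and design choices

* Natural log throughout SSM (the field's convention).
* Centering order: subject means first, voxel means second; the GMP is the
  post-row-centering column mean — required for prospective scoring to be
  well defined.
* PC sign fixed deterministically at the SVD (largest-|loading| voxel
  positive), then re-oriented disease-positive when a classifier is built.
* SSM/PCA2 scores are recomputed by projecting the centered data onto the
  combined pattern (not by combining per-PC scores); equivalent up to
  scaling, stated for determinism.
* Stepwise entry at p < 0.05 over ~9 null candidates admits a noise PC
  with probability ≈ 1 − 0.95^9 ≈ 0.37; the informative component is
  essentially always retained, but "exactly the informative set" happens
  only ~63% of the time. This is a property of the classical thresholds,
  not a defect of the implementation, and the tests assert the calibrated
  expectation.
* k = 10 PCs, mask threshold 0.25, k = 10 folds, all SVM constants and the
  5% outlier fraction are configuration defaults, never inline constants.
* Simulation sizes in the test suite: 100 null replicates (16^3 grid,
  40/40) for classifier calibration, 200 replicates × 199 surrogates for
  similarity-test calibration, chosen as the smallest sizes at which the
  binomial error bands in the assertions are meaningful.

# Known limitations

* ISDA on image-scale Grams terminates by iteration cap, not tolerance;
  designations agree with SMO on separable cohorts, but its dual is less
  converged than SMO's on realistic data.
* The robust-learning step is a reconstruction (see above).
* Prospective cohorts are z-scored against the training (derivation)
  controls by default; site-specific re-referencing is the caller's choice.
* No covariate-adjusted GLM (age/sex regressors), no voxel-wise inference,
  no nonlinear kernels, no probability calibration.
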