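# fdgpattern

Voxel-based machine classification of Alzheimer-like metabolic brain
patterns from spatially normalized FDG-PET (or perfusion-SPECT) volumes.

Dementia workups increasingly use FDG-PET, where Alzheimer's disease shows
a characteristic topography: relative hypometabolism in the precuneus,
posterior cingulate, temporo-parietal and medial frontal cortex, with
relatively preserved sensorimotor cortex, basal ganglia and cerebellum.
`fdgpattern` implements, on one common subjects-by-voxels interface, five
machines that learn such a pattern from a two-group training cohort
(disease vs. normal) and score new scans by how strongly they express it:

1. **GLM** — a voxel-wise linear regression `y = beta * x + c` of uptake on
   the 0/1 group dummy; the beta map is the pattern, and a subject's score
   is the dot product of the beta map with their proportionally scaled
   scan. Under 0/1 coding the beta map equals the group mean-difference
   map.
2. **SSM/PCA1** — the scaled subprofile model: log-transform, double
   centering (subject means, then voxel means), singular value
   decomposition, and selection of the single principal component whose
   subject scores best separate the groups (largest two-sample |t|).
3. **SSM/PCA2** — stepwise linear regression of the group label on the top
   10 PC score vectors (entry p < 0.05, removal p >= 0.10); the retained
   PCs are combined with their regression weights into one pattern.
4. **SVM-ISDA** — a linear soft-margin SVM trained by coordinate dual
   ascent without an equality constraint (bias absorbed by a kernel offset
   of 0.1), gradient tolerance 0 (machine-precision floor), at most
   1,000,000 iterations.
5. **SVM-SMO** — the same SVM trained by sequential minimal optimization
   with the equality constraint, explicit bias, gradient tolerance 0.001.

GLM/SSM scores are z-scored to the normal-control reference and thresholded
at the ROC point maximizing sensitivity x specificity; SVM designations use
the sign of the decision value. Both SVMs apply robust learning: the 5%
of training scans with the largest hinge slack are removed and the machine
is refit once.

The package also provides leakage-free stratified 10-fold cross-validation,
prospective scoring of new cohorts (with the training mask, centering
profile and normalization traveling with the stored model),
autocorrelation-corrected topographic similarity between pattern maps
(Fourier phase-randomized surrogates), and a synthetic phantom-cohort
generator with known ground truth, so the entire pipeline is testable
without access-restricted clinical data.

## Worked example

```r
library(fdgpattern)

# a phantom cohort: 32^3 grid, 40 controls + 40 patients, planted AD-like
# pattern at Cohen's d = 1.5
co   <- generate_cohort(cohort_spec(seed = 1))
mask <- compute_mask(co$volumes)                       # 25% of max
vm   <- proportional_scale(extract_matrix(co$volumes, mask,
                                          co$manifest$group))

glm <- fit_glm_pattern(vm)
dec <- ssm_svd(log_double_center(vm), k = 10)
ssm <- select_best_pc(dec)

truth <- co$ground_truth$pattern_volume$data[which(mask$include)]
cor(glm$pattern, truth)        # 0.945
cor(ssm$pattern, truth)        # 0.982; PC1 selected

cv <- kfold_cv(vm, method = "SSM1", k = 10, seed = 1)
cv
#> <cv_result> SSM1, k = 10: AUC 0.806, sens 0.675, spec 0.8, sens x spec 0.54
```

The AUC of ~0.81 sits just under the theoretical ceiling for this phantom:
with unit within-group expression spread and a mean shift of d = 1.5, no
classifier can exceed AUC = Phi(1.5 / sqrt(2)) ≈ 0.856.

A pattern can then be applied prospectively to cohorts that were never part
of training:

```r
dlb <- make_dlb_like_cohort(cohort_spec(seed = 7), ad_pattern_loading = 1)
vmx <- proportional_scale(extract_matrix(dlb$volumes, mask,
                                         dlb$manifest$group))
svm <- train_svm(vm, config = svm_config("SMO"))
apply_to_cohort(svm, vmx)
#> <cohort_report>
#>   PDD: 34 of 40 designated
```

## Command line

```sh
Rscript inst/cli/fdgpattern.R simulate --spec cohort.yaml --out cohort/
Rscript inst/cli/fdgpattern.R train    --manifest cohort/manifest.tsv --out models/
Rscript inst/cli/fdgpattern.R crossval --manifest cohort/manifest.tsv --out cv/
Rscript inst/cli/fdgpattern.R apply    --model models/glm_model.json --manifest new/manifest.tsv --out applied/
Rscript inst/cli/fdgpattern.R compare  --mapA models/glm_pattern.nii.gz --mapB models/ssm1_pattern.nii.gz --mask models/glm_mask.nii.gz --out sim.json
```

All outputs (model NIfTIs + JSON sidecars, score TSVs, summary tables) are
deterministic under a fixed config and seed.

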