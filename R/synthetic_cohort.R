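default_brain_blobs <- function() {
  # centers/sigmas in fractions of the field of view; amplitudes in
  # arbitrary uptake units. One large central component plus lobes gives a
  # smooth, strictly positive, vaguely brain-shaped template.
  data.frame(
    x = c(0.50, 0.50, 0.30, 0.70, 0.50, 0.50),
    y = c(0.50, 0.70, 0.45, 0.45, 0.26, 0.25),
    z = c(0.52, 0.52, 0.42, 0.42, 0.52, 0.32),
    sigma = c(0.230, 0.110, 0.095, 0.095, 0.090, 0.085),
    amplitude = c(100, 35, 30, 30, 25, 28)
  )
}

default_effect_blobs <- function() {
  # multiplicative regional effects planted in log space: factor < 1 means
  # hypometabolism at unit pattern expression, factor > 1 hypermetabolism.
  # The layout caricatures the AD topography: posterior-midline/parietal
  # and temporal reductions, relative sensorimotor/cerebellar increases.
  data.frame(
    x = c(0.50, 0.31, 0.69, 0.50, 0.50, 0.50, 0.44, 0.56),
    y = c(0.36, 0.46, 0.46, 0.68, 0.50, 0.26, 0.52, 0.52),
    z = c(0.56, 0.42, 0.42, 0.54, 0.68, 0.32, 0.46, 0.46),
    sigma = c(0.110, 0.095, 0.095, 0.090, 0.085, 0.100, 0.060, 0.060),
    factor = c(0.85, 0.88, 0.88, 0.90, 1.08, 1.06, 1.05, 1.05)
  )
}

#' Specification of a synthetic phantom cohort
#'
#' Full recipe for a two-group phantom cohort of post-normalization
#' PET-like volumes with a known planted disease pattern. Each subject i is
#' generated as
#' `global_scale_i * template * exp(expression_i * log_pattern) + noise`,
#' truncated at zero. The template is a sum of Gaussian blobs (strictly
#' positive on its support); the log-pattern is a sum of Gaussian-weighted
#' log multiplicative factors (regional hypo-/hypermetabolism). Expression
#' scores are Normal(0, 1) in controls and Normal(d, 1) in the disease
#' group, so `d` is the target Cohen's d of ground-truth pattern
#' expression; controls additionally express the pattern in proportion to
#' age (slope `age_slope` per year), mimicking aging-related drift. Global
#' scaling is log-normal; noise is white noise smoothed with the same FWHM
#' a PET preprocessing chain would apply, then scaled to `noise_sd` times
#' the in-support template mean.
#'
#' @param grid Integer vector of 3 grid dimensions (default 32^3).
#' @param spacing Voxel size in mm (default 4).
#' @param n_control,n_disease Group sizes (default 40 each).
#' @param d Target Cohen's d of expression scores between groups.
#' @param expression_sd Within-group SD of pattern expression (default 1;
#'   with unit SD the group mean shift equals `d`). Setting it to 0 turns
#'   off individual pattern variability entirely.
#' @param global_scale_sd SD of per-subject log global scaling.
#' @param noise_sd Additive smooth-noise SD, relative to template mean.
#' @param smooth_fwhm Noise smoothing FWHM in mm (default 8).
#' @param age_mean,age_sd,age_slope Age model: ages are
#'   Normal(`age_mean`, `age_sd`); controls gain `age_slope` expression
#'   units per year of age above `age_mean`.
#' @param control_label,disease_label Group labels for the manifest.
#' @param blobs,effects Data frames overriding the default template
#'   geometry / effect regions.
#' @param seed Integer; identical spec + seed gives a bit-identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid = c(32, 32, 32), spacing = 4,
                        n_control = 40, n_disease = 40, d = 1.5,
                        expression_sd = 1,
                        global_scale_sd = 0.2, noise_sd = 0.05,
                        smooth_fwhm = 8, age_mean = 72, age_sd = 6,
                        age_slope = 0.06,
                        control_label = "NL", disease_label = "AD",
                        blobs = default_brain_blobs(),
                        effects = default_effect_blobs(), seed = 1) {
  if (d < 0) stop_fdg("bad_spec", "effect size d must be >= 0")
  if (expression_sd < 0 || global_scale_sd < 0 || noise_sd < 0 ||
      smooth_fwhm < 0)
    stop_fdg("bad_spec", "spread parameters must be >= 0")
  if (any(effects$factor <= 0))
    stop_fdg("bad_spec", "effect factors must be positive")
  structure(list(grid = as.integer(grid), spacing = spacing,
                 n_control = n_control, n_disease = n_disease, d = d,
                 expression_sd = expression_sd,
                 global_scale_sd = global_scale_sd, noise_sd = noise_sd,
                 smooth_fwhm = smooth_fwhm, age_mean = age_mean,
                 age_sd = age_sd, age_slope = age_slope,
                 control_label = control_label,
                 disease_label = disease_label,
                 blobs = blobs, effects = effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

voxel_coords_mm <- function(grid, spacing) {
  lapply(1:3, function(a) (seq_len(grid[a]) - 0.5) * spacing)
}

gaussian_blob <- function(grid, spacing, cx, cy, cz, sigma_frac) {
  fov <- grid * spacing
  co <- voxel_coords_mm(grid, spacing)
  s <- sigma_frac * max(fov)
  gx <- exp(-(co[[1]] - cx * fov[1])^2 / (2 * s^2))
  gy <- exp(-(co[[2]] - cy * fov[2])^2 / (2 * s^2))
  gz <- exp(-(co[[3]] - cz * fov[3])^2 / (2 * s^2))
  outer(outer(gx, gy), gz) |> array(grid)
}

build_template <- function(spec) {
  tpl <- array(0, spec$grid)
  for (i in seq_len(nrow(spec$blobs))) {
    b <- spec$blobs[i, ]
    tpl <- tpl + b$amplitude *
      gaussian_blob(spec$grid, spec$spacing, b$x, b$y, b$z, b$sigma)
  }
  tpl
}

build_log_pattern <- function(spec) {
  pat <- array(0, spec$grid)
  for (i in seq_len(nrow(spec$effects))) {
    e <- spec$effects[i, ]
    pat <- pat + log(e$factor) *
      gaussian_blob(spec$grid, spec$spacing, e$x, e$y, e$z, e$sigma)
  }
  pat
}

# circular Gaussian smoothing via FFT; adequate for phantom noise fields
smooth_gaussian_3d <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  dims <- dim(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ker1 <- lapply(1:3, function(a) {
    n <- dims[a]
    dist <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * spacing
    exp(-dist^2 / (2 * sigma^2))
  })
  ker <- outer(outer(ker1[[1]], ker1[[2]]), ker1[[3]]) |> array(dims)
  ker <- ker / sum(ker)
  Re(fft(fft(arr) * fft(ker), inverse = TRUE)) / length(arr)
}

draw_subjects <- function(spec, n, mean_expr, with_age_slope) {
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  expr <- rnorm(n, mean_expr, spec$expression_sd)
  if (with_age_slope) expr <- expr + spec$age_slope * (age - spec$age_mean)
  list(age = age, expr = expr,
       sex = sample(c("M", "F"), n, replace = TRUE),
       apoe4 = sample(c(0L, 1L), n, replace = TRUE, prob = c(0.7, 0.3)),
       gscale = exp(rnorm(n, 0, spec$global_scale_sd)))
}

assemble_volumes <- function(spec, tpl, logpat, groups) {
  support <- tpl >= 0.25 * max(tpl)
  noise_scale <- spec$noise_sd * mean(tpl[support])
  max_e <- max(abs(vapply(groups, function(g) range(g$expr), numeric(2))))
  if (max_e * max(abs(logpat)) > 50)
    stop_fdg("bad_spec", "effect size so large that exp() would overflow")
  volumes <- list()
  rows <- list()
  expr_all <- numeric(0); gs_all <- numeric(0); age_all <- numeric(0)
  idx <- 0L
  for (g in groups) {
    for (i in seq_along(g$expr)) {
      idx <- idx + 1L
      noise <- array(rnorm(prod(spec$grid)), spec$grid)
      noise <- smooth_gaussian_3d(noise, spec$smooth_fwhm, spec$spacing)
      nsd <- sd(noise[support])
      if (nsd > 0) noise <- noise / nsd * noise_scale
      dat <- g$gscale[i] * tpl * exp(g$expr[i] * logpat) + noise
      dat[dat < 0] <- 0
      sid <- sprintf("%s%03d", g$prefix, i)
      volumes[[idx]] <- brain_volume(dat, spacing = rep(spec$spacing, 3),
                                     subject_id = sid,
                                     modality = "synthetic")
      rows[[idx]] <- data.frame(subject_id = sid,
                                path = paste0(sid, ".nii.gz"),
                                group = g$label, age = round(g$age[i], 1),
                                sex = g$sex[i], apoe4 = g$apoe4[i],
                                stringsAsFactors = FALSE)
      expr_all <- c(expr_all, g$expr[i])
      gs_all <- c(gs_all, g$gscale[i])
      age_all <- c(age_all, g$age[i])
    }
  }
  list(volumes = volumes, manifest = do.call(rbind, rows),
       expression = expr_all, global_scale = gs_all, age = age_all)
}

#' Generate a phantom cohort with known ground truth
#'
#' Draws a two-group cohort from a [cohort_spec()]. The returned ground
#' truth (planted log-pattern volume, per-subject expression, global scale
#' and age) is the oracle against which pattern-recovery and
#' designation-rate experiments are judged. With `out_dir` set, the
#' volumes, a manifest TSV, the ground-truth pattern NIfTI and a JSON with
#' the per-subject truth are written to disk.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @return List with `volumes` (list of [brain_volume]), `manifest`
#'   (data.frame), `ground_truth` (list: `pattern_volume`, `expression`,
#'   `global_scale`, `age`), `template` (array), `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- build_template(spec)
  if (min(tpl) < 0) stop_fdg("bad_spec", "template must be non-negative")
  logpat <- build_log_pattern(spec)
  res <- with_preserved_seed(spec$seed, {
    ctl <- draw_subjects(spec, spec$n_control, 0, with_age_slope = TRUE)
    dis <- draw_subjects(spec, spec$n_disease, spec$d, with_age_slope = FALSE)
    ctl$label <- spec$control_label; ctl$prefix <- "C"
    dis$label <- spec$disease_label; dis$prefix <- "D"
    assemble_volumes(spec, tpl, logpat, list(ctl, dis))
  })
  gt <- list(pattern_volume = brain_volume(logpat,
                                           spacing = rep(spec$spacing, 3),
                                           subject_id = "ground-truth",
                                           modality = "synthetic"),
             expression = res$expression, global_scale = res$global_scale,
             age = res$age)
  out <- list(volumes = res$volumes, manifest = res$manifest,
              ground_truth = gt, template = tpl, spec = spec)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  invisible(out)
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes)
    write_volume(v, file.path(out_dir, paste0(v$subject_id, ".nii.gz")))
  write.table(cohort$manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_volume(cohort$ground_truth$pattern_volume,
               file.path(out_dir, "ground_truth_pattern.nii.gz"))
  gt <- cohort$ground_truth
  jsonlite::write_json(list(subject_id = cohort$manifest$subject_id,
                            expression = gt$expression,
                            global_scale = gt$global_scale, age = gt$age),
                       file.path(out_dir, "ground_truth.json"),
                       digits = NA)
  invisible(out_dir)
}

#' Generate a cohort expressing the planted pattern at a given loading
#'
#' Produces a single-group cohort whose subjects express the same planted
#' disease pattern at mean `ad_pattern_loading` times the disease group's
#' mean expression (`spec$d`). Loading near 1 emulates dementias that
#' share the AD-like topography (PDD/DLB-like); loading 0 emulates
#' cognitively healthy non-AD patients (PDND-like).
#'
#' @param spec A [cohort_spec()]; `n_disease` sets the cohort size.
#' @param ad_pattern_loading Mean pattern loading in `[0, 2]`.
#' @param group_label Manifest label for the cohort (default `"PDD"`).
#' @param out_dir Optional output directory.
#' @return Same structure as [generate_cohort()].
#' @export
make_dlb_like_cohort <- function(spec, ad_pattern_loading,
                                 group_label = "PDD", out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (ad_pattern_loading < 0 || ad_pattern_loading > 2)
    stop_fdg("bad_spec", "ad_pattern_loading must lie in [0, 2]")
  tpl <- build_template(spec)
  logpat <- build_log_pattern(spec)
  res <- with_preserved_seed(spec$seed, {
    grp <- draw_subjects(spec, spec$n_disease,
                         ad_pattern_loading * spec$d, with_age_slope = FALSE)
    grp$label <- group_label; grp$prefix <- "X"
    assemble_volumes(spec, tpl, logpat, list(grp))
  })
  gt <- list(pattern_volume = brain_volume(logpat,
                                           spacing = rep(spec$spacing, 3),
                                           subject_id = "ground-truth",
                                           modality = "synthetic"),
             expression = res$expression, global_scale = res$global_scale,
             age = res$age)
  out <- list(volumes = res$volumes, manifest = res$manifest,
              ground_truth = gt, template = tpl, spec = spec)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  invisible(out)
}
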