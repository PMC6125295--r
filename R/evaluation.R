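# run code under a temporary RNG state so library calls stay reproducible
# without disturbing the caller's stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' ROC analysis with a sensitivity-times-specificity optimal threshold
#'
#' Builds the empirical ROC curve of a score against two group labels
#' (positive designated when `score >= threshold`). The AUC is the area
#' under the empirical curve by the trapezoidal rule, which equals the
#' Mann-Whitney pair-count statistic (ties counted 1/2). Candidate
#' thresholds are placed midway between adjacent distinct scores (plus one
#' below and one above all scores); the optimal threshold maximizes
#' sensitivity x specificity, breaking ties toward higher specificity.
#'
#' @param scores Numeric scores, or a `score_table` (its z-scores are used
#'   when available, raw scores otherwise).
#' @param labels Group labels aligned with `scores` (taken from the score
#'   table when omitted).
#' @param positive Label of the positive (disease) group.
#' @return An object of class `roc_result`: `auc`, `thresholds`,
#'   `sensitivities`, `specificities`, `optimal_threshold`, `optimal_sens`,
#'   `optimal_spec`.
#' @export
roc_analysis <- function(scores, labels = NULL, positive = "AD") {
  if (inherits(scores, "score_table")) {
    if (is.null(labels)) labels <- scores$group
    scores <- if (all(is.na(scores$z_score))) scores$raw_score
              else scores$z_score
  }
  if (any(!is.finite(scores)))
    stop_fdg("nonfinite_data", "scores must be finite")
  code <- binary_codes(labels, positive)
  pos <- scores[code == 1L]; neg <- scores[code == 0L]
  n1 <- length(pos); n0 <- length(neg)
  # Mann-Whitney AUC via mean ranks (exact, ties counted 1/2)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  su <- sort(unique(scores))
  thr <- if (length(su) > 1L)
    c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  else c(su - 1, su + 1)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  ss <- sens * spec
  best <- which(ss == max(ss))
  best <- best[which.max(spec[best])]  # tie-break: higher specificity
  structure(list(auc = auc, thresholds = thr, sensitivities = sens,
                 specificities = spec, optimal_threshold = thr[best],
                 optimal_sens = sens[best], optimal_spec = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", format(round(x$auc, 3)), ", optimal threshold ",
      format(round(x$optimal_threshold, 3)), " (sens ",
      format(round(x$optimal_sens, 3)), " x spec ",
      format(round(x$optimal_spec, 3)), ")\n", sep = "")
  invisible(x)
}

stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (n < k) stop_fdg("bad_k", paste0("k = ", k, " exceeds n = ", n))
  fold <- integer(n)
  with_preserved_seed(seed, {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# train one classifier on a training voxel_matrix and score a test matrix
# prospectively; GLM/SSM thresholds come from the training-fold ROC only
fit_and_score <- function(train_vm, test_vm, method, positive, config,
                          n_pcs = 10) {
  if (method == "GLM") {
    model <- fit_glm_pattern(train_vm, positive)
    tr <- score_subjects(model, train_vm, designate = FALSE)
    model$z_threshold <- roc_analysis(tr, positive = positive)$optimal_threshold
    list(model = model,
         train = score_subjects(model, train_vm),
         test = score_subjects(model, test_vm))
  } else if (method %in% c("SSM1", "SSM2")) {
    dec <- ssm_svd(log_double_center(train_vm),
                   k = min(n_pcs, nrow(train_vm$values) - 1L,
                           ncol(train_vm$values)))
    model <- if (method == "SSM1") select_best_pc(dec, positive)
             else stepwise_combine(dec, positive)
    tr <- prospective_score(model, train_vm, designate = FALSE)
    model$z_threshold <- roc_analysis(tr, positive = positive)$optimal_threshold
    list(model = model,
         train = prospective_score(model, train_vm),
         test = prospective_score(model, test_vm))
  } else if (method %in% c("SVM-ISDA", "SVM-SMO")) {
    if (is.null(config))
      config <- svm_config(if (method == "SVM-ISDA") "ISDA" else "SMO")
    model <- train_svm(train_vm, positive, config)
    list(model = model,
         train = score_subjects(model, train_vm),
         test = score_subjects(model, test_vm))
  } else stop_fdg("bad_method", paste0("unknown method: ", method))
}

subset_matrix <- function(vm, idx) {
  voxel_matrix(vm$values[idx, , drop = FALSE], vm$subject_ids[idx],
               vm$labels[idx], vm$mask, scaled = vm$scaled)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Subjects are assigned to `k` folds by a seeded, group-stratified
#' permutation (class counts per fold differ by at most one). For each
#' fold, everything data-dependent — the analysis mask (when volumes are
#' supplied), the pattern model and, for GLM/SSM, the ROC-optimal
#' z-threshold — is derived from the training subjects only; held-out
#' subjects are then scored prospectively. Metrics (AUC, sensitivity,
#' specificity) are pooled over all held-out scores, not averaged per fold.
#'
#' @param x A list of [brain_volume]s (the mask is recomputed per training
#'   fold) or a `voxel_matrix` (fixed mask, e.g. a precomputed one).
#' @param labels Group labels aligned with `x` (taken from the matrix when
#'   omitted).
#' @param method One of `"GLM"`, `"SSM1"`, `"SSM2"`, `"SVM-ISDA"`,
#'   `"SVM-SMO"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold permutation.
#' @param positive Label of the disease group.
#' @param config Optional [svm_config()] for the SVM methods.
#' @param rel_threshold Mask threshold used when `x` is a volume list.
#' @param n_pcs Number of PCs retained by the SSM methods.
#' @return An object of class `cv_result`: `fold_assignment`,
#'   `pooled_scores` (a `score_table` with fold provenance), `auc`,
#'   `sensitivity`, `specificity`, `sens_x_spec`, `per_fold_models`.
#' @export
kfold_cv <- function(x, labels = NULL, method = "GLM", k = 10, seed = 1,
                     positive = "AD", config = NULL, rel_threshold = 0.25,
                     n_pcs = 10) {
  from_volumes <- !inherits(x, "voxel_matrix")
  if (!from_volumes && is.null(labels)) labels <- x$labels
  if (is.null(labels)) stop_fdg("label_mismatch", "labels are required")
  code <- binary_codes(labels, positive)
  fold <- stratified_folds(labels, k, seed)
  pooled <- NULL
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    if (length(unique(labels[tr_idx])) < 2L)
      stop_fdg("fold_missing_class",
               paste0("training fold ", f, " lacks one class"))
    if (!length(te_idx)) next
    if (from_volumes) {
      mask_f <- compute_mask(x[tr_idx], rel_threshold)
      train_vm <- proportional_scale(
        extract_matrix(x[tr_idx], mask_f, labels[tr_idx]))
      test_vm <- proportional_scale(
        extract_matrix(x[te_idx], mask_f, labels[te_idx]))
    } else {
      xm <- if (isTRUE(x$scaled)) x else proportional_scale(x)
      train_vm <- subset_matrix(xm, tr_idx)
      test_vm <- subset_matrix(xm, te_idx)
    }
    res <- fit_and_score(train_vm, test_vm, method, positive, config, n_pcs)
    st <- res$test
    st$fold <- f
    pooled <- rbind(pooled, st)
    m <- res$model
    fold_models[[f]] <- list(fold = f, method = m$method,
                             z_threshold = m$z_threshold,
                             n_train = length(tr_idx),
                             extras_summary = summarize_extras(m))
  }
  class(pooled) <- c("score_table", "data.frame")
  roc <- roc_analysis(pooled, positive = positive)
  pos_lab <- positive
  is_pos <- pooled$group == pos_lab
  desig_pos <- pooled$designation == pos_lab
  sens <- mean(desig_pos[is_pos])
  spec <- mean(!desig_pos[!is_pos])
  structure(list(fold_assignment = fold, pooled_scores = pooled,
                 auc = roc$auc, sensitivity = sens, specificity = spec,
                 sens_x_spec = sens * spec, per_fold_models = fold_models,
                 method = method, k = k, seed = seed),
            class = "cv_result")
}

summarize_extras <- function(model) {
  ex <- model$extras
  if (model$method %in% c("SSM1", "SSM2"))
    list(selected_pcs = ex$selected_pcs, weights = ex$weights)
  else if (startsWith(model$method, "SVM"))
    list(n_support = length(ex$support_ids),
         removed_outliers = ex$removed_outliers,
         iterations = ex$solver_iterations)
  else NULL
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$method, ", k = ", x$k, ": AUC ",
      format(round(x$auc, 3)), ", sens ", format(round(x$sensitivity, 3)),
      ", spec ", format(round(x$specificity, 3)), ", sens x spec ",
      format(round(x$sens_x_spec, 3)), "\n", sep = "")
  invisible(x)
}

#' Apply a trained model to a (possibly multi-group) cohort
#'
#' Scores every subject with the model's scoring rule and reports, per
#' group, how many received the disease designation, formatted `"x of n"`.
#' When the caller flags which groups count as positive and negative,
#' pooled sensitivity, specificity and their product are also reported.
#'
#' @param model A trained `pattern_model` (GLM/SSM models need their
#'   `z_threshold` set).
#' @param matrix A scaled `voxel_matrix` on the model's mask.
#' @param labels Group labels (defaults to the matrix labels). Factor
#'   levels without subjects are dropped with a warning.
#' @param positive_groups,negative_groups Optional character vectors of
#'   groups treated as disease/control for sensitivity and specificity.
#' @return An object of class `cohort_report`: `scores` (a `score_table`),
#'   `by_group` (data.frame with `group`, `n`, `n_designated`, `fraction`,
#'   `label`), and optional `sensitivity`/`specificity`/`sens_x_spec`.
#' @export
apply_to_cohort <- function(model, matrix, labels = NULL,
                            positive_groups = NULL, negative_groups = NULL) {
  stopifnot(inherits(model, "pattern_model"))
  if (is.null(labels)) labels <- matrix$labels
  if (is.factor(labels)) {
    empty <- setdiff(levels(labels), unique(as.character(labels)))
    if (length(empty))
      warn_fdg("empty_group",
               paste0("group(s) with no subjects omitted: ",
                      paste(empty, collapse = ", ")))
    labels <- as.character(labels)
  }
  matrix$labels <- labels
  st <- if (model$method %in% c("SSM1", "SSM2"))
    prospective_score(model, matrix) else score_subjects(model, matrix)
  pos_lab <- model$positive_class
  groups <- unique(labels)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    sel <- st$group == g
    n <- sum(sel); nd <- sum(st$designation[sel] == pos_lab)
    data.frame(group = g, n = n, n_designated = nd, fraction = nd / n,
               label = paste0(nd, " of ", n), stringsAsFactors = FALSE)
  }))
  out <- list(scores = st, by_group = by_group)
  if (!is.null(positive_groups) && !is.null(negative_groups)) {
    ip <- st$group %in% positive_groups
    ineg <- st$group %in% negative_groups
    out$sensitivity <- mean(st$designation[ip] == pos_lab)
    out$specificity <- mean(st$designation[ineg] != pos_lab)
    out$sens_x_spec <- out$sensitivity * out$specificity
  }
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  for (i in seq_len(nrow(x$by_group)))
    cat("  ", x$by_group$group[i], ": ", x$by_group$label[i],
        " designated\n", sep = "")
  if (!is.null(x$sens_x_spec))
    cat("  sens ", format(round(x$sensitivity, 3)), " x spec ",
        format(round(x$specificity, 3)), " = ",
        format(round(x$sens_x_spec, 3)), "\n", sep = "")
  invisible(x)
}

# embed a pattern vector in the mask's bounding box (zeros elsewhere)
pattern_in_bbox <- function(pattern, mask) {
  idx <- which(mask$include, arr.ind = TRUE)
  rng <- apply(idx, 2L, range)
  dims <- rng[2, ] - rng[1, ] + 1L
  box <- array(0, dims)
  sub_mask <- array(FALSE, dims)
  shifted <- sweep(idx, 2L, rng[1, ] - 1L)
  lin <- shifted[, 1] + (shifted[, 2] - 1L) * dims[1] +
    (shifted[, 3] - 1L) * dims[1] * dims[2]
  box[lin] <- pattern
  sub_mask[lin] <- TRUE
  list(box = box, sub_mask = sub_mask, lin = lin)
}

# phase-randomized surrogate preserving the amplitude spectrum; the random
# phases are taken from the FFT of white noise, which guarantees the
# Hermitian symmetry needed for a real-valued field
phase_randomize <- function(box) {
  amp <- Mod(fft(box))
  noise <- array(rnorm(length(box)), dim(box))
  ph <- fft(noise)
  mod <- Mod(ph)
  mod[mod == 0] <- 1
  Re(fft(amp * ph / mod, inverse = TRUE)) / length(box)
}

#' Topographic similarity between two pattern maps
#'
#' Voxel-wise Pearson correlation between two pattern maps over a shared
#' mask, with significance assessed against surrogate maps that preserve
#' the second map's spatial autocorrelation: the map is embedded in the
#' mask's bounding box and Fourier phase-randomized (amplitude spectrum
#' kept), then re-masked. The permutation p-value
#' `(1 + #{|r_surr| >= |r|}) / (1 + n_surrogates)` may be Bonferroni-scaled
#' by the caller for multi-pair comparison tables.
#'
#' @param patternA,patternB Numeric vectors over the mask voxels, or
#'   `pattern_model`s (their pattern is used; masks must agree).
#' @param mask The shared `brain_mask` (taken from a model if supplied).
#' @param n_surrogates Number of surrogate maps (>= 99; default 999).
#' @param seed Integer seed for the surrogate draw.
#' @param bonferroni Multiplicity factor applied to the p-value.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `similarity_result`: `r`, `p_corrected`,
#'   `n_surrogates`, `significant`.
#' @export
topographic_similarity <- function(patternA, patternB, mask = NULL,
                                   n_surrogates = 999, seed = 1,
                                   bonferroni = 1, alpha = 0.05) {
  if (inherits(patternA, "pattern_model")) {
    if (is.null(mask)) mask <- patternA$mask
    patternA <- patternA$pattern
  }
  if (inherits(patternB, "pattern_model")) {
    if (is.null(mask)) mask <- patternB$mask
    patternB <- patternB$pattern
  }
  if (is.null(mask)) stop_fdg("bad_mask", "a mask is required")
  if (length(patternA) != mask$n_voxels || length(patternB) != mask$n_voxels)
    stop_fdg("mask_mismatch", "patterns must live on the mask's voxels")
  if (n_surrogates < 99)
    stop_fdg("bad_config", "need at least 99 surrogates")
  if (sd(patternA) == 0 || sd(patternB) == 0)
    stop_fdg("constant_pattern", "correlation undefined for a constant map")
  r <- cor(patternA, patternB)
  emb <- pattern_in_bbox(patternB, mask)
  r_surr <- numeric(n_surrogates)
  with_preserved_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      surr <- phase_randomize(emb$box)[emb$lin]
      r_surr[s] <- if (sd(surr) == 0) 0 else cor(patternA, surr)
    }
  })
  p <- (1 + sum(abs(r_surr) >= abs(r))) / (1 + n_surrogates)
  p_corr <- min(1, p * bonferroni)
  structure(list(r = r, p_corrected = p_corr,
                 n_surrogates = n_surrogates,
                 significant = p_corr < alpha),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> r = ", format(round(x$r, 3)), ", corrected p = ",
      format(round(x$p_corrected, 4)),
      if (x$significant) " (significant)" else "", "\n", sep = "")
  invisible(x)
}
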