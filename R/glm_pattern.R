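METHODS <- c("GLM", "SSM1", "SSM2", "SVM-ISDA", "SVM-SMO")

# binary coding: disease (positive class) = 1, control = 0, so that a higher
# subject score always means "more AD-like"
binary_codes <- function(labels, positive) {
  u <- unique(labels)
  if (length(u) != 2L)
    stop_fdg("not_two_groups",
             paste0("exactly two distinct groups required, got: ",
                    paste(u, collapse = ", ")))
  if (!positive %in% u)
    stop_fdg("bad_positive",
             paste0("positive class '", positive, "' not present"))
  as.integer(labels == positive)
}

pattern_model <- function(method, pattern, bias, mask, ref_mean = NULL,
                          ref_sd = NULL, z_threshold = NULL,
                          positive_class = "AD", extras = list()) {
  method <- match.arg(method, METHODS)
  stopifnot(length(pattern) == mask$n_voxels)
  if (!is.null(ref_sd) && ref_sd <= 0)
    stop_fdg("zero_sd", "reference standard deviation must be positive")
  structure(list(method = method, pattern = as.numeric(pattern),
                 bias = as.numeric(bias), mask = mask,
                 mask_checksum = mask_checksum(mask),
                 ref_mean = ref_mean, ref_sd = ref_sd,
                 z_threshold = z_threshold,
                 positive_class = positive_class, extras = extras),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("<pattern_model> ", x$method, ", ", length(x$pattern), " voxels",
      if (!is.null(x$z_threshold)) paste0(", z-threshold ",
                                          format(round(x$z_threshold, 3))),
      "\n", sep = "")
  invisible(x)
}

#' Z-score normalization reference from control subjects
#'
#' Returns the sample mean and sample standard deviation (n - 1 denominator)
#' of the control-group raw scores; subject scores are then reported as
#' z-scores relative to this normal reference.
#'
#' @param raw_scores Numeric vector of control-group raw scores (length >= 2).
#' @return List with elements `ref_mean` and `ref_sd`.
#' @export
zscore_reference <- function(raw_scores) {
  if (length(raw_scores) < 2L)
    stop_fdg("too_few_controls", "need at least 2 control scores")
  s <- sd(raw_scores)
  if (!is.finite(s) || s == 0)
    stop_fdg("zero_sd", "control scores have zero standard deviation")
  list(ref_mean = mean(raw_scores), ref_sd = s)
}

#' Fit the voxel-wise GLM (beta-map) classifier
#'
#' For each voxel a linear regression of the proportionally scaled uptake on
#' the 0/1 group dummy (disease = 1) is fitted; the slope map is the
#' pattern. With 0/1 coding the least-squares slope at each voxel equals the
#' disease-group mean minus the control-group mean, which is how it is
#' computed. The intercept map is fitted implicitly but not stored: it
#' shifts all subject scores equally and is absorbed by z-scoring.
#'
#' @param matrix A scaled `voxel_matrix` containing exactly two groups.
#' @param positive Label of the disease group (coded 1).
#' @return A `pattern_model` with method `"GLM"`. `z_threshold` is left
#'   unset until ROC analysis chooses it.
#' @export
fit_glm_pattern <- function(matrix, positive = "AD") {
  stopifnot(inherits(matrix, "voxel_matrix"))
  if (!isTRUE(matrix$scaled))
    stop_fdg("unscaled", "matrix must be proportionally scaled first")
  code <- binary_codes(matrix$labels, positive)
  if (sum(code == 1L) < 2L || sum(code == 0L) < 2L)
    stop_fdg("too_few_subjects", "need at least 2 subjects per group")
  beta <- colMeans(matrix$values[code == 1L, , drop = FALSE]) -
    colMeans(matrix$values[code == 0L, , drop = FALSE])
  raw_ctl <- as.numeric(matrix$values[code == 0L, , drop = FALSE] %*% beta)
  if (sd(raw_ctl) == 0) {
    warn_fdg("zero_sd",
             "control scores are constant; z-score reference left unset")
    ref <- list(ref_mean = NULL, ref_sd = NULL)
  } else ref <- zscore_reference(raw_ctl)
  pattern_model("GLM", beta, bias = 0, mask = matrix$mask,
                ref_mean = ref$ref_mean, ref_sd = ref$ref_sd,
                positive_class = positive)
}

#' Score subjects against a trained pattern model
#'
#' The raw score of a subject is the dot product of the pattern map with the
#' subject's (proportionally scaled) image vector, plus the model bias.
#' Scores are z-scored to the normal-control reference stored in the model.
#' Designation: GLM/SSM models label a subject as the disease class when
#' `z_score >= z_threshold`; SVM models use the sign of the raw score
#' (positive = disease), with no ROC threshold involved.
#'
#' For SSM models this routine expects pre-centered data; use
#' [prospective_score()] to score raw scaled scans.
#'
#' @param model A `pattern_model`.
#' @param matrix A scaled `voxel_matrix` on the model's mask (identical voxel
#'   order).
#' @param designate If `TRUE` (default) a binary designation is produced;
#'   GLM/SSM models then require a `z_threshold`.
#' @return An object of class `score_table` (a data.frame with columns
#'   `subject_id`, `group`, `raw_score`, `z_score`, `designation`, `fold`).
#' @export
score_subjects <- function(model, matrix, designate = TRUE) {
  stopifnot(inherits(model, "pattern_model"),
            inherits(matrix, "voxel_matrix"))
  if (!identical(model$mask_checksum, mask_checksum(matrix$mask)))
    stop_fdg("mask_mismatch", "matrix mask differs from the model's mask")
  if (!isTRUE(matrix$scaled))
    stop_fdg("unscaled", "matrix must be proportionally scaled first")
  raw <- as.numeric(matrix$values %*% model$pattern) + model$bias
  score_table_from_raw(model, matrix$subject_ids, matrix$labels, raw,
                       designate = designate)
}

score_table_from_raw <- function(model, subject_ids, labels, raw,
                                 designate = TRUE, fold = NA_integer_) {
  z <- if (!is.null(model$ref_mean))
    (raw - model$ref_mean) / model$ref_sd else rep(NA_real_, length(raw))
  desig <- rep(NA_character_, length(raw))
  if (designate) {
    pos <- model$positive_class
    neg <- paste0("non-", pos)
    if (model$method %in% c("GLM", "SSM1", "SSM2")) {
      if (is.null(model$z_threshold))
        stop_fdg("no_threshold",
                 "GLM/SSM model has no z_threshold; run roc_analysis first")
      desig <- ifelse(z >= model$z_threshold, pos, neg)
    } else {
      desig <- ifelse(raw > 0, pos, neg)
    }
  }
  out <- data.frame(subject_id = subject_ids, group = labels,
                    raw_score = raw, z_score = z, designation = desig,
                    fold = fold, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write a score table as TSV
#' @param scores A `score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)
  df$raw_score <- sprintf("%.10g", df$raw_score)
  df$z_score <- sprintf("%.10g", df$z_score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
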