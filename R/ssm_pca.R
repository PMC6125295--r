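#' Log-transform and double-center a voxel matrix
#'
#' First step of the scaled subprofile model (SSM): natural log of the
#' (positive) uptake values, then removal of each subject's row mean (which
#' eliminates residual global scaling), then removal of each voxel's column
#' mean across subjects. The subtracted column-mean profile — the group mean
#' profile (GMP) — is retained because prospective scoring of new scans
#' must subtract the same profile.
#'
#' @param matrix A scaled `voxel_matrix` with strictly positive values.
#' @return An object of class `ssm_decomposition` with fields `centered`,
#'   `gmp`, `mask`, `subject_ids`, `labels` (PC fields filled by
#'   [ssm_svd()]).
#' @export
log_double_center <- function(matrix) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  if (any(matrix$values <= 0))
    stop_fdg("nonpositive_value",
             "log transform requires strictly positive voxel values")
  logv <- log(matrix$values)
  rowc <- logv - rowMeans(logv)
  gmp <- colMeans(rowc)
  centered <- sweep(rowc, 2L, gmp)
  structure(list(centered = centered, gmp = gmp, mask = matrix$mask,
                 subject_ids = matrix$subject_ids, labels = matrix$labels,
                 pcs = NULL, subject_scores = NULL, singular_values = NULL,
                 vaf = NULL),
            class = "ssm_decomposition")
}

#' Principal components of the double-centered log data
#'
#' Singular value decomposition of the centered matrix. The top `k` right
#' singular vectors are the voxel loading patterns (PCs); subject scores are
#' the projections of the centered rows onto them. Each PC's sign is fixed
#' deterministically (its largest-magnitude loading is positive) so repeated
#' runs agree; group-discriminative orientation is applied later when a
#' classifier is built. `vaf` is the variance fraction accounted for,
#' singular value squared over the total sum of squares.
#'
#' @param decomp An `ssm_decomposition` from [log_double_center()].
#' @param k Number of components to retain (default 10).
#' @return The decomposition with `pcs` (voxels x k), `subject_scores`
#'   (subjects x k), `singular_values` and `vaf` filled in.
#' @export
ssm_svd <- function(decomp, k = 10) {
  stopifnot(inherits(decomp, "ssm_decomposition"))
  X <- decomp$centered
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (k > kmax)
    stop_fdg("k_too_large",
             paste0("k = ", k, " exceeds min(n - 1, n_voxels) = ", kmax))
  total_ss <- sum(X^2)
  if (p >= n) {
    # eigen route through the small n x n Gram matrix
    G <- tcrossprod(X)
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    d <- sqrt(d2)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    if (any(d < 1e-12 * max(d)))
      warn_fdg("rank_deficient",
               "near-zero singular values among the retained components")
    V <- crossprod(X, U)
    V <- sweep(V, 2L, pmax(d, 1e-300), "/")
  } else {
    sv <- svd(X, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    U <- sv$u
    V <- sv$v
    if (any(d < 1e-12 * max(d)))
      warn_fdg("rank_deficient",
               "near-zero singular values among the retained components")
  }
  # deterministic sign: largest-|loading| voxel positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  decomp$pcs <- V
  decomp$subject_scores <- sweep(U, 2L, d, "*")
  decomp$singular_values <- d
  decomp$vaf <- d^2 / total_ss
  decomp
}

ssm_ref_model <- function(method, pattern, decomp, code, positive,
                          selected, weights) {
  scores <- as.numeric(decomp$centered %*% pattern)
  # orient so the disease group expresses the pattern positively
  if (mean(scores[code == 1L]) < mean(scores[code == 0L])) {
    pattern <- -pattern
    weights <- -weights
    scores <- -scores
  }
  ref <- zscore_reference(scores[code == 0L])
  pattern_model(method, pattern, bias = 0, mask = decomp$mask,
                ref_mean = ref$ref_mean, ref_sd = ref$ref_sd,
                positive_class = positive,
                extras = list(gmp = decomp$gmp, selected_pcs = selected,
                              weights = weights, log_base = "natural"))
}

#' Single best-discriminating principal component (SSM/PCA1)
#'
#' A two-sample pooled-variance t statistic on subject scores is computed
#' for every PC; the PC with the largest |t| becomes the disease-related
#' pattern (ties break to the lowest PC index). The pattern is oriented so
#' the disease group's mean score is positive, and the control scores give
#' the z-score reference.
#'
#' @param decomp An `ssm_decomposition` with PCs ([ssm_svd()]).
#' @param positive Label of the disease group.
#' @return A `pattern_model` with method `"SSM1"`.
#' @export
select_best_pc <- function(decomp, positive = "AD") {
  stopifnot(inherits(decomp, "ssm_decomposition"), !is.null(decomp$pcs))
  code <- binary_codes(decomp$labels, positive)
  if (sum(code == 1L) < 2L || sum(code == 0L) < 2L)
    stop_fdg("too_few_subjects", "need at least 2 subjects per group")
  tstat <- apply(decomp$subject_scores, 2L, function(s) {
    n1 <- sum(code == 1L); n0 <- sum(code == 0L)
    sp2 <- ((n1 - 1) * stats::var(s[code == 1L]) +
              (n0 - 1) * stats::var(s[code == 0L])) / (n1 + n0 - 2)
    if (sp2 <= 0) return(0)
    (mean(s[code == 1L]) - mean(s[code == 0L])) / sqrt(sp2 * (1/n1 + 1/n0))
  })
  j <- which.max(abs(tstat))  # which.max takes the first (lowest) on ties
  ssm_ref_model("SSM1", decomp$pcs[, j], decomp, code, positive,
                selected = j, weights = 1)
}

#' Stepwise-combined principal components (SSM/PCA2)
#'
#' Stepwise linear regression of the 0/1 group label on the PC subject
#' scores: forward entry when the candidate's coefficient has p < `entry_p`,
#' followed by backward removal of terms with p >= `removal_p`, iterated to
#' convergence. The retained PCs are linearly combined with their regression
#' coefficients to form a single pattern, which is re-oriented
#' disease-positive; subject scores are recomputed by projecting the
#' centered data onto the combined pattern. If no PC enters, the single
#' best PC is used instead (with a warning).
#'
#' @param decomp An `ssm_decomposition` with PCs.
#' @param positive Label of the disease group.
#' @param entry_p Forward-entry p threshold (default 0.05).
#' @param removal_p Backward-removal p threshold (default 0.10).
#' @return A `pattern_model` with method `"SSM2"`; `extras$selected_pcs`
#'   and `extras$weights` record the combination.
#' @export
stepwise_combine <- function(decomp, positive = "AD", entry_p = 0.05,
                             removal_p = 0.10) {
  stopifnot(inherits(decomp, "ssm_decomposition"), !is.null(decomp$pcs))
  code <- binary_codes(decomp$labels, positive)
  if (sum(code == 1L) < 2L || sum(code == 0L) < 2L)
    stop_fdg("too_few_subjects", "need at least 2 subjects per group")
  S <- decomp$subject_scores
  k <- ncol(S)
  included <- integer(0)
  coef_p <- function(set) {
    fit <- lm(code ~ S[, set, drop = FALSE])
    cf <- summary(fit)$coefficients
    # rows after the intercept correspond to `set` in order
    list(fit = fit, p = cf[-1, 4], beta = cf[-1, 1])
  }
  repeat {
    changed <- FALSE
    candidates <- setdiff(seq_len(k), included)
    if (length(candidates)) {
      pvals <- vapply(candidates, function(j) {
        res <- coef_p(c(included, j))
        unname(res$p[length(res$p)])
      }, numeric(1))
      jbest <- which.min(pvals)
      if (is.finite(pvals[jbest]) && pvals[jbest] < entry_p) {
        included <- c(included, candidates[jbest])
        changed <- TRUE
      }
    }
    while (length(included) > 1L) {
      res <- coef_p(included)
      worst <- which.max(res$p)
      if (res$p[worst] >= removal_p) {
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(included)) {
    warn_fdg("stepwise_empty",
             "no PC entered the stepwise model; falling back to best single PC")
    m <- select_best_pc(decomp, positive)
    m$method <- "SSM2"
    return(m)
  }
  included <- sort(included)
  res <- coef_p(included)
  w <- unname(res$beta)
  pattern <- as.numeric(decomp$pcs[, included, drop = FALSE] %*% w)
  ssm_ref_model("SSM2", pattern, decomp, code, positive,
                selected = included, weights = w)
}

#' Prospectively score new scans with an SSM model
#'
#' Each new scan is log-transformed, row-mean-centered, the training group
#' mean profile (GMP) is subtracted, and the result is projected onto the
#' stored pattern. z-scores use the training control reference; designation
#' uses the stored z-threshold. Because the row mean of the log image is
#' removed, scores are invariant to any positive global rescaling of a scan.
#'
#' @param model A `pattern_model` of method `"SSM1"` or `"SSM2"`.
#' @param new_matrix A scaled `voxel_matrix` on the model's mask.
#' @param designate Produce designations (requires a `z_threshold`).
#' @return A `score_table`.
#' @export
prospective_score <- function(model, new_matrix, designate = TRUE) {
  stopifnot(inherits(model, "pattern_model"),
            inherits(new_matrix, "voxel_matrix"))
  if (!model$method %in% c("SSM1", "SSM2"))
    stop_fdg("bad_method", "prospective_score is for SSM models")
  if (!identical(model$mask_checksum, mask_checksum(new_matrix$mask)))
    stop_fdg("mask_mismatch", "matrix mask differs from the model's mask")
  if (any(new_matrix$values <= 0))
    stop_fdg("nonpositive_value",
             "log transform requires strictly positive voxel values")
  logv <- log(new_matrix$values)
  rowc <- logv - rowMeans(logv)
  centered <- sweep(rowc, 2L, model$extras$gmp)
  raw <- as.numeric(centered %*% model$pattern) + model$bias
  score_table_from_raw(model, new_matrix$subject_ids, new_matrix$labels,
                       raw, designate = designate)
}

#' Report an SSM/PCA2 combination in conventional notation
#'
#' Formats the retained PCs and weights as, e.g.,
#' `"1.372 x PC1 + 0.851 x PC3 - 0.204 x PC7"`.
#'
#' @param model A `pattern_model` with SSM extras.
#' @param digits Digits after the decimal point (default 3).
#' @return A single string.
#' @export
format_pc_combination <- function(model, digits = 3) {
  sel <- model$extras$selected_pcs
  w <- model$extras$weights
  stopifnot(length(sel) == length(w), length(sel) >= 1L)
  parts <- character(length(sel))
  for (i in seq_along(sel)) {
    term <- paste0(formatC(abs(w[i]), format = "f", digits = digits),
                   " x PC", sel[i])
    parts[i] <- if (i == 1L) {
      if (w[i] < 0) paste0("-", term) else term
    } else {
      paste0(if (w[i] < 0) "- " else "+ ", term)
    }
  }
  paste(parts, collapse = " ")
}
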