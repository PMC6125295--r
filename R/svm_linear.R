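#' SVM solver configuration
#'
#' Solver settings for the linear soft-margin SVM. Defaults reproduce the
#' two solver configurations used throughout the package: ISDA runs without
#' an equality constraint, absorbing the bias through a kernel offset of
#' 0.1 and driving the KKT residual to a machine-precision floor (its
#' nominal gradient tolerance of 0 is interpreted as
#' `1e-12 * max |gradient|`); SMO keeps the equality constraint with an
#' explicit bias, kernel offset 0 and gradient tolerance 0.001. Both cap
#' work at 1,000,000 iterations, use kernel scale 1, box constraint `C = 1`,
#' and an outlier fraction of 0.05 for robust learning (one remove-and-refit
#' pass dropping the `ceiling(0.05 n)` largest-slack training subjects).
#'
#' @param solver `"ISDA"` or `"SMO"`.
#' @param C Box constraint (> 0).
#' @param kkt_tolerance Gradient/KKT tolerance; `NULL` picks the solver
#'   default (ISDA 0, SMO 0.001).
#' @param max_iterations Iteration cap.
#' @param kernel_offset Constant added to the linear kernel; `NULL` picks
#'   the solver default (ISDA 0.1, SMO 0).
#' @param kernel_scale Kernel scale s in `K(x, z) = x.z / s^2 + offset`.
#' @param outlier_fraction Fraction of training subjects removed as
#'   presumed mislabeled, in `[0, 0.5)`.
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(solver = c("ISDA", "SMO"), C = 1,
                       kkt_tolerance = NULL, max_iterations = 1e6,
                       kernel_offset = NULL, kernel_scale = 1,
                       outlier_fraction = 0.05, seed = NULL) {
  solver <- match.arg(solver)
  if (is.null(kkt_tolerance))
    kkt_tolerance <- if (solver == "ISDA") 0 else 0.001
  if (is.null(kernel_offset))
    kernel_offset <- if (solver == "ISDA") 0.1 else 0
  if (C <= 0) stop_fdg("bad_config", "C must be positive")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop_fdg("bad_config", "outlier_fraction must lie in [0, 0.5)")
  if (max_iterations < 1) stop_fdg("bad_config", "max_iterations must be >= 1")
  structure(list(solver = solver, C = C, kkt_tolerance = kkt_tolerance,
                 max_iterations = max_iterations,
                 kernel_offset = kernel_offset, kernel_scale = kernel_scale,
                 outlier_fraction = outlier_fraction, seed = seed),
            class = "svm_config")
}

svm_gram <- function(X, config) {
  tcrossprod(X) / config$kernel_scale^2 + config$kernel_offset
}

solve_svm_dual <- function(K, y, config) {
  if (config$solver == "ISDA") {
    res <- isda_solve_cpp(K, y, config$C, config$kkt_tolerance,
                          config$max_iterations)
    res$bias <- config$kernel_offset * sum(res$alpha * y)
  } else {
    res <- smo_solve_cpp(K, y, config$C, config$kkt_tolerance,
                         config$max_iterations)
  }
  res
}

#' Train a linear SVM pattern model
#'
#' Solves the soft-margin dual with linear kernel
#' `K(x, z) = x.z / scale^2 + offset` by the configured solver
#' (coordinate-ascent ISDA or pairwise SMO), then performs one robust
#' remove-and-refit pass: the `ceiling(outlier_fraction * n)` training
#' subjects with the largest hinge slack are dropped and the solver is run
#' once more on the remainder. The hyperplane normal
#' `w = sum_i alpha_i y_i x_i / scale^2` becomes the pattern map; new scans
#' are designated by the sign of `w.x + b`. No ROC threshold is used for
#' SVM models; z-scores (relative to the control scores) are reported for
#' plotting parity only.
#'
#' @param matrix A scaled `voxel_matrix` with exactly two groups.
#' @param positive Label of the disease group (coded +1).
#' @param config An [svm_config()].
#' @return A `pattern_model` (method `"SVM-ISDA"` or `"SVM-SMO"`) whose
#'   `extras` store the duals, support-vector ids, removed outliers,
#'   iteration count and final KKT violation.
#' @export
train_svm <- function(matrix, positive = "AD", config = svm_config()) {
  stopifnot(inherits(matrix, "voxel_matrix"), inherits(config, "svm_config"))
  if (!isTRUE(matrix$scaled))
    stop_fdg("unscaled", "matrix must be proportionally scaled first")
  code <- binary_codes(matrix$labels, positive)
  y <- ifelse(code == 1L, 1, -1)
  X <- matrix$values
  if (any(!is.finite(X))) stop_fdg("nonfinite_data", "non-finite features")
  if (all(apply(X, 2L, function(v) diff(range(v)) == 0)))
    stop_fdg("degenerate_features", "all features are constant")
  fit_once <- function(idx) {
    K <- svm_gram(X[idx, , drop = FALSE], config)
    res <- solve_svm_dual(K, y[idx], config)
    res$idx <- idx
    res
  }
  n <- nrow(X)
  res <- fit_once(seq_len(n))
  removed <- character(0)
  n_drop <- ceiling(config$outlier_fraction * n)
  if (n_drop > 0) {
    fdec <- if (config$solver == "ISDA") res$f else res$f + res$bias
    slack <- pmax(0, 1 - y * fdec)
    ord <- order(slack, decreasing = TRUE)
    drop_idx <- ord[seq_len(n_drop)]
    removed <- matrix$subject_ids[drop_idx]
    keep <- setdiff(seq_len(n), drop_idx)
    res <- fit_once(keep)
  }
  if (!isTRUE(res$converged))
    warn_fdg("svm_not_converged",
             paste0(config$solver, " hit the iteration cap (",
                    format(config$max_iterations, scientific = FALSE),
                    "); returning the current iterate"))
  idx <- res$idx
  ay <- res$alpha * y[idx]
  w <- as.numeric(crossprod(X[idx, , drop = FALSE], ay)) /
    config$kernel_scale^2
  b <- res$bias
  raw_all <- as.numeric(X %*% w) + b
  ref <- zscore_reference(raw_all[code == 0L])
  method <- if (config$solver == "ISDA") "SVM-ISDA" else "SVM-SMO"
  pattern_model(method, w, bias = b, mask = matrix$mask,
                ref_mean = ref$ref_mean, ref_sd = ref$ref_sd,
                positive_class = positive,
                extras = list(
                  config = unclass(config),
                  alphas = res$alpha,
                  alpha_subject_ids = matrix$subject_ids[idx],
                  support_ids = matrix$subject_ids[idx][res$alpha > 1e-8],
                  removed_outliers = removed,
                  solver_iterations = res$iterations,
                  final_kkt_violation = res$kkt_violation,
                  converged = isTRUE(res$converged)))
}

#' Initialize an explicit SVM dual state
#'
#' A small, transparent representation of the dual problem used by the
#' single-step routines [isda_step()] and [smo_step()]; useful for
#' inspecting and property-testing solver behaviour at a readable pace.
#' The production solvers iterate the same updates in compiled code.
#'
#' @param K Kernel (Gram) matrix, offset already included for ISDA.
#' @param y Labels in -1/+1.
#' @param C Box constraint.
#' @return A list with `alpha`, `f` (`f_i = sum_j alpha_j y_j K_ij`), `K`,
#'   `y`, `C`.
#' @export
svm_dual_state <- function(K, y, C = 1) {
  stopifnot(nrow(K) == length(y), all(y %in% c(-1, 1)))
  list(alpha = rep(0, length(y)), f = rep(0, length(y)), K = K, y = y, C = C)
}

#' Dual objective of a soft-margin SVM state
#' @param state A state from [svm_dual_state()].
#' @return The dual value `sum alpha - 0.5 * sum alpha_i alpha_j y_i y_j K_ij`.
#' @export
svm_dual_objective <- function(state) {
  ay <- state$alpha * state$y
  sum(state$alpha) - 0.5 * as.numeric(t(ay) %*% state$K %*% ay)
}

#' One ISDA coordinate step
#'
#' Exact single-coordinate maximization of the dual in `alpha[i]`, clipped
#' to `[0, C]`. The dual objective never decreases under this update.
#'
#' @param state A state from [svm_dual_state()].
#' @param i Coordinate (subject index).
#' @return The updated state.
#' @export
isda_step <- function(state, i) {
  kii <- state$K[i, i]
  if (kii <= 0) {
    warn_fdg("zero_curvature", paste0("K[", i, ",", i, "] <= 0; skipping"))
    return(state)
  }
  g <- 1 - state$y[i] * state$f[i]
  anew <- min(max(state$alpha[i] + g / kii, 0), state$C)
  delta <- anew - state$alpha[i]
  if (delta != 0) {
    state$alpha[i] <- anew
    state$f <- state$f + delta * state$y[i] * state$K[i, ]
  }
  state
}

#' One SMO pair step
#'
#' Picks the maximally KKT-violating index on the "up" side and, as second
#' choice, the low-side partner with the largest second-order gain
#' `(v_i - v_t)^2 / (2 eta)` (falling back to the maximal violating pair
#' when that partner cannot move), then solves the two-variable subproblem
#' analytically on the feasible segment, preserving `sum alpha_i y_i = 0`.
#'
#' @param state A state from [svm_dual_state()].
#' @param tol KKT gap below which the state is declared converged.
#' @return The updated state, with `converged = TRUE` when no violating
#'   pair remains.
#' @export
smo_step <- function(state, tol = 1e-3) {
  y <- state$y; a <- state$alpha; C <- state$C; f <- state$f
  v <- y - f
  in_up <- (y > 0 & a < C) | (y < 0 & a > 0)
  in_low <- (y > 0 & a > 0) | (y < 0 & a < C)
  if (!any(in_up) || !any(in_low)) { state$converged <- TRUE; return(state) }
  m_up <- max(v[in_up]); m_low <- min(v[in_low])
  if (m_up - m_low <= tol) { state$converged <- TRUE; return(state) }
  i <- which(in_up)[which.max(v[in_up])]
  i_low <- which(in_low)[which.min(v[in_low])]
  Ei <- f[i] - y[i]
  cand <- setdiff(which(in_low), i)
  if (!length(cand)) { state$converged <- TRUE; return(state) }
  diffs <- m_up - v[cand]
  viol <- cand[diffs > 0]
  j <- if (length(viol)) {
    eta_v <- diag(state$K)[i] + diag(state$K)[viol] - 2 * state$K[i, viol]
    eta_v[eta_v <= 0] <- 1e-12
    viol[which.max((m_up - v[viol])^2 / (2 * eta_v))]
  } else i_low
  pair_update <- function(state, i, j) {
    a <- state$alpha; f <- state$f; y <- state$y; C <- state$C
    Ej <- f[j] - y[j]
    if (y[i] != y[j]) {
      L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
    } else {
      L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
    }
    if (L >= H) return(NULL)
    eta <- state$K[i, i] + state$K[j, j] - 2 * state$K[i, j]
    aj <- if (eta > 0) min(max(a[j] + y[j] * (Ei - Ej) / eta, L), H)
          else if (y[j] * (Ei - Ej) > 0) H else L
    snap <- 1e-12 * C
    if (aj < snap) aj <- 0 else if (aj > C - snap) aj <- C
    ai <- a[i] + y[i] * y[j] * (a[j] - aj)
    if (ai < snap) ai <- 0 else if (ai > C - snap) ai <- C
    if (abs(ai - a[i]) <= snap && abs(aj - a[j]) <= snap) return(NULL)
    state$alpha[i] <- ai; state$alpha[j] <- aj
    state$f <- f + (ai - a[i]) * y[i] * state$K[i, ] +
      (aj - a[j]) * y[j] * state$K[j, ]
    state
  }
  upd <- pair_update(state, i, j)
  if (is.null(upd) && j != i_low) upd <- pair_update(state, i, i_low)
  if (!is.null(upd)) state <- upd
  state$converged <- FALSE
  state
}
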