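# shared fixtures, all generated in code; expensive objects are memoized
# so several test files can reuse one phantom realization

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a voxel_matrix over a trivial all-true 1D-grid mask, for classifier units
toy_matrix <- function(values, labels, scaled = TRUE) {
  values <- as.matrix(values)
  p <- ncol(values)
  mask <- structure(list(include = array(TRUE, c(p, 1L, 1L)),
                         n_voxels = as.integer(p),
                         source_threshold = 0.25, spacing = c(1, 1, 1)),
                    class = "brain_mask")
  fdgpattern:::voxel_matrix(values, paste0("s", seq_len(nrow(values))),
                            labels, mask, scaled = scaled)
}

# random strictly-positive two-group matrix
random_positive_matrix <- function(n = 20, p = 50, seed = 1,
                                   labels = NULL) {
  if (is.null(labels))
    labels <- rep(c("NL", "AD"), c(floor(n / 2), ceiling(n / 2)))
  set.seed(seed)
  toy_matrix(matrix(exp(rnorm(n * p, 0, 0.2)), n, p), labels)
}

# score training subjects by direct projection onto a model's pattern
prospective_score_on_centered <- function(model, dec) {
  as.numeric(dec$centered %*% model$pattern)
}

# the default 32^3 phantom at seed 1, shared across SSM/acceptance tests
default_phantom <- function() cached("phantom", {
  generate_cohort(cohort_spec(seed = 1))
})

phantom_vm <- function() cached("phantom_vm", {
  co <- default_phantom()
  mask <- compute_mask(co$volumes)
  proportional_scale(extract_matrix(co$volumes, mask, co$manifest$group))
})

phantom_truth <- function() {
  co <- default_phantom()
  vm <- phantom_vm()
  co$ground_truth$pattern_volume$data[which(vm$mask$include)]
}

phantom_decomp <- function() cached("phantom_decomp", {
  ssm_svd(log_double_center(phantom_vm()), k = 10)
})

# hand-built SSM decomposition with chosen subject-score structure
synthetic_decomp <- function(S, p = 120, seed = 99,
                             labels = rep(c("NL", "AD"), each = nrow(S) / 2)) {
  set.seed(seed)
  k <- ncol(S)
  P <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  centered <- S %*% t(P)
  mask <- structure(list(include = array(TRUE, c(p, 1L, 1L)),
                         n_voxels = as.integer(p),
                         source_threshold = 0.25, spacing = c(1, 1, 1)),
                    class = "brain_mask")
  structure(list(centered = centered, gmp = rep(0, p), mask = mask,
                 subject_ids = paste0("s", seq_len(nrow(S))),
                 labels = labels, pcs = P, subject_scores = S,
                 singular_values = sqrt(colSums(S^2)),
                 vaf = colSums(S^2) / sum(S^2)),
            class = "ssm_decomposition")
}

# brute-force Mann-Whitney AUC: concordant + half-tied pairs
pair_count_auc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

make_uniform_volume <- function(value, dims = c(4, 4, 4), spacing = 2,
                                id = "u") {
  brain_volume(array(value, dims), spacing = rep(spacing, 3),
               subject_id = id, modality = "synthetic")
}
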