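#' @useDynLib fdgpattern, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd cor rnorm runif lm pf pt qnorm t.test fft
#' @importFrom utils write.table read.delim head
NULL

GROUP_LEVELS <- c("NL", "AD", "stable-MCI", "prodromal-AD", "PDND",
                  "PD-MCI", "PDD", "DLB", "FTD", "VaD")

#' Construct a brain volume
#'
#' A `brain_volume` holds one subject's 3D tracer-uptake grid together with
#' its voxel spacing. Volumes are assumed to be already spatially normalized
#' to a common grid; no resampling is performed anywhere in the package.
#'
#' @param data Numeric 3D array of uptake values (arbitrary tracer units).
#' @param spacing Numeric vector of length 3, voxel edge lengths in mm.
#' @param subject_id Character scalar identifying the subject.
#' @param modality One of `"FDG-PET"`, `"perfusion-SPECT"`, `"synthetic"`.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, spacing = c(1, 1, 1),
                         subject_id = "unknown",
                         modality = c("FDG-PET", "perfusion-SPECT",
                                      "synthetic")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_fdg("invalid_volume", "'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop_fdg("invalid_volume", "all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_fdg("invalid_volume", "'spacing' must be 3 strictly positive values")
  if (any(!is.finite(data)))
    stop_fdg("nonfinite_data", "volume contains non-finite voxel values")
  structure(list(data = data, spacing = spacing, subject_id = subject_id,
                 modality = modality),
            class = "brain_volume")
}

# classed conditions so callers can distinguish failure modes
stop_fdg <- function(class, msg, call. = FALSE) {
  cond <- structure(class = c(paste0("fdgpattern_", class), "error",
                              "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

warn_fdg <- function(class, msg) {
  cond <- structure(class = c(paste0("fdgpattern_", class), "warning",
                              "condition"),
                    list(message = msg, call = NULL))
  warning(cond)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file into a [brain_volume]. 4D files with a
#' singleton fourth dimension are squeezed to 3D; any other extra
#' non-singleton dimension is rejected.
#'
#' @param path Path to a NIfTI file (optionally gzipped).
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param modality Image modality tag.
#' @return A [brain_volume].
#' @export
read_volume <- function(path, subject_id = NULL,
                        modality = c("FDG-PET", "perfusion-SPECT",
                                     "synthetic")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop_fdg("missing_file", paste0("file not found: ", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_fdg("not_nifti",
                             paste0("cannot read as NIfTI: ", path, " (",
                                    conditionMessage(e), ")")))
  dat <- as.array(img)
  dims <- dim(dat)
  if (length(dims) > 3L) {
    extra <- dims[-(1:3)]
    if (any(extra != 1L))
      stop_fdg("too_many_dims",
               paste0("volume has >3 non-singleton dimensions: ",
                      paste(dims, collapse = "x")))
    dat <- array(dat, dims[1:3])
  }
  if (length(dim(dat)) < 3L) dat <- array(dat, c(dim(dat), rep(1L, 3 - length(dim(dat)))))
  if (any(!is.finite(dat)))
    stop_fdg("nonfinite_data",
             paste0("volume contains non-finite voxels: ", path))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  brain_volume(array(as.numeric(dat), dim(dat)), spacing = sp,
               subject_id = subject_id, modality = modality)
}

#' Write a brain volume as NIfTI
#'
#' Data are stored at 64-bit float precision so that a write/read round trip
#' is bit-exact.
#'
#' @param volume A [brain_volume] (or plain 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing, used when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (inherits(volume, "brain_volume")) {
    dat <- volume$data
    spacing <- volume$spacing
  } else dat <- volume
  x <- dat
  RNifti::pixdim(x) <- spacing
  RNifti::writeNifti(x, path, datatype = "double")
  invisible(path)
}

#' Compute the whole-brain analysis mask
#'
#' The mean image over the supplied volumes is thresholded at a fraction of
#' its maximum: voxel v is included iff `mean(v) >= rel_threshold * max(mean)`.
#' The default fraction is 0.25 (relative thresholding at 25% of maximum).
#' Using the group-mean image (rather than per-scan maxima) makes the mask
#' deterministic and robust to single-scan artifacts.
#'
#' @param volumes List of [brain_volume]s on a common grid.
#' @param rel_threshold Fraction of the mean image's maximum, in (0, 1).
#' @return An object of class `brain_mask` with fields `include` (logical 3D
#'   array), `n_voxels`, `source_threshold`, `spacing`.
#' @export
compute_mask <- function(volumes, rel_threshold = 0.25) {
  if (length(volumes) < 1L)
    stop_fdg("empty_input", "need at least one volume to build a mask")
  if (!(rel_threshold > 0 && rel_threshold < 1))
    stop_fdg("bad_threshold", "'rel_threshold' must lie strictly in (0, 1)")
  dims <- dim(volumes[[1]]$data)
  acc <- array(0, dims)
  for (v in volumes) {
    if (!identical(dim(v$data), dims))
      stop_fdg("shape_mismatch", "volumes have differing grid shapes")
    acc <- acc + v$data
  }
  meanimg <- acc / length(volumes)
  cutoff <- rel_threshold * max(meanimg)
  include <- meanimg >= cutoff
  n <- sum(include)
  if (n < 1L)
    stop_fdg("empty_mask", "mask contains zero voxels")
  structure(list(include = include, n_voxels = as.integer(n),
                 source_threshold = rel_threshold,
                 spacing = volumes[[1]]$spacing),
            class = "brain_mask")
}

mask_checksum <- function(mask) {
  idx <- which(mask$include)
  # cheap order-sensitive hash of the voxel index set + shape
  s <- sum(idx * (seq_along(idx) %% 97 + 1)) %% 2147483647
  paste0(paste(dim(mask$include), collapse = "x"), ":", mask$n_voxels, ":", s)
}

#' Vectorize a cohort into a subjects-by-voxels matrix
#'
#' In-mask voxels are laid out in column-major (Fortran) grid order, i.e.
#' `which(mask$include)` order; this fixed order makes pattern vectors
#' portable across runs and is shared by [insert_matrix()].
#'
#' @param volumes List of [brain_volume]s.
#' @param mask A `brain_mask` with the same grid shape.
#' @param labels Character vector of group labels aligned with `volumes`.
#' @return An object of class `voxel_matrix`: `values` (n_subjects x
#'   n_voxels), `subject_ids`, `labels`, `mask`, `scaled` flag.
#' @export
extract_matrix <- function(volumes, mask, labels) {
  if (!inherits(mask, "brain_mask"))
    stop_fdg("bad_mask", "'mask' must be a brain_mask")
  if (length(labels) != length(volumes))
    stop_fdg("label_mismatch", "one label per volume is required")
  idx <- which(mask$include)
  if (length(idx) < 1L) stop_fdg("empty_mask", "mask contains zero voxels")
  n <- length(volumes)
  values <- matrix(NA_real_, n, length(idx))
  ids <- character(n)
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    if (!identical(dim(v$data), dim(mask$include)))
      stop_fdg("shape_mismatch", "volume grid does not match mask grid")
    values[i, ] <- v$data[idx]
    ids[i] <- v$subject_id
  }
  voxel_matrix(values, ids, as.character(labels), mask, scaled = FALSE)
}

voxel_matrix <- function(values, subject_ids, labels, mask, scaled = FALSE) {
  stopifnot(nrow(values) == length(subject_ids),
            nrow(values) == length(labels),
            ncol(values) == mask$n_voxels)
  structure(list(values = values, subject_ids = subject_ids,
                 labels = labels, mask = mask, scaled = scaled),
            class = "voxel_matrix")
}

#' Proportionally scale each subject to its in-mask mean
#'
#' Divides every row by its own mean over mask voxels, so that each scaled
#' scan has in-mask mean 1. This removes global tracer-dose/uptake
#' differences before pattern learning. Applying it twice is a no-op.
#'
#' @param matrix A `voxel_matrix` with `scaled = FALSE`.
#' @return The scaled `voxel_matrix` (`scaled = TRUE`).
#' @export
proportional_scale <- function(matrix) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  if (isTRUE(matrix$scaled)) return(matrix)
  m <- rowMeans(matrix$values)
  if (any(m <= 0))
    stop_fdg("degenerate_scan",
             paste0("non-positive in-mask mean for subject(s): ",
                    paste(matrix$subject_ids[m <= 0], collapse = ", ")))
  matrix$values <- matrix$values / m
  matrix$scaled <- TRUE
  matrix
}

#' Restore a voxel vector into a full 3D volume
#'
#' Inverse of the vectorization in [extract_matrix()]: in-mask voxels are
#' written back in the fixed column-major order, out-of-mask voxels are 0.
#'
#' @param row Numeric vector of length `mask$n_voxels`.
#' @param mask A `brain_mask`.
#' @param subject_id Identifier for the resulting volume.
#' @return A [brain_volume].
#' @export
insert_matrix <- function(row, mask, subject_id = "pattern") {
  if (length(row) != mask$n_voxels)
    stop_fdg("length_mismatch",
             paste0("row has ", length(row), " values but mask has ",
                    mask$n_voxels, " voxels"))
  out <- array(0, dim(mask$include))
  out[which(mask$include)] <- row
  brain_volume(out, spacing = mask$spacing, subject_id = subject_id,
               modality = "synthetic")
}

#' Read a cohort manifest
#'
#' Tab-separated manifest with columns `subject_id`, `path`, `group` and
#' optional `age`, `sex`, `apoe4`. Paths are resolved relative to the
#' manifest's directory when not absolute.
#'
#' @param path Manifest TSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_fdg("missing_file", paste0("manifest not found: ", path))
  man <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(man)))
    stop_fdg("bad_manifest",
             paste0("manifest must have columns: ",
                    paste(need, collapse = ", ")))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Load the volumes listed in a manifest
#'
#' @param manifest Data frame from [read_manifest()].
#' @param modality Modality tag passed to [read_volume()].
#' @return List of [brain_volume]s.
#' @export
load_cohort <- function(manifest, modality = "synthetic") {
  lapply(seq_len(nrow(manifest)), function(i)
    read_volume(manifest$path[i], subject_id = manifest$subject_id[i],
                modality = modality))
}

#' Write a mask as a 0/1 NIfTI
#' @param mask A `brain_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_volume(array(as.numeric(mask$include), dim(mask$include)), path,
               spacing = mask$spacing)
}

#' Read a 0/1 NIfTI as a mask
#' @param path NIfTI path.
#' @return A `brain_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path, modality = "synthetic")
  include <- v$data > 0.5
  n <- sum(include)
  if (n < 1L) stop_fdg("empty_mask", "mask file contains zero voxels")
  structure(list(include = include, n_voxels = as.integer(n),
                 source_threshold = NA_real_, spacing = v$spacing),
            class = "brain_mask")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<brain_volume> ", x$subject_id, " [", paste(dim(x$data), collapse = "x"),
      "] spacing ", paste(x$spacing, collapse = "x"), " mm, ", x$modality,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", paste(dim(x$include), collapse = "x"), " grid, ",
      x$n_voxels, " voxels (threshold ",
      format(x$source_threshold), ")\n", sep = "")
  invisible(x)
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat("<voxel_matrix> ", nrow(x$values), " subjects x ", ncol(x$values),
      " voxels, groups: ", paste(unique(x$labels), collapse = "/"),
      if (x$scaled) ", proportionally scaled" else ", unscaled",
      "\n", sep = "")
  invisible(x)
}
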