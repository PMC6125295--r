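#' Write a pattern model to disk
#'
#' The model is stored as a NIfTI pattern map plus a JSON sidecar (method,
#' bias, normalization reference, threshold, mask checksum and
#' method-specific extras). The mask is written alongside as a 0/1 NIfTI;
#' SSM models also get a companion NIfTI holding the group mean profile.
#'
#' @param model A `pattern_model`.
#' @param dir Output directory (created if needed).
#' @param name File stem (default: the method name, lower case).
#' @return The sidecar path, invisibly.
#' @export
write_model <- function(model, dir, name = tolower(model$method)) {
  stopifnot(inherits(model, "pattern_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(insert_matrix(model$pattern, model$mask,
                             subject_id = paste0(name, "-pattern")),
               file.path(dir, paste0(name, "_pattern.nii.gz")))
  write_mask(model$mask, file.path(dir, paste0(name, "_mask.nii.gz")))
  extras <- model$extras
  if (!is.null(extras$gmp)) {
    write_volume(insert_matrix(extras$gmp, model$mask,
                               subject_id = paste0(name, "-gmp")),
                 file.path(dir, paste0(name, "_gmp.nii.gz")))
    extras$gmp <- paste0(name, "_gmp.nii.gz")
  }
  side <- list(method = model$method, bias = model$bias,
               ref_mean = model$ref_mean, ref_sd = model$ref_sd,
               z_threshold = model$z_threshold,
               positive_class = model$positive_class,
               mask_checksum = model$mask_checksum,
               pattern_file = paste0(name, "_pattern.nii.gz"),
               mask_file = paste0(name, "_mask.nii.gz"),
               extras = extras)
  path <- file.path(dir, paste0(name, "_model.json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pattern model written by [write_model()]
#'
#' @param sidecar Path to the `*_model.json` sidecar.
#' @return A `pattern_model`.
#' @export
read_model <- function(sidecar) {
  if (!file.exists(sidecar))
    stop_fdg("missing_file", paste0("model sidecar not found: ", sidecar))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  mask <- read_mask(file.path(dir, side$mask_file))
  pat_vol <- read_volume(file.path(dir, side$pattern_file),
                         modality = "synthetic")
  pattern <- pat_vol$data[which(mask$include)]
  extras <- side$extras
  if (!is.null(extras$gmp) && is.character(extras$gmp)) {
    gmp_vol <- read_volume(file.path(dir, extras$gmp),
                           modality = "synthetic")
    extras$gmp <- gmp_vol$data[which(mask$include)]
  }
  model <- pattern_model(side$method, pattern, side$bias, mask,
                         ref_mean = side$ref_mean, ref_sd = side$ref_sd,
                         z_threshold = side$z_threshold,
                         positive_class = side$positive_class,
                         extras = as.list(extras))
  if (!identical(model$mask_checksum, side$mask_checksum))
    warn_fdg("mask_checksum",
             "stored mask checksum differs from the reloaded mask")
  model
}
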