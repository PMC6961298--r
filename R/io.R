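# NIfTI-1 and CSV I/O for the pipeline. Volumes, masks and parameter maps
# travel as NIfTI; b-values as FSL-style .bval text; tables as CSV.

#' Write / read a volume as NIfTI-1
#'
#' @param arr 3-D or 4-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixdim Voxel dimensions (mm), length 3.
#' @param datatype NIfTI storage type (`"float"` for parameter maps,
#'   `"int16"` for status/mask volumes).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(arr, path, pixdim = c(2.969, 2.969, 5.5),
                            datatype = "float") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixdim, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attr(arr, "pixdim") <- RNifti::pixdim(arr)
  arr
}

#' Write a simulated cohort to disk
#'
#' One directory per patient holding the 4-D DWI volume and the tumor
#' mask as NIfTI, plus a shared `.bval` file, the true-parameter and
#' covariate tables as CSV, and a JSON manifest recording the generating
#' configuration and seed.
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bval(cohort$config$scheme, file.path(dir, "protocol.bval"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  for (pt in cohort$patients) {
    pdir <- file.path(dir, pt$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    write_nifti_map(pt$volume, file.path(pdir, "dwi.nii.gz"))
    write_nifti_map(pt$mask, file.path(pdir, "mask.nii.gz"),
                    datatype = "int16")
  }
  manifest <- list(package = "dwiresponse",
                   model = cohort$model,
                   n_patients = length(cohort$patients),
                   config = cohort$config[c("n_responders", "n_nonresponders",
                                            "snr_b0", "voxels_per_patient",
                                            "s0", "voxel_cv", "seed")],
                   b_values = cohort$config$scheme$b_values,
                   nex = cohort$config$scheme$nex)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Fit parameter maps for one patient from files
#'
#' File-level wrapper over [fit_volume()]: reads a 4-D DWI NIfTI, a
#' `.bval` file and a mask NIfTI, fits the requested models voxelwise and
#' writes one float32 NIfTI per parameter map (same grid as the input)
#' plus an integer-coded fit-status map.
#'
#' @param dwi_path,bval_path,mask_path Input files.
#' @param out_dir Output directory for the maps.
#' @param models,nex Passed to [fit_volume()] / [read_bval()].
#' @return Invisibly, the list returned by [fit_volume()].
#' @export
fit_volume_files <- function(dwi_path, bval_path, mask_path, out_dir,
                             models = c("mono", "ivim", "sem"), nex = NULL) {
  for (p in c(dwi_path, bval_path, mask_path))
    if (!file.exists(p)) stopf("input file not found: %s", p)
  dwi <- as.array(RNifti::readNifti(dwi_path))
  pix <- RNifti::pixdim(dwi)[1:3]
  mask <- as.array(RNifti::readNifti(mask_path))
  scheme <- read_bval(bval_path, nex)
  res <- fit_volume(dwi, mask, scheme, models)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(res$maps), "status"))
    write_nifti_map(res$maps[[nm]], file.path(out_dir,
                                              paste0(nm, ".nii.gz")), pix)
  status <- res$maps$status
  status[is.na(status)] <- -1L
  write_nifti_map(status, file.path(out_dir, "status.nii.gz"), pix,
                  datatype = "int16")
  invisible(res)
}
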