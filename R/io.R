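#' Write a count image as NIfTI-1 with a JSON truth sidecar
#'
#' The voxel grid goes to `<prefix>.nii.gz`; acquisition metadata and the
#' ground-truth sidecar (when present) go to `<prefix>.json`, so simulated
#' images can be exchanged between analysis stages like reconstructed
#' scanner exports.
#'
#' @param image A [count_image].
#' @param prefix Output path prefix (directories must exist).
#' @return The NIfTI path, invisibly.
#' @export
write_count_image <- function(image, prefix) {
  stopifnot(inherits(image, "count_image"))
  nii <- RNifti::asNifti(image$counts)
  RNifti::pixdim(nii) <- rep(image$voxel_size, 3)
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, path)
  truth <- image$truth
  sidecar <- list(
    voxel_size = image$voxel_size,
    duration_s = image$duration_s,
    origin = c(image$xs[1], image$ys[1], image$zs[1]),
    nuclide = unclass(image$nuclide),
    truth = if (!is.null(truth)) list(
      activities_MBq = as.list(truth$activities_MBq),
      icf_true = truth$icf_true,
      seed = truth$seed,
      system = if (!is.null(truth$system)) unclass(truth$system),
      layout = if (!is.null(truth$layout)) list(
        positions = truth$layout$positions,
        jaszczak_diameter = truth$layout$jaszczak_diameter,
        jaszczak_height = truth$layout$jaszczak_height,
        wall_margin = truth$layout$wall_margin)))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a count image written by [write_count_image()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [count_image]. The truth sidecar is restored as plain lists.
#' @export
read_count_image <- function(prefix) {
  nii <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  counts <- array(as.vector(nii), dim = dim(nii))
  vox <- meta$voxel_size
  d <- dim(counts)
  org <- meta$origin
  nuc <- radionuclide_spec(meta$nuclide$name, meta$nuclide$half_life_s,
                           meta$nuclide$photopeak_keV,
                           meta$nuclide$emission_probability,
                           meta$nuclide$emission_probability_u)
  truth <- meta$truth
  if (!is.null(truth) && !is.null(truth$activities_MBq))
    truth$activities_MBq <- unlist(truth$activities_MBq)
  structure(
    list(counts = counts, voxel_size = vox,
         xs = org[1] + (seq_len(d[1]) - 1) * vox,
         ys = org[2] + (seq_len(d[2]) - 1) * vox,
         zs = org[3] + (seq_len(d[3]) - 1) * vox,
         duration_s = meta$duration_s, nuclide = nuc, truth = truth),
    class = "count_image")
}

#' Write a VOI mask as NIfTI-1 (0/1 voxels)
#'
#' @param voi A [voi_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_voi_mask <- function(voi, path, voxel_size = voi$voxel_size) {
  stopifnot(inherits(voi, "voi_mask"))
  nii <- RNifti::asNifti(array(as.integer(voi$mask), dim = dim(voi$mask)))
  RNifti::pixdim(nii) <- rep(voxel_size, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
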