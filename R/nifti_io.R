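## Thin NIfTI I/O wrappers (RNifti) so every map and series produced by the
## pipeline can be exchanged with standard neuroimaging tools.

#' Write an array as NIfTI
#'
#' @param x 3D or 4D numeric array (e.g. a map, fraction stack, or series).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel dimensions in mm (3rd value is slice thickness).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_mm = c(1, 1, 2)) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep_len(voxel_mm, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array with a `voxel_mm` attribute.
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write per-subject regional volumes as CSV
#'
#' @param volumes Data frame as produced by the pipeline (`region`,
#'   `volume`, `volume_no_lesions`, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(volumes, path) {
  utils::write.csv(volumes, path, row.names = FALSE)
  invisible(path)
}
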