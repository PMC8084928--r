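## NIfTI and JSON I/O. Complex volumes travel as paired `_real`/`_imag`
## NIfTI files; ground truth / model metadata as JSON sidecars.

#' Write a real-valued 3D volume as NIfTI
#'
#' @param vol 3D numeric array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file.
#' @return 3D array with a `spacing` attribute (mm).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)[1:min(3, length(dim(img)))]
  out
}

#' Write a complex volume as paired real/imaginary NIfTI files
#'
#' @param vol complex array.
#' @param prefix path prefix; files `<prefix>_real.nii.gz` and
#'   `<prefix>_imag.nii.gz` are written.
#' @param spacing voxel spacing mm.
#' @return character vector of the two paths, invisibly.
#' @export
write_complex_nifti <- function(vol, prefix, spacing = c(1, 1, 1)) {
  pr <- paste0(prefix, "_real.nii.gz")
  pi_ <- paste0(prefix, "_imag.nii.gz")
  write_nifti_volume(array(Re(vol), dim(vol)), pr, spacing)
  write_nifti_volume(array(Im(vol), dim(vol)), pi_, spacing)
  invisible(c(pr, pi_))
}

#' Read a complex volume written by [write_complex_nifti()]
#'
#' @param prefix path prefix used at write time.
#' @return complex array.
#' @export
read_complex_nifti <- function(prefix) {
  re <- read_nifti_volume(paste0(prefix, "_real.nii.gz"))
  im <- read_nifti_volume(paste0(prefix, "_imag.nii.gz"))
  out <- array(complex(real = as.vector(re), imaginary = as.vector(im)), dim(re))
  attr(out, "spacing") <- attr(re, "spacing")
  out
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
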