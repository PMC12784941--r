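# Thin format helpers: NIfTI volumes via RNifti, tab-separated tables via
# readr. The analysis functions themselves work on in-memory arrays and
# tibbles; these helpers connect them to on-disk data.

require_pkg <- function(pkg, what) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop_thalcon("package '%s' is required to %s", pkg, what)
}

#' Read / write a volume as NIfTI
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol 3-D or 4-D numeric array.
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `read_volume_nifti()` returns a plain numeric array;
#'   `write_volume_nifti()` returns `path` invisibly.
#' @export
read_volume_nifti <- function(path) {
  require_pkg("RNifti", "read NIfTI volumes")
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = 0.5) {
  require_pkg("RNifti", "write NIfTI volumes")
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_mm, min(length(dim(vol)), 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a motion-parameter table
#'
#' One row per volume, six tab-separated columns
#' (`tx`, `ty`, `tz` in mm; `rx`, `ry`, `rz` in radians).
#'
#' @param motion Motion data frame.
#' @param path File path.
#' @return `read_motion_tsv()` returns a tibble with the six motion
#'   columns.
#' @export
read_motion_tsv <- function(path) {
  require_pkg("readr", "read TSV files")
  m <- readr::read_tsv(path, show_col_types = FALSE)
  as_motion_matrix(m)  # validates
  as_tibble(m)[MOTION_COLS]
}

#' @rdname read_motion_tsv
#' @export
write_motion_tsv <- function(motion, path) {
  require_pkg("readr", "write TSV files")
  readr::write_tsv(as_tibble(as.data.frame(as_motion_matrix(motion))), path)
  invisible(path)
}
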