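# Lesion-artifact voxel exclusion: focal lesions and lesion-related
# artifacts (microbleeds, CSF expansion) distort the mean fMRI signal, so
# voxels whose globally-normalized mean intensity changed too much from
# baseline are excluded, and ROIs losing too many voxels are omitted.

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop_thalcon("%s are on different grids: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
}

#' Voxel-wise mean volume of a 4-D series
#'
#' @param series_4d 4-D numeric array (x, y, z, time) with at least one
#'   volume.
#' @return 3-D array of per-voxel means over time.
#' @export
mean_volume <- function(series_4d) {
  d <- dim(series_4d)
  if (is.null(d) || length(d) != 4L || d[4] < 1L)
    stop_thalcon("`series_4d` must be a 4-D array with at least one volume")
  rowMeans(series_4d, dims = 3L)
}

#' Normalize a volume for global intensity changes
#'
#' Divides intensities by the mean intensity inside the brain mask, so the
#' normalized in-mask mean is exactly 1. This removes scanner-gain and other
#' global scale differences between sessions before intensities are
#' compared.
#'
#' @param vol 3-D intensity array.
#' @param brain_mask Logical array on the same grid; must select at least
#'   one voxel and have positive in-mask mean intensity.
#' @return Normalized 3-D array.
#' @export
global_normalize <- function(vol, brain_mask) {
  check_same_grid(vol, brain_mask, "volume and mask")
  if (!any(brain_mask)) stop_thalcon("brain mask is empty")
  m <- mean(vol[brain_mask])
  if (!is.finite(m) || m <= 0)
    stop_thalcon("in-mask mean intensity must be positive, got %g", m)
  vol / m
}

#' Grand mean baseline intensity across a cohort
#'
#' The reference unit for the exclusion threshold: the in-mask mean of the
#' globally-normalized baseline volumes, averaged across all animals.
#' (After [global_normalize()] each scan's in-mask mean is 1, so this is 1
#' by construction; the function exists so the threshold's provenance is
#' explicit and so un-normalized inputs are handled consistently.)
#'
#' @param baseline_vols List of normalized baseline 3-D arrays.
#' @param brain_mask Logical array shared by all volumes.
#' @return Scalar grand mean.
#' @export
grand_baseline_mean <- function(baseline_vols, brain_mask) {
  if (length(baseline_vols) == 0) stop_thalcon("no baseline volumes supplied")
  mean(vapply(baseline_vols, function(v) {
    check_same_grid(v, brain_mask, "volume and mask")
    mean(v[brain_mask])
  }, numeric(1)))
}

#' Voxel exclusion mask from baseline-to-followup intensity change
#'
#' A voxel is excluded when the absolute difference between its normalized
#' followup and baseline mean intensities exceeds (strictly)
#' `factor` times the cohort grand-mean baseline intensity. A difference of
#' exactly `factor * grand_baseline_mean` is therefore retained.
#'
#' @param post_norm,base_norm Globally-normalized mean volumes on the same
#'   grid (followup and baseline).
#' @param grand_baseline_mean Scalar reference intensity (see
#'   [grand_baseline_mean()]); must be positive.
#' @param factor Threshold multiplier (default 2.5).
#' @return Logical 3-D array of excluded voxels.
#' @export
exclusion_mask <- function(post_norm, base_norm, grand_baseline_mean, factor = 2.5) {
  check_same_grid(post_norm, base_norm)
  if (!is.finite(grand_baseline_mean) || grand_baseline_mean <= 0)
    stop_thalcon("grand_baseline_mean must be positive, got %g", grand_baseline_mean)
  abs(post_norm - base_norm) > factor * grand_baseline_mean
}

#' Per-ROI validity under the excluded-voxel fraction rule
#'
#' An ROI is omitted from analysis when strictly more than `max_fraction`
#' (default 30%) of its voxels are excluded; an ROI with exactly 30%
#' excluded voxels is retained.
#'
#' @param excluded Logical 3-D array from [exclusion_mask()].
#' @param roi_masks Named list of logical arrays on the same grid, each
#'   non-empty.
#' @param max_fraction Maximum tolerated excluded fraction (default 0.30).
#' @return Tibble with one row per ROI: `roi`, `n_voxels`, `n_excluded`,
#'   `excluded_fraction`, `valid`.
#' @export
roi_validity <- function(excluded, roi_masks, max_fraction = 0.30) {
  stopifnot(is.list(roi_masks), length(roi_masks) > 0)
  rois <- names(roi_masks) %||% paste0("roi", seq_along(roi_masks))
  rows <- purrr::imap(roi_masks, function(mask, nm) {
    check_same_grid(excluded, mask, "exclusion mask and ROI mask")
    n <- sum(mask)
    if (n == 0) stop_thalcon("ROI '%s' is empty", nm)
    ne <- sum(excluded & mask)
    tibble(roi = nm, n_voxels = n, n_excluded = ne,
           excluded_fraction = ne / n)
  })
  out <- list_rbind(rows)
  out$roi <- rois
  mutate(out, valid = .data$excluded_fraction <= max_fraction)
}

#' ROI mean time series from a 4-D scan
#'
#' Averages the signal over each ROI's voxels at every volume. Voxels
#' flagged by the exclusion mask are dropped from the average of retained
#' ROIs, so lesion-artifact voxels never contribute to connectivity.
#'
#' @param series_4d 4-D array (x, y, z, time).
#' @param roi_masks Named list of logical 3-D arrays.
#' @param excluded Optional logical 3-D array of voxels to drop.
#' @return Tibble with `volume` plus one column per ROI. An ROI whose
#'   voxels are all excluded yields a column of `NA`.
#' @export
roi_mean_timeseries <- function(series_4d, roi_masks, excluded = NULL) {
  d <- dim(series_4d)
  if (length(d) != 4L) stop_thalcon("`series_4d` must be 4-D")
  nt <- d[4]
  mat <- matrix(series_4d, ncol = nt)  # voxels x time
  cols <- purrr::imap(roi_masks, function(mask, nm) {
    if (!identical(dim(mask), d[1:3]))
      stop_thalcon("ROI '%s' mask grid does not match the series", nm)
    use <- as.logical(mask)
    if (!is.null(excluded)) use <- use & !as.logical(excluded)
    if (!any(use)) return(rep(NA_real_, nt))
    colMeans(mat[use, , drop = FALSE])
  })
  dplyr::bind_cols(tibble(volume = seq_len(nt)), as_tibble(cols))
}
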