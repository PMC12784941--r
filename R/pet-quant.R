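# TSPO-PET quantification: duration-weighted summation of dynamic frames
# over a 15-60 min post-injection interval, normalization to total
# rostro-thoracic uptake, and per-ROI uptake (U, %/ml) extraction.

#' Construct a dynamic PET acquisition
#'
#' @param frames List of 3-D activity-concentration arrays (activity per
#'   ml), one per time frame, all on the same grid.
#' @param start_min,end_min Numeric vectors of frame start/end times in
#'   minutes post-injection; frames must be time-ordered and
#'   non-overlapping.
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @return Object of class `dynamic_pet`.
#' @export
dynamic_pet <- function(frames, start_min, end_min, voxel_volume_ml) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (length(start_min) != length(frames) || length(end_min) != length(frames))
    stop_thalcon("frame timing vectors must match the number of frames")
  if (any(end_min <= start_min))
    stop_thalcon("every frame must have end_min > start_min")
  if (any(diff(start_min) < 0) || any(start_min[-1] < end_min[-length(end_min)] - 1e-9))
    stop_thalcon("frames must be time-ordered and non-overlapping")
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    check_same_grid(frames[[i]], frames[[1]], "PET frames")
    if (any(frames[[i]] < 0)) stop_thalcon("negative activity in frame %d", i)
  }
  structure(list(frames = frames, start_min = start_min, end_min = end_min,
                 voxel_volume_ml = voxel_volume_ml, dim = d),
            class = "dynamic_pet")
}

#' @export
print.dynamic_pet <- function(x, ...) {
  cat(sprintf("<dynamic_pet: %d frames, %s grid, %.0f-%.0f min>\n",
              length(x$frames), paste(x$dim, collapse = "x"),
              min(x$start_min), max(x$end_min)))
  invisible(x)
}

#' Duration-weighted frame summation
#'
#' Sums frame activity concentrations over the quantification interval
#' (default 15-60 min post-injection), weighting each frame by the duration
#' of its overlap with the interval, so partially-overlapping edge frames
#' contribute proportionally and frames outside contribute nothing.
#'
#' @param pet A [dynamic_pet()].
#' @param t_start,t_end Interval bounds in minutes (defaults 15 and 60).
#' @return 3-D array of summed activity (concentration x minutes).
#' @export
sum_frames <- function(pet, t_start = 15, t_end = 60) {
  stopifnot(inherits(pet, "dynamic_pet"))
  overlap <- pmax(0, pmin(pet$end_min, t_end) - pmax(pet$start_min, t_start))
  if (all(overlap <= 0))
    stop_thalcon("no PET frame overlaps [%g, %g] min", t_start, t_end)
  out <- array(0, dim = pet$dim)
  for (i in seq_along(pet$frames)) {
    if (overlap[i] > 0) out <- out + pet$frames[[i]] * overlap[i]
  }
  out
}

#' Normalize uptake to the rostro-thoracic total
#'
#' Expresses each voxel's summed activity as a percentage of the total
#' activity inside the body mask per ml (U, %/ml):
#' `U(v) = 100 * a(v) / sum(a * voxel_volume_ml over mask)`. By
#' construction the integral of U over the body mask equals 100, and U is
#' invariant to global activity rescaling (injected dose).
#'
#' @param summed 3-D array from [sum_frames()].
#' @param body_mask Logical array marking the rostro-thoracic field of view.
#' @param voxel_volume_ml Voxel volume in ml.
#' @return List with `u` (3-D array of U values, %/ml) and
#'   `total_activity` (the normalizing integral).
#' @export
normalize_uptake <- function(summed, body_mask, voxel_volume_ml) {
  check_same_grid(summed, body_mask, "summed volume and body mask")
  if (!any(body_mask)) stop_thalcon("body mask is empty")
  total <- sum(summed[body_mask]) * voxel_volume_ml
  if (total <= 0) stop_thalcon("total in-mask activity must be positive")
  list(u = 100 * summed / total, total_activity = total)
}

#' Per-ROI normalized uptake
#'
#' Mean of the normalized uptake U over each ROI's voxels.
#'
#' @param u 3-D array of U values (see [normalize_uptake()]).
#' @param roi_masks Named list of non-empty logical arrays.
#' @return Tibble with columns `roi` and `u_feppa` (%/ml).
#' @export
roi_uptake <- function(u, roi_masks) {
  rows <- purrr::imap(roi_masks, function(mask, nm) {
    check_same_grid(u, mask, "uptake volume and ROI mask")
    if (!any(mask)) stop_thalcon("ROI '%s' is empty", nm)
    tibble(roi = nm, u_feppa = mean(u[mask]))
  })
  list_rbind(rows)
}

#' Injection quality check on the whole-mask time-activity curve
#'
#' A successful tail-vein injection shows a monotone rise of the whole-body
#' activity over the first minutes as the tracer distributes; a faulty
#' (paravenous) injection produces an early spike followed by a drop. The
#' scan is flagged faulty when the whole-mask mean activity drops by more
#' than `drop_tolerance` (relative) between consecutive frames within the
#' first `window_min` minutes.
#'
#' @param pet A [dynamic_pet()].
#' @param body_mask Logical array.
#' @param window_min Early window checked for a monotone rise (default 5).
#' @param drop_tolerance Relative drop tolerated between consecutive early
#'   frames (default 0.05).
#' @return One-row tibble: `faulty_injection` (logical), `max_relative_drop`.
#' @export
pet_injection_qc <- function(pet, body_mask, window_min = 5, drop_tolerance = 0.05) {
  stopifnot(inherits(pet, "dynamic_pet"))
  early <- which(pet$start_min < window_min)
  tac <- vapply(pet$frames[early], function(f) mean(f[body_mask]), numeric(1))
  if (length(tac) < 2)
    return(tibble(faulty_injection = FALSE, max_relative_drop = 0))
  rel_drop <- -diff(tac) / pmax(tac[-length(tac)], .Machine$double.eps)
  mx <- max(rel_drop)
  tibble(faulty_injection = mx > drop_tolerance, max_relative_drop = max(mx, 0))
}
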