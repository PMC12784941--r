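# Motion-aware functional-connectivity stage: framewise displacement,
# least-motion segment selection, ICA scan-discard accounting, motion
# regression, and ROI-pair Pearson / Fisher-z connectivity.

MOTION_COLS <- c("tx", "ty", "tz", "rx", "ry", "rz")

as_motion_matrix <- function(motion) {
  if (is.matrix(motion)) {
    if (ncol(motion) != 6L)
      stop_thalcon("motion matrix must have 6 columns (tx, ty, tz, rx, ry, rz), got %d",
                   ncol(motion))
    m <- motion
    colnames(m) <- MOTION_COLS
    return(m)
  }
  if (!is.data.frame(motion))
    stop_thalcon("`motion` must be a data frame or 6-column matrix")
  missing <- setdiff(MOTION_COLS, names(motion))
  if (length(missing) > 0)
    stop_thalcon("`motion` is missing columns: %s", paste(missing, collapse = ", "))
  as.matrix(motion[MOTION_COLS])
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Summarises per-volume head motion as a single displacement in mm,
#' Power-style: the sum of absolute backward differences of the three
#' translations plus the rotation differences converted to arc length on a
#' sphere of radius `rotation_radius_mm` (default 5 mm, a rat-brain scale).
#' The first volume has no predecessor and is assigned 0.
#'
#' @param motion Data frame (or 6-column matrix) with per-volume rigid-body
#'   parameters: translations `tx`, `ty`, `tz` in mm and rotations `rx`,
#'   `ry`, `rz` in radians; one row per volume.
#' @param rotation_radius_mm Radius (mm) used to convert rotation angles to
#'   displacements.
#' @return A tibble of class `fd_trace` with columns `volume` (1-based) and
#'   `fd` (mm), carrying attributes `mean_fd`, `max_fd` and
#'   `rotation_radius_mm`. Use [glance()] for the scalar summaries.
#' @export
#' @examples
#' m <- tibble::tibble(tx = c(0, 0.1, 0.1), ty = 0, tz = 0,
#'                     rx = 0, ry = 0, rz = 0)
#' framewise_displacement(m)
framewise_displacement <- function(motion, rotation_radius_mm = 5) {
  m <- as_motion_matrix(motion)
  if (nrow(m) < 2L)
    stop_thalcon("need at least 2 volumes to compute framewise displacement")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_thalcon("non-finite motion parameter at volume %d (column %s)",
                 bad[1, 1], MOTION_COLS[bad[1, 2]])
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble(volume = seq_len(nrow(m)), fd = fd)
  structure(out,
            class = c("fd_trace", class(out)),
            mean_fd = mean(fd), max_fd = max(fd),
            rotation_radius_mm = rotation_radius_mm)
}

#' @method glance fd_trace
#' @export
glance.fd_trace <- function(x, ...) {
  tibble(n_volumes = nrow(x),
         mean_fd = attr(x, "mean_fd"),
         max_fd = attr(x, "max_fd"),
         rotation_radius_mm = attr(x, "rotation_radius_mm"))
}

#' Select the contiguous segment with the least motion
#'
#' Finds the `window_length`-volume contiguous window minimising mean
#' framewise displacement, considering only windows that start after the
#' first `exclude_first` volumes (the initial acquisition period is dropped
#' to avoid lingering anesthesia effects). Ties are broken by the earliest
#' start. Volumes are indexed 1-based, so with the defaults the earliest
#' admissible window is volumes 301..600.
#'
#' @param fd An `fd_trace` from [framewise_displacement()], or a data frame
#'   with columns `volume` and `fd`.
#' @param window_length Number of volumes in the analysis window (default
#'   300, i.e. 5 min at TR = 1 s).
#' @param exclude_first Number of initial volumes excluded from selection
#'   (default 300).
#' @return One-row tibble of class `window_selection` with columns `start`
#'   (first volume of the window, 1-based), `length`, and `mean_fd` (the
#'   criterion value inside the window).
#' @export
select_least_motion_window <- function(fd, window_length = 300, exclude_first = 300) {
  if (is.data.frame(fd)) fdv <- fd$fd else fdv <- as.numeric(fd)
  n <- length(fdv)
  needed <- exclude_first + window_length
  if (n < needed)
    stop_thalcon("scan too short: %d volumes, need at least %d (exclude_first + window_length)",
                 n, needed)
  # O(n) running mean over all admissible starts
  cs <- c(0, cumsum(fdv))
  starts <- (exclude_first + 1L):(n - window_length + 1L)
  win_mean <- (cs[starts + window_length] - cs[starts]) / window_length
  # earliest start among (numerically) tied minima
  best_val <- min(win_mean)
  best <- which(win_mean <= best_val + 1e-9 * (1 + abs(best_val)))[1]
  out <- tibble(start = starts[best], length = as.integer(window_length),
                mean_fd = win_mean[best])
  structure(out, class = c("window_selection", class(out)))
}

window_volumes <- function(window) {
  seq.int(window$start, window$start + window$length - 1L)
}

#' Apply the ICA scan-discard rule
#'
#' A scan is discarded from the connectivity analysis when more than
#' `max_removed` of its `n_components` independent components were removed
#' during ICA-based motion correction ("more than" is strict: a scan with
#' exactly `max_removed` removed components is retained).
#'
#' @param qc Data frame with one row per scan and columns `n_removed` and
#'   `n_components` (counts).
#' @param max_removed Strict threshold (default 20 of 30 components).
#' @return The input tibble with a logical `discarded` column added.
#' @export
#' @examples
#' apply_scan_discard_rule(tibble::tibble(n_removed = c(0, 20, 21),
#'                                        n_components = 30))
apply_scan_discard_rule <- function(qc, max_removed = 20) {
  if (!is.data.frame(qc) || !all(c("n_removed", "n_components") %in% names(qc)))
    stop_thalcon("`qc` must have columns n_removed and n_components")
  if (any(qc$n_removed < 0 | qc$n_components < 0))
    stop_thalcon("component counts must be non-negative")
  over <- which(qc$n_removed > qc$n_components)
  if (length(over) > 0)
    stop_thalcon("n_removed exceeds n_components in row %d", over[1])
  dplyr::mutate(as_tibble(qc), discarded = .data$n_removed > max_removed)
}

#' Scan retention summary
#'
#' Accounting helper: given per-scan QC with a `discarded` flag (see
#' [apply_scan_discard_rule()]), returns counts and percentages of retained
#' and discarded scans.
#'
#' @param qc Data frame with a logical `discarded` column.
#' @return One-row tibble with `n_scans`, `n_retained`, `n_discarded`,
#'   `retained_percent`, `discarded_percent`.
#' @export
scan_retention <- function(qc) {
  stopifnot(is.data.frame(qc), "discarded" %in% names(qc))
  n <- nrow(qc)
  nd <- sum(qc$discarded)
  tibble(n_scans = n, n_retained = n - nd, n_discarded = nd,
         retained_percent = 100 * (n - nd) / n,
         discarded_percent = 100 * nd / n)
}

#' Attrition rate as a percentage
#'
#' Cohort accounting: percentage of animals lost or excluded out of a total.
#'
#' @param n_excluded,n_total Counts.
#' @return Percentage (0-100).
#' @export
#' @examples
#' attrition_rate(13, 59)
attrition_rate <- function(n_excluded, n_total) {
  if (!is_count(n_excluded) || !is_count(n_total) || n_total == 0)
    stop_thalcon("counts must be non-negative integers with n_total > 0")
  if (n_excluded > n_total)
    stop_thalcon("n_excluded (%d) exceeds n_total (%d)", n_excluded, n_total)
  100 * n_excluded / n_total
}

series_matrix <- function(series) {
  if (is.matrix(series)) return(series)
  if (!is.data.frame(series))
    stop_thalcon("`series` must be a data frame (volume + one column per ROI) or matrix")
  cols <- setdiff(names(series), "volume")
  as.matrix(series[cols])
}

#' Regress motion parameters from ROI (or voxel) time series
#'
#' Ordinary least squares of each series, restricted to the selected window,
#' on an intercept plus the six rigid-body motion parameters. Residuals are
#' returned; they are orthogonal to the (retained) regressors to numerical
#' precision. Collinear motion columns (e.g. constant motion) are dropped
#' with a warning, so zero motion reduces to demeaning.
#'
#' @param series Data frame with an optional `volume` column and one numeric
#'   column per ROI (full-scan length), or a volumes-by-series matrix.
#' @param motion Motion parameters for the same scan (see
#'   [framewise_displacement()]).
#' @param window A `window_selection`; if `NULL`, the whole scan is used.
#' @return Tibble with `volume` plus one residual column per input series,
#'   one row per window volume.
#' @export
regress_motion <- function(series, motion, window = NULL) {
  y <- series_matrix(series)
  m <- as_motion_matrix(motion)
  if (nrow(y) != nrow(m))
    stop_thalcon("series has %d volumes but motion has %d", nrow(y), nrow(m))
  vols <- if (is.null(window)) seq_len(nrow(y)) else window_volumes(window)
  if (max(vols) > nrow(y))
    stop_thalcon("window [%d, %d] exceeds scan length %d",
                 min(vols), max(vols), nrow(y))
  X <- cbind(intercept = 1, m[vols, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    rlang::warn(sprintf("dropping collinear motion regressor(s): %s",
                        paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, y[vols, , drop = FALSE])
  out <- as_tibble(as.data.frame(res))
  dplyr::bind_cols(tibble(volume = vols), out)
}

#' Fisher z transform with clipping
#'
#' `atanh` of a correlation, with `|r|` clipped to `1 - 1e-7` first so that
#' perfectly correlated pairs map to a large finite value rather than
#' infinity.
#'
#' @param r Correlations in \[-1, 1\].
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
}

#' ROI-pair functional connectivity
#'
#' Pearson correlation of every ROI pair's (motion-regressed) mean time
#' series within the analysis window, with Fisher-z values alongside.
#' ROIs flagged invalid (lesion-artifact exclusion) or with zero variance
#' get missing entries, never zeros.
#'
#' @param series Data frame / matrix of series (see [regress_motion()]);
#'   typically the residuals already restricted to the window. If `window`
#'   is supplied the rows are subset first.
#' @param window Optional `window_selection` used to subset rows when
#'   `series` still spans the full scan.
#' @param valid Optional named logical vector marking per-ROI validity.
#' @return An object of class `fc_matrix`: list with `roi_names`, `r` and
#'   `z` (symmetric matrices, unit/clipped diagonal), and `n_samples`.
#'   [tidy()] returns the lower triangle as a long tibble.
#' @export
roi_connectivity <- function(series, window = NULL, valid = NULL) {
  y <- series_matrix(series)
  if (!is.null(window)) {
    vols <- window_volumes(window)
    if (!is.null(series$volume)) {
      idx <- match(vols, series$volume)
      if (anyNA(idx))
        stop_thalcon("window volumes not present in `series`")
      y <- y[idx, , drop = FALSE]
    } else {
      y <- y[vols, , drop = FALSE]
    }
  }
  if (nrow(y) < 3) stop_thalcon("need at least 3 samples for correlation")
  rois <- colnames(y) %||% paste0("roi", seq_len(ncol(y)))
  keep <- rep(TRUE, ncol(y))
  if (!is.null(valid)) {
    if (is.null(names(valid))) names(valid) <- rois
    keep <- as.logical(valid[rois])
    keep[is.na(keep)] <- TRUE
  }
  zero_var <- apply(y, 2, function(col) isTRUE(all.equal(var(col), 0)) || var(col) == 0)
  if (any(zero_var & keep))
    rlang::inform(sprintf("zero-variance series set missing: %s",
                          paste(rois[zero_var & keep], collapse = ", ")))
  use <- keep & !zero_var
  if (sum(use) < 2) stop_thalcon("fewer than 2 valid ROIs with signal variance")
  p <- length(rois)
  r <- matrix(NA_real_, p, p, dimnames = list(rois, rois))
  r[use, use] <- cor(y[, use, drop = FALSE])
  diag(r)[use] <- 1
  z <- fisher_z(r)
  structure(list(roi_names = rois, r = r, z = z, n_samples = nrow(y),
                 valid = setNames(use, rois)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix: %d ROIs, %d samples>\n", length(x$roi_names), x$n_samples))
  print(round(x$r, 3))
  invisible(x)
}

#' @method tidy fc_matrix
#' @export
tidy.fc_matrix <- function(x, ...) {
  p <- length(x$roi_names)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble(roi1 = x$roi_names[idx[, 2]], roi2 = x$roi_names[idx[, 1]],
         r = x$r[idx], z = x$z[idx], n = x$n_samples)
}

#' @method glance fc_matrix
#' @export
glance.fc_matrix <- function(x, ...) {
  lt <- x$r[lower.tri(x$r)]
  tibble(n_rois = length(x$roi_names), n_valid = sum(x$valid),
         n_samples = x$n_samples,
         mean_r = mean(lt, na.rm = TRUE), mean_z = mean(fisher_z(lt), na.rm = TRUE))
}

#' One-call connectivity for a single scan
#'
#' Convenience wrapper chaining the stage: framewise displacement,
#' least-motion window selection, within-window motion regression, then
#' ROI-pair connectivity.
#'
#' @inheritParams framewise_displacement
#' @inheritParams select_least_motion_window
#' @param series Full-scan ROI time-series data frame.
#' @param valid Optional per-ROI validity flags.
#' @return List with `fc` (an `fc_matrix`), `window`, and `fd_summary`.
#' @export
scan_connectivity <- function(series, motion, rotation_radius_mm = 5,
                              window_length = 300, exclude_first = 300,
                              valid = NULL) {
  fd <- framewise_displacement(motion, rotation_radius_mm)
  win <- select_least_motion_window(fd, window_length, exclude_first)
  resid <- regress_motion(series, motion, win)
  fc <- roi_connectivity(resid[setdiff(names(resid), "volume")], valid = valid)
  list(fc = fc, window = win, fd_summary = glance(fd))
}
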