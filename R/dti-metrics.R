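# Diffusion-tensor scalar metrics: log-linear tensor fit from
# diffusion-weighted signals, eigenvalue decomposition, and the standard
# rotation-invariant scalars FA, MD, AD, RD with per-ROI means.

#' Construct a diffusion acquisition protocol
#'
#' @param bvals Numeric vector of b-values in s/mm^2, one per measurement
#'   (0 for non-diffusion-weighted images).
#' @param bvecs 3-column matrix of gradient directions (rows), unit norm for
#'   diffusion-weighted measurements. The protocol must contain at least 6
#'   unique non-collinear diffusion directions.
#' @return Object of class `dti_protocol` with the precomputed design
#'   matrix for the log-linear fit.
#' @export
dti_protocol <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals))
    stop_thalcon("bvecs must be an n x 3 matrix matching length(bvals)")
  dw <- bvals > 0
  if (sum(dw) > 0) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop_thalcon("diffusion gradient directions must be unit-norm")
  }
  g <- bvecs
  # log S = log S0 - b g' D g, D = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  X <- cbind(log_s0 = 1,
             dxx = -bvals * g[, 1]^2,
             dyy = -bvals * g[, 2]^2,
             dzz = -bvals * g[, 3]^2,
             dxy = -2 * bvals * g[, 1] * g[, 2],
             dxz = -2 * bvals * g[, 1] * g[, 3],
             dyz = -2 * bvals * g[, 2] * g[, 3])
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-10 * sv[1])
    stop_thalcon(paste0("rank-deficient diffusion design (condition number %.3g); ",
                        "need >= 6 unique non-collinear directions"),
                 sv[1] / max(sv[length(sv)], .Machine$double.xmin))
  structure(list(bvals = bvals, bvecs = bvecs, design = X,
                 n_b0 = sum(!dw), condition = sv[1] / sv[length(sv)]),
            class = "dti_protocol")
}

#' @export
print.dti_protocol <- function(x, ...) {
  cat(sprintf("<dti_protocol: %d measurements (%d b0), b_max = %g s/mm^2>\n",
              length(x$bvals), x$n_b0, max(x$bvals)))
  invisible(x)
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares of `log(S)` on the diffusion design, recovering
#' `log(S0)` and the six unique tensor components per voxel. Noise-free
#' signals are recovered exactly. Non-positive signals (possible under
#' noise) are clipped to machine epsilon before the log, and the number of
#' clipped values is reported.
#'
#' @param signals Numeric vector (one voxel) or measurements-by-voxels
#'   matrix of diffusion-weighted signals.
#' @param protocol A [dti_protocol()].
#' @return List with `tensors` (6-row matrix: dxx, dyy, dzz, dxy, dxz,
#'   dyz, one column per voxel), `s0`, and `n_clipped`.
#' @export
fit_tensor_loglinear <- function(signals, protocol) {
  stopifnot(inherits(protocol, "dti_protocol"))
  S <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (nrow(S) != nrow(protocol$design))
    stop_thalcon("signals have %d measurements but protocol has %d",
                 nrow(S), nrow(protocol$design))
  n_clipped <- sum(S <= 0)
  if (n_clipped > 0) S[S <= 0] <- .Machine$double.eps
  beta <- qr.coef(qr(protocol$design), log(S))
  list(tensors = beta[-1, , drop = FALSE], s0 = exp(beta[1, ]),
       n_clipped = n_clipped)
}

#' Tensor eigenvalues, sorted descending
#'
#' @param tensors 6-row matrix from [fit_tensor_loglinear()] (or length-6
#'   vector).
#' @return Voxels-by-3 matrix of eigenvalues, columns lambda1 >= lambda2 >=
#'   lambda3.
#' @export
tensor_eigenvalues <- function(tensors) {
  B <- if (is.matrix(tensors)) tensors else matrix(tensors, ncol = 1)
  out <- t(apply(B, 2, function(d) {
    D <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  }))
  colnames(out) <- c("lambda1", "lambda2", "lambda3")
  out
}

#' Rotation-invariant tensor scalars
#'
#' From eigenvalues sorted descending: mean diffusivity
#' `MD = (l1 + l2 + l3) / 3`, axial diffusivity `AD = l1`, radial
#' diffusivity `RD = (l2 + l3) / 2`, and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))`, defined as 0
#' for an all-zero tensor. Negative eigenvalues (possible from noisy fits)
#' are clipped to 0 before the scalar computation and flagged.
#'
#' @param eigenvalues Length-3 vector or voxels-by-3 matrix, sorted
#'   descending per voxel.
#' @return Tibble with columns `fa`, `md`, `ad`, `rd`, `clipped`.
#' @export
tensor_scalars <- function(eigenvalues) {
  L <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, ncol = 3)
  if (ncol(L) != 3) stop_thalcon("eigenvalues must have 3 columns")
  if (any(L[, 1] < L[, 2] - 1e-12) || any(L[, 2] < L[, 3] - 1e-12))
    stop_thalcon("eigenvalues must be sorted descending per voxel")
  clipped <- rowSums(L < 0) > 0
  L[L < 0] <- 0
  md <- rowMeans(L)
  ss <- rowSums(L^2)
  fa <- ifelse(ss > 0,
               sqrt(1.5) * sqrt(rowSums((L - md)^2)) / sqrt(ss),
               0)
  tibble(fa = pmin(fa, 1), md = md, ad = L[, 1], rd = (L[, 2] + L[, 3]) / 2,
         clipped = clipped)
}

#' Per-ROI means of scalar maps
#'
#' Masked arithmetic mean of each scalar map over each ROI.
#'
#' @param scalar_maps Named list of 3-D arrays (e.g. `fa`, `md`, `ad`,
#'   `rd`) on a shared grid.
#' @param roi_masks Named list of non-empty logical arrays on that grid.
#' @return Long tibble with columns `roi`, `metric`, `value`.
#' @export
roi_metric_means <- function(scalar_maps, roi_masks) {
  stopifnot(is.list(scalar_maps), is.list(roi_masks))
  rows <- purrr::imap(roi_masks, function(mask, roi) {
    if (!any(mask)) stop_thalcon("ROI '%s' is empty", roi)
    purrr::imap(scalar_maps, function(map, metric) {
      check_same_grid(map, mask, "scalar map and ROI mask")
      tibble(roi = roi, metric = metric, value = mean(map[mask]))
    }) |> list_rbind()
  })
  list_rbind(rows)
}
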