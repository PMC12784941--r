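# Per-modality synthetic generators. Each is deterministic given its seed,
# draws observed data from an explicit model, and keeps ground truth
# separate from the observed tables.

#' Generate correlated ROI time series
#'
#' Stationary Gaussian series with a target instantaneous cross-correlation:
#' independent unit-variance AR(1) processes (`x_t = phi x_{t-1} +
#' sqrt(1 - phi^2) e_t`) are mixed through the symmetric matrix square root
#' of the target correlation, so the population lag-0 cross-correlation of
#' the output equals `corr_target` and each marginal has unit variance.
#'
#' @param corr_target Symmetric positive-semidefinite matrix with unit
#'   diagonal; dimnames (if any) become the ROI column names.
#' @param n_volumes Number of volumes.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param seed Optional seed (see [with_seed()]).
#' @param roi_names Optional ROI names overriding the dimnames.
#' @return Tibble with `volume` plus one column per ROI.
#' @export
generate_roi_timeseries <- function(corr_target, n_volumes,
                                    ar_coefficient = 0.3, seed = NULL,
                                    roi_names = NULL) {
  check_correlation_target(corr_target)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop_thalcon("ar_coefficient must be in [0, 1)")
  p <- ncol(corr_target)
  rois <- roi_names %||% colnames(corr_target) %||% paste0("roi", seq_len(p))
  e <- eigen(corr_target, symmetric = TRUE)
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  with_seed(seed, {
    innov <- matrix(rnorm(n_volumes * p), n_volumes, p)
    if (ar_coefficient > 0) {
      innov <- apply(innov, 2, function(col)
        as.numeric(stats::filter(col * sqrt(1 - ar_coefficient^2),
                                 ar_coefficient, method = "recursive")))
    }
    y <- innov %*% root
    colnames(y) <- rois
    dplyr::bind_cols(tibble(volume = seq_len(n_volumes)),
                     as_tibble(as.data.frame(y)))
  })
}

#' Generate a rigid-body motion trace
#'
#' Baseline Gaussian jitter on all six parameters (rotations at 10% of the
#' translation scale), plus randomly placed additive translation steps
#' (spikes) of the given amplitude on a random axis with random sign. The
#' true spike volumes are recorded in the `spike_volumes` attribute, not in
#' the observed columns.
#'
#' @param n_volumes Number of volumes.
#' @param spike_rate Per-volume spike probability in `[0, 1]`.
#' @param spike_amplitude_mm Step amplitude in mm.
#' @param jitter_sd_mm Baseline jitter SD in mm (0 gives an exactly
#'   motion-free trace when `spike_rate = 0`).
#' @param seed Optional seed.
#' @return Tibble with columns `tx`, `ty`, `tz` (mm), `rx`, `ry`, `rz`
#'   (rad); attribute `spike_volumes` holds the ground-truth spike indices.
#' @export
generate_motion_trace <- function(n_volumes, spike_rate = 0.005,
                                  spike_amplitude_mm = 0.15,
                                  jitter_sd_mm = 0.01, seed = NULL) {
  if (spike_rate < 0 || spike_rate > 1)
    stop_thalcon("spike_rate must be in [0, 1]")
  with_seed(seed, {
    m <- matrix(rnorm(n_volumes * 6), n_volumes, 6)
    m[, 1:3] <- m[, 1:3] * jitter_sd_mm
    m[, 4:6] <- m[, 4:6] * jitter_sd_mm * 0.1
    spikes <- which(runif(n_volumes) < spike_rate)
    spikes <- spikes[spikes > 1]
    for (s in spikes) {
      axis <- sample.int(3, 1)
      m[s:n_volumes, axis] <- m[s:n_volumes, axis] +
        sample(c(-1, 1), 1) * spike_amplitude_mm
    }
    out <- as_tibble(as.data.frame(m))
    names(out) <- MOTION_COLS
    attr(out, "spike_volumes") <- spikes
    out
  })
}

#' Generate a synthetic nucleus table
#'
#' Nuclear areas drawn per class from Gaussian distributions truncated at
#' zero (negative draws are resampled and counted). True class labels are
#' recorded in a `true_class` column, which downstream observed tables must
#' strip.
#'
#' @param n_neuronal,n_glial Nucleus counts (>= 0).
#' @param nuclei_params Named list with per-class `c(mean, sd)` in um^2
#'   (defaults from [synth_config()]).
#' @param seed Optional seed.
#' @return Tibble with columns `area` (um^2) and `true_class`; attribute
#'   `n_resampled` counts truncation resamples.
#' @export
generate_nuclei <- function(n_neuronal, n_glial,
                            nuclei_params = list(neuronal = c(mean = 133.5, sd = 40.75),
                                                 glial = c(mean = 21, sd = 6.5)),
                            seed = NULL) {
  if (n_neuronal < 0 || n_glial < 0) stop_thalcon("counts must be >= 0")
  draw <- function(n, pars) {
    resampled <- 0L
    x <- rnorm(n, pars[["mean"]], pars[["sd"]])
    while (any(x <= 0)) {
      bad <- x <= 0
      resampled <- resampled + sum(bad)
      x[bad] <- rnorm(sum(bad), pars[["mean"]], pars[["sd"]])
    }
    list(x = x, resampled = resampled)
  }
  with_seed(seed, {
    ne <- draw(n_neuronal, nuclei_params$neuronal)
    gl <- draw(n_glial, nuclei_params$glial)
    out <- tibble(
      area = c(ne$x, gl$x),
      true_class = c(rep("neuronal", n_neuronal), rep("glial", n_glial)))
    attr(out, "n_resampled") <- ne$resampled + gl$resampled
    out
  })
}

#' Generate baseline and followup mean volumes with a focal lesion
#'
#' Baseline mean-intensity volume (unit intensity inside the brain mask
#' plus Gaussian noise, scaled to arbitrary scanner units) and a followup
#' volume in which the geometry's lesion region is shifted by
#' `intensity_change` normalized-intensity units. The true lesion mask is
#' returned separately as ground truth.
#'
#' @param geometry A [synth_geometry()].
#' @param lesion_spec List with `intensity_change` and `noise_sd`.
#' @param scanner_scale Arbitrary global intensity scale of the followup
#'   scan relative to baseline (exercises global normalization).
#' @param seed Optional seed.
#' @return List with `base`, `post` (3-D arrays, un-normalized),
#'   `truth_lesion` (logical array).
#' @export
generate_lesion_volume <- function(geometry, lesion_spec = list(intensity_change = 3.5,
                                                                noise_sd = 0.05),
                                   scanner_scale = 1, seed = NULL) {
  with_seed(seed, {
    d <- geometry$dim
    base <- array(rnorm(prod(d), 0, lesion_spec$noise_sd), d)
    base[geometry$brain_mask] <- base[geometry$brain_mask] + 1
    post <- array(rnorm(prod(d), 0, lesion_spec$noise_sd), d)
    post[geometry$brain_mask] <- post[geometry$brain_mask] + 1
    post[geometry$lesion_mask] <- post[geometry$lesion_mask] +
      lesion_spec$intensity_change
    list(base = base * 700, post = post * 700 * scanner_scale,
         truth_lesion = geometry$lesion_mask)
  })
}

#' Generate dynamic PET frames for one subject
#'
#' Builds a spatial activity-concentration map from per-ROI target uptake
#' values (%/ml) over a body-mask background, applies a rise-and-plateau
#' time-activity curve across 5-min frames over 0-70 min, and adds
#' per-voxel and per-frame multiplicative noise. A faulty tail-vein
#' injection is emulated as an early activity spike followed by a drop,
#' which the injection QC detects.
#'
#' @param geometry A [synth_geometry()].
#' @param roi_u Named vector of target uptake per ROI (%/ml) over
#'   `geometry$roi_masks`.
#' @param background_u Background uptake inside the body mask (%/ml).
#' @param voxel_sd SD of the per-voxel multiplicative noise (fraction).
#' @param faulty Emulate a faulty injection (default `FALSE`).
#' @param seed Optional seed.
#' @return A [dynamic_pet()] (14 frames of 5 min, 0-70 min).
#' @export
generate_pet_frames <- function(geometry, roi_u, background_u = 4.5,
                                voxel_sd = 0.25, faulty = FALSE, seed = NULL) {
  with_seed(seed, {
    d <- geometry$dim
    base <- array(0, d)
    base[geometry$body_mask] <- background_u
    for (nm in names(roi_u)) base[geometry$roi_masks[[nm]]] <- roi_u[[nm]]
    base <- base * array(pmax(1 + rnorm(prod(d), 0, voxel_sd), 0.05), d)
    starts <- c(0:9, seq(10, 65, by = 5))   # 1-min early frames, 5-min later
    ends <- c(1:10, seq(15, 70, by = 5))
    mids <- (starts + ends) / 2
    tac <- 1 - exp(-mids / 8)          # rise and plateau
    if (faulty) tac[1:4] <- c(0.6, 1.9, 0.8, 0.5)  # paravenous spike then drop
    frames <- lapply(seq_along(tac), function(k)
      base * tac[k] * (1 + rnorm(1, 0, 0.01)))
    dynamic_pet(frames, starts, ends, geometry$voxel_volume_ml)
  })
}

#' Uniformly spaced gradient directions
#'
#' Deterministic Fibonacci-sphere construction of approximately uniformly
#' distributed unit vectors.
#'
#' @param n Number of directions.
#' @return n-by-3 matrix of unit vectors.
#' @export
uniform_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' The study's diffusion protocol
#'
#' b = 2800 s/mm^2 in 42 uniformly spaced diffusion directions plus 4
#' non-diffusion-weighted images.
#'
#' @return A [dti_protocol()].
#' @export
default_dti_protocol <- function() {
  dirs <- uniform_directions(42)
  dti_protocol(bvals = c(rep(0, 4), rep(2800, 42)),
               bvecs = rbind(matrix(0, 4, 3), dirs))
}

#' Generate diffusion-weighted signals for one ROI
#'
#' Forward-simulates the single-tensor model per voxel: each voxel carries
#' the given eigenvalues in a random orientation, signals follow
#' `S = S0 exp(-b g' D g)`, and Rician noise at the given SNR (relative to
#' S0) is added unless `snr = Inf`. The true per-voxel tensors are
#' returned separately.
#'
#' @param eigenvalues Length-3 vector (mm^2/s), descending.
#' @param protocol A [dti_protocol()].
#' @param n_voxels Number of voxels.
#' @param snr Rician signal-to-noise ratio at b = 0; `Inf` for noise-free.
#' @param s0 Non-diffusion-weighted signal level.
#' @param seed Optional seed.
#' @return List with `signals` (measurements x voxels) and `truth_tensors`
#'   (6 x voxels, dxx dyy dzz dxy dxz dyz).
#' @export
generate_dti_signals <- function(eigenvalues, protocol, n_voxels = 20,
                                 snr = Inf, s0 = 1000, seed = NULL) {
  stopifnot(inherits(protocol, "dti_protocol"), length(eigenvalues) == 3)
  with_seed(seed, {
    b <- protocol$bvals; g <- protocol$bvecs
    tensors <- matrix(0, 6, n_voxels)
    S <- matrix(0, length(b), n_voxels)
    for (v in seq_len(n_voxels)) {
      Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      D <- Q %*% diag(eigenvalues) %*% t(Q)
      tensors[, v] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
      quad <- rowSums((g %*% D) * g)
      S[, v] <- s0 * exp(-b * quad)
    }
    if (is.finite(snr)) {
      sigma <- s0 / snr
      S <- sqrt((S + matrix(rnorm(length(S), 0, sigma), nrow(S)))^2 +
                  matrix(rnorm(length(S), 0, sigma), nrow(S))^2)
    }
    list(signals = S, truth_tensors = tensors)
  })
}
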