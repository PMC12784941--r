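# Synthetic-cohort configuration: study design (two groups, four
# timepoints, six ROIs), target correlation structure, effect sizes and
# noise levels for every modality, with validation of the correlation
# targets.

#' Evaluate code with a temporarily-set RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards; with `seed = NULL` the current stream is used
#' unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_correlation_target <- function(C, name = "corr_target") {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop_thalcon("%s must be a square matrix", name)
  if (max(abs(C - t(C))) > 1e-8)
    stop_thalcon("%s is not symmetric", name)
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop_thalcon("%s must have unit diagonal", name)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_thalcon("%s is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev))
  invisible(C)
}

#' Repair a perturbed correlation matrix
#'
#' Effect-size perturbations of a valid correlation matrix can push it
#' slightly outside the positive-semidefinite cone; this clips eigenvalues
#' at a small floor and rescales to unit diagonal (a one-step Higham-style
#' projection), leaving already-valid matrices essentially unchanged.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @param floor Minimum eigenvalue after repair.
#' @return A valid correlation matrix.
#' @export
repair_correlation <- function(C, floor = 1e-4) {
  dn <- dimnames(C)
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  M <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dn
  M
}

#' Shared synthetic imaging geometry
#'
#' One small voxel grid carrying the masks every volumetric stage uses: a
#' brain mask, six disjoint box ROIs (in the canonical order of
#' [roi_names()], plus `RSi`/`RSc` halves of RS used by histology layouts),
#' a cortical lesion region placed away from the analysis ROIs, and a body
#' mask for PET normalization.
#'
#' @param dim Grid dimensions (default `c(24, 24, 12)`).
#' @param voxel_mm Isotropic voxel size in mm (default 0.5).
#' @return List with `dim`, `voxel_mm`, `voxel_volume_ml`, `brain_mask`,
#'   `body_mask`, `roi_masks` (named list), `lesion_mask`.
#' @export
synth_geometry <- function(dim = c(24, 24, 12), voxel_mm = 0.5) {
  box <- function(x, y, z) {
    m <- array(FALSE, dim)
    m[x[1]:x[2], y[1]:y[2], z[1]:z[2]] <- TRUE
    m
  }
  brain <- box(c(3, dim[1] - 2), c(3, dim[2] - 2), c(2, dim[3] - 1))
  # thalamic ROIs central, cortical ROIs dorsal-midline, lesion lateral cortex
  rois <- list(
    VPNi = box(c(6, 8),   c(10, 12), c(5, 7)),
    VPNc = box(c(16, 18), c(10, 12), c(5, 7)),
    LNi  = box(c(6, 8),   c(14, 16), c(5, 7)),
    LNc  = box(c(16, 18), c(14, 16), c(5, 7)),
    RS   = box(c(11, 13), c(14, 16), c(9, 11)),
    CG   = box(c(11, 13), c(8, 10),  c(9, 11)))
  lesion <- box(c(4, 7), c(4, 8), c(9, 11))
  list(dim = dim, voxel_mm = voxel_mm,
       voxel_volume_ml = (voxel_mm / 10)^3,  # mm^3 -> ml
       brain_mask = brain, body_mask = box(c(2, dim[1] - 1), c(2, dim[2] - 1),
                                           c(1, dim[3])),
       roi_masks = rois, lesion_mask = lesion)
}

#' Default group-average correlation targets
#'
#' A plausible resting corticothalamic correlation structure: moderate
#' thalamo-thalamic coupling (r = 0.5), corticothalamic coupling (0.4) and
#' cortico-cortical RS-CG coupling (0.45), identical across hemispheres at
#' baseline.
#'
#' @return 6x6 correlation matrix over [roi_names()].
#' @export
default_fc_target <- function() {
  rois <- THALCON_ROIS
  C <- matrix(0.0, 6, 6, dimnames = list(rois, rois))
  thal <- c("VPNi", "VPNc", "LNi", "LNc")
  C[thal, thal] <- 0.5
  for (cx in c("RS", "CG")) {
    C[cx, thal] <- 0.4
    C[thal, cx] <- 0.4
  }
  C["RS", "CG"] <- C["CG", "RS"] <- 0.45
  diag(C) <- 1
  check_correlation_target(C, "default_fc_target")
  C
}

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions: 36 injured (TBI) and 11
#' sham-operated animals over four timepoints (BL, W2, M2, M6); 1500 fMRI
#' volumes at TR = 1 s; a PET subgroup at W2 of 25 TBI and 9 SHAM animals
#' of which 7 TBI and 1 SHAM have faulty injections; DTI at M2 and M6;
#' terminal histology in 14 TBI and 6 SHAM of the PET-successful animals.
#' Group/timepoint correlation targets start from [default_fc_target()];
#' lateralized effects are parameterized per subject through a positive
#' latent severity (TBI only) that jointly drives ipsilateral uptake
#' elevation, diffusivity increase, glial density increase, neuronal loss,
#' myelin OD reduction, and the M2 connectivity deficit (so the
#' delta-correlation structure couples uptake to diffusivity and histology
#' at all measured timepoints but to connectivity only at M2).
#'
#' @param n_tbi,n_sham Group sizes.
#' @param timepoints Ordered timepoint labels.
#' @param n_volumes fMRI volumes per scan (>= 600).
#' @param tr_seconds Repetition time in seconds.
#' @param ar_coefficient AR(1) coefficient of the ROI series in `[0, 1)`.
#' @param motion Motion-trace parameters: `jitter_sd_mm`, `spike_rate`,
#'   `spike_amplitude_mm`.
#' @param lesion_spec Focal-anomaly parameters: `intensity_change`
#'   (normalized-intensity units) applied inside the geometry's lesion
#'   region, plus `noise_sd`.
#' @param pet Uptake parameters (%/ml): `base_thalamic`, `base_cortical`,
#'   `background`, `uptake_coupling` (per unit severity, ipsilateral
#'   thalamic), `subject_sd`, `voxel_sd`.
#' @param dti Eigenvalue parameters: `lambda` (baseline, mm^2/s, descending),
#'   `md_coupling` (relative ipsilateral diffusivity increase per unit
#'   severity), `subject_sd` (relative), `snr` (Rician), `n_voxels` per ROI.
#' @param histology Cell/myelin parameters: `nuclei_params` (per-class area
#'   mean/SD, um^2), densities and couplings (cells/mm^2), OD levels.
#' @param fc_effects Connectivity effect sizes (Fisher-z units): bilateral
#'   and lateralized deficits per timepoint, and the M2 severity coupling.
#' @param qc ICA scan-discard simulation: `p_high_motion`, component-count
#'   ranges.
#' @param severity Latent severity distribution for TBI animals
#'   (gamma `shape`, `scale`).
#' @param pet_design,histology_design Subgroup sizes.
#' @param seed Integer seed making the whole cohort deterministic.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_tbi = 36, n_sham = 11,
                         timepoints = c("BL", "W2", "M2", "M6"),
                         n_volumes = 1500, tr_seconds = 1,
                         ar_coefficient = 0.3,
                         motion = list(jitter_sd_mm = 0.01, spike_rate = 0.005,
                                       spike_amplitude_mm = 0.15),
                         lesion_spec = list(intensity_change = 3.5, noise_sd = 0.05),
                         pet = list(base_thalamic = 5.5, base_cortical = 5.0,
                                    background = 4.5, uptake_coupling = 1.8,
                                    subject_sd = 0.12, voxel_sd = 0.25),
                         dti = list(lambda = c(1.0e-3, 0.6e-3, 0.5e-3),
                                    md_coupling = 0.20, subject_sd = 0.02,
                                    aniso_sd = 0.03, snr = Inf, n_voxels = 20),
                         histology = list(
                           nuclei_params = list(neuronal = c(mean = 133.5, sd = 40.75),
                                                glial = c(mean = 21, sd = 6.5)),
                           roi_area_um2 = 5e5,
                           cd_ne_base = 600, cd_gl_base = 800,
                           cd_ne_coupling = 150, cd_gl_coupling = 400,
                           cd_subject_sd = 15,
                           od_base = 0.55, od_coupling = 0.12, od_sd = 0.015,
                           i_bg = 0.10, i_wm = 1.0),
                         fc_effects = list(
                           w2_bilateral = 0.18,
                           w2_thalamic = 0.12,
                           w2_ipsi_extra_mean = 0, w2_ipsi_extra_sd = 0.12,
                           w2_edge_sd = 0.05,
                           m2_coupling = 0.35, m2_noise_sd = 0.03,
                           m2_uncoupled_mean = 0, m2_uncoupled_sd = 0.05,
                           m6_ipsi_mean = 0, m6_ipsi_sd = 0.06),
                         qc = list(p_high_motion = 0.085,
                                   low_range = c(3, 15), high_range = c(21, 28)),
                         severity = list(shape = 4, scale = 0.25),
                         pet_design = list(n_tbi = 25, n_sham = 9,
                                           faulty_tbi = 7, faulty_sham = 1),
                         histology_design = list(n_tbi = 14, n_sham = 6),
                         seed = 1L) {
  if (!is_count(n_tbi) || !is_count(n_sham))
    stop_thalcon("group sizes must be non-negative integers")
  if (n_volumes < 600)
    stop_thalcon("n_volumes must be >= 600 (first-segment exclusion + window), got %d",
                 n_volumes)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop_thalcon("ar_coefficient must be in [0, 1)")
  if (motion$spike_rate < 0 || motion$spike_rate > 1)
    stop_thalcon("motion spike_rate must be in [0, 1]")
  for (cls in names(histology$nuclei_params)) {
    if (histology$nuclei_params[[cls]][["sd"]] <= 0)
      stop_thalcon("nuclei_params: class '%s' must have positive SD", cls)
  }
  base <- default_fc_target()
  fc_target <- list(
    TBI = list(BL = base,
               W2 = tbi_w2_group_target(base, fc_effects),
               M2 = base, M6 = base),
    SHAM = list(BL = base, W2 = base, M2 = base, M6 = base))
  for (g in names(fc_target)) for (tp in names(fc_target[[g]]))
    check_correlation_target(fc_target[[g]][[tp]],
                             sprintf("fc_target$%s$%s", g, tp))
  structure(list(n_tbi = n_tbi, n_sham = n_sham, timepoints = timepoints,
                 n_volumes = n_volumes, tr_seconds = tr_seconds,
                 roi_names = THALCON_ROIS, fc_target = fc_target,
                 ar_coefficient = ar_coefficient, motion = motion,
                 lesion_spec = lesion_spec, pet = pet, dti = dti,
                 histology = histology, fc_effects = fc_effects, qc = qc,
                 severity = severity, pet_design = pet_design,
                 histology_design = histology_design,
                 geometry = synth_geometry(), seed = as.integer(seed)),
            class = "synth_config")
}

# Group-level W2 matrix for TBI: bilateral corticothalamic and
# thalamo-thalamic hypoconnectivity (r units), repaired to stay PSD.
tbi_w2_group_target <- function(base, fx) {
  C <- base
  thal <- c("VPNi", "VPNc", "LNi", "LNc")
  for (cx in c("RS", "CG")) {
    C[cx, thal] <- C[cx, thal] - fx$w2_bilateral
    C[thal, cx] <- C[cx, thal]
  }
  off <- which(upper.tri(C), arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    i <- off[k, 1]; j <- off[k, 2]
    if (rownames(C)[i] %in% thal && colnames(C)[j] %in% thal) {
      C[i, j] <- C[i, j] - fx$w2_thalamic
      C[j, i] <- C[i, j]
    }
  }
  repair_correlation(C)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config: %d TBI + %d SHAM, timepoints %s, %d volumes, seed %d>\n",
              x$n_tbi, x$n_sham, paste(x$timepoints, collapse = "/"),
              x$n_volumes, x$seed))
  invisible(x)
}
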