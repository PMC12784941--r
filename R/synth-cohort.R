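# Whole-cohort synthesis: two groups, four timepoints, all modalities,
# with a per-subject latent severity driving the configured lateralized
# effects and all ground truth kept in a separate `truth` slot.

cortical_ipsi_edges <- function() {
  list(c("CG", "VPNi"), c("CG", "LNi"), c("RS", "VPNi"), c("RS", "LNi"))
}

# Per-subject, per-timepoint correlation target in z-space
subject_fc_target <- function(base, group, tp, u, truth_fc, fx) {
  if (group != "TBI" || tp == "BL") return(base)
  Z <- fisher_z(base)
  apply_deficit <- function(Z, edge, d) {
    Z[edge[1], edge[2]] <- Z[edge[1], edge[2]] - d
    Z[edge[2], edge[1]] <- Z[edge[1], edge[2]]
    Z
  }
  edges <- cortical_ipsi_edges()
  if (tp == "W2") {
    for (e in edges)
      Z <- apply_deficit(Z, e, truth_fc$w2_ipsi_extra + rnorm(1, 0, fx$w2_edge_sd))
  } else if (tp == "M2") {
    coupled <- list(c("CG", "VPNi"), c("CG", "LNi"), c("RS", "LNi"))
    for (e in coupled)
      Z <- apply_deficit(Z, e, fx$m2_coupling * u + rnorm(1, 0, fx$m2_noise_sd))
    Z <- apply_deficit(Z, c("RS", "VPNi"),
                       rnorm(1, fx$m2_uncoupled_mean, fx$m2_uncoupled_sd))
  } else if (tp == "M6") {
    for (e in edges)
      Z <- apply_deficit(Z, e, rnorm(1, fx$m6_ipsi_mean, fx$m6_ipsi_sd))
  }
  R <- tanh(Z)
  diag(R) <- 1
  repair_correlation(R)
}

#' Generate a full synthetic cohort
#'
#' Draws every subject's multimodal data from the configured study design:
#' ROI fMRI time series with motion traces and ICA-QC counts at all four
#' timepoints, baseline/followup anatomical mean volumes with a focal
#' lesion (TBI only), dynamic PET at W2 for the PET subgroup (with the
#' configured number of faulty injections), per-ROI diffusion-weighted
#' signals at M2 and M6, and terminal nucleus/OD tables for the histology
#' subgroup, plus one shared manually-labeled training nucleus sample. TBI
#' subjects carry the configured ipsilateral effects through a latent
#' severity. Fully deterministic given `config$seed`; all latent values
#' live in each subject's `truth` slot, never in the observed tables.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_cohort`: list with `config`, `protocol`,
#'   `training_nuclei`, and `subjects`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  geom <- config$geometry
  fx <- config$fc_effects
  protocol <- default_dti_protocol()
  n <- config$n_tbi + config$n_sham
  groups <- c(rep("TBI", config$n_tbi), rep("SHAM", config$n_sham))
  ids <- sprintf("%s%02d", groups, c(seq_len(config$n_tbi), seq_len(config$n_sham)))

  with_seed(config$seed, {
    # --- design: PET and histology subgroups -------------------------------
    pd <- config$pet_design
    pet_tbi <- ids[groups == "TBI"][seq_len(min(pd$n_tbi, config$n_tbi))]
    pet_sham <- ids[groups == "SHAM"][seq_len(min(pd$n_sham, config$n_sham))]
    pet_ids <- c(pet_tbi, pet_sham)
    faulty_ids <- c(sample(pet_tbi, min(pd$faulty_tbi, max(length(pet_tbi) - 2, 0))),
                    sample(pet_sham, min(pd$faulty_sham, max(length(pet_sham) - 2, 0))))
    ok_pet <- setdiff(pet_ids, faulty_ids)
    hd <- config$histology_design
    ok_tbi <- intersect(ids[groups == "TBI"], ok_pet)
    ok_sham <- intersect(ids[groups == "SHAM"], ok_pet)
    histo_ids <- c(ok_tbi[seq_len(min(hd$n_tbi, length(ok_tbi)))],
                   ok_sham[seq_len(min(hd$n_sham, length(ok_sham)))])

    # manually-selected training nuclei (shared across the cohort)
    training <- generate_nuclei(966, 731, config$histology$nuclei_params)

    subjects <- vector("list", n)
    for (s in seq_len(n)) {
      id <- ids[s]; group <- groups[s]
      u <- if (group == "TBI")
        stats::rgamma(1, shape = config$severity$shape,
                      scale = config$severity$scale) else 0
      truth <- list(severity = u,
                    fc = list(w2_ipsi_extra = if (group == "TBI")
                      rnorm(1, fx$w2_ipsi_extra_mean, fx$w2_ipsi_extra_sd) else 0),
                    faulty_injection = id %in% faulty_ids)

      # --- fMRI + anatomy per timepoint ------------------------------------
      fmri <- list(); anat <- list()
      base_anat <- generate_lesion_volume(geom, config$lesion_spec)
      anat[["BL"]] <- base_anat$base
      for (tp in config$timepoints) {
        if (tp != "BL") {
          vol <- generate_lesion_volume(geom, config$lesion_spec,
                                        scanner_scale = exp(rnorm(1, 0, 0.1)))
          anat[[tp]] <- if (group == "TBI") vol$post else vol$base
        }
        C <- subject_fc_target(config$fc_target[[group]][[tp]], group, tp, u,
                               truth$fc, fx)
        series <- generate_roi_timeseries(C, config$n_volumes,
                                          config$ar_coefficient)
        motion <- generate_motion_trace(
          config$n_volumes, config$motion$spike_rate,
          config$motion$spike_amplitude_mm, config$motion$jitter_sd_mm)
        high <- runif(1) < config$qc$p_high_motion
        n_removed <- if (high)
          sample(config$qc$high_range[1]:config$qc$high_range[2], 1)
        else sample(config$qc$low_range[1]:config$qc$low_range[2], 1)
        motion_obs <- motion[, MOTION_COLS]
        attr(motion_obs, "spike_volumes") <- NULL  # ground truth stays in `truth`
        truth[[paste0("spikes_", tp)]] <- attr(motion, "spike_volumes")
        fmri[[tp]] <- list(series = series,
                           motion = motion_obs,
                           qc = tibble(n_removed = n_removed, n_components = 30L))
        truth$fc[[paste0("target_", tp)]] <- C
      }

      # --- PET at W2 --------------------------------------------------------
      pet <- NULL
      if (id %in% pet_ids) {
        pp <- config$pet
        roi_u <- c(VPNi = pp$base_thalamic, VPNc = pp$base_thalamic,
                   LNi = pp$base_thalamic, LNc = pp$base_thalamic,
                   RS = pp$base_cortical, CG = pp$base_cortical)
        roi_u <- roi_u + rnorm(6, 0, pp$subject_sd)
        if (group == "TBI") {
          roi_u["VPNi"] <- roi_u["VPNi"] + pp$uptake_coupling * u
          roi_u["LNi"] <- roi_u["LNi"] + pp$uptake_coupling * u
        }
        pet <- generate_pet_frames(geom, roi_u, pp$background,
                                   pp$voxel_sd, faulty = truth$faulty_injection)
        truth$pet_roi_u <- roi_u
      }

      # --- DTI at M2, M6 ----------------------------------------------------
      dti <- list()
      dd <- config$dti
      for (tp in c("M2", "M6")) {
        per_roi <- list()
        factors <- numeric(0)
        for (roi in config$roi_names) {
          f <- 1 + rnorm(1, 0, dd$subject_sd)
          if (group == "TBI" && roi %in% c("VPNi", "LNi"))
            f <- f + dd$md_coupling * u
          factors[roi] <- f
          # independent per-component jitter: FA varies across subjects
          # without being tied to the (isotropic) severity scaling
          lam <- sort(dd$lambda * f * (1 + rnorm(3, 0, dd$aniso_sd)),
                      decreasing = TRUE)
          per_roi[[roi]] <- generate_dti_signals(lam, protocol,
                                                 dd$n_voxels, dd$snr)$signals
        }
        dti[[tp]] <- per_roi
        truth[[paste0("dti_factor_", tp)]] <- factors
      }

      # --- terminal histology ----------------------------------------------
      histology <- NULL
      if (id %in% histo_ids) {
        hh <- config$histology
        area_mm2 <- hh$roi_area_um2 / 1e6
        rois <- c("VPNi", "VPNc", "LNi", "LNc", "RSi", "RSc")
        cd_ne <- setNames(rep(hh$cd_ne_base, 6), rois) + rnorm(6, 0, hh$cd_subject_sd)
        cd_gl <- setNames(rep(hh$cd_gl_base, 6), rois) + rnorm(6, 0, hh$cd_subject_sd)
        od <- setNames(rep(hh$od_base, 6), rois) + rnorm(6, 0, hh$od_sd)
        if (group == "TBI") {
          ipsi <- c("VPNi", "LNi")
          cd_ne[ipsi] <- cd_ne[ipsi] - hh$cd_ne_coupling * u
          cd_gl[ipsi] <- cd_gl[ipsi] + hh$cd_gl_coupling * u
          od[ipsi] <- od[ipsi] - hh$od_coupling * u
        }
        nuc_rows <- list(); od_rows <- list(); area_rows <- list()
        for (sec in 1:3) for (roi in rois) {
          n_ne <- stats::rpois(1, max(cd_ne[roi], 0) * area_mm2)
          n_gl <- stats::rpois(1, max(cd_gl[roi], 0) * area_mm2)
          tab <- generate_nuclei(n_ne, n_gl, hh$nuclei_params)
          nuc_rows[[length(nuc_rows) + 1]] <-
            tibble(section = sec, roi = roi, area = tab$area)  # truth label stripped
          area_rows[[length(area_rows) + 1]] <-
            tibble(section = sec, roi = roi, roi_area_um2 = hh$roi_area_um2)
          i_wm <- hh$i_wm + rnorm(1, 0, 0.02)
          i_bg <- hh$i_bg + rnorm(1, 0, 0.005)
          od_rows[[length(od_rows) + 1]] <-
            tibble(section = sec, roi = roi,
                   i_roi = i_bg + (od[roi] + rnorm(1, 0, 0.01)) * i_wm,
                   i_bg = i_bg, i_wm = i_wm)
        }
        histology <- list(nuclei = list_rbind(nuc_rows),
                          roi_areas = list_rbind(area_rows),
                          od = list_rbind(od_rows))
        truth$histology <- list(cd_ne = cd_ne, cd_gl = cd_gl, od = od)
      }

      subjects[[s]] <- list(id = id, group = group, truth = truth,
                            fmri = fmri, anat = anat, pet = pet, dti = dti,
                            histology = histology)
    }
    structure(list(config = config, protocol = protocol,
                   training_nuclei = training, subjects = subjects),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<synth_cohort: %d subjects (%d TBI, %d SHAM), seed %d>\n",
              length(x$subjects), sum(groups == "TBI"), sum(groups == "SHAM"),
              x$config$seed))
  invisible(x)
}

#' Cohort roster
#'
#' @param cohort A `synth_cohort`.
#' @return Tibble with `id`, `group`, and availability flags for PET and
#'   histology.
#' @export
cohort_roster <- function(cohort) {
  list_rbind(purrr::map(cohort$subjects, function(s)
    tibble(id = s$id, group = s$group,
           has_pet = !is.null(s$pet),
           has_histology = !is.null(s$histology))))
}
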