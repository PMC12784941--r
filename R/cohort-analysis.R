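# End-to-end cohort analysis: every observed modality is pushed through
# its quantification stage, collected into one tidy measurement table, and
# reduced to lateralization deltas and the delta-vs-uptake correlation
# matrix.

#' Analyze a synthetic (or equivalently structured) cohort
#'
#' Runs the full pipeline on each subject: lesion-artifact voxel exclusion
#' and per-ROI validity from the anatomical mean volumes; framewise
#' displacement, least-motion window selection, motion regression and
#' Fisher-z ROI connectivity (scans failing the ICA discard rule dropped);
#' PET frame summation, rostro-thoracic normalization and ROI uptake
#' (faulty-injection scans excluded by QC); log-linear tensor fits and
#' ROI-mean FA/MD/AD/RD; nuclear-area classification with thresholds
#' derived from the training sample, cell densities and corrected OD,
#' section-averaged. The per-animal measurements are then reduced to
#' ipsilateral-contralateral deltas and the Spearman delta-correlation
#' matrix against subacute uptake.
#'
#' @param cohort A [generate_cohort()] result.
#' @param max_removed ICA scan-discard threshold (default 20).
#' @param exclusion_factor Lesion-exclusion threshold multiplier (2.5).
#' @param max_excluded_fraction Per-ROI omission threshold (0.30).
#' @param window_length,exclude_first Connectivity window parameters.
#' @param alpha Per-cell significance level of the correlation matrix.
#' @return Object of class `cohort_analysis`: list with `measurements`
#'   (long tibble: animal, group, timepoint, metric, roi, value), `deltas`,
#'   `delta_corr` (a `delta_corr` tibble), `scan_qc`, `pet_qc`,
#'   `thresholds`.
#' @export
analyze_cohort <- function(cohort, max_removed = 20, exclusion_factor = 2.5,
                           max_excluded_fraction = 0.30,
                           window_length = 300, exclude_first = 300,
                           alpha = 0.05) {
  stopifnot(inherits(cohort, "synth_cohort"))
  geom <- cohort$config$geometry
  rois <- cohort$config$roi_names

  # Classification thresholds from the manually-labeled training sample
  tr <- cohort$training_nuclei
  thresholds <- derive_class_thresholds(split(tr$area, tr$true_class),
                                        k = 2)

  # Grand-mean baseline intensity across the cohort (normalized units)
  norm_bl <- purrr::map(cohort$subjects, function(s)
    global_normalize(s$anat[["BL"]], geom$brain_mask))
  gbm <- grand_baseline_mean(norm_bl, geom$brain_mask)

  meas <- list(); scan_qc <- list(); pet_qc <- list()
  for (k in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[k]]
    base_norm <- norm_bl[[k]]

    for (tp in names(s$fmri)) {
      # per-ROI validity from the lesion-artifact exclusion rule
      valid <- setNames(rep(TRUE, length(rois)), rois)
      if (tp != "BL") {
        post_norm <- global_normalize(s$anat[[tp]], geom$brain_mask)
        excl <- exclusion_mask(post_norm, base_norm, gbm, exclusion_factor)
        vt <- roi_validity(excl, geom$roi_masks, max_excluded_fraction)
        valid <- setNames(vt$valid, vt$roi)
      }
      qc <- apply_scan_discard_rule(s$fmri[[tp]]$qc, max_removed)
      scan_qc[[length(scan_qc) + 1]] <-
        mutate(qc, animal = s$id, group = s$group, timepoint = tp)
      if (qc$discarded) next
      res <- scan_connectivity(s$fmri[[tp]]$series, s$fmri[[tp]]$motion,
                               window_length = window_length,
                               exclude_first = exclude_first, valid = valid)
      z <- res$fc$z
      cx <- rep(c("CG", "RS"), each = 4)
      th <- rep(c("VPNi", "VPNc", "LNi", "LNc"), 2)
      meas[[length(meas) + 1]] <- tibble(
        animal = s$id, group = s$group, timepoint = tp,
        metric = paste0("fc_", cx), roi = th, value = z[cbind(cx, th)])
    }

    if (!is.null(s$pet)) {
      iqc <- pet_injection_qc(s$pet, geom$body_mask)
      pet_qc[[length(pet_qc) + 1]] <-
        mutate(iqc, animal = s$id, group = s$group)
      if (!iqc$faulty_injection) {
        summed <- sum_frames(s$pet, 15, 60)
        nu <- normalize_uptake(summed, geom$body_mask, geom$voxel_volume_ml)
        ut <- roi_uptake(nu$u, geom$roi_masks)
        meas[[length(meas) + 1]] <- mutate(ut, animal = s$id, group = s$group,
                                           timepoint = "W2", metric = "u_feppa") |>
          rename(value = "u_feppa") |>
          select("animal", "group", "timepoint", "metric", "roi", "value")
      }
    }

    for (tp in names(s$dti)) {
      for (roi in names(s$dti[[tp]])) {
        fit <- fit_tensor_loglinear(s$dti[[tp]][[roi]], cohort$protocol)
        sc <- tensor_scalars(tensor_eigenvalues(fit$tensors))
        mets <- c("fa", "md", "ad", "rd")
        meas[[length(meas) + 1]] <- tibble(
          animal = s$id, group = s$group, timepoint = tp,
          metric = mets, roi = roi,
          value = vapply(mets, function(m) mean(sc[[m]]), numeric(1)))
      }
    }

    if (!is.null(s$histology)) {
      cd <- cell_density_table(s$histology$nuclei, thresholds,
                               s$histology$roi_areas)
      cd$metric <- ifelse(cd$class == "neuronal", "cd_ne", "cd_gl")
      meas[[length(meas) + 1]] <- tibble(
        animal = s$id, group = s$group, timepoint = "M8",
        metric = cd$metric, roi = cd$roi, value = cd$cd)
      odt <- s$histology$od |>
        mutate(od = corrected_od(.data$i_roi, .data$i_bg, .data$i_wm)) |>
        group_by(.data$roi) |>
        summarise(value = mean(.data$od), .groups = "drop")
      meas[[length(meas) + 1]] <- tibble(
        animal = s$id, group = s$group, timepoint = "M8",
        metric = "od", roi = odt$roi, value = odt$value)
    }
  }

  measurements <- list_rbind(meas)
  deltas <- measurements |>
    filter(!(.data$metric %in% c("fc_CG", "fc_RS") & .data$timepoint == "BL")) |>
    lateralization_deltas()
  corr <- build_delta_correlation_matrix(deltas, nuclei = c("LN", "VPN"),
                                         alpha = alpha)
  structure(list(measurements = measurements, deltas = deltas,
                 delta_corr = corr,
                 scan_qc = list_rbind(scan_qc),
                 pet_qc = if (length(pet_qc)) list_rbind(pet_qc) else NULL,
                 thresholds = thresholds),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis: %d measurements, %d delta-correlation cells>\n",
              nrow(x$measurements), nrow(x$delta_corr)))
  invisible(x)
}

#' The coupling pattern a configuration generates
#'
#' The ground-truth counterpart of the delta-correlation matrix: which
#' (nucleus, metric, timepoint) cells are generated with severity coupling
#' to the subacute uptake. Diffusivities (MD, AD, RD) and the histological
#' metrics are coupled; FA is not (the ipsilateral eigenvalue change is an
#' isotropic scaling); connectivity is coupled only at M2, for CG in both
#' nuclei and RS in LN only.
#'
#' @param config A [synth_config()].
#' @return Tibble with `nucleus`, `metric`, `timepoint`, `coupled`.
#' @export
coupling_truth <- function(config) {
  rows <- list()
  add <- function(nucleus, metric, timepoint, coupled)
    rows[[length(rows) + 1]] <<- tibble(nucleus = nucleus, metric = metric,
                                        timepoint = timepoint, coupled = coupled)
  for (nuc in c("LN", "VPN")) {
    for (tp in c("M2", "M6")) {
      for (m in c("md", "ad", "rd")) add(nuc, m, tp, TRUE)
      add(nuc, "fa", tp, FALSE)
    }
    for (m in c("cd_ne", "cd_gl", "od")) add(nuc, m, "M8", TRUE)
    for (tp in c("W2", "M2", "M6")) {
      add(nuc, "fc_CG", tp, tp == "M2")
      add(nuc, "fc_RS", tp, tp == "M2" && nuc == "LN")
    }
  }
  list_rbind(rows)
}

#' Replicate end-to-end pattern recovery
#'
#' Generates and analyzes `n_reps` independent cohorts (seeds derived from
#' `seed`) and scores each replicate's delta-correlation significance
#' pattern against the generating coupling pattern.
#'
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed.
#' @param min_agreement Per-replicate agreement fraction counted as a
#'   recovered pattern (default 0.9).
#' @param config_fn Function taking a seed and returning a
#'   [synth_config()]; defaults to `synth_config(seed = seed)`.
#' @return List with `per_replicate` (tibble of agreement scores) and
#'   `recovery_rate` (fraction of replicates with agreement >=
#'   `min_agreement`).
#' @export
replicate_pattern_recovery <- function(n_reps = 20, seed = 1,
                                       min_agreement = 0.9,
                                       config_fn = NULL) {
  config_fn <- config_fn %||% function(s) synth_config(seed = s)
  truth <- coupling_truth(config_fn(seed))
  rows <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- config_fn(seed + r * 1000L)
    an <- suppressMessages(analyze_cohort(generate_cohort(cfg)))
    mutate(pattern_agreement(an$delta_corr, truth), replicate = r)
  })
  per_rep <- list_rbind(rows)
  list(per_replicate = per_rep,
       recovery_rate = mean(per_rep$agreement >= min_agreement))
}
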