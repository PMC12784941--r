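# Histological quantification: nuclear-area classification thresholds
# (mean +/- k SD per manually-selected training population), nucleus
# classification, cell densities CD = CC / ROI_area, corrected optical
# density OD = (I_ROI - I_BG) / I_WM, and 3-section averaging.

#' Derive nuclear-area classification thresholds
#'
#' For each manually-selected training population (typically `neuronal` and
#' `glial`), the class interval is the sample mean plus/minus `k` sample
#' standard deviations (n-1 denominator) of the nuclear areas.
#'
#' @param training_areas Named list of numeric vectors of nuclear areas
#'   (micrometers squared), one entry per class, each with at least 2
#'   nuclei.
#' @param k SD multiplier (default 2).
#' @return Tibble of class `class_thresholds` with columns `class`, `n`,
#'   `mean`, `sd`, `low`, `high`, `degenerate` (zero-width interval).
#' @export
#' @examples
#' derive_class_thresholds(list(neuronal = c(90, 120, 150, 174),
#'                              glial = c(15, 20, 25, 24)))
derive_class_thresholds <- function(training_areas, k = 2) {
  stopifnot(is.list(training_areas), !is.null(names(training_areas)))
  rows <- purrr::imap(training_areas, function(areas, cls) {
    if (length(areas) < 2)
      stop_thalcon("class '%s' has %d training nuclei; need at least 2",
                   cls, length(areas))
    if (any(areas <= 0)) stop_thalcon("non-positive area in class '%s'", cls)
    m <- mean(areas); s <- sd(areas)
    tibble(class = cls, n = length(areas), mean = m, sd = s,
           low = m - k * s, high = m + k * s, degenerate = s == 0)
  })
  out <- list_rbind(rows)
  if (any(out$degenerate))
    rlang::warn(sprintf("degenerate (zero-width) threshold interval for class: %s",
                        paste(out$class[out$degenerate], collapse = ", ")))
  structure(out, class = c("class_thresholds", class(out)), k = k)
}

#' The published nuclear-area thresholds
#'
#' Reference intervals for Nissl nuclear-area classification in the rat
#' thalamus: neuronal nuclei 52-215 um^2, glial nuclei 8-34 um^2
#' (mean +/- 2 SD of manually selected training populations).
#'
#' @return A `class_thresholds` tibble.
#' @export
reference_thresholds <- function() {
  out <- tibble(class = c("neuronal", "glial"),
                n = NA_integer_,
                mean = c(133.5, 21), sd = c(40.75, 6.5),
                low = c(52, 8), high = c(215, 34),
                degenerate = FALSE)
  structure(out, class = c("class_thresholds", class(out)), k = 2)
}

#' Classify detected nuclei by area
#'
#' Assigns each nucleus to the class whose interval (closed at both ends)
#' contains its area. Nuclei inside no interval are left unclassified
#' (`NA`) and excluded from both cell counts. If intervals overlap (cannot
#' happen with the published thresholds, handled for robustness), the class
#' with the smaller standardized distance `|area - mean| / sd` wins.
#'
#' @param nuclei Data frame with a numeric `area` column (um^2); other
#'   columns (section, roi, ...) pass through.
#' @param thresholds A `class_thresholds` tibble.
#' @return The input tibble with a `class` column added.
#' @export
classify_nuclei <- function(nuclei, thresholds) {
  stopifnot(is.data.frame(nuclei), "area" %in% names(nuclei))
  th <- as_tibble(thresholds)
  area <- nuclei$area
  inside <- vapply(seq_len(nrow(th)), function(i)
    area >= th$low[i] & area <= th$high[i], logical(length(area)))
  inside <- matrix(inside, nrow = length(area))
  zdist <- vapply(seq_len(nrow(th)), function(i)
    abs(area - th$mean[i]) / ifelse(th$sd[i] > 0, th$sd[i], Inf),
    numeric(length(area)))
  zdist <- matrix(zdist, nrow = length(area))
  zdist[!inside] <- Inf
  pick <- apply(zdist, 1, which.min)
  cls <- th$class[pick]
  cls[rowSums(inside) == 0] <- NA_character_
  mutate(as_tibble(nuclei), class = cls)
}

#' Cell density from a count and an ROI area
#'
#' `CD = CC / ROI_area`, reported in cells per mm^2. Areas supplied in
#' um^2 are converted (1 mm^2 = 1e6 um^2).
#'
#' @param count Cell count (non-negative).
#' @param roi_area ROI area, in the unit given by `area_unit`.
#' @param area_unit `"mm2"` (default) or `"um2"`.
#' @return Density in cells/mm^2 (vectorized).
#' @export
#' @examples
#' cell_density(100, 2)               # 50 cells/mm^2
#' cell_density(731, 10)              # 73.1
#' cell_density(50, 5e5, "um2")       # 100
cell_density <- function(count, roi_area, area_unit = c("mm2", "um2")) {
  area_unit <- match.arg(area_unit)
  if (any(count < 0)) stop_thalcon("cell count must be non-negative")
  if (any(roi_area <= 0)) stop_thalcon("ROI area must be positive")
  area_mm2 <- if (area_unit == "um2") roi_area / 1e6 else roi_area
  count / area_mm2
}

#' Corrected optical density
#'
#' `OD = (I_ROI - I_BG) / I_WM`, where `I_BG` is a cell/myelin-free
#' background reference and `I_WM` a high-myelin white-matter reference
#' taken from the same section. Negative values (ROI lighter than
#' background) are allowed but flagged with a warning.
#'
#' @param i_roi,i_bg,i_wm Raw optical densities (vectorized); `i_wm` must
#'   be positive.
#' @return Corrected OD (unitless).
#' @export
#' @examples
#' corrected_od(0.8, 0.2, 1.2)  # 0.5
corrected_od <- function(i_roi, i_bg, i_wm) {
  if (any(i_wm <= 0)) stop_thalcon("white-matter reference I_WM must be positive")
  od <- (i_roi - i_bg) / i_wm
  if (any(od < 0))
    rlang::warn(sprintf("%d corrected OD value(s) are negative (ROI lighter than background)",
                        sum(od < 0)))
  od
}

#' Average a metric across sections
#'
#' Arithmetic mean of per-section values. Three analysed sections are
#' expected; missing values are dropped with a warning, and an unexpected
#' section count is reported.
#'
#' @param values Numeric vector of per-section values.
#' @param expected_sections Expected number of sections (default 3).
#' @return Scalar mean.
#' @export
section_average <- function(values, expected_sections = 3) {
  ok <- !is.na(values)
  if (!any(ok)) stop_thalcon("no section values to average")
  if (sum(!ok) > 0)
    rlang::warn(sprintf("%d missing section value(s) omitted from the average", sum(!ok)))
  if (length(values) != expected_sections)
    rlang::inform(sprintf("averaging %d section(s); %d expected",
                          length(values), expected_sections))
  mean(values[ok])
}

#' Section-averaged cell densities per ROI
#'
#' Full Nissl quantification: classifies nuclei, counts neuronal and glial
#' cells per section and ROI, converts to densities with the per-section
#' ROI areas, and averages across sections.
#'
#' @param nuclei Data frame with columns `section`, `roi`, `area` (um^2).
#' @param thresholds A `class_thresholds` tibble.
#' @param roi_areas Data frame with columns `section`, `roi`,
#'   `roi_area_um2`.
#' @return Tibble with one row per ROI and class: `roi`, `class`,
#'   `cd` (cells/mm^2, section-averaged), `n_sections`.
#' @export
cell_density_table <- function(nuclei, thresholds, roi_areas) {
  labeled <- classify_nuclei(nuclei, thresholds)
  counts <- labeled |>
    filter(!is.na(.data$class)) |>
    dplyr::count(.data$section, .data$roi, .data$class, name = "cc")
  grid <- tidyr::expand_grid(
    dplyr::distinct(roi_areas, .data$section, .data$roi, .data$roi_area_um2),
    class = as_tibble(thresholds)$class)
  grid |>
    left_join(counts, by = c("section", "roi", "class")) |>
    mutate(cc = tidyr::replace_na(.data$cc, 0L),
           cd = cell_density(.data$cc, .data$roi_area_um2, "um2")) |>
    group_by(.data$roi, .data$class) |>
    summarise(cd = mean(.data$cd), n_sections = n(), .groups = "drop")
}
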