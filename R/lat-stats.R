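# Lateralization statistics: ipsilateral - contralateral deltas, Student /
# paired t-tests, Benjamini-Hochberg FDR, Spearman correlation, and the
# delta-vs-uptake correlation matrix.

#' Ipsilateral minus contralateral difference
#'
#' The lateralization index of a metric for one animal:
#' `delta = ipsi - contra`. Missing values propagate (never imputed), and
#' swapping hemisphere labels negates every delta. For functional
#' connectivity the inputs must be Fisher-z values.
#'
#' @param ipsi,contra Numeric vectors (recycled pairwise).
#' @return `ipsi - contra`.
#' @export
delta_metric <- function(ipsi, contra) ipsi - contra

#' Lateralization deltas from a long measurement table
#'
#' Pivots a tidy measurement table into per-animal deltas. ROI labels must
#' carry the hemisphere as a trailing `i` (ipsilateral) or `c`
#' (contralateral), e.g. `LNi`/`LNc`; the stem (`LN`) is the nucleus. Rows
#' whose ROI has no hemisphere-paired counterpart are dropped.
#'
#' @param data Long data frame with columns `animal`, `metric`, `roi`,
#'   `value`, and optionally `timepoint` and `group`.
#' @return Tibble with columns `animal` (plus `group`/`timepoint` if
#'   present), `nucleus`, `metric`, `delta`. Animals missing either side
#'   get `NA`.
#' @export
lateralization_deltas <- function(data) {
  stopifnot(all(c("animal", "metric", "roi", "value") %in% names(data)))
  d <- as_tibble(data) |>
    filter(grepl("[ic]$", .data$roi)) |>
    mutate(nucleus = sub("[ic]$", "", .data$roi),
           side = sub("^.*([ic])$", "\\1", .data$roi))
  keys <- intersect(c("animal", "group", "timepoint", "nucleus", "metric"), names(d))
  wide <- d |>
    select(dplyr::all_of(c(keys, "side", "value"))) |>
    tidyr::pivot_wider(names_from = "side", values_from = "value")
  if (!"i" %in% names(wide)) wide$i <- NA_real_
  if (!"c" %in% names(wide)) wide$c <- NA_real_
  wide |>
    mutate(delta = delta_metric(.data$i, .data$c)) |>
    select(-dplyr::any_of(c("i", "c")))
}

ttest_result <- function(label, estimate, statistic, df, p) {
  tibble(comparison = label, estimate = estimate, statistic = statistic,
         df = df, p_value = p)
}

#' Two-sample t-test
#'
#' Student's t-test (equal-variance pooled by default; Welch optional) for
#' a group difference, two-sided.
#'
#' @param x,y Numeric vectors, each with at least 2 non-missing values.
#' @param var_equal Pool variances (default `TRUE`).
#' @param label Comparison label carried into the result.
#' @return One-row tibble: `comparison`, `estimate` (mean of `x` minus mean
#'   of `y`), `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
two_sample_ttest <- function(x, y, var_equal = TRUE, label = "x vs y") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_thalcon("each group needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(ttest_result(label, 0, 0, length(x) + length(y) - 2, 1))
    stop_thalcon("zero pooled variance with unequal means; t is undefined")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  ttest_result(label, unname(diff(rev(tt$estimate))),
               unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Paired t-test
#'
#' One-sample t-test on within-animal differences, two-sided. Incomplete
#' pairs are dropped with a message. All-zero differences give `t = 0`,
#' `p = 1`; a constant nonzero difference has zero variance and is an
#' error.
#'
#' @param x,y Numeric vectors paired by position (animal).
#' @param label Comparison label.
#' @return One-row tibble as in [two_sample_ttest()]; `estimate` is the
#'   mean difference `x - y`.
#' @export
paired_ttest <- function(x, y, label = "paired x vs y") {
  if (length(x) != length(y)) stop_thalcon("paired vectors must have equal length")
  ok <- complete.cases(x, y)
  if (sum(!ok) > 0)
    rlang::inform(sprintf("dropping %d incomplete pair(s)", sum(!ok)))
  d <- x[ok] - y[ok]
  if (length(d) < 2) stop_thalcon("need at least 2 complete pairs")
  if (sd(d) == 0) {
    if (all(d == 0)) return(ttest_result(label, 0, 0, length(d) - 1, 1))
    stop_thalcon("constant nonzero paired difference: zero variance, t undefined")
  }
  tt <- t.test(d)
  ttest_result(label, unname(tt$estimate), unname(tt$statistic),
               unname(tt$parameter), tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement; order
#' preserving. `NA` p-values yield `NA` q-values without affecting the
#' family size.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_thalcon("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Annotate a results table with q-values and significance flags
#'
#' Applies [bh_fdr()] to the `p_value` column of one analysis table (the
#' FDR family), adding `q_value` and logical `sig_p` / `sig_q` flags at the
#' given level.
#'
#' @param results Data frame with a `p_value` column.
#' @param alpha Significance level (default 0.05).
#' @return The tibble with `q_value`, `sig_p`, `sig_q` added.
#' @export
adjust_family <- function(results, alpha = 0.05) {
  stopifnot("p_value" %in% names(results))
  mutate(as_tibble(results),
         q_value = bh_fdr(.data$p_value),
         sig_p = !is.na(.data$p_value) & .data$p_value < alpha,
         sig_q = !is.na(.data$q_value) & .data$q_value < alpha)
}

mid_rank_rho <- function(x, y) {
  cor(rank(x), rank(y))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' or an exact permutation p-value (`p_method = "permutation"`, enumerated
#' for n <= 8). Pairwise-complete observations are used; a constant vector
#' gives an undefined correlation, returned as `NA` with a warning. The
#' least-squares regression line of `y` on `x` is included for scatter
#' overlays.
#'
#' @param x,y Numeric vectors.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @return One-row tibble: `rho`, `p_value`, `n`, `slope`, `intercept`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_thalcon("need at least 4 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("constant vector: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  slope = NA_real_, intercept = NA_real_))
  }
  rho <- mid_rank_rho(x, y)
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8)
      stop_thalcon("exact permutation p-value enumerated only for n <= 8; use p_method = 't'")
    perms <- permutations_of(n)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(idx) mid_rank_rho(x, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  tibble(rho = rho, p_value = p, n = n,
         slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Delta-correlation matrix against subacute uptake
#'
#' Builds the nucleus-by-metric-by-timepoint grid of Spearman correlations
#' between the lateralized subacute tracer uptake (`delta` of the
#' `uptake_metric`) and every other lateralized metric, across animals
#' (both injury and sham groups). Cells with fewer than `min_n` complete
#' pairs are returned missing.
#'
#' @param deltas Long tibble of lateralization deltas with columns
#'   `animal`, `nucleus`, `metric`, `timepoint`, `delta` (see
#'   [lateralization_deltas()]).
#' @param nuclei Nuclei to analyse (default `c("LN", "VPN")`).
#' @param uptake_metric Name of the uptake metric (default `"u_feppa"`).
#' @param alpha Per-cell significance level on the unadjusted p (default
#'   0.05).
#' @param min_n Minimum complete pairs per cell (default 4).
#' @return Tibble of class `delta_corr`: `nucleus`, `metric`, `timepoint`,
#'   `n`, `rho`, `p_value`, `significant`, `slope`, `intercept`.
#' @export
build_delta_correlation_matrix <- function(deltas, nuclei = c("LN", "VPN"),
                                           uptake_metric = "u_feppa",
                                           alpha = 0.05, min_n = 4) {
  stopifnot(all(c("animal", "nucleus", "metric", "delta") %in% names(deltas)))
  if (!"timepoint" %in% names(deltas)) deltas$timepoint <- NA_character_
  up <- deltas |>
    filter(.data$metric == uptake_metric, .data$nucleus %in% nuclei) |>
    select("animal", "nucleus", du = "delta") |>
    filter(!is.na(.data$du))
  if (nrow(up) < min_n)
    stop_thalcon("uptake deltas available for %d animal(s); need >= %d",
                 nrow(dplyr::distinct(up, .data$animal)), min_n)
  cells <- deltas |>
    filter(.data$metric != uptake_metric, .data$nucleus %in% nuclei) |>
    inner_join(up, by = c("animal", "nucleus"))
  grid <- cells |>
    dplyr::distinct(.data$nucleus, .data$metric, .data$timepoint)
  rows <- purrr::pmap(grid, function(nucleus, metric, timepoint) {
    sub <- cells[cells$nucleus == nucleus & cells$metric == metric &
                   (cells$timepoint == timepoint |
                      (is.na(cells$timepoint) & is.na(timepoint))), ]
    sub <- sub[complete.cases(sub$delta, sub$du), ]
    base <- tibble(nucleus = nucleus, metric = metric, timepoint = timepoint,
                   n = nrow(sub))
    if (nrow(sub) < min_n) {
      rlang::inform(sprintf("cell %s/%s/%s has n = %d < %d: returned missing",
                            nucleus, metric, timepoint %||% "-", nrow(sub), min_n))
      return(mutate(base, rho = NA_real_, p_value = NA_real_,
                    significant = NA, slope = NA_real_, intercept = NA_real_))
    }
    sc <- spearman_cor(sub$du, sub$delta)
    mutate(base, rho = sc$rho, p_value = sc$p_value,
           significant = !is.na(sc$p_value) & sc$p_value < alpha,
           slope = sc$slope, intercept = sc$intercept)
  })
  out <- list_rbind(rows) |> arrange(.data$nucleus, .data$metric, .data$timepoint)
  structure(out, class = c("delta_corr", class(out)), alpha = alpha)
}

#' Agreement between an observed and a generating significance pattern
#'
#' Compares the per-cell significance of a [build_delta_correlation_matrix()]
#' result with a ground-truth coupling pattern, cell by cell.
#'
#' @param corr A `delta_corr` tibble.
#' @param truth Data frame with columns `nucleus`, `metric`, `timepoint`
#'   and logical `coupled`.
#' @return One-row tibble: `n_cells`, `n_agree`, `agreement` (fraction),
#'   `coupled_detected` (fraction of truly coupled cells significant),
#'   `uncoupled_flagged` (fraction of uncoupled cells significant).
#' @export
pattern_agreement <- function(corr, truth) {
  j <- inner_join(as_tibble(corr), as_tibble(truth),
                  by = c("nucleus", "metric", "timepoint"))
  if (nrow(j) == 0) stop_thalcon("no cells in common between result and truth")
  obs <- j$significant
  obs[is.na(obs)] <- FALSE
  tibble(n_cells = nrow(j),
         n_agree = sum(obs == j$coupled),
         agreement = mean(obs == j$coupled),
         coupled_detected = mean(obs[j$coupled]),
         uncoupled_flagged = mean(obs[!j$coupled]))
}
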