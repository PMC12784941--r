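# Synthetic-data generators: determinism, calibration, and ground-truth
# separation.

test_that("generators are deterministic given a seed", {
  C <- default_fc_target()
  s1 <- generate_roi_timeseries(C, 100, seed = 5)
  s2 <- generate_roi_timeseries(C, 100, seed = 5)
  expect_identical(s1, s2)

  m1 <- generate_motion_trace(200, seed = 9)
  m2 <- generate_motion_trace(200, seed = 9)
  expect_identical(m1, m2)

  n1 <- generate_nuclei(50, 30, seed = 4)
  n2 <- generate_nuclei(50, 30, seed = 4)
  expect_identical(n1, n2)

  cfg <- synth_config(n_tbi = 3, n_sham = 2, n_volumes = 600, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("an identity correlation target yields near-zero mean sample FC", {
  C <- diag(6)
  dimnames(C) <- list(roi_names(), roi_names())
  set.seed(100)
  offdiag <- replicate(50, {
    s <- generate_roi_timeseries(C, 300)
    r <- cor(as.matrix(s[, -1]))
    mean(r[lower.tri(r)])
  })
  expect_lt(abs(mean(offdiag)), 0.05)

  # and every |r| stays below the n = 300 Fisher bound
  set.seed(101)
  s <- generate_roi_timeseries(C, 300, ar_coefficient = 0)
  r <- cor(as.matrix(s[, -1]))
  expect_lt(max(abs(r[lower.tri(r)])), 0.3)
})

test_that("a strong off-diagonal target is recovered in sample correlation", {
  C <- matrix(c(1, 0.8, 0.8, 1), 2)
  set.seed(55)
  s <- generate_roi_timeseries(C, 300)
  r <- cor(s[[2]], s[[3]])
  expect_gt(r, 0.6)
  expect_lt(r, 0.95)
})

test_that("white-noise series have near-zero lag-1 autocorrelation", {
  C <- diag(2)
  set.seed(66)
  s <- generate_roi_timeseries(C, 500, ar_coefficient = 0)
  ac <- stats::acf(s[[2]], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.15)
})

test_that("non-PSD correlation targets are rejected with a diagnostic", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(generate_roi_timeseries(bad, 100), "positive semidefinite")
  expect_error(check_psd_name <- generate_roi_timeseries(diag(3) * 2, 100),
               "unit diagonal")
})

test_that("motion traces have calibrated spikes and exact zero-motion limit", {
  zero <- generate_motion_trace(100, spike_rate = 0, jitter_sd_mm = 0, seed = 1)
  fd <- framewise_displacement(zero)
  expect_equal(fd$fd, rep(0, 100))

  set.seed(2)
  counts <- replicate(30, {
    m <- generate_motion_trace(1500, spike_rate = 0.01)
    length(attr(m, "spike_volumes"))
  })
  band <- qbinom(c(0.005, 0.995), 1500, 0.01)
  expect_gte(mean(counts), band[1])
  expect_lte(mean(counts), band[2])
})

test_that("a single spike inside the admissible region steers the window away", {
  m <- generate_motion_trace(900, spike_rate = 0.002, spike_amplitude_mm = 0.2,
                             jitter_sd_mm = 0.005, seed = 7)
  sp <- attr(m, "spike_volumes")
  expect_length(sp, 1)
  expect_true(sp >= 301 && sp <= 600)
  w <- select_least_motion_window(framewise_displacement(m))
  vols <- seq(w$start, w$start + w$length - 1)
  expect_false(sp %in% vols)
  # and the choice matches the exhaustive oracle
  or <- oracle_window(framewise_displacement(m)$fd)
  expect_equal(w$start, or$start)
})

test_that("generated nuclei have separable class intervals and honest edge cases", {
  tab <- generate_nuclei(966, 731, seed = 12)
  th <- derive_class_thresholds(split(tab$area, tab$true_class))
  ne <- th[th$class == "neuronal", ]; gl <- th[th$class == "glial", ]
  expect_gt(ne$low, gl$high)   # non-overlapping intervals
  expect_true(all(tab$area > 0))

  only_glial <- generate_nuclei(0, 25, seed = 3)
  expect_identical(unique(only_glial$true_class), "glial")
  expect_equal(nrow(only_glial), 25)
})

test_that("the default cohort reproduces the study design counts", {
  co <- get_default_cohort()
  roster <- cohort_roster(co)
  expect_equal(nrow(roster), 47)
  expect_equal(sum(roster$group == "TBI"), 36)
  expect_equal(sum(roster$group == "SHAM"), 11)
  # PET subgroup: 34 scanned
  expect_equal(sum(roster$has_pet), 34)
  expect_equal(sum(roster$has_pet & roster$group == "TBI"), 25)
  # histology subgroup: 20 (14 TBI, 6 SHAM)
  expect_equal(sum(roster$has_histology), 20)
  expect_equal(sum(roster$has_histology & roster$group == "TBI"), 14)
  # faulty injections: 7 TBI + 1 SHAM
  faulty <- sapply(co$subjects, function(s) isTRUE(s$truth$faulty_injection))
  groups <- sapply(co$subjects, `[[`, "group")
  expect_equal(sum(faulty & groups == "TBI"), 7)
  expect_equal(sum(faulty & groups == "SHAM"), 1)
})

test_that("observed cohort tables carry no ground-truth fields", {
  co <- get_default_cohort()
  s <- co$subjects[[1]]
  expect_false("true_class" %in% names(s$histology$nuclei %||% tibble::tibble()))
  for (tp in names(s$fmri)) {
    expect_null(attr(s$fmri[[tp]]$motion, "spike_volumes"))
    expect_false(any(grepl("true|severity", names(s$fmri[[tp]]$series))))
  }
  # truth lives in its own slot
  expect_true(is.numeric(s$truth$severity))
})

test_that("TBI subjects carry the configured ipsilateral effects in truth", {
  co <- get_default_cohort()
  tbi <- Filter(function(s) s$group == "TBI" && !is.null(s$pet) &&
                  !s$truth$faulty_injection, co$subjects)
  up_delta <- sapply(tbi, function(s)
    s$truth$pet_roi_u[["LNi"]] - s$truth$pet_roi_u[["LNc"]])
  sev <- sapply(tbi, function(s) s$truth$severity)
  expect_gt(mean(up_delta), 0)
  expect_gt(cor(up_delta, sev), 0.8)
  dti_f <- sapply(tbi, function(s) s$truth$dti_factor_M2[["LNi"]] -
                    s$truth$dti_factor_M2[["LNc"]])
  expect_gt(cor(dti_f, sev), 0.8)
})
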