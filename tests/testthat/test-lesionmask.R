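# Lesion-artifact voxel exclusion and per-ROI validity.

test_that("mean volume is the per-voxel average over time", {
  d <- c(4, 4, 3)
  s <- array(2, c(d, 5))
  expect_equal(mean_volume(s), array(2, d))

  two <- array(c(rep(0, prod(d)), rep(2, prod(d))), c(d, 2))
  expect_equal(mean_volume(two), array(1, d))

  set.seed(2)
  r <- array(rnorm(prod(d) * 7), c(d, 7))
  expect_equal(mean_volume(r), apply(r, 1:3, mean), tolerance = 1e-12)
})

test_that("global normalization divides by the in-mask mean and is scale invariant", {
  d <- c(5, 5, 4)
  mask <- array(FALSE, d); mask[2:4, 2:4, 2:3] <- TRUE
  vol <- array(5, d)
  norm <- global_normalize(vol, mask)
  expect_equal(norm[mask], rep(1, sum(mask)))

  set.seed(3)
  vol2 <- array(runif(prod(d), 1, 10), d)
  expect_equal(global_normalize(vol2 * 7, mask), global_normalize(vol2, mask))
  expect_equal(mean(global_normalize(vol2, mask)[mask]), 1, tolerance = 1e-12)

  expect_error(global_normalize(array(0, d), mask), "positive")
})

test_that("exclusion threshold is strict at 2.5x the grand baseline mean", {
  d <- c(6, 6, 4)
  base <- array(1, d)
  post <- base
  expect_false(any(exclusion_mask(post, base, 1, 2.5)))

  post[3, 3, 2] <- 1 + 2.6          # exceeds 2.5 x 1
  excl <- exclusion_mask(post, base, 1, 2.5)
  expect_identical(which(excl), which(array(seq_len(prod(d)), d) ==
                                        (3 + (3 - 1) * 6 + (2 - 1) * 36)))

  post2 <- base; post2[2, 2, 2] <- 1 + 2.5   # exactly at threshold: retained
  expect_false(any(exclusion_mask(post2, base, 1, 2.5)))

  expect_error(exclusion_mask(array(1, c(2, 2, 2)), base, 1), "grids")
})

test_that("ROI validity applies the strict more-than-30-percent rule", {
  d <- c(10, 10, 1)
  roi <- array(FALSE, d); roi[1:10, 1:10, 1] <- TRUE   # 100 voxels
  make_excl <- function(k) {
    e <- array(FALSE, d); e[seq_len(k)] <- TRUE; e
  }
  v31 <- roi_validity(make_excl(31), list(R = roi))
  expect_false(v31$valid)
  v30 <- roi_validity(make_excl(30), list(R = roi))
  expect_true(v30$valid)
  expect_equal(v30$excluded_fraction, 0.30)
  v0 <- roi_validity(make_excl(0), list(R = roi))
  expect_true(v0$valid)
})

test_that("the excluded set grows monotonically as the factor decreases", {
  set.seed(9)
  d <- c(8, 8, 4)
  base <- array(runif(prod(d), 0.5, 1.5), d)
  post <- base + array(rnorm(prod(d), 0, 1.2), d)
  prev <- exclusion_mask(post, base, 1, 3.5)
  for (f in c(2.5, 1.5, 0.5)) {
    cur <- exclusion_mask(post, base, 1, f)
    expect_true(all(cur[prev]))   # every previously excluded voxel stays excluded
    prev <- cur
  }
})

test_that("scale invariance: rescaling a raw scan leaves the exclusion mask unchanged", {
  geom <- synth_geometry()
  vols <- generate_lesion_volume(geom, seed = 5)
  base_n <- global_normalize(vols$base, geom$brain_mask)
  post_n1 <- global_normalize(vols$post, geom$brain_mask)
  post_n2 <- global_normalize(vols$post * 3.1, geom$brain_mask)
  expect_identical(exclusion_mask(post_n1, base_n, 1),
                   exclusion_mask(post_n2, base_n, 1))
})

test_that("a generated focal lesion is recovered with Dice >= 0.8", {
  geom <- synth_geometry()
  vols <- generate_lesion_volume(geom, lesion_spec = list(intensity_change = 3.5,
                                                          noise_sd = 0.05),
                                 seed = 21)
  base_n <- global_normalize(vols$base, geom$brain_mask)
  post_n <- global_normalize(vols$post, geom$brain_mask)
  excl <- exclusion_mask(post_n, base_n, 1, 2.5)
  dice <- 2 * sum(excl & vols$truth_lesion) /
    (sum(excl) + sum(vols$truth_lesion))
  expect_gte(dice, 0.8)
})

test_that("excluded voxels are dropped from retained-ROI mean time series", {
  d <- c(4, 4, 2)
  roi <- array(FALSE, d); roi[1:2, 1, 1] <- TRUE   # two voxels
  s <- array(0, c(d, 3))
  s[1, 1, 1, ] <- c(1, 2, 3)
  s[2, 1, 1, ] <- c(11, 12, 13)
  excl <- array(FALSE, d); excl[2, 1, 1] <- TRUE
  ts_all <- roi_mean_timeseries(s, list(R = roi))
  ts_dropped <- roi_mean_timeseries(s, list(R = roi), excluded = excl)
  expect_equal(ts_all$R, c(6, 7, 8))
  expect_equal(ts_dropped$R, c(1, 2, 3))
})
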