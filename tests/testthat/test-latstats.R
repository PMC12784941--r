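# Delta metrics, t-tests, BH-FDR, Spearman correlation and the
# delta-correlation matrix.

test_that("delta is ipsi minus contra and antisymmetric under hemisphere swap", {
  expect_equal(delta_metric(3, 3), 0)
  expect_equal(delta_metric(5, 2), 3)
  expect_true(is.na(delta_metric(NA, 2)))

  d <- tibble::tibble(animal = rep(c("a1", "a2"), each = 2),
                      metric = "md",
                      roi = rep(c("LNi", "LNc"), 2),
                      value = c(4, 1, 2, 5))
  del <- lateralization_deltas(d)
  expect_equal(del$delta, c(3, -3))

  swapped <- d
  swapped$roi <- ifelse(swapped$roi == "LNi", "LNc", "LNi")
  expect_equal(lateralization_deltas(swapped)$delta, -del$delta)
})

test_that("two-sample t matches the pooled-variance closed form", {
  res <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("paired t works on differences and flags degenerate inputs", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  expect_equal(paired_ttest(x, y)$p_value, 1)

  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "constant nonzero")

  set.seed(14)
  a <- rnorm(10); b <- rnorm(10)
  res <- paired_ttest(a, b)
  oracle <- t.test(a - b)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)

  expect_message(paired_ttest(c(1, 2, NA, 4), c(2, 1, 5, 0)), "incomplete")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # exhaustive small grid over all tuples of length <= 4
  grid <- c(0.004, 0.01, 0.2, 0.8)
  for (len in 1:4) {
    tuples <- as.matrix(expand.grid(rep(list(grid), len)))
    for (k in seq_len(nrow(tuples))) {
      p <- as.numeric(tuples[k, ])
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  # random longer vectors
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("q-values never fall below p and flags are consistent", {
  set.seed(54)
  res <- adjust_family(tibble::tibble(p_value = runif(20, 0, 0.2)))
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$q_value <= 1))
  expect_identical(res$sig_p, res$p_value < 0.05)
  expect_identical(res$sig_q, res$q_value < 0.05)
})

test_that("Spearman correlation equals the mid-rank oracle and handles ties", {
  x <- 1:8
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x)^3)$rho, -1)

  xt <- c(1, 2, 2, 3, 4, 4, 4, 9)
  yt <- c(3, 1, 4, 4, 2, 8, 8, 5)
  expect_equal(spearman_cor(xt, yt)$rho, oracle_spearman_rho(xt, yt),
               tolerance = 1e-12)
  # and against the independent stats implementation
  expect_equal(spearman_cor(xt, yt)$rho,
               unname(cor.test(xt, yt, method = "spearman",
                               exact = FALSE)$estimate),
               tolerance = 1e-12)

  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:3, 1:3), "at least 4")

  # permutation p agrees with the t approximation to first order
  set.seed(19)
  x2 <- rnorm(7); y2 <- 0.8 * x2 + rnorm(7, 0, 0.5)
  pt_ <- spearman_cor(x2, y2)$p_value
  pp <- spearman_cor(x2, y2, p_method = "permutation")$p_value
  expect_lt(abs(pt_ - pp), 0.07)
})

test_that("the delta-correlation matrix recovers a noiseless coupling", {
  set.seed(8)
  n <- 12
  du <- rnorm(n, 1, 0.5)
  deltas <- dplyr::bind_rows(
    tibble::tibble(animal = paste0("a", 1:n), nucleus = "LN",
                   metric = "u_feppa", timepoint = "W2", delta = du),
    tibble::tibble(animal = paste0("a", 1:n), nucleus = "LN",
                   metric = "md", timepoint = "M2", delta = 2 * du))
  corr <- build_delta_correlation_matrix(deltas, nuclei = "LN")
  expect_equal(corr$rho, 1)
  expect_true(corr$significant)
  expect_equal(corr$slope, 2, tolerance = 1e-9)

  # a cell with fewer than 4 pairs is reported missing
  small <- deltas[deltas$metric == "u_feppa" | deltas$animal %in% paste0("a", 1:3), ]
  expect_message(
    corr2 <- build_delta_correlation_matrix(small, nuclei = "LN"), "n = 3")
  expect_true(is.na(corr2$rho))
})

test_that("relabeling hemispheres leaves |rho| unchanged", {
  set.seed(23)
  n <- 15
  du <- rnorm(n); dm <- 0.7 * du + rnorm(n, 0, 0.4)
  mk <- function(sign) dplyr::bind_rows(
    tibble::tibble(animal = paste0("a", 1:n), nucleus = "VPN",
                   metric = "u_feppa", timepoint = "W2", delta = sign * du),
    tibble::tibble(animal = paste0("a", 1:n), nucleus = "VPN",
                   metric = "rd", timepoint = "M6", delta = sign * dm))
  c1 <- build_delta_correlation_matrix(mk(1), nuclei = "VPN")
  c2 <- build_delta_correlation_matrix(mk(-1), nuclei = "VPN")
  expect_equal(abs(c1$rho), abs(c2$rho), tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})

test_that("t-test power increases with simulated effect size", {
  set.seed(61)
  power_at <- function(delta) {
    mean(replicate(400, {
      two_sample_ttest(rnorm(10, delta), rnorm(10))$p_value < 0.05
    }))
  }
  p0 <- power_at(0); p1 <- power_at(1); p2 <- power_at(2)
  expect_lt(p0, p1)
  expect_lt(p1, p2)
  expect_gt(p2, 0.9)
})
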