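# Framewise displacement, window selection, discard accounting, motion
# regression and ROI connectivity.

make_motion <- function(m) {
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  tibble::as_tibble(m)
}

test_that("framewise displacement matches its definition", {
  # constant parameters: no displacement at all
  m <- make_motion(matrix(0.3, 10, 6))
  fd <- framewise_displacement(m)
  expect_equal(fd$fd, rep(0, 10))
  expect_equal(glance(fd)$mean_fd, 0)
  expect_equal(glance(fd)$max_fd, 0)

  # a single 0.1 mm translation step at volume k displaces only volume k
  m2 <- matrix(0, 20, 6)
  m2[8:20, 1] <- 0.1
  fd2 <- framewise_displacement(make_motion(m2))
  expect_equal(fd2$fd[8], 0.1)
  expect_equal(fd2$fd[-8], rep(0, 19))

  # random trace against the brute-force oracle
  set.seed(41)
  m3 <- matrix(rnorm(60 * 6, sd = 0.05), 60, 6)
  fd3 <- framewise_displacement(make_motion(m3), rotation_radius_mm = 5)
  expect_equal(fd3$fd, oracle_fd(m3, 5), tolerance = 1e-12)

  # non-finite parameter is reported with its volume index
  m4 <- matrix(0, 5, 6); m4[3, 2] <- NA
  expect_error(framewise_displacement(make_motion(m4)), "volume 3")
})

test_that("least-motion window selection minimises mean FD with earliest-tie rule", {
  # all-equal FD: tie broken at the earliest admissible start
  fd <- tibble::tibble(volume = 1:700, fd = rep(0.02, 700))
  w <- select_least_motion_window(fd)
  expect_equal(w$start, 301L)

  # a large spike is avoided
  fdv <- rep(0.01, 900); fdv[450] <- 5
  w2 <- select_least_motion_window(tibble::tibble(volume = 1:900, fd = fdv))
  vols <- seq(w2$start, w2$start + w2$length - 1)
  expect_false(450 %in% vols)

  # random traces agree with the exhaustive oracle
  set.seed(7)
  for (i in 1:50) {
    fdv <- abs(rnorm(750, 0.03, 0.02))
    w3 <- select_least_motion_window(fdv, 300, 300)
    or <- oracle_window(fdv, 300, 300)
    expect_identical(w3$start, as.integer(or$start))
    expect_equal(w3$mean_fd, or$mean_fd, tolerance = 1e-12)
  }

  expect_error(select_least_motion_window(rep(0, 599)), "at least 600")
})

test_that("ICA scan-discard rule is strict at the component threshold", {
  qc <- apply_scan_discard_rule(
    tibble::tibble(n_removed = c(21L, 20L, 0L), n_components = 30L))
  expect_equal(qc$discarded, c(TRUE, FALSE, FALSE))
  expect_error(
    apply_scan_discard_rule(tibble::tibble(n_removed = 31, n_components = 30)),
    "exceeds")
})

test_that("scan retention and attrition accounting are exact", {
  qc <- tibble::tibble(discarded = rep(c(FALSE, TRUE), c(172, 16)))
  ret <- scan_retention(qc)
  expect_equal(ret$n_retained, 172)
  expect_equal(ret$discarded_percent, 100 * 16 / 188)
  expect_equal(attrition_rate(13, 59), 100 * 13 / 59)
  expect_error(attrition_rate(5, 4), "exceeds")
})

test_that("motion regression produces residuals orthogonal to the design", {
  set.seed(11)
  n <- 700
  m <- matrix(rnorm(n * 6, sd = 0.02), n, 6)
  motion <- make_motion(m)
  win <- select_least_motion_window(
    framewise_displacement(motion), 300, 300)
  vols <- seq(win$start, win$start + 299)

  # a series that is exactly a linear combination of the regressors
  y_exact <- 2 + m %*% c(1, -3, 0.5, 10, 0, 4)
  res <- regress_motion(tibble::tibble(a = as.numeric(y_exact)), motion, win)
  expect_lt(sqrt(mean(res$a^2)), 1e-8)

  # zero motion: residuals are the demeaned series (collinear columns dropped)
  y <- rnorm(n)
  expect_warning(
    res0 <- regress_motion(tibble::tibble(a = y),
                           make_motion(matrix(0, n, 6)), win),
    "collinear")
  expect_equal(res0$a, y[vols] - mean(y[vols]), tolerance = 1e-12)

  # random case: residual-regressor inner products vanish (normal equations)
  y2 <- rnorm(n)
  res2 <- regress_motion(tibble::tibble(a = y2), motion, win)
  X <- cbind(1, m[vols, ])
  expect_lt(max(abs(crossprod(X, res2$a))), 1e-8)
})

test_that("ROI connectivity handles perfect, inverse and missing correlation", {
  set.seed(3)
  a <- rnorm(300)
  series <- tibble::tibble(A = a, B = a, C = -a, D = rnorm(300))
  fc <- roi_connectivity(series)
  expect_equal(fc$r["A", "B"], 1)
  expect_equal(fc$z["A", "B"], atanh(1 - 1e-7))
  expect_equal(fc$r["A", "C"], -1)
  expect_equal(fc$z["A", "C"], -atanh(1 - 1e-7))
  # symmetry
  expect_equal(fc$r, t(fc$r))
  expect_equal(fc$z, t(fc$z))

  # invalid ROI entries are missing, not zero
  fc2 <- roi_connectivity(series, valid = c(A = TRUE, B = FALSE, C = TRUE, D = TRUE))
  expect_true(all(is.na(fc2$r["B", ])))
  expect_false(anyNA(fc2$r[c("A", "C", "D"), c("A", "C", "D")]))

  # zero-variance series flagged missing
  series$E <- 1
  expect_message(fc3 <- roi_connectivity(series), "zero-variance")
  expect_true(all(is.na(fc3$r["E", ])))

  # tidy view covers each unordered pair once
  td <- tidy(fc)
  expect_equal(nrow(td), choose(4, 2))
})

test_that("sample correlation of generated series falls in the Fisher interval", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  set.seed(15)
  series <- generate_roi_timeseries(C, 300, ar_coefficient = 0)
  r <- cor(series[[2]], series[[3]])
  expect_gt(r, 0.44)  # 99% Fisher-z interval at n = 300 around 0.6
  expect_lt(r, 0.72)
})

test_that("Fisher z is odd, monotone, and clipped at |r| = 1", {
  r <- seq(-0.999, 0.999, length.out = 101)
  z <- fisher_z(r)
  expect_equal(z, -fisher_z(-r))
  expect_true(all(diff(z) > 0))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
})

test_that("permuting ROI order permutes the connectivity matrix consistently", {
  set.seed(8)
  y <- matrix(rnorm(300 * 4), 300, 4)
  colnames(y) <- c("A", "B", "C", "D")
  fc1 <- roi_connectivity(y)
  perm <- c("C", "A", "D", "B")
  fc2 <- roi_connectivity(y[, perm])
  expect_equal(fc2$r, fc1$r[perm, perm])
})
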