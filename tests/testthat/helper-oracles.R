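# Independent brute-force oracles used across tests. These deliberately use
# naive direct computation, not the package's algorithms.

oracle_fd <- function(m, radius = 5) {
  n <- nrow(m)
  fd <- numeric(n)
  for (t in 2:n) {
    fd[t] <- sum(abs(m[t, 1:3] - m[t - 1, 1:3])) +
      radius * sum(abs(m[t, 4:6] - m[t - 1, 4:6]))
  }
  fd
}

oracle_window <- function(fd, len = 300, skip = 300) {
  starts <- (skip + 1):(length(fd) - len + 1)
  means <- sapply(starts, function(s) mean(fd[s:(s + len - 1)]))
  list(start = starts[which.min(means)], mean_fd = min(means))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- sapply(seq_len(m), function(i) min(m * ps[i:m] / (i:m)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# mid-ranks computed by explicit counting, then the textbook Pearson formula
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

oracle_fa <- function(l1, l2, l3) {
  md <- (l1 + l2 + l3) / 3
  sqrt(3 / 2) * sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
}

# tiny cached default cohort shared by expensive tests
default_cohort_cache <- new.env()
get_default_cohort <- function() {
  if (is.null(default_cohort_cache$cohort))
    default_cohort_cache$cohort <- generate_cohort(synth_config(seed = 20260101))
  default_cohort_cache$cohort
}
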