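# Independent oracles used across the suite. These reimplement the checked
# quantities by the most transparent route available (full-matrix dynamic
# programming, exhaustive enumeration, direct arithmetic) and are kept
# separate from the package code paths they validate.

# DTW by explicit full cost-matrix dynamic programming (pure R)
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# agglomerative average linkage by direct recomputation of all
# cluster-pair mean distances at every merge
average_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1]] <- list(clusters[[best[1]]],
                                         clusters[[best[2]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# two-sided Mann-Whitney p-value by exhaustive enumeration over all
# choose(n1+n2, n1) assignments of the pooled values to group 1
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# central 99% binomial interval for a count
binom_central99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

expect_in_binom99 <- function(k, n, p) {
  iv <- binom_central99(n, p)
  expect_gte(k, iv[1])
  expect_lte(k, iv[2])
}

# small noiseless lineage built from explicit division times and a constant
# per-cycle rate (for feature-extraction tests)
make_piecewise_lineage <- function(div_times, rate = 0.462, dt = 1 / 30,
                                   t_range = NULL, L0 = 2, noise_sd = 0) {
  if (is.null(t_range)) t_range <- range(div_times) + c(-1, 1)
  times <- seq(t_range[1], t_range[2], by = dt)
  cyc <- findInterval(times, div_times)
  Lb <- L0 * 0.5^0  # birth length reset at each division
  lnL <- numeric(length(times))
  for (k in unique(cyc)) {
    sel <- cyc == k
    tb <- if (k == 0) t_range[1] else div_times[k]
    lnL[sel] <- log(L0) + rate * (times[sel] - tb)
  }
  division <- c(FALSE, diff(cyc) > 0)
  L <- exp(lnL)
  if (noise_sd > 0) L <- L * exp(rnorm(length(L), 0, noise_sd))
  data.frame(time_h = times, length_um = L,
             fl_ch1 = 100, fl_ch2 = NA_real_, division = division)
}
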