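# Population statistics.

test_that("fractions carry exact point estimates and Wald errors", {
  f <- fraction_with_se(97, 260)
  expect_equal(f$p, 97 / 260)
  expect_equal(f$percent, 37.3)
  f0 <- fraction_with_se(0, 195)
  expect_equal(f0$p, 0)
  expect_equal(f0$se, 0)
  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample(1:500, 1); k <- sample(0:n, 1)
      f <- fraction_with_se(k, n)
      expect_equal(f$p * f$n, k)                       # arithmetic oracle
      expect_equal(f$se, sqrt((k / n) * (1 - k / n) / n))
    }
  })
  # SE maximal at p = 0.5 for fixed n
  ses <- vapply(0:100, function(k) fraction_with_se(k, 100)$se, numeric(1))
  expect_equal(which.max(ses) - 1, 50)
  expect_error(fraction_with_se(5, 0), "n")
  expect_error(fraction_with_se(-1, 10), "k")
})

test_that("printed-precision rounding is half-up", {
  expect_equal(lineadapt:::round_half_up(91.25, 1), 91.3)
  expect_equal(lineadapt:::round_half_up(-91.25, 1), -91.3)
  expect_equal(lineadapt:::round_half_up(0.085, 2), 0.09)
})

test_that("two-proportion z-test matches its closed form", {
  r <- two_proportion_ztest(10, 100, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  expect_lt(two_proportion_ztest(50, 100, 0, 100)$p_value, 1e-12)
  withr::with_seed(3, {
    for (i in 1:20) {
      n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
      k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
      r <- two_proportion_ztest(k1, n1, k2, n2)
      # independent recomputation from the normal CDF
      pp <- (k1 + k2) / (n1 + n2)
      z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      expect_equal(r$p_value, 2 * pnorm(abs(z), lower.tail = FALSE),
                   tolerance = 1e-12)
      # group exchange flips z, keeps p
      r2 <- two_proportion_ztest(k2, n2, k1, n1)
      expect_equal(r2$z, -r$z)
      expect_equal(r2$p_value, r$p_value)
      # z^2 equals the uncorrected chi-square statistic
      ct <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2),
                                       correct = FALSE))
      expect_equal(r$z^2, unname(ct$statistic), tolerance = 1e-9)
    }
  })
  expect_warning(two_proportion_ztest(0, 10, 0, 10), "degenerate")
})

test_that("Mann-Whitney matches enumeration and the tie-corrected normal", {
  expect_equal(mann_whitney_u(1:5, 1:5 + 100)$U, 0)
  expect_equal(mann_whitney_u(1:5 + 100, 1:5)$U, 25)   # full separation
  expect_equal(mann_whitney_u(c(1, 1, 1), c(1, 1))$p_value, 1)
  withr::with_seed(4, {
    for (i in 1:10) {
      x <- sample(1:8, 5, replace = TRUE)  # ties likely
      y <- sample(1:8, 5, replace = TRUE)
      got <- mann_whitney_u(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, mw_enumeration_oracle(x, y))
    }
    # large samples: tie-corrected normal approximation, cross-checked
    x <- rnorm(40); y <- rnorm(40, 0.5)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "normal")
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  expect_equal(spearman_with_ci(1:10, (1:10)^3)$rho, 1)
  withr::with_seed(5, {
    for (i in 1:10) {
      x <- rnorm(30); y <- rnorm(30)
      s <- spearman_with_ci(x, y)
      expect_equal(s$rho, cor(rank(x), rank(y)))     # rank oracle
      expect_true(s$ci_lo <= s$rho && s$rho <= s$ci_hi)
    }
    # bootstrap CI is reproducible and brackets rho
    x <- rnorm(50); y <- x + rnorm(50)
    b1 <- spearman_with_ci(x, y, method = "bootstrap", seed = 9)
    b2 <- spearman_with_ci(x, y, method = "bootstrap", seed = 9)
    expect_identical(b1, b2)
    expect_true(b1$ci_lo <= b1$rho && b1$rho <= b1$ci_hi)
  })
  expect_error(spearman_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "4")
})

test_that("bootstrap band resamples lineages and honours its invariants", {
  m_id <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6)
  b <- bootstrap_median_band(m_id, n_resamples = 50, seed = 1)
  expect_equal(b$median, c(1, 2, 3, 4))
  expect_equal(b$ci_lo, b$ci_hi)          # zero-width band
  expect_equal(b$q25, b$q75)
  withr::with_seed(6, {
    m <- matrix(rnorm(40 * 8), nrow = 40)
    b <- bootstrap_median_band(m, n_resamples = 300, seed = 2)
    expect_true(all(b$q25 <= b$median & b$median <= b$q75))
    expect_true(all(b$ci_lo <= b$median & b$median <= b$ci_hi))
    b2 <- bootstrap_median_band(m, n_resamples = 300, seed = 2)
    expect_identical(b, b2)
  })
  # sparse grid points are reported missing
  m_na <- matrix(rnorm(20), nrow = 4)
  m_na[2:4, 1] <- NA
  b <- bootstrap_median_band(m_na, n_resamples = 20, seed = 3)
  expect_true(is.na(b$median[1]))
  expect_error(bootstrap_median_band(matrix(1, 1, 3), seed = 1), "two")
})

test_that("bootstrap CI width shrinks like n^(-1/2)", {
  widths <- vapply(c(25, 100, 400), function(n) {
    m <- withr::with_seed(n, matrix(rnorm(n * 4), nrow = n))
    b <- bootstrap_median_band(m, n_resamples = 400, seed = 7)
    mean(b$ci_hi - b$ci_lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_gt(widths[1] / widths[3], 2.2)   # ideal sqrt(16) = 4
  expect_lt(widths[1] / widths[3], 7)
})

test_that("binned means agree with a group-by oracle", {
  one <- binned_mean_table(1.03, 0.5)
  expect_equal(one$bin_center, 1.0)
  expect_equal(one$se_rate, 0)
  expect_equal(one$n, 1L)
  const <- binned_mean_table(runif(50, 0, 3), rep(0.7, 50))
  expect_true(all(const$mean_rate == 0.7))
  withr::with_seed(8, {
    x <- runif(200, 0.5, 3.5); y <- rnorm(200)
    got <- binned_mean_table(x, y, width = 0.2)
    ctr <- floor(x / 0.2 + 0.5) * 0.2
    for (i in seq_len(nrow(got))) {
      sel <- abs(ctr - got$bin_center[i]) < 1e-9
      expect_equal(got$mean_rate[i], mean(y[sel]))
      expect_equal(got$n[i], sum(sel))
    }
    expect_equal(sum(got$n), 200L)        # bins partition the data
  })
  expect_equal(nrow(binned_mean_table(numeric(0), numeric(0))), 0)
})

test_that("central interval uses type-7 empirical quantiles", {
  u <- withr::with_seed(9, runif(20000))
  ci <- central_interval(u)
  expect_equal(ci[1], 0.025, tolerance = 0.01)
  expect_equal(ci[2], 0.975, tolerance = 0.01)
  expect_equal(central_interval(rep(3, 30)), c(3, 3))
  expect_warning(central_interval(1:5), "few values")
})

test_that("median split partitions lineages with the stated tie rule", {
  s <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_setequal(s$bottom, c("a", "b"))
  expect_setequal(s$top, c("c", "d"))
  odd <- median_split(c(a = 1, b = 2, c = 3))
  expect_equal(length(odd$bottom), 2)     # median element to the bottom
  eq <- median_split(c(x = 5, y = 5, z = 5, w = 5))
  expect_true(eq$degenerate)
  expect_setequal(c(eq$top, eq$bottom), c("x", "y", "z", "w"))
  withr::with_seed(10, {
    for (i in 1:10) {
      n <- sample(2:30, 1)
      v <- setNames(rnorm(n), paste0("L", seq_len(n)))
      s <- median_split(v)
      expect_lte(abs(length(s$top) - length(s$bottom)), 1)
      expect_setequal(c(s$top, s$bottom), names(v))
    }
  })
})
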