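# Population-level statistics: proportions with standard errors, group
# tests, lineage-resampled median bands, binned ratio-growth curves,
# correlation with confidence interval.

#' Fraction with Wald standard error
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @return a list of class `fraction_estimate` with `k`, `n`, `p = k/n`,
#'   `se = sqrt(p (1 - p) / n)` and `percent` (half-up rounded to one
#'   decimal, the printed convention).
#' @examples
#' fraction_with_se(97, 260)$percent  # 37.3
#' @export
fraction_with_se <- function(k, n) {
  if (n < 1) stop("`n` must be at least 1")
  if (k < 0 || k > n) stop("`k` must lie in [0, n]")
  p <- k / n
  structure(list(k = k, n = n, p = p, se = sqrt(p * (1 - p) / n),
                 percent = round_half_up(100 * p, 1)),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (SE %.3f)\n", x$k, x$n, x$percent, x$se))
  invisible(x)
}

# round half away from zero at `digits` decimals (printed-report rounding;
# base round() is half-even, which prints 91.25 as 91.2 instead of 91.3)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-proportion z-test (pooled, no continuity correction)
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return a list with `z`, `p_value` (two-sided), and the two sample
#'   proportions. When the pooled proportion is 0 or 1 the test is
#'   degenerate; `z = 0`, `p_value = 1` with a warning.
#' @examples
#' two_proportion_ztest(10, 100, 10, 100)$p_value  # 1
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both groups need at least one trial")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is degenerate (0 or 1); p-value set to 1")
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

# midranks of the pooled sample
mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (`n1 * n2 <= exact_limit`)
#' the p-value is computed by exhaustive enumeration over all
#' choose(n1 + n2, n1) group labelings of the pooled sample (handling ties
#' by midranks), as `2 * min(P(U <= u), P(U >= u))` capped at 1. Larger
#' samples use the normal approximation with the tie-corrected variance.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_limit enumeration threshold on `n1 * n2` (default 400).
#' @return a list with `U` (for the first sample), `p_value` and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(1:5, 6:10)$U  # 0
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u <- mw_u_stat(x, y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = u, p_value = 1, method = "degenerate"))
  if (n1 * n2 <= exact_limit) {
    r <- rank(pooled)
    sets <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    return(list(U = u, p_value = min(1, p), method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation with confidence interval
#'
#' @param x,y paired samples (pairs with missing values dropped; n >= 4).
#' @param method `"fisher"` (default): CI from the Fisher z-transform,
#'   `atanh(rho) +/- 1.96 / sqrt(n - 3)`; or `"bootstrap"`: percentile CI
#'   from pair resampling.
#' @param n_boot bootstrap resamples (bootstrap method).
#' @param seed seed for the bootstrap (required for reproducibility).
#' @param level confidence level.
#' @return a list with `rho`, `ci_lo`, `ci_hi`, `n`, `method`.
#' @examples
#' spearman_with_ci(1:10, (1:10)^2)$rho  # 1
#' @export
spearman_with_ci <- function(x, y, method = c("fisher", "bootstrap"),
                             n_boot = 1000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant sample")
  rho <- cor(x, y, method = "spearman")
  zq <- qnorm(1 - (1 - level) / 2)
  if (method == "fisher") {
    if (abs(rho) >= 1) {
      ci <- c(rho, rho)
    } else {
      z <- atanh(rho)
      ci <- tanh(z + c(-1, 1) * zq / sqrt(n - 3))
    }
  } else {
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
        cor(x[idx], y[idx], method = "spearman")
      }, numeric(1))
    })
    ci <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
  }
  list(rho = rho, ci_lo = ci[1], ci_hi = ci[2], n = n, method = method)
}

#' Bootstrap median band from lineage resampling
#'
#' Pointwise median trajectory with the 25-75% range of the pooled data and
#' a 95% confidence interval for the median obtained by resampling whole
#' cell lineages (never individual time points) with replacement.
#'
#' @param trajectories numeric matrix, one row per lineage, one column per
#'   grid point (`NA` allowed for unobserved points).
#' @param grid grid values (times or generation indices); defaults to
#'   column indices.
#' @param n_resamples number of lineage resamples (default 1000).
#' @param seed integer seed.
#' @param ci_level level of the median confidence band.
#' @return a data frame of class `bootstrap_band` with columns `grid`,
#'   `median`, `q25`, `q75`, `ci_lo`, `ci_hi`, `n_lineages`. Grid points
#'   covered by fewer than two lineages are `NA`.
#' @examples
#' m <- matrix(rnorm(200), nrow = 20)
#' b <- bootstrap_median_band(m, n_resamples = 200, seed = 1)
#' head(b)
#' @export
bootstrap_median_band <- function(trajectories, grid = NULL,
                                  n_resamples = 1000, seed,
                                  ci_level = 0.95) {
  m <- as.matrix(trajectories)
  n <- nrow(m); g <- ncol(m)
  if (n < 2) stop("need at least two lineages to resample")
  if (is.null(grid)) grid <- seq_len(g)
  stopifnot(length(grid) == g)
  n_cov <- colSums(!is.na(m))
  ok <- n_cov >= 2
  med <- q25 <- q75 <- rep(NA_real_, g)
  med[ok] <- apply(m[, ok, drop = FALSE], 2, median, na.rm = TRUE)
  q25[ok] <- apply(m[, ok, drop = FALSE], 2, quantile, probs = 0.25,
                   na.rm = TRUE, names = FALSE)
  q75[ok] <- apply(m[, ok, drop = FALSE], 2, quantile, probs = 0.75,
                   na.rm = TRUE, names = FALSE)
  alpha <- (1 - ci_level) / 2
  boot_meds <- withr::with_seed(as.integer(seed), {
    res <- matrix(NA_real_, n_resamples, g)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      res[b, ok] <- apply(m[idx, ok, drop = FALSE], 2, median, na.rm = TRUE)
    }
    res
  })
  ci_lo <- ci_hi <- rep(NA_real_, g)
  ci_lo[ok] <- apply(boot_meds[, ok, drop = FALSE], 2, quantile,
                     probs = alpha, na.rm = TRUE, names = FALSE)
  ci_hi[ok] <- apply(boot_meds[, ok, drop = FALSE], 2, quantile,
                     probs = 1 - alpha, na.rm = TRUE, names = FALSE)
  structure(data.frame(grid = grid, median = med, q25 = q25, q75 = q75,
                       ci_lo = ci_lo, ci_hi = ci_hi, n_lineages = n_cov),
            class = c("bootstrap_band", "data.frame"))
}

#' Binned mean table (ratio versus elongation rate)
#'
#' Means and standard errors of `y` in fixed-width half-open bins
#' `[c - width/2, c + width/2)` of `x`; error bars are conventionally drawn
#' as 1.96 SE. Bin centres are multiples of `width`, so with the default
#' width a ratio of exactly 1.0 sits at a bin centre.
#'
#' @param x binning variable (e.g. subunit ratio, a.u.).
#' @param y response (e.g. elongation rate, 1/h).
#' @param width bin width (default 0.2).
#' @return a data frame with `bin_center`, `mean_rate`, `se_rate`
#'   (0 for singleton bins, flagged by `n = 1`), `n`.
#' @export
binned_mean_table <- function(x, y, width = 0.2) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0)
    return(data.frame(bin_center = numeric(0), mean_rate = numeric(0),
                      se_rate = numeric(0), n = integer(0)))
  centre <- (floor(x / width + 0.5)) * width
  agg <- tapply(y, centre, function(v)
    c(mean(v), if (length(v) > 1) sd(v) / sqrt(length(v)) else 0, length(v)))
  out <- do.call(rbind, agg)
  data.frame(bin_center = as.numeric(names(agg)),
             mean_rate = out[, 1], se_rate = out[, 2],
             n = as.integer(out[, 3]), row.names = NULL)
}

#' Central empirical interval
#'
#' Empirical central interval of a sample (type-7 linear-interpolation
#' quantiles), e.g. the 95% range within which the subunit ratio of
#' unstressed cells is maintained.
#'
#' @param values numeric sample.
#' @param level interval mass (default 0.95).
#' @return two-element numeric `(lo, hi)`.
#' @examples
#' central_interval(0:100 / 100)  # ~ (0.025, 0.975)
#' @export
central_interval <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < ceiling(1 / (1 - level)))
    warning("few values for a ", level * 100, "% interval; computed anyway")
  alpha <- (1 - level) / 2
  unname(quantile(values, c(alpha, 1 - alpha), type = 7))
}

#' Median split of per-lineage values
#'
#' Splits lineages into a top and a bottom half at the median of their
#' values (e.g. reporter fluorescence at the onset of drug exposure). With
#' an odd number of lineages the median element goes to the bottom half;
#' ties are resolved by id order, so the two halves always partition the
#' input and differ in size by at most one.
#'
#' @param values named numeric vector (names = lineage ids) or plain
#'   numeric with `ids` supplied.
#' @param ids lineage ids, if `values` is unnamed.
#' @return a list with `top`, `bottom` (character id vectors) and
#'   `degenerate` (`TRUE` when all values are equal).
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))
#' @export
median_split <- function(values, ids = names(values)) {
  if (is.null(ids)) ids <- as.character(seq_along(values))
  stopifnot(length(ids) == length(values), length(values) >= 2)
  ord <- order(values, ids)      # stable: ties by id order
  n <- length(values)
  n_bottom <- ceiling(n / 2)
  list(bottom = ids[ord[seq_len(n_bottom)]],
       top = ids[ord[(n_bottom + 1):n]],
       degenerate = length(unique(values)) == 1L)
}
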