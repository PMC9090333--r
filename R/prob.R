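# Closed-form probability calculators.

#' Ancestry probability of sampled populations
#'
#' Probability that all of `n_samples` independently sampled clonal
#' populations derive from growth-halted (rather than growth-restored)
#' resistance-gene-deleted lineages, given the fraction `f_restored` of
#' restored lineages among deleted ones and the probabilities `q_restored`
#' and `q_halted` that lineages of each fate regrow after drug removal:
#' \deqn{\left[\frac{(1-f)\,q_h}{f\,q_r + (1-f)\,q_h}\right]^{n}}
#' With the observed values f = 0.373, q_r = 0.913, q_h = 0.693 and n = 5
#' this evaluates to 0.055 (5.5%).
#'
#' @param f_restored fraction of restored lineages among deleted ones.
#' @param q_restored,q_halted regrowth probabilities after drug removal.
#' @param n_samples number of sampled populations (>= 0).
#' @return the probability.
#' @examples
#' ancestry_probability(0.373, 0.913, 0.693, 5)  # ~0.055
#' @export
ancestry_probability <- function(f_restored, q_restored, q_halted,
                                 n_samples) {
  for (p in c(f_restored, q_restored, q_halted))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (n_samples < 0 || n_samples != round(n_samples))
    stop("`n_samples` must be a non-negative integer")
  denom <- f_restored * q_restored + (1 - f_restored) * q_halted
  if (denom <= 0) stop("degenerate parameters: zero total regrowth mass")
  ((1 - f_restored) * q_halted / denom)^n_samples
}

#' Limiting-dilution Poisson plan
#'
#' Cell counts per well under limiting dilution follow a Poisson law with
#' mean `lam` cells per well; returns the probabilities of 0, 1, 2 and 3 or
#' more cells. At the plating density used for clonal isolation
#' (lam = 0.54) these are about 0.58, 0.31, 0.085 and 0.018.
#'
#' @param lam mean number of cells per well (>= 0).
#' @return a list of class `poisson_plan` with `lam`, `p0`, `p1`, `p2`,
#'   `p_ge3` (summing to 1).
#' @examples
#' limiting_dilution(0.54)
#' @export
limiting_dilution <- function(lam) {
  if (lam < 0) stop("`lam` must be non-negative")
  p0 <- exp(-lam)
  p1 <- lam * exp(-lam)
  p2 <- lam^2 * exp(-lam) / 2
  structure(list(lam = lam, p0 = p0, p1 = p1, p2 = p2,
                 p_ge3 = 1 - p0 - p1 - p2),
            class = "poisson_plan")
}

#' @export
print.poisson_plan <- function(x, ...) {
  cat(sprintf("Poisson plan, lambda = %g cells/well\n", x$lam))
  cat(sprintf("  P(0)=%.2f P(1)=%.2f P(2)=%.3g P(>=3)=%.3g\n",
              x$p0, x$p1, x$p2, x$p_ge3))
  invisible(x)
}

#' Dilution fold over consecutive divisions
#'
#' `2^generations`: with production prevented, this is the factor by which
#' consecutive cell divisions dilute a cytoplasmic protein (30 divisions
#' give about 1.07e9-fold, beyond any plausible initial copy number).
#'
#' @param generations non-negative integer.
#' @return the fold as an exact double (`2^g`).
#' @examples
#' dilution_fold(30)
#' @export
dilution_fold <- function(generations) {
  if (generations < 0 || generations != round(generations))
    stop("`generations` must be a non-negative integer")
  2^generations
}

#' Minimum inhibitory concentration from an OD table
#'
#' Applies the plate-reader decision rule: the MIC is the lowest drug
#' concentration at which the culture OD600 after the fixed incubation
#' falls below the threshold (default 0.01). Returns `Inf` when no tested
#' concentration suppresses growth below the threshold ("above range"; no
#' extrapolation is attempted).
#'
#' @param concentration drug concentrations (strictly increasing, µg/mL).
#' @param od600 measured OD600 per concentration (>= 0).
#' @param threshold OD600 threshold (default 0.01).
#' @return the MIC (µg/mL), or `Inf` for above range.
#' @examples
#' mic_from_od(c(5, 10, 20), c(0.3, 0.004, 0.002))  # 10
#' @export
mic_from_od <- function(concentration, od600, threshold = 0.01) {
  if (length(concentration) == 0) stop("empty MIC table")
  stopifnot(length(concentration) == length(od600))
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(od600 < 0)) stop("OD600 must be non-negative")
  hit <- which(od600 < threshold)
  if (length(hit) == 0) return(Inf)
  concentration[min(hit)]
}
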