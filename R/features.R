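# Per-lineage derived signals: elongation rates, generation tables,
# normalized fluorescence, subunit ratio, expected dilution curve.

# accept either an mm_lineage or a bare frames data frame
lineage_frames <- function(ls) {
  if (inherits(ls, "mm_lineage")) return(ls$frames)
  stopifnot(is.data.frame(ls), all(c("time_h", "length_um") %in% names(ls)))
  ls
}

# division flags, falling back to >30% length drops between frames
division_flags <- function(fr, fallback = TRUE) {
  dv <- fr$division
  if (!is.null(dv) && any(dv)) return(as.logical(dv))
  if (!fallback) return(rep(FALSE, nrow(fr)))
  drop <- c(FALSE, fr$length_um[-1] / head(fr$length_um, -1) < 0.7)
  drop
}

#' Windowed elongation-rate series
#'
#' Estimates the instantaneous specific growth rate (1/h) as the
#' least-squares slope of `ln(length)` versus time inside a sliding window,
#' computed piecewise within cell cycles (frames on either side of a
#' division never enter the same fit) and averaged across the cycle
#' segments in the window, weighted by the number of frames. Exact on
#' noiseless exponentials; invariant to rescaling all lengths.
#'
#' @param ls an `mm_lineage` or a frames data frame with `time_h`,
#'   `length_um` and (optionally) `division`.
#' @param window_h window width in hours (>= 2 frame intervals).
#' @param step_h spacing of the window centres (hours); defaults to the
#'   window width, i.e. non-overlapping windows.
#' @return a data frame with columns `time_h` (window centre) and
#'   `rate_per_hr` (`NA` where no cycle segment with two frames falls in
#'   the window).
#' @examples
#' t <- seq(0, 4, by = 1 / 30)
#' fr <- data.frame(time_h = t, length_um = 2 * exp(0.5 * t),
#'                  division = FALSE)
#' elongation_rate_series(fr, window_h = 2)$rate_per_hr
#' @export
elongation_rate_series <- function(ls, window_h = 2, step_h = window_h) {
  fr <- lineage_frames(ls)
  if (nrow(fr) < 2) return(data.frame(time_h = numeric(0),
                                      rate_per_hr = numeric(0)))
  dt_frame <- median(diff(fr$time_h))
  if (window_h < 2 * dt_frame)
    stop("`window_h` must cover at least two frame intervals")
  cyc <- cumsum(division_flags(fr))
  lnL <- log(fr$length_um)
  tt <- fr$time_h
  centres <- seq(min(tt) + window_h / 2, max(tt) - window_h / 2 + 1e-9,
                 by = step_h)
  if (length(centres) == 0) centres <- mean(range(tt))
  rate <- vapply(centres, function(ct) {
    sel <- which(tt >= ct - window_h / 2 & tt < ct + window_h / 2)
    if (length(sel) < 2) return(NA_real_)
    slopes <- c(); wts <- c()
    for (cc in unique(cyc[sel])) {
      ss <- sel[cyc[sel] == cc]
      if (length(ss) < 2) next
      x <- tt[ss]; y <- lnL[ss]
      slopes <- c(slopes, sum((x - mean(x)) * (y - mean(y))) /
                    sum((x - mean(x))^2))
      wts <- c(wts, length(ss))
    }
    if (length(slopes) == 0) return(NA_real_)
    sum(slopes * wts) / sum(wts)
  }, numeric(1))
  data.frame(time_h = centres, rate_per_hr = rate)
}

#' Generation table of a lineage
#'
#' One record per completed interdivision interval of the mother cell, with
#' the generation time and per-generation mean fluorescence. Generation
#' indices are anchored so that the generation in progress at t = 0 (the
#' end of blue-light illumination) has index 0; earlier generations are
#' negative.
#'
#' @param ls an `mm_lineage` or frames data frame. Division flags are used
#'   when present; otherwise a >30% length drop between consecutive frames
#'   marks a division.
#' @return a data frame with columns `gen_index`, `start_h`, `end_h`,
#'   `gen_time_h`, `mean_fl_ch1`, `mean_fl_ch2`, `mean_ratio` (the latter
#'   `NA` for single-channel lineages). Empty (0 rows) when fewer than two
#'   divisions are observed.
#' @examples
#' cond <- mm_condition("reporter_cat", cp_conc = 0, duration_h = 10,
#'                      pre_hours = 4)
#' gt <- generation_table(simulate_lineage(cond, seed = 2))
#' head(gt[, c("gen_index", "gen_time_h")])
#' @export
generation_table <- function(ls) {
  fr <- lineage_frames(ls)
  div_t <- fr$time_h[division_flags(fr)]
  if (length(div_t) < 2)
    return(data.frame(gen_index = integer(0), start_h = numeric(0),
                      end_h = numeric(0), gen_time_h = numeric(0),
                      mean_fl_ch1 = numeric(0), mean_fl_ch2 = numeric(0),
                      mean_ratio = numeric(0)))
  start_h <- head(div_t, -1)
  end_h <- div_t[-1]
  # index 0 = the generation whose interval contains t = 0; when every
  # completed generation starts after t = 0 the first one gets index 1
  k0 <- findInterval(0, start_h)   # number of starts <= 0
  gen_index <- seq_along(start_h) - k0
  has_ch2 <- "fl_ch2" %in% names(fr) && any(!is.na(fr$fl_ch2))
  bin <- findInterval(fr$time_h, div_t)      # 0 before first division
  inside <- bin >= 1 & bin <= length(start_h)
  m1 <- tapply(fr$fl_ch1[inside], bin[inside], mean)
  mean_fl_ch1 <- as.numeric(m1[as.character(seq_along(start_h))])
  if (has_ch2) {
    m2 <- tapply(fr$fl_ch2[inside], bin[inside], mean)
    mr <- tapply(fr$fl_ch1[inside] / fr$fl_ch2[inside], bin[inside], mean)
    mean_fl_ch2 <- as.numeric(m2[as.character(seq_along(start_h))])
    mean_ratio <- as.numeric(mr[as.character(seq_along(start_h))])
  } else {
    mean_fl_ch2 <- rep(NA_real_, length(start_h))
    mean_ratio <- rep(NA_real_, length(start_h))
  }
  data.frame(gen_index = gen_index, start_h = start_h, end_h = end_h,
             gen_time_h = end_h - start_h, mean_fl_ch1 = mean_fl_ch1,
             mean_fl_ch2 = mean_fl_ch2, mean_ratio = mean_ratio)
}

#' Normalize a fluorescence series by its pre-illumination mean
#'
#' Divides each value by the mean over the pre-illumination window, so the
#' output has mean 1 over that window. This is the normalization applied to
#' each reporter channel before forming the subunit ratio.
#'
#' @param values per-frame fluorescence values (a.u.).
#' @param times frame times (hours), same length as `values`.
#' @param pre_window two-element numeric, the time interval (default
#'   `c(-Inf, illumination start)` must be supplied explicitly as there is
#'   no condition attached to a bare series).
#' @param background optional background level; normalization is refused
#'   when the pre-window mean does not exceed it.
#' @return the normalized numeric series.
#' @examples
#' normalize_fluor(c(2, 2, 2, 4), times = c(-2, -1.5, -1, 1),
#'                 pre_window = c(-3, 0))
#' @export
normalize_fluor <- function(values, times, pre_window, background = 0) {
  stopifnot(length(values) == length(times), length(pre_window) == 2L)
  sel <- times >= pre_window[1] & times <= pre_window[2]
  if (sum(sel) < 3) stop("pre-illumination window must contain >= 3 frames")
  m <- mean(values[sel])
  if (m <= background)
    stop("normalization undefined: pre-window mean does not exceed background")
  values / m
}

#' Per-frame subunit-reporter ratio
#'
#' Ratio of the two fluorescence channels, each first normalized by its own
#' pre-illumination mean (see [normalize_fluor()]). A proxy for the
#' stoichiometric balance of large- and small-subunit ribosomal proteins;
#' about 1 in balanced, unstressed cells.
#'
#' @param ls an `mm_lineage` or frames data frame with both channels.
#' @param pre_window time interval used for normalization; defaults to
#'   everything before the illumination window (before t = -0.5 h).
#' @return data frame with `time_h` and `ratio`.
#' @export
subunit_ratio <- function(ls, pre_window = NULL) {
  fr <- lineage_frames(ls)
  if (!("fl_ch2" %in% names(fr)) || all(is.na(fr$fl_ch2)))
    stop("subunit ratio requires a dual-channel lineage")
  if (is.null(pre_window)) {
    if (inherits(ls, "mm_lineage") && !is.na(ls$condition$illum_start))
      pre_window <- c(-Inf, ls$condition$illum_start)
    else pre_window <- c(-Inf, -0.5)
  }
  ch1 <- normalize_fluor(fr$fl_ch1, fr$time_h, pre_window)
  ch2 <- normalize_fluor(fr$fl_ch2, fr$time_h, pre_window)
  data.frame(time_h = fr$time_h, ratio = ch1 / ch2)
}

#' Expected fluorescence after dilution by growth
#'
#' With production stopped, a stable cytoplasmic protein is diluted two-fold
#' by each doubling of cell volume, so after `g` generations the expected
#' intensity is `i0 * 2^-g`. Thirty consecutive divisions dilute about
#' 2^30 ~ 1.07e9-fold.
#'
#' @param i0 initial intensity (a.u., >= 0).
#' @param g generation count (>= 0, need not be integer).
#' @return expected intensity `i0 * 2^-g`.
#' @examples
#' expected_dilution(1, 1)    # half per generation
#' expected_dilution(1, 30)   # ~9.3e-10
#' @export
expected_dilution <- function(i0, g) {
  if (any(i0 < 0)) stop("`i0` must be non-negative")
  if (any(g < 0)) stop("generation count must be non-negative")
  i0 * 2^(-g)
}
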