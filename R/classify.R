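# Per-lineage deletion and fate calls.
#
# Deletion is called either from the reporter fluorescence (the signal of a
# deleted lineage decays to the background level within a few generations
# and never recovers) or, for strains whose resistance gene is untagged,
# from the distinctive decline of the elongation rate after illumination.
# Growth fate among deleted lineages is called from late-run divisions and
# elongation rate. Threshold calls are validated by DTW trajectory
# clustering against generator truth.

#' Call resistance-gene deletion from reporter fluorescence
#'
#' A lineage is called deleted when its post-illumination per-generation
#' mean fluorescence, background subtracted, falls below a threshold
#' (default twice the background noise SD) within `max_gens` generations
#' and stays below it for every later complete generation.
#'
#' @param ls an `mm_lineage` or frames data frame (channel 1 used).
#' @param background additive background level (a.u.).
#' @param background_sd SD of the measured background; defaults to 6% of
#'   `background` (the generator's default measurement noise).
#' @param max_gens generations allowed for the decay (default 5; the decay
#'   of a genuinely deleted lineage completes in 4-5 generations).
#' @return `TRUE`/`FALSE`, or `NA` (flagged undetermined) when fewer than
#'   `max_gens` complete post-illumination generations are observed.
#' @export
call_deletion_fluorescence <- function(ls, background = 200,
                                       background_sd = 0.06 * background,
                                       max_gens = 5) {
  gt <- generation_table(ls)
  post <- gt[gt$gen_index >= 1, , drop = FALSE]
  if (nrow(post) < max_gens) return(NA)
  thr <- 2 * background_sd
  sig <- post$mean_fl_ch1 - background
  below <- sig < thr
  cross <- which(below)[1]
  if (is.na(cross) || cross > max_gens) return(FALSE)
  all(below[cross:length(below)])
}

# first post-illumination generation whose background-subtracted mean
# fluorescence is below threshold (NA when it never crosses)
deletion_crossing_generation <- function(ls, background = 200,
                                         background_sd = 0.06 * background) {
  gt <- generation_table(ls)
  post <- gt[gt$gen_index >= 1, , drop = FALSE]
  sig <- post$mean_fl_ch1 - background
  idx <- which(sig < 2 * background_sd)[1]
  if (is.na(idx)) NA_integer_ else post$gen_index[idx]
}

#' Call resistance-gene deletion from the growth decline
#'
#' For strains whose resistance gene carries no fluorescent tag, deletion
#' under drug is called from the elongation-rate decline: the lineage is
#' deleted when its median post-illumination rate falls below
#' `drop_fraction` of its median pre-illumination rate.
#'
#' @param ls an `mm_lineage` or frames data frame.
#' @param baseline_window,post_window two-element time intervals (hours)
#'   over which the median windowed elongation rate is taken.
#' @param drop_fraction decline threshold (default 0.5).
#' @param window_h elongation-rate window width.
#' @return `TRUE`/`FALSE`, or `NA` when either window has no rate estimate.
#' @export
call_deletion_growth <- function(ls, baseline_window = c(-10, -0.5),
                                 post_window = c(5, 15),
                                 drop_fraction = 0.5, window_h = 2) {
  er <- elongation_rate_series(ls, window_h = window_h,
                               step_h = window_h / 2)
  base <- er$rate_per_hr[er$time_h >= baseline_window[1] &
                           er$time_h <= baseline_window[2]]
  post <- er$rate_per_hr[er$time_h >= post_window[1] &
                           er$time_h <= post_window[2]]
  base <- base[is.finite(base)]; post <- post[is.finite(post)]
  if (length(base) == 0 || length(post) == 0) return(NA)
  median(post) < drop_fraction * median(base)
}

#' Call the growth fate of a deleted lineage
#'
#' Restored lineages sustain division late in the run; halted lineages
#' cease dividing. The call is `"restored"` when at least `min_divisions`
#' divisions occur in the late window and the median late elongation rate
#' is at least `rate_floor`; `"halted"` when no divisions occur there;
#' `"undetermined"` otherwise (including lineages flushed away before the
#' late window).
#'
#' @param ls an `mm_lineage` or frames data frame.
#' @param late_window two-element time interval (hours); default the last
#'   20 h of a 72 h run.
#' @param min_divisions divisions required to call restoration (default 3).
#' @param rate_floor minimum median late elongation rate (1/h).
#' @param window_h elongation-rate window width.
#' @return a list with `fate` (`"restored"`, `"halted"` or
#'   `"undetermined"`) and `method = "growth"`.
#' @export
call_fate <- function(ls, late_window = c(52, 72), min_divisions = 3,
                      rate_floor = 0.05, window_h = 2) {
  fr <- lineage_frames(ls)
  if (max(fr$time_h) < late_window[2] - 1e-9)
    return(list(fate = "undetermined", method = "growth"))
  sel <- fr$time_h >= late_window[1] & fr$time_h <= late_window[2]
  ndiv <- sum(division_flags(fr)[sel])
  if (ndiv == 0) return(list(fate = "halted", method = "growth"))
  late <- fr[sel, , drop = FALSE]
  er <- elongation_rate_series(late, window_h = window_h,
                               step_h = window_h / 2)
  med_rate <- median(er$rate_per_hr[is.finite(er$rate_per_hr)])
  if (ndiv >= min_divisions && isTRUE(med_rate >= rate_floor))
    list(fate = "restored", method = "growth")
  else
    list(fate = "undetermined", method = "growth")
}

#' Classify every lineage of an experiment
#'
#' Applies the deletion call (fluorescence for `reporter_cat`, growth
#' decline otherwise) and, for lineages called deleted under drug, the fate
#' call. Returns one row per lineage.
#'
#' @param ex an `mm_experiment`.
#' @param background,background_sd passed to
#'   [call_deletion_fluorescence()].
#' @param late_window,min_divisions,rate_floor passed to [call_fate()].
#' @return a data frame with `lineage_id`, `deleted`, `fate`, `method`.
#' @export
classify_experiment <- function(ex, background = ex$params$background,
                                background_sd = background * ex$params$noise_cv,
                                late_window = c(ex$condition$duration_h - 20,
                                                ex$condition$duration_h),
                                min_divisions = 3, rate_floor = 0.05) {
  stopifnot(inherits(ex, "mm_experiment"))
  fluor_mode <- ex$condition$strain_mode == "reporter_cat"
  drug <- ex$condition$cp_conc > 0
  rows <- lapply(ex$lineages, function(l) {
    if (fluor_mode) {
      del <- call_deletion_fluorescence(l, background = background,
                                        background_sd = background_sd)
      method <- "fluorescence"
    } else if (ex$condition$strain_mode == "pre_deleted") {
      del <- TRUE
      method <- "growth_decline"
    } else {
      del <- call_deletion_growth(l)
      method <- "growth_decline"
    }
    fate <- "none"
    if (isTRUE(del) && drug) {
      fate <- call_fate(l, late_window = late_window,
                        min_divisions = min_divisions,
                        rate_floor = rate_floor)$fate
    }
    data.frame(lineage_id = l$lineage_id,
               deleted = del, fate = fate, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# all permutations of 1..k (k small)
perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in perms(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Agreement between two labelings up to label permutation
#'
#' Compares a clustering-derived labeling with a threshold-derived labeling
#' of the same lineages: the agreement is the fraction of identical labels
#' after the optimal one-to-one relabeling (exhaustive over permutations;
#' the number of distinct labels must be small).
#'
#' @param labels_cluster,labels_threshold equal-length label vectors.
#' @return a list with `agreement` (in \[0, 1\]), `confusion` (the
#'   contingency table under the optimal relabeling) and `mapping`.
#' @examples
#' validate_calls(c(1, 1, 2, 2), c("b", "b", "a", "a"))$agreement  # 1
#' @export
validate_calls <- function(labels_cluster, labels_threshold) {
  if (length(labels_cluster) != length(labels_threshold))
    stop("labelings must cover the same lineage set")
  a <- as.integer(factor(labels_cluster))
  b <- as.integer(factor(labels_threshold))
  k <- max(max(a), max(b))
  if (k > 6) stop("exhaustive permutation matching supports at most 6 labels")
  best <- -1; best_perm <- NULL
  for (p in perms(k)) {
    agr <- mean(p[a] == b)
    if (agr > best) { best <- agr; best_perm <- p }
  }
  list(agreement = best,
       confusion = table(mapped_cluster = best_perm[a], threshold = b),
       mapping = best_perm)
}
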