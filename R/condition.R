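#' Experiment design for a mother-machine run
#'
#' A condition bundles the experimental design knobs of one mother-machine
#' run: which strain is observed, the chloramphenicol (Cp) concentration in
#' the flowing medium, the gap `tc_hours` between the end of blue-light
#' illumination and the onset of Cp exposure, the illumination window, the
#' imaging frame interval and the observation span. Time is measured in
#' hours with t = 0 at the end of blue-light illumination; for the
#' `pre_deleted` mode (resistance gene removed before loading, no
#' illumination event) t = 0 marks the onset of Cp exposure.
#'
#' @param strain_mode one of `"reporter_cat"` (fluorescently tagged
#'   resistance gene, single fluorescence channel, 2-min frames),
#'   `"ribosome_reporter"` (dual ribosomal-subunit reporters plus an
#'   untagged removable resistance gene, 10-min frames) or `"pre_deleted"`
#'   (resistance gene absent from the start; ribosomal reporters).
#' @param cp_conc Cp concentration in the flowing medium (µg/mL, >= 0;
#'   0 means drug-free).
#' @param tc_hours gap between illumination end and Cp onset, in hours
#'   (>= 0), or the string `"continuous"` meaning Cp is present from the
#'   start of the experiment.
#' @param illum_start,illum_end blue-light illumination window (hours);
#'   defaults -0.5 to 0, i.e. a 30-min exposure ending at t = 0.
#' @param frame_interval_min imaging interval in minutes; defaults to 2
#'   for `reporter_cat` and 10 otherwise.
#' @param duration_h observation span after t = 0 (hours).
#' @param pre_hours observation span before t = 0 (hours); long enough by
#'   default to cover ten pre-illumination generations.
#'
#' @return an object of class `mm_condition` (a validated list).
#' @examples
#' mm_condition("reporter_cat", cp_conc = 15, tc_hours = "continuous")
#' @export
mm_condition <- function(strain_mode = c("reporter_cat", "ribosome_reporter",
                                         "pre_deleted"),
                         cp_conc = 15,
                         tc_hours = "continuous",
                         illum_start = -0.5,
                         illum_end = 0,
                         frame_interval_min = NULL,
                         duration_h = 72,
                         pre_hours = 16) {
  strain_mode <- match.arg(strain_mode)
  if (!is.numeric(cp_conc) || length(cp_conc) != 1L || cp_conc < 0)
    stop("`cp_conc` must be a single non-negative concentration (ug/mL)")
  continuous <- identical(tc_hours, "continuous")
  if (!continuous &&
      (!is.numeric(tc_hours) || length(tc_hours) != 1L || tc_hours < 0))
    stop("`tc_hours` must be a non-negative number of hours or \"continuous\"")
  if (strain_mode == "pre_deleted") {
    # no illumination event; Cp onset at t = 0 defines the alignment
    illum_start <- NA_real_
    illum_end <- NA_real_
    tc_hours <- 0
    continuous <- FALSE
  } else {
    if (!(illum_start < illum_end))
      stop("`illum_start` must be earlier than `illum_end`")
  }
  if (is.null(frame_interval_min))
    frame_interval_min <- if (strain_mode == "reporter_cat") 2 else 10
  if (frame_interval_min <= 0) stop("`frame_interval_min` must be positive")
  if (duration_h <= 0) stop("`duration_h` must be positive")
  if (pre_hours < 0) stop("`pre_hours` must be non-negative")
  structure(list(
    strain_mode = strain_mode,
    cp_conc = cp_conc,
    tc_hours = if (continuous) "continuous" else tc_hours,
    illum_start = illum_start,
    illum_end = illum_end,
    frame_interval_min = frame_interval_min,
    duration_h = duration_h,
    pre_hours = pre_hours
  ), class = "mm_condition")
}

#' @export
print.mm_condition <- function(x, ...) {
  cat("<mm_condition>\n")
  cat(sprintf("  strain_mode: %s\n", x$strain_mode))
  cat(sprintf("  cp_conc: %g ug/mL; Tc: %s\n", x$cp_conc,
              if (identical(x$tc_hours, "continuous")) "continuous"
              else sprintf("%g h", x$tc_hours)))
  cat(sprintf("  frames every %g min; t in [-%g, %g] h\n",
              x$frame_interval_min, x$pre_hours, x$duration_h))
  invisible(x)
}

# time at which Cp appears in the medium; -Inf for continuous exposure,
# +Inf for drug-free runs
cp_onset_time <- function(cond) {
  if (cond$cp_conc <= 0) return(Inf)
  if (identical(cond$tc_hours, "continuous")) return(-Inf)
  cond$tc_hours
}

#' Default restoration probability as a function of Tc
#'
#' Fraction of resistance-gene-deleted lineages expected to restore growth
#' under 15 µg/mL Cp, as a function of the gap `tc_hours` between deletion
#' and drug onset. Anchors follow the observed fractions: 37.3% under
#' continuous exposure and at Tc = 0 h or 3 h, 18.5% at Tc = 6 h, and zero
#' at Tc = 10 h or beyond (and for pre-deleted lineages). Values between
#' anchors are linearly interpolated.
#'
#' @param tc_hours numeric gap in hours, or `"continuous"`.
#' @return a probability in \[0, 1\].
#' @examples
#' default_p_restore("continuous")
#' default_p_restore(6)
#' default_p_restore(10)
#' @export
default_p_restore <- function(tc_hours) {
  if (identical(tc_hours, "continuous")) return(0.373)
  stopifnot(is.numeric(tc_hours), length(tc_hours) == 1L, tc_hours >= 0)
  anchors_tc <- c(0, 3, 6, 10)
  anchors_p  <- c(0.373, 0.373, 0.185, 0)
  if (tc_hours >= 10) return(0)
  stats::approx(anchors_tc, anchors_p, xout = tc_hours)$y
}

#' Parameters of the stochastic lineage generator
#'
#' Defaults encode the statistical structure of the study system: a baseline
#' generation time of 1.5 h (so a 72-h run spans over 30 generations), sizer
#' division at twice the birth length with the mother retaining half, a
#' deletion probability around 1/4 per illuminated lineage, a post-deletion
#' growth decline over `decline_gens` generations under drug, a logistic
#' recovery of generation time (about 6.3 h around generations 6-9 easing to
#' 3.0 h by generations 21-30) for restored lineages, fluorescence produced
#' in proportion to growth and diluted by it (halving per generation once
#' production stops), and a roughly three-fold disruption of the ribosomal
#' subunit-reporter ratio whose recovery in restored lineages becomes
#' evident about 37 h after deletion.
#'
#' @param r0 baseline elongation rate (1/h); default log(2)/1.5.
#' @param r0_cv lineage-to-lineage CV of the baseline rate.
#' @param div_length_ratio mean division-trigger ratio (division when length
#'   reaches this multiple of birth length).
#' @param div_ratio_cv CV of the division-trigger ratio (per cycle).
#' @param retention_mean,retention_sd mother-retained length fraction at
#'   division (truncated to \[0.42, 0.58\]).
#' @param p_del deletion probability per illuminated lineage.
#' @param p_restore restoration probability among deleted lineages under
#'   drug: a single probability, a function of `tc_hours`, or `NULL` to use
#'   [default_p_restore()].
#' @param fluor_gate_hill Hill-type exponent weighting each lineage's
#'   restoration probability by its residual reporter fluorescence at drug
#'   onset (relative to the condition's expected residual); 0 disables the
#'   weighting. Active only when `0 < tc_hours < Inf`.
#' @param decline_gens generations over which growth declines after deletion
#'   under drug.
#' @param decline_to_h generation time reached at the end of the decline (h).
#' @param halt_factor per-generation generation-time inflation after the
#'   decline for growth-halted lineages.
#' @param halt_rate_floor rate (1/h) below which a halted lineage stops
#'   dividing (length plateau; shrinkage is not modelled).
#' @param recovery_profile list with `t_rec`, `amp`, `g_mid`, `g_scale`:
#'   restored-lineage generation time at stressed generation g is
#'   `t_rec + amp / (1 + exp((g - g_mid)/g_scale))`.
#' @param gen_rate_cv per-cycle multiplicative noise on the elongation rate.
#' @param fluor_steady steady-state reporter fluorescence (a.u.) while the
#'   gene is present (production/dilution balance).
#' @param background additive background fluorescence (a.u.).
#' @param noise_cv multiplicative (log-normal) measurement noise CV on
#'   fluorescence.
#' @param length_noise_cv multiplicative measurement noise CV on length.
#' @param birth_length_um typical birth length (µm).
#' @param ratio_fold peak disruption of the subunit-reporter ratio.
#' @param ratio_rise_mid_h,ratio_rise_tau_h midpoint and time constant (h)
#'   of the logistic ratio disruption after deletion under drug.
#' @param ratio_recovery_onset_h time (h) after deletion at which restored
#'   and halted ratio trajectories visibly diverge.
#' @param ratio_recovery_tau_h time constant (h) of the ratio recovery.
#' @param pre_deleted_rise_mid_h,pre_deleted_rise_tau_h faster disruption
#'   kinetics for pre-deleted lineages exposed to drug.
#' @param coupling_gamma exponent of the monotone-decreasing map from the
#'   subunit ratio to the elongation rate,
#'   `rate = r0 * ((ratio_fold - ratio) / (ratio_fold - 1))^coupling_gamma`
#'   clamped to \[0, r0\].
#' @param censor_prob probability that a lineage is flushed away before the
#'   end of the run (its series is truncated at a uniform random time).
#'
#' @return an object of class `mm_params` (a validated list).
#' @examples
#' p <- generator_params()
#' p$r0
#' @export
generator_params <- function(r0 = log(2) / 1.5,
                             r0_cv = 0.05,
                             div_length_ratio = 2.0,
                             div_ratio_cv = 0.05,
                             retention_mean = 0.5,
                             retention_sd = 0.03,
                             p_del = 0.25,
                             p_restore = NULL,
                             fluor_gate_hill = 1,
                             decline_gens = 6,
                             decline_to_h = 6.45,
                             halt_factor = 2.2,
                             halt_rate_floor = 0.03,
                             recovery_profile = list(t_rec = 3.0, amp = 3.6,
                                                     g_mid = 14, g_scale = 2.5),
                             gen_rate_cv = 0.04,
                             fluor_steady = 400,
                             background = 200,
                             noise_cv = 0.06,
                             length_noise_cv = 0.02,
                             birth_length_um = 2.2,
                             ratio_fold = 3,
                             ratio_rise_mid_h = 7,
                             ratio_rise_tau_h = 2.5,
                             ratio_recovery_onset_h = 37,
                             ratio_recovery_tau_h = 8,
                             pre_deleted_rise_mid_h = 4,
                             pre_deleted_rise_tau_h = 2,
                             coupling_gamma = 1,
                             censor_prob = 0) {
  p <- as.list(environment())
  if (p$r0 <= 0) stop("`r0` must be positive")
  if (p$p_del < 0 || p$p_del > 1) stop("`p_del` must lie in [0, 1]")
  if (is.numeric(p$p_restore) &&
      (p$p_restore < 0 || p$p_restore > 1))
    stop("numeric `p_restore` must lie in [0, 1]")
  if (p$background < 0) stop("`background` must be non-negative")
  if (p$fluor_steady <= 0) stop("`fluor_steady` must be positive")
  if (p$ratio_fold <= 1) stop("`ratio_fold` must exceed 1")
  if (p$censor_prob < 0 || p$censor_prob > 1)
    stop("`censor_prob` must lie in [0, 1]")
  stopifnot(all(c("t_rec", "amp", "g_mid", "g_scale") %in%
                  names(p$recovery_profile)))
  structure(p, class = "mm_params")
}

# restoration probability for a condition (before fluorescence weighting)
resolve_p_restore <- function(params, cond) {
  if (cond$strain_mode == "pre_deleted" || cond$cp_conc <= 0) return(0)
  pr <- params$p_restore
  if (is.null(pr)) return(default_p_restore(cond$tc_hours))
  if (is.function(pr)) return(pr(cond$tc_hours))
  pr
}

# target generation time (h) at stressed generation g (0-based, counted from
# the first generation starting after both deletion and drug are active)
stress_gen_time <- function(g, fate, params) {
  t0 <- log(2) / params$r0
  dg <- params$decline_gens
  decline <- t0 * (params$decline_to_h / t0)^(pmin(g + 1, dg) / dg)
  if (fate == "restored") {
    pr <- params$recovery_profile
    rec <- pr$t_rec + pr$amp / (1 + exp((g - pr$g_mid) / pr$g_scale))
    ifelse(g < dg, decline, rec)
  } else {
    ifelse(g < dg, decline,
           params$decline_to_h * params$halt_factor^(g - dg + 1))
  }
}
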