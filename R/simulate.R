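# Stochastic generator of mother-machine lineage tables.
#
# A lineage is the cell at the closed end of one growth channel, followed
# across consecutive cell cycles. Within a cycle the cell elongates
# exponentially; division is triggered when length reaches a (noisy) target
# multiple of the birth length and the mother retains about half. Reporter
# fluorescence is produced in proportion to growth while the gene is
# present and diluted by growth afterwards, so it halves per generation
# once production stops.

# division schedule for generation-time-profile-driven modes (reporter_cat):
# one row per cycle with birth time, rate, birth length, cumulative growth
# integral at birth, and division time (Inf for the final/plateau cycle).
build_schedule <- function(cond, params, deleted, t_recomb) {
  t_start <- -cond$pre_hours
  t_end <- cond$duration_h
  onset <- cp_onset_time(cond)
  stress_start <- if (deleted && is.finite(cond$cp_conc) && cond$cp_conc > 0)
    max(t_recomb, onset) else Inf

  r0_i <- params$r0 * exp(rnorm(1, 0, params$r0_cv))
  t_base <- log(2) / r0_i
  plateau_rate <- 0.002

  tb <- numeric(0); rr <- numeric(0); Lb <- numeric(0); dv <- numeric(0)
  # random cell-cycle phase at the start of observation
  t_cur <- t_start - runif(1, 0, t_base)
  L_cur <- params$birth_length_um * exp(rnorm(1, 0, 0.1))
  fate <- NULL          # decided when the stress phase begins
  g <- 0L               # stressed-generation counter

  repeat {
    if (t_cur >= stress_start && is.null(fate)) {
      fate <- "pending"  # caller resolves; placeholder never used directly
      break
    }
    stressed <- t_cur >= stress_start
    r <- r0_i * exp(rnorm(1, 0, params$gen_rate_cv))
    rho <- max(1.5, rnorm(1, params$div_length_ratio,
                          params$div_length_ratio * params$div_ratio_cv))
    tgen <- log(rho) / r
    tb <- c(tb, t_cur); rr <- c(rr, r); Lb <- c(Lb, L_cur)
    t_div <- t_cur + tgen
    if (t_div > t_end) { dv <- c(dv, Inf); break }
    dv <- c(dv, t_div)
    ret <- pmin(0.58, pmax(0.42, rnorm(1, params$retention_mean,
                                       params$retention_sd)))
    L_cur <- ret * rho * L_cur
    t_cur <- t_div
  }
  list(tb = tb, r = rr, Lb = Lb, dv = dv, r0_i = r0_i,
       t_cur = t_cur, L_cur = L_cur, stress_start = stress_start)
}

# continue a schedule through the stressed phase once the fate is known
extend_schedule_stressed <- function(sched, cond, params, fate) {
  t_end <- cond$duration_h
  plateau_rate <- 0.002
  tb <- sched$tb; rr <- sched$r; Lb <- sched$Lb; dv <- sched$dv
  t_cur <- sched$t_cur; L_cur <- sched$L_cur
  g <- 0L
  repeat {
    if (t_cur >= t_end) break
    tg_target <- stress_gen_time(g, fate, params)
    r <- (log(2) / tg_target) * exp(rnorm(1, 0, params$gen_rate_cv))
    if (fate == "halted" && r < params$halt_rate_floor) {
      # growth effectively stops: length plateau, no further divisions
      tb <- c(tb, t_cur); rr <- c(rr, plateau_rate); Lb <- c(Lb, L_cur)
      dv <- c(dv, Inf)
      break
    }
    rho <- max(1.5, rnorm(1, params$div_length_ratio,
                          params$div_length_ratio * params$div_ratio_cv))
    tgen <- log(rho) / r
    tb <- c(tb, t_cur); rr <- c(rr, r); Lb <- c(Lb, L_cur)
    t_div <- t_cur + tgen
    if (t_div > t_end) { dv <- c(dv, Inf); break }
    dv <- c(dv, t_div)
    ret <- pmin(0.58, pmax(0.42, rnorm(1, params$retention_mean,
                                       params$retention_sd)))
    L_cur <- ret * rho * L_cur
    t_cur <- t_div
    g <- g + 1L
  }
  list(tb = tb, r = rr, Lb = Lb, dv = dv, r0_i = sched$r0_i)
}

# cumulative growth integral (= ln length gain, divisions removed) at time t
schedule_growth_integral <- function(sched, t) {
  tb <- sched$tb; r <- sched$r
  Gb <- cumsum(c(0, head(r * (c(tb[-1], Inf) - tb), -1)))
  idx <- pmax(1L, findInterval(t, tb))
  Gb[idx] + r[idx] * (t - tb[idx])
}

sim_lineage_reporter_cat <- function(cond, params, lineage_id) {
  onset <- cp_onset_time(cond)
  drug <- cond$cp_conc > 0
  deleted <- runif(1) < params$p_del
  t_recomb <- if (deleted) runif(1, cond$illum_start, cond$illum_end) else NA_real_

  sched <- build_schedule(cond, params, deleted, t_recomb)

  fate <- "none"
  if (deleted && drug) {
    p_base <- resolve_p_restore(params, cond)
    w <- 1
    if (is.finite(onset) && onset > 0 && params$fluor_gate_hill > 0) {
      # restoration requires residual resistance protein at drug onset:
      # weight by the lineage's simulated residual relative to expectation
      g_rec <- schedule_growth_integral(sched, t_recomb)
      g_on  <- schedule_growth_integral(sched, onset)
      f_onset <- params$fluor_steady * exp(-(g_on - g_rec))
      mean_recomb <- (cond$illum_start + cond$illum_end) / 2
      f_expect <- params$fluor_steady * exp(-params$r0 * (onset - mean_recomb))
      w <- (f_onset / f_expect)^params$fluor_gate_hill
    }
    fate <- if (runif(1) < min(1, p_base * w)) "restored" else "halted"
  }
  if (deleted && drug) {
    sched <- extend_schedule_stressed(sched, cond, params, fate)
  }

  dt <- cond$frame_interval_min / 60
  times <- seq(-cond$pre_hours, cond$duration_h, by = dt)
  idx <- pmax(1L, findInterval(times, sched$tb))
  lnL <- log(sched$Lb[idx]) + sched$r[idx] * (times - sched$tb[idx])
  length_um <- exp(lnL) * exp(rnorm(length(times), 0, params$length_noise_cv))
  division <- c(FALSE, diff(idx) > 0L)

  # fluorescence: steady state while producing, diluted by growth afterwards
  Gb <- cumsum(c(0, head(sched$r * (c(sched$tb[-1], Inf) - sched$tb), -1)))
  G <- Gb[idx] + sched$r[idx] * (times - sched$tb[idx])
  if (deleted) {
    G_rec <- schedule_growth_integral(sched, t_recomb)
    fl_true <- ifelse(times < t_recomb, params$fluor_steady,
                      params$fluor_steady * exp(-(G - G_rec)))
  } else {
    fl_true <- rep(params$fluor_steady, length(times))
  }
  fl_ch1 <- (fl_true + params$background) *
    exp(rnorm(length(times), 0, params$noise_cv))

  frames <- data.frame(time_h = times, length_um = length_um,
                       fl_ch1 = fl_ch1, fl_ch2 = NA_real_,
                       division = division)
  list(frames = frames, deleted = deleted, fate = fate, t_recomb = t_recomb)
}

# deterministic subunit-ratio trajectory for ribosome-reporter modes
ratio_profile <- function(times, t_stress, fate, params, pre_deleted = FALSE) {
  if (!is.finite(t_stress)) return(rep(1, length(times)))
  mid <- if (pre_deleted) params$pre_deleted_rise_mid_h else params$ratio_rise_mid_h
  tau <- if (pre_deleted) params$pre_deleted_rise_tau_h else params$ratio_rise_tau_h
  rise <- stats::plogis((times - t_stress - mid) / tau)
  rec <- if (fate == "restored") {
    mid_rec <- params$ratio_recovery_onset_h + 1.4 * params$ratio_recovery_tau_h
    1 - 0.9 * stats::plogis((times - t_stress - mid_rec) /
                              params$ratio_recovery_tau_h)
  } else rep(1, length(times))
  1 + (params$ratio_fold - 1) * rise * rec
}

sim_lineage_ribosome <- function(cond, params, lineage_id) {
  pre_del <- cond$strain_mode == "pre_deleted"
  onset <- cp_onset_time(cond)
  drug <- cond$cp_conc > 0
  if (pre_del) {
    deleted <- TRUE
    t_recomb <- -Inf
  } else {
    deleted <- runif(1) < params$p_del
    t_recomb <- if (deleted) runif(1, cond$illum_start, cond$illum_end) else NA_real_
  }
  t_stress <- if (deleted && drug) max(if (pre_del) 0 else t_recomb, onset) else Inf

  fate <- "none"
  if (deleted && drug) {
    p_base <- resolve_p_restore(params, cond)
    w <- 1
    if (!pre_del && is.finite(onset) && onset > 0 && params$fluor_gate_hill > 0) {
      # residual (untagged) resistance protein at drug onset, diluted at the
      # baseline rate between recombination and onset
      r0_i <- params$r0 * exp(rnorm(1, 0, params$r0_cv))
      f_onset <- params$fluor_steady *
        exp(-r0_i * (onset - t_recomb) * exp(rnorm(1, 0, 0.2)))
      mean_recomb <- (cond$illum_start + cond$illum_end) / 2
      f_expect <- params$fluor_steady * exp(-params$r0 * (onset - mean_recomb))
      w <- (f_onset / f_expect)^params$fluor_gate_hill
    }
    fate <- if (runif(1) < min(1, p_base * w)) "restored" else "halted"
  }

  dt <- cond$frame_interval_min / 60
  times <- seq(-cond$pre_hours, cond$duration_h, by = dt)
  n <- length(times)
  ratio <- ratio_profile(times, t_stress, fate, params, pre_deleted = pre_del)

  # elongation rate from the ratio through the monotone-decreasing coupling
  r0_i <- params$r0 * exp(rnorm(1, 0, params$r0_cv))
  coup <- pmax(0, pmin(1, (params$ratio_fold - ratio) /
                         (params$ratio_fold - 1)))^params$coupling_gamma
  rate <- r0_i * coup * exp(rnorm(n, 0, params$gen_rate_cv))

  # Euler sizer: grow each frame, divide when the target ratio is reached
  L <- numeric(n); division <- logical(n)
  L_birth <- params$birth_length_um * exp(rnorm(1, 0, 0.1))
  L_cur <- L_birth * exp(runif(1, 0, log(2)))  # random cycle phase
  rho <- max(1.5, rnorm(1, params$div_length_ratio,
                        params$div_length_ratio * params$div_ratio_cv))
  for (i in seq_len(n)) {
    if (i > 1) L_cur <- L_cur * exp(rate[i] * dt)
    if (L_cur >= rho * L_birth) {
      ret <- pmin(0.58, pmax(0.42, rnorm(1, params$retention_mean,
                                         params$retention_sd)))
      L_cur <- ret * L_cur
      L_birth <- L_cur
      rho <- max(1.5, rnorm(1, params$div_length_ratio,
                            params$div_length_ratio * params$div_ratio_cv))
      division[i] <- TRUE
    }
    L[i] <- L_cur
  }
  length_um <- L * exp(rnorm(n, 0, params$length_noise_cv))

  # channel 2 (small-subunit reporter) responds modestly; channel 1 carries
  # the ratio disruption. Pre-deleted cells lose channel-2 expression first.
  ch2_prof <- if (!is.finite(t_stress)) rep(1, n) else if (pre_del) {
    1 - 0.35 * stats::plogis((times - t_stress - params$pre_deleted_rise_mid_h) /
                               params$pre_deleted_rise_tau_h)
  } else {
    1 + 0.3 * stats::plogis((times - t_stress - params$ratio_rise_mid_h) /
                              params$ratio_rise_tau_h)
  }
  ch1_base <- 1000 * exp(rnorm(1, 0, 0.15))
  ch2_base <- 800 * exp(rnorm(1, 0, 0.15))
  fl_ch1 <- ch1_base * ratio * ch2_prof * exp(rnorm(n, 0, params$noise_cv))
  fl_ch2 <- ch2_base * ch2_prof * exp(rnorm(n, 0, params$noise_cv))

  frames <- data.frame(time_h = times, length_um = length_um,
                       fl_ch1 = fl_ch1, fl_ch2 = fl_ch2,
                       division = division)
  list(frames = frames, deleted = deleted, fate = fate, t_recomb = t_recomb)
}

#' Simulate one mother-cell lineage
#'
#' Generates the per-frame time series (time, length, one or two
#' fluorescence channels, division flags) of a single mother-cell lineage
#' under the given condition, together with its ground truth (whether the
#' resistance gene was deleted and the growth fate).
#'
#' In `reporter_cat` mode the elongation rate follows a generation-indexed
#' profile after deletion under drug: a geometric decline over
#' `decline_gens` generations, then either a logistic recovery of the
#' generation time (restored) or a further slowdown to a length plateau
#' (halted). In `ribosome_reporter` and `pre_deleted` modes two channels are
#' emitted; the subunit ratio is disrupted after deletion under drug and
#' recovers only in restored lineages, and the elongation rate is driven by
#' the ratio through a monotone-decreasing coupling map.
#'
#' @param cond an [mm_condition()].
#' @param params a [generator_params()].
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param lineage_id identifier stored with the lineage.
#' @return an object of class `mm_lineage`: a list with `lineage_id`,
#'   `condition`, `frames` (data frame with columns `time_h`, `length_um`,
#'   `fl_ch1`, `fl_ch2`, `division`) and `truth` (list with `deleted`,
#'   `fate` in `{"restored", "halted", "none"}`).
#' @examples
#' cond <- mm_condition("reporter_cat", cp_conc = 0, duration_h = 12,
#'                      pre_hours = 4)
#' ls <- simulate_lineage(cond, generator_params(), seed = 1)
#' head(ls$frames)
#' @export
simulate_lineage <- function(cond, params = generator_params(), seed,
                             lineage_id = "L0001") {
  stopifnot(inherits(cond, "mm_condition"), inherits(params, "mm_params"))
  if (cond$strain_mode == "pre_deleted" && params$p_del < 1 && params$p_del > 0) {
    # deletion is not an event in this mode; p_del is ignored
  }
  out <- withr::with_seed(as.integer(seed), {
    res <- if (cond$strain_mode == "reporter_cat")
      sim_lineage_reporter_cat(cond, params, lineage_id)
    else
      sim_lineage_ribosome(cond, params, lineage_id)
    if (params$censor_prob > 0 && runif(1) < params$censor_prob) {
      t_cut <- runif(1, 0.3 * cond$duration_h, cond$duration_h)
      res$frames <- res$frames[res$frames$time_h <= t_cut, , drop = FALSE]
      res$censored <- TRUE
    } else res$censored <- FALSE
    res
  })
  structure(list(
    lineage_id = lineage_id,
    condition = cond,
    frames = out$frames,
    truth = list(deleted = out$deleted, fate = out$fate,
                 t_recomb = out$t_recomb, censored = out$censored)
  ), class = "mm_lineage")
}

#' Simulate a mother-machine experiment
#'
#' Runs [simulate_lineage()] for `n_lineages` lineages under one condition.
#' Per-lineage sub-seeds are derived deterministically from the master seed,
#' so the output is reproducible given `(seed, cond, params, n_lineages)`
#' and lineage `i` is identical across runs.
#'
#' @param cond an [mm_condition()].
#' @param params a [generator_params()].
#' @param n_lineages number of lineages (>= 1).
#' @param seed integer master seed.
#' @return an object of class `mm_experiment`: a list with `lineages`
#'   (a list of `mm_lineage`), `truth` (data frame: `lineage_id`,
#'   `deleted`, `fate`), `condition`, `params`, `seed`.
#' @examples
#' cond <- mm_condition("reporter_cat", cp_conc = 0, duration_h = 8,
#'                      pre_hours = 2)
#' ex <- simulate_experiment(cond, generator_params(), n_lineages = 4,
#'                           seed = 7)
#' ex$truth
#' @export
simulate_experiment <- function(cond, params = generator_params(),
                                n_lineages, seed) {
  stopifnot(n_lineages >= 1)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                floor(runif(n_lineages) * (2^31 - 1)))
  ids <- sprintf("L%05d", seq_len(n_lineages))
  lineages <- vector("list", n_lineages)
  for (i in seq_len(n_lineages)) {
    lineages[[i]] <- simulate_lineage(cond, params, seed = sub_seeds[i],
                                      lineage_id = ids[i])
  }
  truth <- data.frame(
    lineage_id = ids,
    deleted = vapply(lineages, function(l) l$truth$deleted, logical(1)),
    fate = vapply(lineages, function(l) l$truth$fate, character(1)),
    censored = vapply(lineages, function(l) l$truth$censored, logical(1)),
    stringsAsFactors = FALSE
  )
  structure(list(lineages = lineages, truth = truth, condition = cond,
                 params = params, seed = as.integer(seed)),
            class = "mm_experiment")
}

#' @export
print.mm_experiment <- function(x, ...) {
  cat(sprintf("<mm_experiment> %d lineages, %s, seed %d\n",
              length(x$lineages), x$condition$strain_mode, x$seed))
  cat(sprintf("  truth: %d deleted (%d restored, %d halted)\n",
              sum(x$truth$deleted), sum(x$truth$fate == "restored"),
              sum(x$truth$fate == "halted")))
  invisible(x)
}

#' Bind experiment frames into one tidy table
#'
#' @param ex an `mm_experiment`.
#' @return a data frame with columns `lineage_id`, `time_h`, `length_um`,
#'   `fl_ch1`, `fl_ch2`, `division`.
#' @export
experiment_frames <- function(ex) {
  stopifnot(inherits(ex, "mm_experiment"))
  dt <- data.table::rbindlist(lapply(ex$lineages, function(l) {
    cbind(lineage_id = l$lineage_id, l$frames)
  }))
  data.table::setDF(dt)
  dt
}
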