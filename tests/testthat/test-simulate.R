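# Synthetic lineage generator: invariants, determinism, truth frequencies.

cond_free <- mm_condition("reporter_cat", cp_conc = 0, duration_h = 20,
                          pre_hours = 6)
cond_cp <- mm_condition("reporter_cat", cp_conc = 15,
                        tc_hours = "continuous")

test_that("condition constructor validates its inputs", {
  expect_error(mm_condition(cp_conc = -1), "cp_conc")
  expect_error(mm_condition(tc_hours = -2), "tc_hours")
  expect_error(mm_condition(illum_start = 0, illum_end = -0.5),
               "illum_start")
  expect_error(generator_params(r0 = -1), "r0")
  expect_error(generator_params(p_del = 1.4), "p_del")
  cond <- mm_condition("pre_deleted")
  expect_true(is.na(cond$illum_start))
})

test_that("frames satisfy the lineage-series invariants", {
  for (seed in 1:5) {
    ls <- simulate_lineage(cond_cp, generator_params(p_del = 0.5),
                           seed = seed)
    fr <- ls$frames
    dt <- diff(fr$time_h)
    expect_true(all(dt > 0))
    expect_equal(max(dt) - min(dt), 0, tolerance = 1e-9)
    expect_true(all(fr$length_um > 0))
    expect_true(all(fr$fl_ch1 >= 0))
    drops <- fr$length_um[which(fr$division)] /
      fr$length_um[which(fr$division) - 1]
    expect_true(all(drops > 0.35 & drops < 0.65))
    expect_gt(median(drops), 0.45)
    expect_lt(median(drops), 0.55)
  }
})

test_that("same seed gives byte-identical experiments", {
  p <- generator_params()
  ex1 <- simulate_experiment(cond_free, p, n_lineages = 5, seed = 31)
  ex2 <- simulate_experiment(cond_free, p, n_lineages = 5, seed = 31)
  expect_identical(experiment_frames(ex1), experiment_frames(ex2))
  expect_identical(ex1$truth, ex2$truth)
})

test_that("without deletion the fluorescence never declines", {
  ls <- simulate_lineage(cond_free, generator_params(p_del = 0), seed = 8)
  expect_false(ls$truth$deleted)
  gt <- generation_table(ls)
  p <- generator_params()
  expect_true(all(gt$mean_fl_ch1 > 0.8 * (p$fluor_steady + p$background)))
})

test_that("deleted drug-free lineages halve their fluorescence per generation", {
  p <- generator_params(p_del = 1)
  decs <- unlist(lapply(1:4, function(s) {
    ls <- simulate_lineage(cond_free, p, seed = s)
    gt <- generation_table(ls)
    sig <- gt$mean_fl_ch1 - p$background
    keep <- gt$gen_index >= 1 & sig > 2 * p$background  # before background dominates
    diff(log2(sig[keep]))
  }))
  expect_true(all(abs(decs + 1) < 0.2))
})

test_that("deletion counts follow the binomial law", {
  ex <- simulate_experiment(cond_free, generator_params(p_del = 0.25),
                            n_lineages = 1000, seed = 123)
  expect_in_binom99(sum(ex$truth$deleted), 1000, 0.25)
})

test_that("no restoration when the deletion precedes drug exposure by 10 h", {
  cond <- mm_condition("reporter_cat", cp_conc = 15, tc_hours = 10)
  ex <- simulate_experiment(cond, generator_params(p_del = 0.3),
                            n_lineages = 300, seed = 5)
  expect_identical(default_p_restore(10), 0)
  expect_equal(sum(ex$truth$fate == "restored"), 0)
})

test_that("restored lineages recover the programmed late generation time", {
  # a recovering lineage needs ~110 h to complete 30 generations, so this
  # generator-consistency check observes longer than a standard run
  cond_long <- mm_condition("reporter_cat", cp_conc = 15,
                            tc_hours = "continuous", duration_h = 120,
                            pre_hours = 4)
  ex <- simulate_experiment(cond_long, generator_params(p_del = 0.6,
                                                        p_restore = 0.6),
                            n_lineages = 60, seed = 17)
  rest <- ex$lineages[ex$truth$fate == "restored"]
  expect_gt(length(rest), 5)
  late_med <- vapply(rest, function(l) {
    gt <- generation_table(l)
    median(gt$gen_time_h[gt$gen_index >= 21 & gt$gen_index <= 30])
  }, numeric(1))
  terminal <- ex$params$recovery_profile$t_rec
  expect_lt(abs(median(late_med, na.rm = TRUE) - terminal) / terminal, 0.2)
  # and the mid-recovery plateau sits near 6.3 h (generations 6-9)
  mid_med <- vapply(rest, function(l) {
    gt <- generation_table(l)
    median(gt$gen_time_h[gt$gen_index >= 6 & gt$gen_index <= 9])
  }, numeric(1))
  expect_lt(abs(median(mid_med, na.rm = TRUE) - 6.3), 1.0)
})

test_that("restored fraction converges to p_restore", {
  ex <- simulate_experiment(cond_cp, generator_params(p_del = 0.5,
                                                      p_restore = 0.373),
                            n_lineages = 2000, seed = 99)
  tr <- ex$truth[ex$truth$deleted, ]
  expect_in_binom99(sum(tr$fate == "restored"), nrow(tr), 0.373)
})

test_that("ribosome-mode ratio and coupling behave as constructed", {
  cond <- mm_condition("ribosome_reporter", cp_conc = 15,
                       tc_hours = "continuous")
  ex <- simulate_experiment(cond, generator_params(p_del = 0.6,
                                                   p_restore = 0.5),
                            n_lineages = 30, seed = 21)
  for (l in ex$lineages[ex$truth$deleted][1:5]) {
    r <- subunit_ratio(l)
    pre <- r$ratio[r$time_h < -0.5]
    expect_equal(mean(pre), 1, tolerance = 0.05)
    # roughly 3-fold disruption at the peak (median over the plateau)
    peak <- median(r$ratio[r$time_h > 15 & r$time_h < 30])
    expect_gt(peak, 2.4)
    expect_lt(peak, 3.6)
    if (l$truth$fate == "restored")
      expect_lt(median(r$ratio[r$time_h > 68]), 1.6)
    else
      expect_gt(median(r$ratio[r$time_h > 68]), 2.4)
  }
  # negative ratio-rate association across deleted lineages
  xs <- c(); ys <- c()
  for (l in ex$lineages[ex$truth$deleted]) {
    er <- elongation_rate_series(l, window_h = 2)
    rt <- subunit_ratio(l)
    rb <- tapply(rt$ratio, findInterval(rt$time_h, er$time_h - 1), mean)
    idx <- as.integer(names(rb)); ok <- idx >= 1 & idx <= nrow(er)
    xs <- c(xs, rb[ok]); ys <- c(ys, er$rate_per_hr[idx[ok]])
  }
  expect_lt(cor(xs, ys, method = "spearman"), 0)
})

test_that("censored lineages are truncated and flagged", {
  p <- generator_params(censor_prob = 1)
  ls <- simulate_lineage(cond_cp, p, seed = 4)
  expect_true(ls$truth$censored)
  expect_lt(max(ls$frames$time_h), cond_cp$duration_h)
})
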