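# Deletion and fate calls, DTW, clustering, call validation.

cond_cp <- mm_condition("reporter_cat", cp_conc = 15,
                        tc_hours = "continuous")

test_that("fluorescence deletion call separates deleted from non-deleted", {
  p <- generator_params(p_del = 1)
  ls_del <- simulate_lineage(cond_cp, p, seed = 1)
  expect_true(call_deletion_fluorescence(ls_del))
  cross <- lineadapt:::deletion_crossing_generation(ls_del)
  expect_true(cross %in% c(4L, 5L))
  p0 <- generator_params(p_del = 0)
  ls_keep <- simulate_lineage(cond_cp, p0, seed = 2)
  expect_false(call_deletion_fluorescence(ls_keep))
})

test_that("deletion calls match generator truth on a mixed experiment", {
  ex <- simulate_experiment(cond_cp, generator_params(p_del = 0.25),
                            n_lineages = 300, seed = 14)
  calls <- classify_experiment(ex)
  m <- merge(calls, ex$truth, by = "lineage_id", suffixes = c("_c", "_t"))
  expect_equal(mean(m$deleted_c == m$deleted_t), 1)
})

test_that("growth-decline deletion call works without a reporter tag", {
  t <- seq(-10, 30, by = 1 / 6)
  const <- data.frame(time_h = t, length_um = 2 * exp(0.4 * (t %% 1.7)),
                      division = c(FALSE, diff(t %% 1.7) < 0))
  expect_false(call_deletion_growth(const))

  cond_r <- mm_condition("ribosome_reporter", cp_conc = 15,
                         tc_hours = "continuous")
  ex <- simulate_experiment(cond_r, generator_params(p_del = 0.5),
                            n_lineages = 40, seed = 6)
  calls <- vapply(ex$lineages, call_deletion_growth, logical(1))
  expect_equal(mean(calls == ex$truth$deleted), 1)
})

test_that("fluorescence and growth deletion calls agree under drug", {
  ex <- simulate_experiment(cond_cp, generator_params(p_del = 0.5),
                            n_lineages = 80, seed = 9)
  fl <- vapply(ex$lineages, call_deletion_fluorescence, logical(1))
  gr <- vapply(ex$lineages, call_deletion_growth, logical(1))
  expect_gte(mean(fl == gr), 0.99)
})

test_that("fate calls distinguish restored from halted lineages", {
  # a lineage with no divisions late in the run is halted
  t <- seq(0, 72, by = 1 / 6)
  flat <- data.frame(time_h = t, length_um = 3, division = FALSE)
  expect_equal(call_fate(flat)$fate, "halted")
  # truncated observation cannot be called
  short <- data.frame(time_h = t[t < 40], length_um = 3, division = FALSE)
  expect_equal(call_fate(short)$fate, "undetermined")

  ex <- simulate_experiment(cond_cp, generator_params(p_del = 0.6,
                                                      p_restore = 0.5),
                            n_lineages = 80, seed = 12)
  calls <- classify_experiment(ex)
  m <- merge(calls, ex$truth, by = "lineage_id", suffixes = c("_c", "_t"))
  dd <- m[m$deleted_t, ]
  expect_gte(mean(dd$fate_c == dd$fate_t), 0.95)
})

test_that("fate frequencies on a 260-lineage run match the binomial oracle", {
  ex <- simulate_experiment(cond_cp, generator_params(p_del = 1,
                                                      p_restore = 0.373),
                            n_lineages = 260, seed = 37)
  calls <- classify_experiment(ex)
  known <- calls[calls$fate != "undetermined", ]
  expect_in_binom99(sum(known$fate == "restored"), nrow(known), 0.373)
})

test_that("DTW satisfies its defining identities", {
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_equal(dtw_distance(1:7, 1:7), 0)
  expect_error(dtw_distance(numeric(0), 1:3), "empty")
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
      expect_equal(dtw_distance(a, b), dtw_distance(b, a))
      expect_equal(dtw_distance(a, b), dtw_oracle(a, b))
    }
  })
})

test_that("clustering separates trajectory families and is shift-invariant", {
  withr::with_seed(8, {
    fam1 <- replicate(5, 100 * 2^-(0:20) + rnorm(21, 0, 2), simplify = FALSE)
    fam2 <- replicate(5, rep(100, 21) + rnorm(21, 0, 2), simplify = FALSE)
    trajs <- c(fam1, fam2)
    cl <- cluster_lineages(trajs, k = 2)
    expect_equal(cl$labels, rep(1:2, each = 5))
    # uniform additive shift leaves the (unscaled) DTW geometry unchanged
    shifted <- lapply(trajs, function(x) x + 55)
    d1 <- dtw_distance_matrix(trajs)
    d2 <- dtw_distance_matrix(shifted)
    expect_equal(d1, d2, tolerance = 1e-9)
  })
  expect_error(cluster_lineages(list(1:3, 1:3), k = 5), "k")
})

test_that("identical trajectories merge at height zero", {
  trajs <- replicate(4, c(1, 2, 3), simplify = FALSE)
  cl <- cluster_lineages(trajs, k = 1, scale = FALSE)
  expect_equal(cl$labels, rep(1, 4))
  expect_true(all(cl$hclust$height == 0))
})

test_that("average-linkage merge heights match the exhaustive oracle", {
  withr::with_seed(13, {
    trajs <- lapply(1:6, function(i) rnorm(8, mean = i %% 3))
    d <- dtw_distance_matrix(trajs)
    hc <- hclust(as.dist(d), method = "average")
    oracle <- average_linkage_oracle(d)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-9)
  })
})

test_that("label agreement is permutation-invariant", {
  expect_equal(validate_calls(c(1, 1, 2, 2), c(1, 1, 2, 2))$agreement, 1)
  expect_equal(validate_calls(c(1, 1, 2, 2), c(2, 2, 1, 1))$agreement, 1)
  expect_equal(validate_calls(c(1, 2, 1, 2), c("a", "a", "b", "b"))$agreement,
               0.5)
  expect_error(validate_calls(1:3, 1:4), "same lineage set")
})

test_that("clustering reproduces threshold deletion calls on simulated data", {
  ex <- simulate_experiment(cond_cp, generator_params(p_del = 0.5),
                            n_lineages = 40, seed = 19)
  trajs <- lapply(ex$lineages, function(l) {
    fr <- l$frames
    as.numeric(tapply(fr$fl_ch1, floor(fr$time_h), mean))
  })
  cl <- cluster_lineages(trajs, k = 2)
  calls <- vapply(ex$lineages, call_deletion_fluorescence, logical(1))
  v <- validate_calls(cl$labels, calls)
  expect_gte(v$agreement, 0.98)
})
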