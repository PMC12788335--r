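mk_pairs <- function(gt, pred, step = seq_along(gt), stream = "s") {
  structure(
    tibble::tibble(
      stream_id = stream, step = step, gt_ms = gt, pred_ms = pred,
      ic_dev_ms = 0, tc_dev_ms = pred - gt
    ),
    class = c("gc_pairs", class(tibble::tibble())), fs = 250
  )
}

test_that("duration pairing keeps matched, closed contacts only", {
  truth <- extract_segments(rep(c(0, 1, 1, 1, 0), 10), fs = 250)
  p <- pair_durations(truth, truth)
  expect_equal(nrow(p), 10)
  expect_equal(p$gt_ms, p$pred_ms)
  expect_equal(attr(p, "n_unmatched_pred"), 0)

  spurious <- dplyr::bind_rows(
    truth,
    tibble::tibble(
      step = 11L, ic = 200L, tc = 216L, duration_frames = 16L,
      duration_ms = 64, open_ended = FALSE
    )
  )
  p <- pair_durations(spurious, truth)
  expect_equal(nrow(p), 10)
  expect_equal(attr(p, "n_unmatched_pred"), 1)
})

test_that("Bland-Altman reproduces closed-form bias and LOA", {
  p <- mk_pairs(gt = rep(150, 6), pred = rep(150, 6))
  ba <- bland_altman(p)
  expect_equal(ba$bias_ms, 0)
  expect_equal(ba$loa_low_ms, 0)
  expect_equal(ba$loa_high_ms, 0)
  expect_false(ba$heteroscedastic)

  p <- mk_pairs(gt = c(150, 150, 150, 150), pred = c(154, 146, 154, 146))
  ba <- bland_altman(p)
  expect_equal(ba$bias_ms, 0)
  expect_equal(ba$sd_ms, sqrt(64 / 3)) # sample SD 4.6188
  expect_equal(ba$loa_high_ms, 1.96 * sqrt(64 / 3)) # +/- 9.0528
  expect_equal(ba$mean_abs_diff_ms, 4)

  # proportional error produces a heteroscedasticity flag
  gt <- seq(100, 200, length.out = 30)
  set.seed(8)
  p <- mk_pairs(gt, gt + (gt - 100) * 0.2 * rep(c(1, -1), 15))
  expect_true(bland_altman(p)$heteroscedastic)
  expect_error(bland_altman(mk_pairs(1:2, 1:2)), "at least 3")
})

test_that("LOA cover about 95% of Gaussian differences", {
  set.seed(9)
  n <- 4000
  gt <- runif(n, 100, 190)
  d <- rnorm(n, 0, 6)
  ba <- bland_altman(mk_pairs(gt, gt + d))
  cover <- mean(d >= ba$loa_low_ms & d <= ba$loa_high_ms)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("signed-rank p-values agree with exhaustive enumeration (n <= 12)", {
  set.seed(10)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, 0.4, 1), 3) # continuous: no zeros, no ties
    got <- sprintgc:::wilcoxon_signed_rank(d)
    expect_equal(got$method, "exact")
    expect_equal(got$p, wilcoxon_exact_brute(d))
    # cross-check against the standard implementation
    expect_equal(got$p, wilcox.test(d)$p.value)
  }
})

test_that("rank statistics label correlations and effect sizes", {
  gt <- c(100, 120, 140, 160, 180, 200)
  rs <- rank_stats(mk_pairs(gt, gt + 7))
  expect_equal(rs$spearman_rho, 1)
  expect_equal(rs$spearman_label, "almost perfect")

  # symmetric +/- 4 differences: no systematic shift
  rs <- rank_stats(mk_pairs(rep(150, 8), 150 + rep(c(4, -4), 4)))
  expect_gt(rs$wilcoxon_p, 0.05)

  # zero differences handled by the Pratt rule, not a crash
  rs <- rank_stats(mk_pairs(gt, gt))
  expect_equal(rs$spearman_rho, 1)
  expect_equal(rs$effect_size, 0)
  expect_equal(rs$wilcoxon_p, 1)

  expect_equal(sprintgc:::label_effect_size(0.42), "small")
  expect_equal(sprintgc:::label_effect_size(0.1), "trivial")
  expect_equal(sprintgc:::label_effect_size(0.6), "medium")
  expect_equal(sprintgc:::label_effect_size(0.85), "large")
  expect_error(rank_stats(mk_pairs(1:3, 1:3)), "at least 5")
})

test_that("MAPE and RMSE match hand arithmetic", {
  p <- mk_pairs(c(100, 200), c(110, 190))
  em <- error_measures(p)
  expect_equal(em$mape_pct, 7.5) # (10/100 + 10/200)/2 * 100
  expect_equal(em$rmse_ms, 10)
  em0 <- error_measures(mk_pairs(c(120, 140), c(120, 140)))
  expect_equal(em0$mape_pct, 0)
  expect_equal(em0$rmse_ms, 0)
  expect_error(error_measures(mk_pairs(c(0, 10), c(1, 9))), "positive")
})

test_that("event deviations are signed, in ms, on the 4 ms frame grid", {
  truth <- extract_segments(rep(c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0), 5), fs = 250)
  perfect <- pair_durations(truth, truth)
  ed <- event_deviation_summary(perfect)
  expect_true(all(ed$deviations$deviation_ms == 0))

  shifted <- dplyr::mutate(truth, ic = ic + 1L) # IC one frame late
  p <- pair_durations(shifted, truth)
  ed <- event_deviation_summary(p)
  expect_equal(
    ed$deviations$deviation_ms[ed$deviations$kind == "IC"],
    rep(4, 5)
  )
  expect_equal(ed$summary$mean_ms[ed$summary$kind == "IC"], 4)

  set.seed(11)
  jig_ic <- sample(-2:2, 5, replace = TRUE)
  jig_tc <- sample(-2:2, 5, replace = TRUE)
  jig <- dplyr::mutate(truth, ic = ic + jig_ic, tc = tc + jig_tc)
  ed <- event_deviation_summary(pair_durations(jig, truth))
  # every deviation is a multiple of the 4 ms frame period
  expect_true(all(ed$deviations$deviation_ms %% 4 == 0))
  expect_equal(
    ed$deviations$deviation_ms[ed$deviations$kind == "IC"],
    jig_ic * 4
  )
  expect_equal(
    ed$deviations$deviation_ms[ed$deviations$kind == "TC"],
    jig_tc * 4
  )
})

test_that("step-wise tables summarize GT and PRED per step with pooled total", {
  set.seed(12)
  runs <- lapply(1:40, function(i) {
    attr(generate_run(gait_sim_config(seed = 700 + i), "A01", "R1", "left"), "true_segments")
  })
  pairs <- dplyr::bind_rows(lapply(runs, function(s) {
    mk_pairs(s$duration_ms, s$duration_ms, step = s$step)
  }))
  tab <- stepwise_table(pairs)
  s1 <- tab[tab$step == "1", ]
  expect_equal(s1$n, 40)
  expect_lt(abs(s1$gt_mean_ms - 184), 3 * 30 / sqrt(40) + 2)
  tot <- tab[tab$step == "total", ]
  expect_equal(tot$n, 400)
  expect_equal(tot$gt_mean_ms, mean(pairs$gt_ms)) # pooled mean over all steps

  single <- stepwise_table(mk_pairs(150, 154, step = 1))
  expect_equal(single$gt_sd_ms, c(0, 0)) # SD 0 where one observation
})

test_that("quantization error follows 2 frame periods over the contact time", {
  expect_equal(round(quantization_error_pct(100), 1), 21.3)
  expect_equal(round(quantization_error_pct(250), 1), 8.5)
  expect_equal(round(quantization_error_pct(500), 1), 4.3)
  expect_equal(round(quantization_error_pct(1000), 1), 2.1)
  expect_lt(quantization_error_pct(1e9), 1e-5) # vanishes as fs grows
  # strictly decreasing in both arguments
  fs <- seq(100, 1000, by = 50)
  expect_true(all(diff(quantization_error_pct(fs)) < 0))
  gc <- seq(90, 200, by = 10)
  expect_true(all(diff(quantization_error_pct(250, gc)) < 0))
  expect_error(quantization_error_pct(-1), "positive")
})

test_that("the normality gate chooses the documented branch", {
  set.seed(13)
  skewed <- rexp(80)
  normal <- rnorm(80)
  g <- normality_gate(a = skewed, b = normal)
  expect_equal(g$decision, "nonparametric")
  expect_lt(g$shapiro$p[g$shapiro$sample == "a"], 0.05)

  set.seed(14)
  g <- normality_gate(a = rnorm(300), b = rnorm(300))
  expect_equal(g$decision, "parametric")
  expect_false(is.na(g$levene_p))

  expect_error(normality_gate(a = c(1, 2), b = rnorm(10)), "insufficient sample")
})
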