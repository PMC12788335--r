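test_that("min-max scaling maps each channel onto [-1.5, 1.5]", {
  run <- gc_run(c(0, 5, 10), c(4, 4, 4), fs = 250)
  sc <- scale_minmax(run)
  expect_equal(sc$a_res, c(-1.5, 0, 1.5))
  expect_equal(sc$w_res, c(0, 0, 0)) # degenerate channel -> midpoint

  set.seed(12)
  x <- runif(100, 3, 50)
  sc <- scale_minmax(gc_run(x, x + 1, fs = 250))
  # independent two-point-fit oracle: solve y = a x + b from (min,max)
  a <- 3 / (max(x) - min(x))
  b <- -1.5 - a * min(x)
  expect_equal(sc$a_res, a * x + b, tolerance = 1e-12)
  expect_equal(range(sc$a_res), c(-1.5, 1.5))

  params <- attr(sc, "scale_params")
  expect_equal(params$min, c(min(x), min(x + 1)))
})

test_that("scaling is idempotent on already-scaled data", {
  set.seed(2)
  x <- rnorm(50)
  df <- tibble::tibble(a_res = x, w_res = rev(x))
  once <- scale_minmax(df)
  twice <- scale_minmax(once)
  expect_equal(twice$a_res, once$a_res, tolerance = 1e-12)
  expect_error(scale_minmax(tibble::tibble(a_res = c(1, NaN), w_res = c(1, 2))), "a_res")
})

test_that("window slicing enumerates exactly the full windows", {
  mk <- function(L) gc_run(seq_len(L), seq_len(L) + 1, rep(0L, L), fs = 250)
  ws <- slice_windows(scale_minmax(mk(1000)), 100, 15)
  expect_equal(length(ws$starts), 61)
  expect_equal(ws$starts[1], 1)
  expect_equal(ws$starts[61], 901) # frames 901..1000, last full window
  expect_equal(dim(ws$X), c(61, 2, 100))
  expect_equal(dim(ws$Y), c(61, 100))

  expect_equal(length(slice_windows(scale_minmax(mk(100)), 100, 15)$starts), 1)
  # frames 101..109 fall into no window
  expect_equal(length(slice_windows(scale_minmax(mk(109)), 100, 15)$starts), 1)

  expect_error(slice_windows(scale_minmax(mk(100)), 50, 50), "stride")
  expect_warning(ws0 <- slice_windows(scale_minmax(mk(50)), 100, 15), "shorter")
  expect_equal(dim(ws0$X)[1], 0)
})

test_that("window contents are verbatim stream slices", {
  run <- generate_run(gait_sim_config(n_steps = 3, seed = 4), "A01", "R1", "left")
  sc <- scale_minmax(run)
  ws <- slice_windows(sc, 60, 20)
  for (i in c(1, length(ws$starts))) {
    idx <- ws$starts[i]:(ws$starts[i] + 59)
    expect_equal(ws$X[i, 1, ], sc$a_res[idx])
    expect_equal(ws$X[i, 2, ], sc$w_res[idx])
    expect_equal(ws$Y[i, ], sc$label[idx])
  }
})

test_that("overlap averaging matches the per-frame sum/count oracle", {
  # constant predictions pass through; uncovered tail is zero
  starts <- c(1L, 16L, 31L)
  probs <- matrix(0.8, 3, 100)
  out <- reassemble_probs(probs, starts, 140)
  expect_equal(out[1:130], rep(0.8, 130))
  expect_equal(out[131:140], rep(0, 10))

  # two overlapping windows averaging 0.2 and 0.6 -> 0.4
  out <- reassemble_probs(rbind(rep(0.2, 10), rep(0.6, 10)), c(1L, 6L), 20)
  expect_equal(out[6:10], rep(0.4, 5))

  # random case against an explicit loop oracle
  set.seed(3)
  starts <- seq(1L, 61L, by = 12L)
  probs <- matrix(runif(length(starts) * 40), length(starts), 40)
  got <- reassemble_probs(probs, starts, 110)
  acc <- numeric(110)
  cnt <- numeric(110)
  for (i in seq_along(starts)) {
    for (t in 0:39) {
      acc[starts[i] + t] <- acc[starts[i] + t] + probs[i, t + 1]
      cnt[starts[i] + t] <- cnt[starts[i] + t] + 1
    }
  }
  oracle <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  expect_equal(got, oracle)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("slicing labels and reassembling them reproduces the labels", {
  run <- generate_run(gait_sim_config(seed = 8), "A01", "R1", "left")
  ws <- slice_windows(scale_minmax(run), 100, 15)
  rec <- reassemble_probs(ws$Y, ws$starts, ws$source_length)
  covered <- seq_len(max(ws$starts) + 99)
  expect_equal(rec[covered], as.numeric(run$label[covered]))
})

test_that("dataset assembly concatenates streams with provenance", {
  cfg <- gait_sim_config(seed = 6)
  runs <- list(
    generate_run(cfg, "A01", "R1", "left"),
    generate_run(cfg, "A01", "R1", "right")
  )
  # pad/crop both streams to exactly 1000 frames for the arithmetic check
  runs <- lapply(runs, function(r) crop_stream(r, 1, min(nrow(r), 601) + 0))
  ws <- build_dataset(runs, 100, 15)
  expect_equal(dim(ws$X)[1], sum(vapply(
    runs,
    function(r) floor((nrow(r) - 100) / 15) + 1, numeric(1)
  )))
  expect_equal(nrow(ws$streams), 2)
  expect_setequal(unique(ws$stream_ids), ws$streams$stream_id)

  # provenance round-trip: every stream reassembled exactly once, full length
  rec <- reassemble_dataset(ws, matrix(0.5, dim(ws$X)[1], 100))
  expect_equal(names(rec), ws$streams$stream_id)
  expect_equal(
    vapply(rec, length, integer(1)),
    setNames(ws$streams$source_length, ws$streams$stream_id)
  )

  empty <- build_dataset(list(), 100, 15)
  expect_equal(dim(empty$X)[1], 0)

  r2 <- runs
  attr(r2[[2]], "fs") <- 500
  expect_error(build_dataset(r2, 100, 15), "mixed sampling rates")
})

test_that("two 1000-frame streams at window 100 stride 15 give 122 windows", {
  runs <- lapply(c("left", "right"), function(leg) {
    gc_run(runif(1000), runif(1000), rep(0L, 1000),
      fs = 250,
      athlete_id = "A01", run_id = "R1", leg = leg
    )
  })
  ws <- build_dataset(runs, 100, 15)
  expect_equal(dim(ws$X)[1], 122)
})
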