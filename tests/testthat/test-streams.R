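test_that("resultant is the per-frame Euclidean norm", {
  df <- tibble::tibble(
    accel_x = c(3, 0), accel_y = c(4, 0), accel_z = c(0, 0),
    gyro_x = c(1, 0), gyro_y = c(2, 0), gyro_z = c(2, 0)
  )
  run <- compute_resultant(df, fs = 1125)
  expect_equal(run$a_res, c(5, 0))
  expect_equal(run$w_res, c(3, 0))
  expect_equal(attr(run, "fs"), 1125)

  set.seed(91)
  raw <- tibble::as_tibble(setNames(
    as.data.frame(matrix(rnorm(50 * 6), 50, 6)),
    c("accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z")
  ))
  run <- compute_resultant(raw)
  oracle <- vapply(seq_len(50), function(i) {
    sqrt(sum(c(raw$accel_x[i], raw$accel_y[i], raw$accel_z[i])^2))
  }, numeric(1))
  expect_equal(run$a_res, oracle)
})

test_that("resultant is invariant under rotations of the sensor frame", {
  set.seed(7)
  acc <- matrix(rnorm(30), 10, 3)
  gyr <- matrix(rnorm(30), 10, 3)
  base <- compute_resultant(tibble::tibble(
    accel_x = acc[, 1], accel_y = acc[, 2], accel_z = acc[, 3],
    gyro_x = gyr[, 1], gyro_y = gyr[, 2], gyro_z = gyr[, 3]
  ))
  for (k in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    ar <- acc %*% R
    gr <- gyr %*% R
    rot <- compute_resultant(tibble::tibble(
      accel_x = ar[, 1], accel_y = ar[, 2], accel_z = ar[, 3],
      gyro_x = gr[, 1], gyro_y = gr[, 2], gyro_z = gr[, 3]
    ))
    expect_equal(rot$a_res, base$a_res, tolerance = 1e-9)
    expect_equal(rot$w_res, base$w_res, tolerance = 1e-9)
  }
})

test_that("resultant rejects mismatched channel lengths", {
  df <- list(
    accel_x = 1:3, accel_y = 1:3, accel_z = 1:2,
    gyro_x = 1:3, gyro_y = 1:3, gyro_z = 1:3
  )
  expect_error(compute_resultant(df), "share one length")
  expect_error(compute_resultant(data.frame(accel_x = 1)), "missing tri-axial")
})

test_that("resampling preserves constants, sines and lengths", {
  const <- gc_run(rep(9.81, 1125), rep(1, 1125), fs = 1125)
  out <- resample_stream(const, 250)
  expect_equal(nrow(out), 250)
  expect_equal(out$a_res, rep(9.81, 250), tolerance = 1e-9)

  x <- sin(2 * pi * 2 * (0:4499) / 1125) + 2
  out <- resample_stream(gc_run(x, x, fs = 1125), 250)
  expect_equal(nrow(out), 1000)
  t2 <- (0:999) / 250
  interior <- 60:940
  rms <- sqrt(mean((out$a_res[interior] - (sin(2 * pi * 2 * t2[interior]) + 2))^2))
  expect_lt(rms, 1e-3)

  empty <- resample_stream(gc_run(numeric(0), numeric(0), fs = 1125), 250)
  expect_equal(nrow(empty), 0)
})

test_that("resampling there and back preserves band-limited content", {
  t <- (0:999) / 250
  sig <- 5 + sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 17 * t) + 0.3 * sin(2 * pi * 41 * t)
  run <- gc_run(sig, sig, fs = 250)
  expect_message(up <- resample_stream(run, 1125), "upsampling")
  back <- resample_stream(up, 250)
  interior <- 100:900
  expect_lt(sqrt(mean((back$a_res[interior] - sig[interior])^2)), 1e-3)
})

test_that("event-train synchronization recovers shifts, tolerates jitter", {
  set.seed(37)
  ev <- sort(sample(1:2000, 10))
  expect_identical(synchronize_by_events(ev, ev, 100), 0L)
  expect_identical(synchronize_by_events(ev, ev + 37L, 100), 37L)
  # antisymmetry for jitter-free inputs
  expect_identical(
    synchronize_by_events(ev + 37L, ev, 100),
    -synchronize_by_events(ev, ev + 37L, 100)
  )
  # +/- 1 frame jitter on 3 of 10 events leaves the peak unchanged
  jit <- ev + 37L
  jit[c(2, 5, 8)] <- jit[c(2, 5, 8)] + c(1L, -1L, 1L)
  expect_identical(synchronize_by_events(ev, sort(jit), 100), 37L)

  expect_error(synchronize_by_events(c(1, 5), c(500, 600), max_lag = 10), "unsynchronizable")
  expect_error(synchronize_by_events(integer(0), 1:3), "nonempty")
})

test_that("run files round-trip and invalid files are rejected by field", {
  run <- generate_run(gait_sim_config(n_steps = 3, seed = 2), "A01", "R1", "left")
  path <- withr::local_tempfile(fileext = ".csv")
  write_run(run, path)
  back <- read_run(path, athlete_id = "A01", run_id = "R1", leg = "left")
  expect_equal(back$a_res, run$a_res, tolerance = 1e-12) # printed precision
  expect_equal(back$w_res, run$w_res, tolerance = 1e-12)
  expect_identical(back$label, run$label)
  expect_equal(attr(back, "fs"), 250)

  rds <- withr::local_tempfile(fileext = ".rds")
  write_run(run, rds, format = "rds")
  expect_identical(read_run(rds, format = "rds"), run)

  df <- readr::read_csv(path, show_col_types = FALSE)
  bad <- withr::local_tempfile(fileext = ".csv")
  df2 <- df
  df2$label[5] <- 2
  readr::write_csv(df2, bad)
  expect_error(read_run(bad), "label")
  readr::write_csv(df[, c("time_s", "a_res", "label")], bad)
  expect_error(read_run(bad), "missing w_res")
  df3 <- df
  df3$a_res[1] <- NA
  readr::write_csv(df3, bad)
  expect_error(read_run(bad), "a_res")
})

test_that("crop_stream keeps the half-open frame interval", {
  run <- gc_run(1:10, 1:10, c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0), fs = 250)
  cropped <- crop_stream(run, 3, 7)
  expect_equal(nrow(cropped), 4)
  expect_equal(cropped$a_res, 3:6)
  expect_equal(cropped$label, rep(1L, 4))
  expect_error(crop_stream(run, 0, 5), "start")
})

test_that("gc_run validates its invariants", {
  expect_error(gc_run(1:3, 1:2), "same length")
  expect_error(gc_run(-1, 1), "nonnegative")
  expect_error(gc_run(1, 1, label = 2), "binary")
  expect_error(gc_run(1, 1, fs = 0), "positive")
})
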