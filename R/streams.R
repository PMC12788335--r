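#' Construct an IMU run stream
#'
#' A run stream is a tibble with one row per frame and columns `time_s`,
#' `a_res` (resultant acceleration), `w_res` (resultant angular velocity) and,
#' when ground truth is available, a binary `label` column (1 = ground
#' contact, 0 = flight). Sampling rate and athlete/run/leg identity travel as
#' attributes. Frame indices are 1-based and contact intervals are half-open
#' `[ic, tc)` throughout the package.
#'
#' @param a_res,w_res Nonnegative numeric vectors of equal length.
#' @param label Optional binary vector (0/1) of the same length.
#' @param fs Sampling rate in Hz.
#' @param athlete_id,run_id,leg Stream identity (leg is `"left"` or
#'   `"right"`).
#' @param true_segments Optional tibble of ground-truth contacts with columns
#'   `ic` and `tc` (half-open frame intervals).
#' @return A `gc_run` tibble.
#' @export
gc_run <- function(a_res, w_res, label = NULL, fs = 250,
                   athlete_id = NA_character_, run_id = NA_character_,
                   leg = NA_character_, true_segments = NULL) {
  if (length(a_res) != length(w_res)) {
    abort("a_res and w_res must have the same length")
  }
  if (!is.null(label) && length(label) != length(a_res)) {
    abort("label must have the same length as the signal channels")
  }
  if (fs <= 0) abort("fs must be positive")
  if (length(a_res) && (anyNA(a_res) || anyNA(w_res))) {
    abort("signal channels must not contain missing values")
  }
  if (length(a_res) && (min(a_res) < 0 || min(w_res) < 0)) {
    abort("resultant channels are Euclidean norms and must be nonnegative")
  }
  check_binary(label, "label")
  n <- length(a_res)
  out <- tibble(
    time_s = if (n) (seq_len(n) - 1) / fs else numeric(),
    a_res = as.numeric(a_res),
    w_res = as.numeric(w_res)
  )
  if (!is.null(label)) out$label <- as.integer(label)
  structure(out,
    class = c("gc_run", class(out)),
    fs = fs, athlete_id = athlete_id, run_id = run_id, leg = leg,
    true_segments = true_segments
  )
}

check_binary <- function(x, field) {
  if (is.null(x)) return(invisible(x))
  if (anyNA(x)) abort(paste0("field '", field, "' contains missing values"))
  if (!all(x %in% c(0, 1))) {
    abort(paste0("field '", field, "' must be binary (0/1); found other values"))
  }
  invisible(x)
}

#' @export
print.gc_run <- function(x, ...) {
  cat(sprintf(
    "<gc_run> %s/%s/%s: %d frames @ %g Hz%s\n",
    attr(x, "athlete_id"), attr(x, "run_id"), attr(x, "leg"),
    nrow(x), attr(x, "fs"),
    if ("label" %in% names(x)) sprintf(", %d contact frames", sum(x$label)) else ""
  ))
  NextMethod()
}

run_fs <- function(run) attr(run, "fs")

#' Compute resultant IMU channels from tri-axial data
#'
#' Collapses raw tri-axial accelerometer and gyroscope channels to their
#' per-frame Euclidean norms, the two input channels of the contact detector.
#' The resultant is invariant under rotations of the sensor frame, which is
#' what makes it usable across mounting orientations.
#'
#' @param data Data frame with columns `accel_x`, `accel_y`, `accel_z`,
#'   `gyro_x`, `gyro_y`, `gyro_z`.
#' @param fs Sampling rate of the raw recording in Hz (default 1125).
#' @inheritParams gc_run
#' @return A [gc_run()] stream with `a_res` and `w_res` at the input rate.
#' @export
compute_resultant <- function(data, fs = 1125, athlete_id = NA_character_,
                              run_id = NA_character_, leg = NA_character_) {
  need <- c("accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("missing tri-axial channel(s): ", paste(miss, collapse = ", ")))
  }
  lens <- vapply(data[need], length, integer(1))
  if (length(unique(lens)) != 1) {
    abort("all six tri-axial channels must share one length")
  }
  a <- sqrt(data$accel_x^2 + data$accel_y^2 + data$accel_z^2)
  w <- sqrt(data$gyro_x^2 + data$gyro_y^2 + data$gyro_z^2)
  gc_run(a, w, fs = fs, athlete_id = athlete_id, run_id = run_id, leg = leg)
}

# Kaiser-windowed polyphase FIR rational resampler (zero-stuff by `up`,
# lowpass at the tighter of the two Nyquist limits, keep every `down`-th
# sample, compensating the filter group delay). Signal tails are padded with
# the edge values, and the output is normalized by the resampler's response
# to a constant, so constant signals are reproduced exactly.
resample_poly <- function(x, up, down, half_width = 10L, beta = 5.0) {
  n_out <- round(length(x) * up / down)
  if (length(x) == 0 || n_out == 0) return(numeric(0))
  if (up == down) return(x)
  max_rate <- max(up, down)
  half_len <- half_width * max_rate
  n <- -half_len:half_len
  fc <- 1 / max_rate # cutoff as a fraction of the upsampled Nyquist
  h_ideal <- fc * ifelse(n == 0, 1, sin(pi * fc * n) / (pi * fc * n))
  w <- besselI(beta * sqrt(pmax(0, 1 - (n / half_len)^2)), 0) / besselI(beta, 0)
  h <- h_ideal * w * up
  pad <- ceiling(half_len / up) + 1L
  one_pass <- function(sig) {
    xp <- c(rep(sig[1], pad), sig, rep(sig[length(sig)], pad))
    x_up <- numeric(length(xp) * up)
    x_up[seq(1, length(x_up), by = up)] <- xp
    full <- convolve(x_up, rev(h), type = "open")
    idx <- half_len + 1 + pad * up + (0:(n_out - 1)) * down
    full[idx]
  }
  one_pass(x) / one_pass(rep(1, length(x)))
}

# smallest integer p/q with p/q == a/b for near-rational a, b
rational_ratio <- function(target, source) {
  scale <- 1
  while ((abs(target * scale - round(target * scale)) > 1e-9 ||
    abs(source * scale - round(source * scale)) > 1e-9) && scale < 1e6) {
    scale <- scale * 10
  }
  p <- round(target * scale)
  q <- round(source * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Resample a run stream to a new rate
#'
#' Rational polyphase FIR resampling (Kaiser-windowed sinc, anti-aliased),
#' e.g. 1125 Hz recordings to the 250 Hz working rate (ratio 2/9). The output
#' length is `round(n * target_fs / fs)`. A binary `label` column, if present,
#' is carried over by nearest-frame lookup and stays binary.
#'
#' @param run A [gc_run()] stream.
#' @param target_fs Target sampling rate in Hz.
#' @return The resampled `gc_run`.
#' @export
resample_stream <- function(run, target_fs) {
  fs <- run_fs(run)
  if (target_fs <= 0) abort("target_fs must be positive")
  if (target_fs > fs) {
    rlang::inform(sprintf("upsampling from %g Hz to %g Hz", fs, target_fs))
  }
  pq <- rational_ratio(target_fs, fs)
  a <- resample_poly(run$a_res, pq[1], pq[2])
  w <- resample_poly(run$w_res, pq[1], pq[2])
  # FIR ringing can dip marginally below zero on a nonnegative signal
  a <- pmax(a, 0)
  w <- pmax(w, 0)
  lab <- NULL
  if ("label" %in% names(run) && length(a)) {
    src <- pmin(nrow(run), pmax(1, round((seq_along(a) - 1) * fs / target_fs) + 1))
    lab <- run$label[src]
  }
  gc_run(a, w, lab, fs = target_fs,
    athlete_id = attr(run, "athlete_id"), run_id = attr(run, "run_id"),
    leg = attr(run, "leg"), true_segments = NULL
  )
}

#' Crop a run stream to a frame window
#'
#' @param run A [gc_run()] stream.
#' @param start,end Half-open 1-based frame interval `[start, end)`.
#' @return The cropped `gc_run`.
#' @export
crop_stream <- function(run, start, end) {
  if (start < 1 || end > nrow(run) + 1 || start >= end) {
    abort("need 1 <= start < end <= n_frames + 1")
  }
  idx <- start:(end - 1)
  gc_run(run$a_res[idx], run$w_res[idx],
    if ("label" %in% names(run)) run$label[idx] else NULL,
    fs = run_fs(run), athlete_id = attr(run, "athlete_id"),
    run_id = attr(run, "run_id"), leg = attr(run, "leg")
  )
}

#' Align two event trains by cross-correlation
#'
#' Builds binary impulse trains from two sorted lists of event frames and
#' scans integer lags in `[-max_lag, max_lag]` for the lag maximizing their
#' cross-correlation (the number of exactly coinciding events). Used to
#' synchronize IMU-derived contact events against video-derived label events;
#' the count-based peak is robust to a minority of events being off by a
#' frame. Ties are broken toward the smallest `|lag|`.
#'
#' The returned lag is the shift of `label_events` relative to `imu_events`:
#' `label_events - lag` best aligns with `imu_events`.
#'
#' @param imu_events,label_events Sorted integer frame indices (nonempty).
#' @param max_lag Largest admissible lag in frames.
#' @return Integer lag.
#' @export
synchronize_by_events <- function(imu_events, label_events, max_lag = 100) {
  if (!length(imu_events) || !length(label_events)) {
    abort("both event lists must be nonempty")
  }
  if (is.unsorted(imu_events) || is.unsorted(label_events)) {
    abort("event lists must be sorted")
  }
  lags <- -max_lag:max_lag
  score <- vapply(
    lags,
    function(l) sum((label_events - l) %in% imu_events),
    numeric(1)
  )
  if (max(score) == 0) {
    abort("unsynchronizable: no events coincide at any admissible lag")
  }
  cand <- lags[score == max(score)]
  cand[order(abs(cand), cand)][1]
}

#' Write / read a run stream file
#'
#' Delimited-text streams carry the header `time_s,a_res,w_res,label`, one
#' row per frame; values are printed at 15 significant digits and round-trip
#' to that precision. The `rds` format keeps the full object bit-exactly,
#' including identity attributes.
#'
#' @param run A [gc_run()] with a `label` column.
#' @param path Output file.
#' @param format `"csv"` or `"rds"`.
#' @return `write_run()` returns `path` invisibly; `read_run()` returns the
#'   validated `gc_run`.
#' @export
write_run <- function(run, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(run, path)
  } else {
    df <- tibble(
      time_s = run$time_s, a_res = run$a_res, w_res = run$w_res,
      label = if ("label" %in% names(run)) run$label else integer(nrow(run))
    )
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @param athlete_id,run_id,leg Identity to attach when reading delimited
#'   text (csv files do not carry attributes).
#' @rdname write_run
#' @export
read_run <- function(path, format = c("csv", "rds"), athlete_id = NA_character_,
                     run_id = NA_character_, leg = NA_character_) {
  format <- match.arg(format)
  if (format == "rds") {
    run <- readRDS(path)
    if (!inherits(run, "gc_run")) abort("file does not contain a gc_run")
    return(run)
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  for (field in c("time_s", "a_res", "w_res", "label")) {
    if (!field %in% names(df)) abort(paste0("missing ", field))
    if (anyNA(df[[field]]) || any(!is.finite(df[[field]]))) {
      abort(paste0("field '", field, "' contains missing or non-finite values"))
    }
  }
  check_binary(df$label, "label")
  fs <- if (nrow(df) > 1) 1 / median(diff(df$time_s)) else 250
  gc_run(df$a_res, df$w_res, df$label, fs = round(fs, 6),
    athlete_id = athlete_id, run_id = run_id, leg = leg
  )
}
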