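#' Per-run min-max scaling to [-1.5, 1.5]
#'
#' Each channel of a run is independently mapped by the affine
#' `x -> -1.5 + 3 (x - min) / (max - min)`, so the run's minimum lands on
#' -1.5 and its maximum on +1.5. Scaling is per run because touchdown peak
#' magnitudes vary strongly across athletes, runs and steps; it is per
#' channel because the two channels have unrelated units. A degenerate
#' (constant) channel maps to all zeros, the range midpoint.
#'
#' @param run A [gc_run()] or data frame with `a_res` and `w_res` columns.
#' @return A `gc_scaled` tibble with scaled `a_res`, `w_res` (and `label`
#'   passed through), carrying a `scale_params` attribute recording the
#'   per-channel (min, max) used.
#' @export
scale_minmax <- function(run) {
  for (ch in c("a_res", "w_res")) {
    if (!ch %in% names(run)) abort(paste0("missing channel ", ch))
    if (anyNA(run[[ch]]) || any(!is.finite(run[[ch]]))) {
      abort(paste0("field '", ch, "' contains missing or non-finite values"))
    }
  }
  if (!nrow(run)) abort("cannot scale an empty stream")
  scale1 <- function(x) {
    lo <- min(x)
    hi <- max(x)
    if (hi == lo) list(x = rep(0, length(x)), lo = lo, hi = hi)
    else list(x = -1.5 + 3 * (x - lo) / (hi - lo), lo = lo, hi = hi)
  }
  a <- scale1(run$a_res)
  w <- scale1(run$w_res)
  out <- tibble(a_res = a$x, w_res = w$x)
  if ("label" %in% names(run)) out$label <- run$label
  structure(out,
    class = c("gc_scaled", class(out)),
    fs = attr(run, "fs") %||% NA_real_,
    athlete_id = attr(run, "athlete_id"), run_id = attr(run, "run_id"),
    leg = attr(run, "leg"), true_segments = attr(run, "true_segments"),
    scale_params = tibble(
      channel = c("a_res", "w_res"),
      min = c(a$lo, w$lo), max = c(a$hi, w$hi)
    )
  )
}

#' Slice a stream into fixed-length overlapping windows
#'
#' Windows of `window` frames start at frame 1 and advance by `stride`
#' while they still fit; the incomplete remainder at the end of the run is
#' discarded. With source length L the number of windows is
#' `floor((L - window) / stride) + 1`.
#'
#' @param x A `gc_scaled` (from [scale_minmax()]) or [gc_run()]; a `label`
#'   column, when present, is sliced into the label tensor `Y`.
#' @param window Window length T in frames.
#' @param stride Step between window starts in frames; must satisfy
#'   `0 < stride < window` (strides >= window are rejected, matching the
#'   tuning-grid rule).
#' @return A `gc_windows` list: `X` (N x 2 x T array), `Y` (N x T binary
#'   matrix or NULL), `starts` (1-based window starts), `window`, `stride`,
#'   `source_length`, `fs`, `stream_id`.
#' @export
slice_windows <- function(x, window, stride) {
  if (stride < 1) abort("stride must be a positive number of frames")
  if (stride >= window) abort("stride must be smaller than the window size")
  L <- nrow(x)
  id <- paste(attr(x, "athlete_id"), attr(x, "run_id"), attr(x, "leg"), sep = "/")
  if (window > L) {
    warn(sprintf("stream of %d frames is shorter than the window (%d); no windows produced", L, window))
    starts <- integer(0)
  } else {
    starts <- seq(1L, L - window + 1L, by = stride)
  }
  N <- length(starts)
  X <- array(0, dim = c(N, 2, window))
  Y <- if ("label" %in% names(x)) matrix(0L, N, window) else NULL
  for (i in seq_len(N)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    X[i, 1, ] <- x$a_res[idx]
    X[i, 2, ] <- x$w_res[idx]
    if (!is.null(Y)) Y[i, ] <- x$label[idx]
  }
  structure(list(
    X = X, Y = Y, starts = starts, window = window, stride = stride,
    source_length = L, fs = attr(x, "fs") %||% NA_real_,
    stream_id = id
  ), class = "gc_windows")
}

#' Reassemble per-window predictions into a per-frame series
#'
#' Frame t covered by k >= 1 windows receives the arithmetic mean of the k
#' window predictions at t; frames covered by no window (the discarded
#' remainder at the end of a run, or any uncovered boundary) are set to 0,
#' which also implements the rule that incomplete window predictions at
#' stream edges are reset to 0.
#'
#' @param probs N x T matrix of per-window predictions.
#' @param starts 1-based window start frames (length N).
#' @param source_length Length of the original stream.
#' @return Numeric vector of length `source_length`.
#' @export
reassemble_probs <- function(probs, starts, source_length) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(starts)) {
    abort("probs must have one row per window start")
  }
  T_ <- ncol(probs)
  acc <- numeric(source_length)
  cnt <- numeric(source_length)
  for (i in seq_along(starts)) {
    if (starts[i] + T_ - 1L > source_length) abort("window extends beyond the source stream")
    idx <- starts[i]:(starts[i] + T_ - 1L)
    acc[idx] <- acc[idx] + probs[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out <- numeric(source_length)
  covered <- cnt > 0
  out[covered] <- acc[covered] / cnt[covered]
  out
}

#' Assemble a windowed dataset from several runs
#'
#' Scales each run (per-run min-max), slices it, and concatenates the window
#' tensors across streams, retaining per-window provenance so predictions can
#' be routed back and reassembled per stream.
#'
#' @param runs List of [gc_run()] streams (e.g. one split of
#'   [study_splits()]).
#' @param window,stride Window length and stride in frames.
#' @param scale Scale each run before slicing (default TRUE).
#' @return A `gc_dataset` list: `X` (N x 2 x T), `Y` (N x T), `stream_ids`
#'   (per window), and a `streams` tibble (`stream_id`, `source_length`,
#'   `n_windows`, `fs`) plus per-stream `starts`.
#' @export
build_dataset <- function(runs, window, stride, scale = TRUE) {
  if (!length(runs)) {
    return(structure(list(
      X = array(0, c(0, 2, window)), Y = matrix(0L, 0, window),
      stream_ids = character(0), starts = list(),
      streams = tibble(stream_id = character(), source_length = integer(), n_windows = integer(), fs = numeric()),
      window = window, stride = stride, fs = NA_real_
    ), class = "gc_dataset"))
  }
  fs_all <- vapply(runs, function(r) as.numeric(attr(r, "fs")), numeric(1))
  if (length(unique(fs_all)) != 1) abort("runs have mixed sampling rates")
  ws <- lapply(runs, function(r) {
    slice_windows(if (scale) scale_minmax(r) else r, window, stride)
  })
  X <- do.call(abind1, lapply(ws, function(w) w$X))
  Y <- if (!is.null(ws[[1]]$Y)) do.call(rbind, lapply(ws, function(w) w$Y)) else NULL
  ids <- unlist(lapply(ws, function(w) rep(w$stream_id, length(w$starts))), use.names = FALSE)
  streams <- dplyr::bind_rows(lapply(ws, function(w) {
    tibble(
      stream_id = w$stream_id, source_length = w$source_length,
      n_windows = length(w$starts), fs = w$fs
    )
  }))
  structure(list(
    X = X, Y = Y, stream_ids = ids,
    starts = stats::setNames(lapply(ws, function(w) w$starts), streams$stream_id),
    streams = streams, window = window, stride = stride, fs = fs_all[1]
  ), class = "gc_dataset")
}

# rbind for 3-d arrays along the first margin
abind1 <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) dim(p)[1] > 0, logical(1))]
  if (!length(parts)) {
    return(array(0, c(0, 2, 0)))
  }
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k) out[(at + 1):(at + k), , ] <- p
    at <- at + k
  }
  out
}

#' Route dataset-level window predictions back to per-stream series
#'
#' @param ds A `gc_dataset` from [build_dataset()].
#' @param probs N x T matrix of window predictions aligned with `ds$X`.
#' @return Named list of per-frame probability vectors, one per stream.
#' @export
reassemble_dataset <- function(ds, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(ds$stream_ids)) {
    abort("probs must have one row per dataset window")
  }
  out <- list()
  for (i in seq_len(nrow(ds$streams))) {
    sid <- ds$streams$stream_id[i]
    rows <- ds$stream_ids == sid
    out[[sid]] <- reassemble_probs(
      probs[rows, , drop = FALSE],
      ds$starts[[sid]], ds$streams$source_length[i]
    )
  }
  out
}
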