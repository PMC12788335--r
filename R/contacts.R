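#' Binarize per-frame contact probabilities
#'
#' Probabilities greater than or equal to the threshold become contact (1),
#' anything below becomes flight (0).
#'
#' @param probs Numeric vector of values in \[0, 1\].
#' @param threshold Decision threshold (default 0.5; 0.5 itself maps to 1).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (length(probs) && (anyNA(probs) || min(probs) < 0 || max(probs) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  as.integer(probs >= threshold)
}

#' Remove implausibly short predicted contacts
#'
#' Every maximal run of 1s shorter than `min_frames` is set to 0. The
#' default of 12 frames corresponds to 48 ms at 250 Hz, roughly half of the
#' shortest elite sprint contact times (> 90 ms), so such spikes cannot be
#' real touchdowns. The comparison is strict: an exactly 12-frame contact is
#' kept. Flight (0-runs) is never modified, and the operation is idempotent.
#'
#' @param x Binary 0/1 vector.
#' @param min_frames Minimum contact length kept, in frames.
#' @return Binary vector with short contacts zeroed.
#' @export
remove_short_contacts <- function(x, min_frames = 12) {
  check_binary(x, "binary series")
  if (!length(x)) return(integer(0))
  r <- rle(as.integer(x))
  r$values[r$values == 1L & r$lengths < min_frames] <- 0L
  inverse.rle(r)
}

#' Extract contact segments and IC/TC events from a binary series
#'
#' Each maximal run of 1s becomes one contact segment with half-open frame
#' interval `[ic, tc)`: `ic` is the first contact frame (the 0->1
#' transition) and `tc` the first flight frame after it (the 1->0
#' transition), so `duration_frames = tc - ic`. A contact still in progress
#' at the end of the stream gets `tc = length(x) + 1` and is flagged
#' `open_ended`; open-ended contacts are excluded from duration statistics
#' downstream.
#'
#' @param x Binary 0/1 vector.
#' @param fs Sampling rate in Hz, used for `duration_ms`.
#' @return A `gc_segments` tibble: `step`, `ic`, `tc`, `duration_frames`,
#'   `duration_ms`, `open_ended`; sampling rate in attribute `fs`.
#' @export
extract_segments <- function(x, fs = 250) {
  check_binary(x, "binary series")
  n <- length(x)
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  ic <- starts[keep]
  tc <- ends[keep] + 1L
  out <- tibble(
    step = seq_along(ic),
    ic = as.integer(ic), tc = as.integer(tc),
    duration_frames = as.integer(tc - ic),
    duration_ms = (tc - ic) * 1000 / fs,
    open_ended = as.integer(tc) == n + 1L & n > 0 & rev(r$values)[1] == 1L
  )
  structure(out, class = c("gc_segments", class(out)), fs = fs)
}

#' All flight/contact transitions of a segment table
#'
#' The sorted union of IC events (0->1) and TC events (1->0). The trailing
#' boundary of an open-ended contact is not a transition and is omitted.
#'
#' @param segments A `gc_segments` tibble.
#' @return Sorted integer frame indices.
#' @export
all_transitions <- function(segments) {
  sort(c(segments$ic, segments$tc[!segments$open_ended]))
}

#' End-to-end contact prediction for one run
#'
#' Composition of the full inference path: per-run min-max scaling, window
#' slicing, evaluation-mode forward pass, overlap-averaged reassembly,
#' binarization at 0.5 and, optionally, removal of contacts shorter than
#' `min_frames`, followed by segment extraction.
#'
#' @param fit A `gc_fit` (or trained `gc_model` plus explicit `window` and
#'   `stride`).
#' @param run A [gc_run()] stream at the model's working rate.
#' @param window,stride Window parameters; default to those the model was
#'   trained with.
#' @param threshold Binarization threshold.
#' @param min_frames Postprocessing cutoff in frames.
#' @param postprocess Apply the short-contact filter (default TRUE).
#' @return A `gc_prediction` list: `probs` (per-frame probabilities),
#'   `binary_raw`, `binary` (postprocessed), `segments`
#'   (postprocessed [extract_segments()] table), `segments_raw`,
#'   `stream_id`, `fs`.
#' @export
predict_contacts <- function(fit, run, window = NULL, stride = NULL,
                             threshold = 0.5, min_frames = 12,
                             postprocess = TRUE) {
  if (inherits(fit, "gc_fit")) {
    model <- fit$model
    window <- window %||% fit$window
    stride <- stride %||% fit$stride
  } else if (inherits(fit, "gc_model")) {
    model <- fit
    if (is.null(window) || is.null(stride)) {
      abort("window and stride must be given when predicting from a bare gc_model")
    }
  } else {
    abort("fit must be a gc_fit or gc_model")
  }
  if (nrow(run) < window) {
    abort(sprintf(
      "stream has %d frames but the window is %d; use a smaller window",
      nrow(run), window
    ))
  }
  fs <- attr(run, "fs")
  ws <- slice_windows(scale_minmax(run), window, stride)
  probs_w <- predict_proba(model, ws$X)
  probs <- reassemble_probs(probs_w, ws$starts, ws$source_length)
  braw <- binarize(probs, threshold)
  b <- if (postprocess) remove_short_contacts(braw, min_frames) else braw
  structure(list(
    probs = probs,
    binary_raw = braw,
    binary = b,
    segments = extract_segments(b, fs),
    segments_raw = extract_segments(braw, fs),
    stream_id = paste(attr(run, "athlete_id"), attr(run, "run_id"),
      attr(run, "leg"),
      sep = "/"
    ),
    fs = fs
  ), class = "gc_prediction")
}

#' @export
print.gc_prediction <- function(x, ...) {
  cat(sprintf(
    "<gc_prediction> %s: %d frames, %d contacts (%d before postprocessing)\n",
    x$stream_id, length(x$probs), nrow(x$segments), nrow(x$segments_raw)
  ))
  invisible(x)
}

#' Contact table of one or more predictions
#'
#' @param predictions A `gc_prediction` or list of them.
#' @return Tidy tibble: `stream_id`, `step`, `ic`, `tc`, `duration_frames`,
#'   `duration_ms`, `open_ended`.
#' @export
contact_table <- function(predictions) {
  if (inherits(predictions, "gc_prediction")) predictions <- list(predictions)
  dplyr::bind_rows(lapply(predictions, function(p) {
    dplyr::mutate(as_tibble(p$segments), stream_id = p$stream_id, .before = 1)
  }))
}
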