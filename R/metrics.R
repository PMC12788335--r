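#' Symmetric nearest-neighbour distances between two event lists
#'
#' For every true event the distance (in frames) to the nearest predicted
#' event, and for every predicted event the distance to the nearest true
#' event, as one multiset. Its mean and median are the per-stream "mean
#' Hausdorff" and "median Hausdorff" statistics: the averaged symmetric
#' form is used rather than the classical max-of-min Hausdorff, which, as a
#' maximum, could not produce sub-frame per-run means. The classical
#' directed maxima are available via `summary = "max"`.
#'
#' @param pred_events,true_events Sorted nonempty frame-index vectors.
#' @param summary `"all"` (default) returns the distance multiset; `"max"`
#'   returns the classical symmetric Hausdorff distance.
#' @return Numeric vector of distances, or a single max distance.
#' @export
transition_distances <- function(pred_events, true_events, summary = c("all", "max")) {
  summary <- match.arg(summary)
  if (!length(pred_events) || !length(true_events)) {
    abort("both event lists must be nonempty (metric undefined otherwise)")
  }
  nn <- function(a, b) vapply(a, function(x) min(abs(x - b)), numeric(1))
  d <- c(nn(true_events, pred_events), nn(pred_events, true_events))
  if (summary == "max") max(d) else d
}

# greedy one-to-one overlap matching of predicted to true segments, in
# temporal order; overlap means >= 1 shared frame of the half-open intervals
match_segments <- function(pred, true) {
  used <- rep(FALSE, nrow(true))
  pairs <- list()
  for (i in seq_len(nrow(pred))) {
    for (j in which(!used)) {
      if (max(pred$ic[i], true$ic[j]) < min(pred$tc[i], true$tc[j])) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(pred_idx = i, true_idx = j)
        break
      }
    }
  }
  if (!length(pairs)) {
    return(tibble(pred_idx = integer(), true_idx = integer()))
  }
  as_tibble(do.call(rbind, pairs))
}

#' Event-level precision and recall of contact detection
#'
#' A predicted contact is a true positive iff it overlaps (shares at least
#' one frame with) an as-yet-unmatched true contact; matching is greedy in
#' temporal order and one-to-one. Precision = TP / (TP + FP),
#' recall = TP / (TP + FN). When there are no predicted contacts, precision
#' has an empty denominator and is reported as 1 with `undefined_precision`
#' flagged (no false positives were produced); symmetrically for recall
#' with an empty truth.
#'
#' @param pred_segments,true_segments `gc_segments` tibbles
#'   (see [extract_segments()]).
#' @return One-row tibble: `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `undefined_precision`, `undefined_recall`.
#' @export
event_precision_recall <- function(pred_segments, true_segments) {
  m <- match_segments(pred_segments, true_segments)
  tp <- nrow(m)
  fp <- nrow(pred_segments) - tp
  fn <- nrow(true_segments) - tp
  tibble(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn,
    undefined_precision = tp + fp == 0,
    undefined_recall = tp + fn == 0
  )
}

#' Rand index between two binary frame labelings
#'
#' Treating each frame's binary label as a cluster assignment, the Rand
#' index is the fraction of the `choose(L, 2)` frame pairs on which the two
#' labelings agree: both frames in the same class under both labelings, or
#' in different classes under both. Computed in closed form from the 2 x 2
#' label confusion counts; symmetric, equal to 1 iff the sequences are
#' identical.
#'
#' @param a,b Binary 0/1 vectors of equal length L >= 2.
#' @return Value in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  check_binary(a, "a")
  check_binary(b, "b")
  L <- length(a)
  if (length(b) != L) abort("sequences must have equal length")
  if (L < 2) abort("need at least two frames")
  ch2 <- function(n) n * (n - 1) / 2
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  same_a <- ch2(n11 + n10) + ch2(n01 + n00)
  same_b <- ch2(n11 + n01) + ch2(n10 + n00)
  same_both <- ch2(n11) + ch2(n10) + ch2(n01) + ch2(n00)
  (ch2(L) - same_a - same_b + 2 * same_both) / ch2(L)
}

#' Per-stream model metrics
#'
#' Computes, for one stream, the mean/median Hausdorff distance between
#' predicted and true transitions (IC and TC events pooled), event-level
#' precision and recall, and the frame-level Rand index. When either
#' transition list is empty the Hausdorff statistics are undefined and
#' reported as `NA` with the cause in `note`.
#'
#' @param pred,truth Binary 0/1 vectors of equal length (predicted and
#'   ground-truth contact series).
#' @param fs Sampling rate in Hz (for the ms columns).
#' @param stream_id Optional identifier carried into the output.
#' @return One-row tibble of `RunMetrics`: Hausdorff statistics in frames
#'   and ms, `precision`, `recall`, `rand_index`, event counts, `note`.
#' @export
stream_metrics <- function(pred, truth, fs = 250, stream_id = NA_character_) {
  ps <- extract_segments(pred, fs)
  ts <- extract_segments(truth, fs)
  pe <- all_transitions(ps)
  te <- all_transitions(ts)
  if (length(pe) && length(te)) {
    d <- transition_distances(pe, te)
    mh <- mean(d)
    mdh <- median(d)
    note <- NA_character_
  } else {
    mh <- NA_real_
    mdh <- NA_real_
    note <- if (!length(pe)) "no predicted transitions" else "no true transitions"
  }
  pr <- event_precision_recall(ps, ts)
  tibble(
    stream_id = stream_id,
    mean_hausdorff_frames = mh, mean_hausdorff_ms = mh * 1000 / fs,
    median_hausdorff_frames = mdh, median_hausdorff_ms = mdh * 1000 / fs,
    precision = pr$precision, recall = pr$recall,
    rand_index = rand_index(pred, truth),
    n_true_events = length(te), n_pred_events = length(pe),
    note = note
  )
}

#' Aggregate per-stream metrics across a dataset
#'
#' Streams are first summarized individually ([stream_metrics()]), then
#' averaged across the dataset: mean +/- SD (sample SD, n - 1) for the mean
#' Hausdorff, precision, recall and Rand index; median +/- median absolute
#' deviation (raw MAD, no consistency constant) for the median Hausdorff.
#' Hausdorff rows are reported in frames with the ms equivalents
#' (`x 1000 / fs`) alongside. Streams with undefined (missing) values are
#' dropped from the affected row with their count recorded in `n_missing`.
#'
#' @param per_stream Tibble of per-stream rows from [stream_metrics()].
#' @param fs Sampling rate in Hz.
#' @return Tibble with one row per metric: `metric`, `center`, `spread`,
#'   `center_ms`, `spread_ms`, `n`, `n_missing`.
#' @export
aggregate_metrics <- function(per_stream, fs = 250) {
  if (!nrow(per_stream)) abort("no streams to aggregate")
  row <- function(metric, x, stat = c("mean", "median"), ms = FALSE) {
    stat <- match.arg(stat)
    ok <- !is.na(x)
    x <- x[ok]
    center <- if (stat == "mean") mean(x) else median(x)
    spread <- if (length(x) < 2) 0 else if (stat == "mean") sd(x) else mad(x, constant = 1)
    tibble(
      metric = metric, center = center, spread = spread,
      center_ms = if (ms) center * 1000 / fs else NA_real_,
      spread_ms = if (ms) spread * 1000 / fs else NA_real_,
      n = sum(ok), n_missing = sum(!ok)
    )
  }
  dplyr::bind_rows(
    row("mean_hausdorff", per_stream$mean_hausdorff_frames, "mean", ms = TRUE),
    row("median_hausdorff", per_stream$median_hausdorff_frames, "median", ms = TRUE),
    row("precision", per_stream$precision),
    row("recall", per_stream$recall),
    row("rand_index", per_stream$rand_index)
  )
}

#' Evaluate a fitted model over a set of labelled runs
#'
#' Runs the end-to-end prediction path on every stream and assembles the
#' per-stream metric table, with and without postprocessing.
#'
#' @param fit A `gc_fit`.
#' @param runs List of labelled [gc_run()] streams.
#' @param postprocess Use the postprocessed predictions (default TRUE);
#'   `FALSE` evaluates the raw binarized output.
#' @return Tibble of per-stream metrics (one row per stream).
#' @export
evaluate_runs <- function(fit, runs, postprocess = TRUE) {
  dplyr::bind_rows(lapply(runs, function(r) {
    p <- predict_contacts(fit, r, postprocess = TRUE)
    b <- if (postprocess) p$binary else p$binary_raw
    stream_metrics(b, r$label, fs = attr(r, "fs"), stream_id = p$stream_id)
  }))
}
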