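#' Pair predicted and ground-truth contact durations
#'
#' Matches predicted to true contacts with the same greedy one-to-one
#' overlap rule as [event_precision_recall()]; only matched pairs enter the
#' paired-duration table, and pairs involving an open-ended contact are
#' excluded from duration statistics. Unmatched segments are counted in the
#' attributes `n_unmatched_pred` / `n_unmatched_true`.
#'
#' @param pred_segments,true_segments `gc_segments` tibbles from one stream.
#' @param stream_id Identifier carried into the table.
#' @return A `gc_pairs` tibble: `stream_id`, `step` (true contact's
#'   temporal index), `gt_ms`, `pred_ms`, `ic_dev_ms`, `tc_dev_ms`.
#' @export
pair_durations <- function(pred_segments, true_segments,
                           stream_id = NA_character_) {
  fs <- attr(true_segments, "fs") %||% attr(pred_segments, "fs") %||% 250
  m <- match_segments(pred_segments, true_segments)
  keep <- !pred_segments$open_ended[m$pred_idx] & !true_segments$open_ended[m$true_idx]
  m <- m[keep, , drop = FALSE]
  out <- tibble(
    stream_id = stream_id,
    step = true_segments$step[m$true_idx],
    gt_ms = true_segments$duration_ms[m$true_idx],
    pred_ms = pred_segments$duration_ms[m$pred_idx],
    ic_dev_ms = (pred_segments$ic[m$pred_idx] - true_segments$ic[m$true_idx]) * 1000 / fs,
    tc_dev_ms = (pred_segments$tc[m$pred_idx] - true_segments$tc[m$true_idx]) * 1000 / fs
  )
  structure(out,
    class = c("gc_pairs", class(out)),
    n_unmatched_pred = nrow(pred_segments) - nrow(m),
    n_unmatched_true = nrow(true_segments) - nrow(m),
    fs = fs
  )
}

#' Paired durations across a whole evaluation set
#'
#' @param predictions List of `gc_prediction` objects (see
#'   [predict_contacts()]).
#' @param runs The matching list of labelled [gc_run()] streams.
#' @return A pooled `gc_pairs` tibble.
#' @export
pair_study <- function(predictions, runs) {
  stopifnot(length(predictions) == length(runs))
  parts <- lapply(seq_along(runs), function(i) {
    truth <- extract_segments(runs[[i]]$label, fs = attr(runs[[i]], "fs"))
    pair_durations(predictions[[i]]$segments, truth,
      stream_id = predictions[[i]]$stream_id
    )
  })
  out <- dplyr::bind_rows(parts)
  structure(out,
    class = c("gc_pairs", class(tibble())),
    n_unmatched_pred = sum(vapply(parts, attr, numeric(1), "n_unmatched_pred")),
    n_unmatched_true = sum(vapply(parts, attr, numeric(1), "n_unmatched_true")),
    fs = attr(parts[[1]], "fs")
  )
}

#' Bland-Altman agreement analysis of contact times
#'
#' Differences are taken as PRED - GT throughout. Reports the bias (mean
#' difference), the 95% limits of agreement `bias +/- 1.96 SD` (sample SD),
#' the mean absolute difference +/- SD, and a heteroscedasticity check:
#' `|d|` (or, optionally, signed `d`) is regressed on the pair means and
#' proportional bias is flagged when r^2 > 0.1.
#'
#' @param pairs A `gc_pairs` tibble with at least 3 rows.
#' @param regress `"absolute"` (default) regresses `|d|` on the means;
#'   `"signed"` regresses `d`.
#' @return A `gc_bland_altman` one-row tibble: `bias_ms`, `sd_ms`,
#'   `loa_low_ms`, `loa_high_ms`, `mean_abs_diff_ms`, `sd_abs_diff_ms`,
#'   `het_r2`, `heteroscedastic`, `n`; the per-pair means/differences are
#'   attached as attribute `data` for plotting.
#' @export
bland_altman <- function(pairs, regress = c("absolute", "signed")) {
  regress <- match.arg(regress)
  if (nrow(pairs) < 3) abort("Bland-Altman needs at least 3 pairs")
  d <- pairs$pred_ms - pairs$gt_ms
  mns <- (pairs$pred_ms + pairs$gt_ms) / 2
  bias <- mean(d)
  s <- sd(d)
  y <- if (regress == "absolute") abs(d) else d
  r2 <- if (sd(y) == 0 || sd(mns) == 0) 0 else summary(lm(y ~ mns))$r.squared
  out <- tibble(
    bias_ms = bias, sd_ms = s,
    loa_low_ms = bias - 1.96 * s, loa_high_ms = bias + 1.96 * s,
    mean_abs_diff_ms = mean(abs(d)), sd_abs_diff_ms = sd(abs(d)),
    het_r2 = r2, heteroscedastic = r2 > 0.1, n = length(d)
  )
  structure(out,
    class = c("gc_bland_altman", class(out)),
    data = tibble(mean_ms = mns, diff_ms = d, step = pairs$step)
  )
}

# Wilcoxon signed-rank statistic; exact null via psignrank when there are
# no zero differences and no tied magnitudes, else a normal approximation
# with Pratt handling of zeros and a tie correction
wilcoxon_signed_rank <- function(d) {
  n <- length(d)
  z_ct <- sum(d == 0)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  ties <- any(duplicated(abs(d[d != 0])))
  # Pratt: zeros are ranked but their ranks belong to neither sign
  e_w <- n * (n + 1) / 4 - z_ct * (z_ct + 1) / 4
  tab <- table(abs(d[d != 0])) # tie groups among nonzero magnitudes
  v_w <- n * (n + 1) * (2 * n + 1) / 24 - z_ct * (z_ct + 1) * (2 * z_ct + 1) / 24 -
    sum(tab^3 - tab) / 48
  zstat <- if (v_w <= 0) 0 else (w_pos - e_w) / sqrt(v_w)
  if (z_ct == 0 && !ties && n <= 25) {
    p <- 2 * min(psignrank(w_pos, n), 1 - psignrank(w_pos - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- if (v_w <= 0) 1 else 2 * pnorm(-abs(zstat))
    method <- "normal-pratt"
  }
  list(statistic = w_pos, p = p, z = zstat, method = method)
}

label_effect_size <- function(r) {
  dplyr::case_when(
    r < 0.2 ~ "trivial", r < 0.5 ~ "small", r < 0.8 ~ "medium", TRUE ~ "large"
  )
}

label_spearman <- function(rho) {
  a <- abs(rho)
  dplyr::case_when(
    a < 0.1 ~ "trivial", a < 0.3 ~ "small", a < 0.5 ~ "moderate",
    a < 0.7 ~ "large", a < 0.9 ~ "very large", TRUE ~ "almost perfect"
  )
}

#' Rank-based agreement statistics for paired contact times
#'
#' Spearman correlation between ground-truth and predicted contact times
#' (with the Hopkins magnitude labels), a two-sided Wilcoxon signed-rank
#' test on the paired differences (PRED - GT; exact null when feasible,
#' otherwise a normal approximation with the Pratt rule for zero
#' differences), and the effect size `r = |Z| / sqrt(n)` with the
#' conventional bands (<0.2 trivial, 0.2-0.49 small, 0.5-0.79 medium,
#' >= 0.8 large).
#'
#' @param pairs A `gc_pairs` tibble with at least 5 rows.
#' @return One-row tibble: `spearman_rho`, `spearman_p`, `spearman_label`,
#'   `wilcoxon_p`, `wilcoxon_method`, `effect_size`, `effect_label`, `n`.
#' @export
rank_stats <- function(pairs) {
  if (nrow(pairs) < 5) abort("rank statistics need at least 5 pairs")
  d <- pairs$pred_ms - pairs$gt_ms
  ct <- suppressWarnings(
    cor.test(pairs$gt_ms, pairs$pred_ms, method = "spearman", exact = FALSE)
  )
  wt <- wilcoxon_signed_rank(d)
  es <- abs(wt$z) / sqrt(length(d))
  tibble(
    spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
    spearman_label = label_spearman(unname(ct$estimate)),
    wilcoxon_p = wt$p, wilcoxon_method = wt$method,
    effect_size = es, effect_label = label_effect_size(es),
    n = length(d)
  )
}

#' MAPE and RMSE of predicted contact times
#'
#' @param pairs A `gc_pairs` tibble; ground-truth durations must be
#'   positive.
#' @return One-row tibble: `mape_pct`, `rmse_ms`, `n`.
#' @export
error_measures <- function(pairs) {
  if (any(pairs$gt_ms <= 0)) abort("ground-truth durations must be positive")
  d <- pairs$pred_ms - pairs$gt_ms
  tibble(
    mape_pct = mean(abs(d) / pairs$gt_ms) * 100,
    rmse_ms = sqrt(mean(d^2)),
    n = length(d)
  )
}

#' Signed IC/TC event deviations
#'
#' Per matched contact, the signed deviation of the predicted IC and TC
#' events from the ground truth, in ms (PRED - GT; at 250 Hz every
#' deviation is a multiple of the 4 ms frame period).
#'
#' @param pairs A `gc_pairs` tibble (its `ic_dev_ms` / `tc_dev_ms`
#'   columns).
#' @return List with `deviations` (tibble `kind`, `stream_id`, `step`,
#'   `deviation_ms`) and `summary` (per-kind mean, SD, n).
#' @export
event_deviation_summary <- function(pairs) {
  dev <- dplyr::bind_rows(
    tibble(
      kind = "IC", stream_id = pairs$stream_id, step = pairs$step,
      deviation_ms = pairs$ic_dev_ms
    ),
    tibble(
      kind = "TC", stream_id = pairs$stream_id, step = pairs$step,
      deviation_ms = pairs$tc_dev_ms
    )
  )
  summ <- dplyr::summarise(dplyr::group_by(dev, .data$kind),
    mean_ms = mean(.data$deviation_ms),
    sd_ms = if (dplyr::n() < 2) 0 else sd(.data$deviation_ms),
    n = dplyr::n(), .groups = "drop"
  )
  list(deviations = dev, summary = summ)
}

#' Step-wise contact-time table
#'
#' Mean +/- SD contact times per step (steps numbered by temporal order
#' within each stream) for ground truth and predictions, plus a pooled
#' total-steps column.
#'
#' @param pairs A `gc_pairs` tibble.
#' @return Tibble with one row per step and a final `"total"` row:
#'   `step`, `n`, `gt_mean_ms`, `gt_sd_ms`, `pred_mean_ms`, `pred_sd_ms`.
#' @export
stepwise_table <- function(pairs) {
  one <- function(df, label) {
    tibble(
      step = label, n = nrow(df),
      gt_mean_ms = mean(df$gt_ms),
      gt_sd_ms = if (nrow(df) < 2) 0 else sd(df$gt_ms),
      pred_mean_ms = mean(df$pred_ms),
      pred_sd_ms = if (nrow(df) < 2) 0 else sd(df$pred_ms)
    )
  }
  per_step <- dplyr::bind_rows(lapply(
    split(pairs, pairs$step),
    function(df) one(df, as.character(df$step[1]))
  ))
  dplyr::bind_rows(per_step, one(pairs, "total"))
}

#' Worst-case contact-time quantization error
#'
#' At sampling rate `fs` a frame lasts `1000 / fs` ms; with frame-perfect
#' event detection the true IC can still lie up to one frame before the
#' detected frame and the true TC up to one frame after, so a contact of
#' `gc_ms` can be mis-measured by up to two frame periods:
#' `2 * (1000 / fs) / gc_ms * 100` percent. Strictly decreasing in both
#' arguments. The default contact time of 94 ms is a short elite-level
#' sprint contact.
#'
#' @param fs Sampling rate in Hz.
#' @param gc_ms Ground-contact duration in ms.
#' @return Worst-case error in percent.
#' @export
quantization_error_pct <- function(fs, gc_ms = 94) {
  if (any(fs <= 0) || any(gc_ms <= 0)) abort("fs and gc_ms must be positive")
  2 * (1000 / fs) / gc_ms * 100
}

#' Normality / homogeneity gate for parametric vs nonparametric testing
#'
#' Shapiro-Wilk per sample and Levene's test (Brown-Forsythe, median
#' centred) across samples; the decision is "nonparametric" if any
#' Shapiro-Wilk p or the Levene p falls below `alpha`.
#'
#' @param ... Named numeric samples (or one list of them), each with at
#'   least 3 observations.
#' @param alpha Significance level of the gate.
#' @return List: `shapiro` (tibble `sample`, `p`), `levene_p`, `decision`
#'   (`"parametric"` or `"nonparametric"`).
#' @export
normality_gate <- function(..., alpha = 0.05) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]]) && !is.numeric(samples[[1]])) {
    samples <- samples[[1]]
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 3)) abort("insufficient sample: every group needs at least 3 observations")
  shap <- tibble(
    sample = names(samples),
    p = vapply(samples, function(x) shapiro.test(x)$p.value, numeric(1))
  )
  lev_p <- NA_real_
  if (length(samples) >= 2) {
    df <- data.frame(
      value = unlist(samples, use.names = FALSE),
      group = factor(rep(names(samples), ns))
    )
    lev <- car::leveneTest(value ~ group, data = df, center = median)
    lev_p <- lev[["Pr(>F)"]][1]
  }
  nonpar <- any(shap$p < alpha) || (!is.na(lev_p) && lev_p < alpha)
  list(
    shapiro = shap, levene_p = lev_p,
    decision = if (nonpar) "nonparametric" else "parametric"
  )
}

#' Full agreement report for an evaluation set
#'
#' Bundles the Bland-Altman, rank, error and event-deviation summaries for
#' a paired-duration table.
#'
#' @param pairs A `gc_pairs` tibble.
#' @return A `gc_agreement` list with elements `bland_altman`,
#'   `rank_stats`, `error_measures`, `event_deviations`, `stepwise`, `n`.
#' @export
agreement_report <- function(pairs) {
  structure(list(
    bland_altman = bland_altman(pairs),
    rank_stats = rank_stats(pairs),
    error_measures = error_measures(pairs),
    event_deviations = event_deviation_summary(pairs),
    stepwise = stepwise_table(pairs),
    n = nrow(pairs)
  ), class = "gc_agreement")
}

#' @export
print.gc_agreement <- function(x, ...) {
  ba <- x$bland_altman
  rs <- x$rank_stats
  em <- x$error_measures
  cat(sprintf(
    paste0(
      "<gc_agreement> n = %d contact pairs\n",
      "  bias %.2f ms, LOA [%.2f, %.2f] ms%s\n",
      "  Spearman rho %.3f (%s), Wilcoxon p %.3f, ES %.3f (%s)\n",
      "  MAPE %.2f%%, RMSE %.2f ms\n"
    ),
    x$n, ba$bias_ms, ba$loa_low_ms, ba$loa_high_ms,
    if (ba$heteroscedastic) sprintf(" (heteroscedastic, r2 %.2f)", ba$het_r2) else "",
    rs$spearman_rho, rs$spearman_label, rs$wilcoxon_p,
    rs$effect_size, rs$effect_label, em$mape_pct, em$rmse_ms
  ))
  invisible(x)
}

#' @rdname agreement_report
#' @param x A `gc_agreement`.
#' @param ... Unused.
#' @export
glance.gc_agreement <- function(x, ...) {
  dplyr::bind_cols(
    x$bland_altman[, c("bias_ms", "loa_low_ms", "loa_high_ms", "mean_abs_diff_ms", "sd_abs_diff_ms", "heteroscedastic")],
    x$rank_stats[, c("spearman_rho", "spearman_p", "wilcoxon_p", "effect_size", "effect_label")],
    x$error_measures[, c("mape_pct", "rmse_ms")],
    tibble(n = x$n)
  )
}
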