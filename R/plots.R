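#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a run stream with contact shading
#'
#' @param object A [gc_run()].
#' @param ... Unused.
#' @return A ggplot: both resultant channels over time, ground-contact
#'   periods shaded.
#' @export
autoplot.gc_run <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(
      time_s = object$time_s, `a[RES]` = object$a_res,
      `omega[RES]` = object$w_res
    ),
    -"time_s",
    names_to = "channel", values_to = "value"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value))
  if ("label" %in% names(object)) {
    fs <- attr(object, "fs")
    segs <- extract_segments(object$label, fs)
    if (nrow(segs)) {
      p <- p + ggplot2::geom_rect(
        data = tibble(
          xmin = (segs$ic - 1) / fs, xmax = (segs$tc - 1) / fs
        ),
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "grey85"
      )
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel,
      ncol = 1, scales = "free_y",
      labeller = ggplot2::label_parsed
    ) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf(
        "%s / %s / %s", attr(object, "athlete_id"),
        attr(object, "run_id"), attr(object, "leg")
      )
    )
}

#' Plot the training history of a fitted model
#'
#' @param object A `gc_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation BCE per epoch with the best epoch
#'   marked.
#' @export
autoplot.gc_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL)
}

#' Bland-Altman plot of contact-time agreement
#'
#' Differences (PRED - GT) against pair means, with the bias and the 95%
#' limits of agreement. At 250 Hz the points fall on a 4 ms grid (the frame
#' period), which gives the plot its characteristic banded look.
#'
#' @param object A `gc_bland_altman` (see [bland_altman()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_bland_altman <- function(object, ...) {
  dat <- attr(object, "data")
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean_ms, .data$diff_ms, colour = factor(.data$step))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias_ms) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low_ms, object$loa_high_ms),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "mean of GT and PRED contact time (ms)",
      y = "PRED - GT (ms)", colour = "step"
    )
}

#' Identity plot of predicted vs ground-truth contact times
#'
#' @param pairs A `gc_pairs` tibble.
#' @return A ggplot with the identity line dashed.
#' @export
plot_identity <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$gt_ms, .data$pred_ms, colour = factor(.data$step))) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "GT contact time (ms)", y = "PRED contact time (ms)", colour = "step")
}
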