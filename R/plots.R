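#' Plot a pooled ROC curve
#'
#' @param object A `perim_roc` from [pooled_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.perim_roc <- function(object, ...) {
  d <- tibble::tibble(fpr = 1 - object$specificity,
                      tpr = object$sensitivity)
  d <- d[order(d$fpr, d$tpr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Pooled ROC (%s), AUROC = %.4f",
                      attr(object, "predictor") %||% "predictor",
                      auroc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-second quality series for one subject
#'
#' Shows the normalized RT and RTV traces and the error rate, with
#' increased-error periods shaded. Useful to inspect how vigilance episodes
#' surface in the three series.
#'
#' @param series A `perim_series` tibble.
#' @param subject Subject to plot; defaults to the first.
#' @return A ggplot with one facet per variable.
#' @export
plot_session_series <- function(series, subject = NULL) {
  subject <- subject %||% series$subject_id[1]
  d <- dplyr::filter(tibble::as_tibble(series), .data$subject_id == subject)
  long <- tidyr::pivot_longer(
    d[, c("t_s", "rt", "rtv", "error_rate")],
    cols = c("rt", "rtv", "error_rate"),
    names_to = "variable", values_to = "value"
  )
  shade <- mask_runs(d$t_s, d$err_mask)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value))
  if (nrow(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL, title = subject) +
    ggplot2::theme_minimal()
}

# contiguous TRUE runs of a mask as (start_s, end_s) intervals
mask_runs <- function(t_s, mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(start_s = t_s[starts[keep]], end_s = t_s[ends[keep]])
}
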