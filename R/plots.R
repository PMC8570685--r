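# ggplot2 graphics: trace plot with immobility epochs in magenta and
# mobility in green, immobility raster, ROC curve, Bland-Altman plot.

#' Plot a motion trace
#'
#' Line plot of the per-second delta-area % with epochs colored by state
#' (immobility magenta, mobility green) when a threshold is available.
#'
#' @param object A `motion_trace`.
#' @param threshold Optional cut-point used to color the epochs; defaults to
#'   the trace's `threshold_used` attribute.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motion_trace <- function(object, threshold = NULL, ...) {
  threshold <- threshold %||% attr(object, "threshold_used")
  df <- as_tibble(object)
  if (!is.null(threshold)) {
    df$state <- ifelse(df$value < threshold, "immobile", "mobile")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$second, y = .data$value)) +
    ggplot2::labs(
      x = "time (s)", y = "Δ area (% of previous frame)",
      title = "Per-second motion statistic"
    ) +
    ggplot2::theme_minimal()
  if (is.null(threshold)) {
    return(p + ggplot2::geom_line())
  }
  p +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$state), size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_color_manual(
      values = c(immobile = "magenta3", mobile = "green4")
    )
}

#' Raster plot of immobility bouts
#'
#' Filled black intervals mark immobile seconds against time, revealing the
#' evolution of behavioral despair over the test.
#'
#' @param object An `immobility_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.immobility_track <- function(object, ...) {
  iv <- raster_intervals(object)
  n <- nrow(object)
  ggplot2::ggplot() +
    {
      if (nrow(iv) > 0) {
        ggplot2::geom_rect(
          data = iv,
          ggplot2::aes(
            xmin = .data$start_s, xmax = .data$end_s, ymin = 0, ymax = 1
          ),
          fill = "black"
        )
      }
    } +
    ggplot2::xlim(0, n) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Immobility raster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Plot an ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble(
    fpr = 1 - object$specificity,
    tpr = object$sensitivity
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC (AUC = %.4f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences (automatic - manual) against pair means, with the bias
#' (dotted black) and 95% limits of agreement (dotted magenta).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$mean_pair, y = .data$diff)
  ) +
    ggplot2::geom_hline(yintercept = 0, color = "black") +
    ggplot2::geom_hline(
      yintercept = attr(object, "bias"),
      linetype = "dotted", color = "black"
    ) +
    ggplot2::geom_hline(
      yintercept = c(attr(object, "loa_low"), attr(object, "loa_high")),
      linetype = "dotted", color = "magenta3"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "mean of methods", y = "automatic - manual",
      title = "Bland-Altman agreement"
    ) +
    ggplot2::theme_minimal()
}
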