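#' Box plots of detected angles by axis and nominal angle
#'
#' Mirrors the standard presentation of twist-recovery experiments: detected
#' angles per axis, faceted by the nominal (true) angle, with the truth as a
#' dashed line. Same-subject validation records are overplotted as stars.
#'
#' @param records A records tibble from [run_verification()] or
#'   [run_validation()].
#' @return A ggplot object.
#' @export
plot_detection <- function(records) {
  long <- records_long(records)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$axis,
                                          y = .data$detected,
                                          fill = .data$axis)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$true),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~angle, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "axis", y = "detected angle (deg)")
  if (any(long$same_subject) && !all(long$same_subject)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(long, .data$same_subject),
      shape = 8, colour = "black", size = 1.6
    )
  }
  p
}

#' Bland-Altman plot of true vs detected angles
#'
#' @param records A records tibble.
#' @param relative Plot relative (percent-of-true) differences, as used for
#'   verification; absolute differences otherwise.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(records, relative = FALSE) {
  long <- records_long(records)
  ba <- bland_altman(long$true, long$detected, relative = relative)
  long$diff <- if (relative) {
    100 * (long$true - long$detected) / long$true
  } else {
    long$true - long$detected
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$diff,
                                     colour = .data$axis)) +
    ggplot2::geom_jitter(width = 0.3, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "black") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "true angle (deg)",
                  y = if (relative) "true - detected (% of true)"
                      else "true - detected (deg)")
}

#' Histogram of normalized detected angles
#'
#' Distribution of `100 * detected / true` across all trials, with the mean
#' (solid) and the 100% truth (dashed) marked.
#'
#' @param records A records tibble.
#' @return A ggplot object.
#' @export
plot_normalized <- function(records) {
  long <- records_long(records)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$normalized)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(long$normalized), colour = "red") +
    ggplot2::geom_vline(xintercept = 100, colour = "blue",
                        linetype = "dashed") +
    ggplot2::labs(x = "normalized detected angle (%)", y = "count")
}
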