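#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Loss and validation DSC per epoch for a trained model.
#'
#' @param object a trained `seg_model` (with attached history).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.seg_model <- function(object, ...) {
  hist <- tidy(object)
  assert_that(nrow(hist) > 0, "model has no training history")
  df <- tidyr_longer(hist)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (avoids importing tidyr for one call)
tidyr_longer <- function(hist) {
  dplyr::bind_rows(
    tibble(epoch = hist$epoch, metric = "cross-entropy loss", value = hist$loss),
    tibble(epoch = hist$epoch, metric = "validation DSC", value = hist$val_dsc)
  )
}

#' Plot a metrics report
#'
#' Distribution of per-case metric values by label.
#'
#' @param report tibble from [evaluate_cohort()].
#' @param metric one of `"dsc"`, `"hd95_mm"`, `"msd_mm"`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(report, metric = "dsc") {
  assert_that(metric %in% c("dsc", "hd95_mm", "msd_mm"), "unknown metric")
  ggplot2::ggplot(report, ggplot2::aes(x = .data$label, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
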