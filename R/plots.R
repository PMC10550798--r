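# ggplot2 views of the main result types.

#' Plot amplification curves
#'
#' Linear- or log-scale amplification plot of raw or baseline-corrected
#' fluorescence, one line per well, optionally with a horizontal threshold.
#'
#' @param curves Long curve tibble; pass the output of [subtract_baseline()]
#'   with `corrected = TRUE` to plot corrected signal.
#' @param corrected Plot `rn_corrected` instead of `rn`.
#' @param threshold Optional horizontal threshold line.
#' @param log_y Log10 fluorescence axis (clips non-positive values).
#' @return A ggplot object.
#' @export
plot_amplification <- function(curves, corrected = FALSE, threshold = NULL,
                               log_y = FALSE) {
  ycol <- if (corrected) "rn_corrected" else "rn"
  if (!ycol %in% names(curves)) {
    abort(sprintf("Column `%s` not found in `curves`.", ycol))
  }
  df <- curves |>
    mutate(curve = paste(.data$sample_id, .data$well, sep = ":"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data[[ycol]],
                                        group = .data$curve,
                                        colour = .data$target_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Cycle",
                  y = if (corrected) "Baseline-corrected Rn" else "Rn",
                  colour = "Target") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname call_rate_table
#' @param tbl A call-rate table from [call_rate_table()].
#' @export
plot_call_rate_table <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$call_rate_category,
                                               levels = sort(unique(.data$call_rate_category))),
                                    y = .data$n_targets)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Call-rate category (%)",
                  y = "Cumulative targets with reliable amplification") +
    ggplot2::theme_minimal()
}

#' @rdname rank_stability
#' @param object A `stability_report`.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- tidy.stability_report(object) |>
    mutate(target_id = stats::reorder(.data$target_id, -.data$comprehensive_score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comprehensive_score,
                                   y = .data$target_id)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::facet_wrap(~card, scales = "free_y") +
    ggplot2::labs(x = "Comprehensive stability score (geometric mean of ranks)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname relative_expression
#' @param object An `expression_result`.
#' @method autoplot expression_result
#' @export
autoplot.expression_result <- function(object, ...) {
  df <- tidy.expression_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$ddcq,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-Delta * Delta * "Cq (log2 fold change)"),
                  y = expression(-log[10] ~ "p")) +
    ggplot2::theme_minimal()
}
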