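#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_col geom_hline
#'   geom_tile geom_text geom_histogram geom_rect labs scale_fill_manual
#'   scale_fill_gradient theme_minimal
NULL

DIRECTION_COLORS <- c(activator = "#2166ac", repressor = "#b2182b")

#' Plot a sensitivity profile with its called sites
#'
#' Smoothed mutation sensitivity along the sequence, the calling
#' threshold (mean + 1 sd, dashed), and shaded spans for retained calls
#' coloured by direction.
#'
#' @param object A [sensitivity_profile()].
#' @param calls Optional call tibble from [call_sites()] or
#'   [merge_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_profile
#' @export
autoplot.sensitivity_profile <- function(object, calls = NULL, ...) {
  p <- ggplot(object, aes(x = .data$position, y = .data$E_smooth)) +
    geom_line(linewidth = 0.4)
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + geom_rect(
      data = calls,
      aes(xmin = .data$start, xmax = .data$end, fill = .data$direction),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE) +
      scale_fill_manual(values = DIRECTION_COLORS)
  }
  thr <- attr(calls, "threshold") %||%
    (mean(object$E_smooth) + pop_sd(object$E_smooth))
  p + geom_hline(yintercept = thr, linetype = "dashed") +
    labs(x = "position (bp)", y = "smoothed sensitivity E",
         title = "Gene-expression sensitivity to mutation") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `classifier_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classifier_evaluation
#' @export
autoplot.classifier_evaluation <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "count")
  ggplot(df, aes(x = .data$predicted, y = .data$measured, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "#2166ac") +
    labs(title = sprintf("Accuracy %.1f%% (macro F1 %.2f)",
                         object$accuracy, object$macro_f1)) +
    theme_minimal()
}

#' Plot the expression-bin assignment
#'
#' Histogram of log normalized expression coloured by bin, with the
#' low/high threshold; zero-expression records are counted separately in
#' the subtitle (their log expression is -Inf).
#'
#' @param object An [bin_expression()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expression_binning
#' @export
autoplot.expression_binning <- function(object, bins = 50, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$log_expr), ]
  n_zero <- sum(object$labels == 1L)
  ggplot(df, aes(x = .data$log_expr, fill = .data$bin)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.8) +
    geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    scale_fill_manual(values = c(low = "#fdb863", high = "#5e3c99")) +
    labs(x = "log(normalized mRNA count)", y = "records",
         title = "Expression binning",
         subtitle = sprintf("%d zero-expression records (bin 1) not shown; best p = %.2g",
                            n_zero, object$best_p_value)) +
    theme_minimal()
}

#' Plot training history
#'
#' @param classifier A trained `seq_classifier`.
#' @return A ggplot of per-epoch loss and accuracy on train and
#'   validation partitions.
#' @export
plot_training_history <- function(classifier) {
  h <- tidy(classifier)
  long <- tidyr::pivot_longer(h, -"epoch",
                              names_to = c("partition", "metric"),
                              names_pattern = "(train|val)_(.*)")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$partition)) +
    geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    theme_minimal()
}
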