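# ggplot2 display helpers for the result objects.

#' Plot one or more ROC curves
#'
#' @param ... Named `xtal_cv` objects or `roc_curve()` tibbles; names
#'   label the curves.
#' @return A ggplot object.
#' @export
plot_roc <- function(...) {
  curves <- list(...)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  tbl <- dplyr::bind_rows(lapply(curves, function(x) {
    if (inherits(x, "xtal_cv")) x$roc else x
  }), .id = "predictor")
  ggplot2::ggplot(tbl, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$predictor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xtal_cv <- function(object, ...) {
  plot_roc(`out-of-fold` = object)
}

#' Heatmap of the inter-task output correlations
#'
#' @param corr 5x5 matrix from [output_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_task_correlations <- function(corr) {
  tbl <- tibble::as_tibble(as.data.frame(corr), rownames = "task1") |>
    tidyr::pivot_longer(-"task1", names_to = "task2", values_to = "r") |>
    dplyr::mutate(task1 = factor(.data$task1, levels = TASKS),
                  task2 = factor(.data$task2, levels = rev(TASKS)))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$task1, .data$task2,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Bar chart of the most significant features
#'
#' @param significance Tibble from [feature_significance()].
#' @param top Number of features to show (default 20).
#' @return A ggplot object.
#' @export
plot_feature_significance <- function(significance, top = 20L) {
  tbl <- significance |>
    dplyr::slice_min(.data$rank, n = top) |>
    dplyr::arrange(.data$neg_log10_p)
  tbl$feature_id <- factor(tbl$feature_id, levels = tbl$feature_id)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$neg_log10_p, .data$feature_id)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a wrapper-selection AUC trajectory
#'
#' @param object An `xtal_selection` from [ifs()] or [ffs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xtal_selection <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(.data$size, .data$auc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = length(object$selected),
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(x = "Feature subset size",
                  y = "Cross-validated AUC") +
    ggplot2::theme_minimal()
}
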