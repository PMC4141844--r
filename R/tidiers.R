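# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a wrapper-selection result
#' @param x An `xtal_selection`.
#' @param ... Unused.
#' @return The AUC trajectory as a tibble (one row per evaluated subset
#'   size / accepted round).
#' @export
tidy.xtal_selection <- function(x, ...) x$trajectory

#' @rdname tidy.xtal_selection
#' @return For `glance()`: a one-row summary (method, subset size, AUC).
#' @export
glance.xtal_selection <- function(x, ...) {
  tibble::tibble(method = x$method, n_selected = length(x$selected),
                 auc = x$auc)
}

#' Tidy a cross-validation result
#' @param x An `xtal_cv`.
#' @param ... Unused.
#' @return Per-fold threshold metrics as a tibble.
#' @export
tidy.xtal_cv <- function(x, ...) x$fold_metrics

#' @rdname tidy.xtal_cv
#' @return For `glance()`: one row with the pooled out-of-fold AUC and
#'   mean fold metrics.
#' @export
glance.xtal_cv <- function(x, ...) {
  tibble::tibble(
    folds = max(x$fold_id),
    auc = x$auc,
    accuracy = mean(x$fold_metrics$accuracy),
    mcc = mean(x$fold_metrics$mcc)
  )
}

#' Tidy a trained classifier
#' @param x An `xtal_svm`.
#' @param ... Unused.
#' @return One row per feature used by the model, with its frozen
#'   standardization statistics.
#' @export
tidy.xtal_svm <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids,
                 center = unname(x$center), scale = unname(x$scale))
}

#' @rdname tidy.xtal_svm
#' @return For `glance()`: one-row model summary.
#' @export
glance.xtal_svm <- function(x, ...) {
  tibble::tibble(kernel = x$config$kernel, cost = x$config$cost,
                 gamma = x$fit$gamma,
                 n_features = length(x$feature_ids),
                 n_support = nrow(x$fit$SV))
}

#' Tidy a stacked model
#' @param x An `xtal_stack`.
#' @param ... Unused.
#' @return One row per task with level-1 subset size and kernel.
#' @export
tidy.xtal_stack <- function(x, ...) {
  tibble::tibble(
    task = x$tasks,
    n_features = unname(vapply(x$selected, length, integer(1))[x$tasks]),
    kernel = unname(vapply(x$level1, function(m) m$config$kernel,
                           character(1))[x$tasks])
  )
}

#' Tidy a grid-search result
#' @param x An `xtal_grid`.
#' @param ... Unused.
#' @return The full grid table (kernel, cost, gamma, auc).
#' @export
tidy.xtal_grid <- function(x, ...) x$grid

#' @rdname tidy.xtal_grid
#' @return For `glance()`: the winning configuration and its AUC.
#' @export
glance.xtal_grid <- function(x, ...) {
  tibble::tibble(kernel = x$best$kernel, cost = x$best$cost,
                 gamma = x$best$gamma, auc = x$best_auc)
}
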