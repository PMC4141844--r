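# Probability-output kernel classifiers, kernel/parameter grid search, the
# two-level stacked predictor over the five pipeline tasks, and the mapping
# from crystallizability scores to difficulty tiers.
#
# libsvm's built-in probability training is internally randomized at the C
# level, so calibrated probabilities are produced instead by a
# deterministic Platt-style sigmoid (binomial glm) fitted on the training
# decision values; the whole fit is then reproducible given the data.

TASKS <- c("CLF", "MF", "PF", "CF", "CRYS")

#' SVM configuration
#'
#' @param kernel One of `"RBF"`, `"POLY"`, `"SIG"` (radial basis function,
#'   polynomial, sigmoid).
#' @param cost Soft-margin cost C (> 0, default 1).
#' @param gamma Kernel coefficient (> 0; default `NULL` = libsvm's 1/dim).
#' @param degree Polynomial degree (POLY only, default 3).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("RBF", "POLY", "SIG"), cost = 1,
                       gamma = NULL, degree = 3L) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 degree = as.integer(degree)),
            class = "svm_config")
}

e1071_kernel <- function(kernel) {
  c(RBF = "radial", POLY = "polynomial", SIG = "sigmoid")[[kernel]]
}

# deterministic stratified fold assignment (1..folds per row)
stratified_folds <- function(y, folds, seed) {
  y <- as.integer(factor(y))
  fold_id <- integer(length(y))
  rng <- local({
    set.seed(seed)
    lapply(sort(unique(y)), function(cl) sample(sum(y == cl)))
  })
  for (i in seq_along(sort(unique(y)))) {
    cl <- sort(unique(y))[[i]]
    idx <- which(y == cl)[rng[[i]]]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Train a probability-output SVM classifier
#'
#' Features are standardized to zero mean and unit variance with statistics
#' frozen at training time (constant columns get unit scale). The margin
#' classifier is a libsvm C-SVC; probabilities come from a Platt-style
#' sigmoid calibration (binomial glm on the decision value) fitted on the
#' training set, clamped away from 0/1. Deterministic given (data, config,
#' seed).
#'
#' @param data Feature tibble or matrix (an `id`/`label` column is
#'   ignored if present).
#' @param y Binary labels (coerced to factor; must have two classes).
#' @param config An [svm_config()] list.
#' @param seed Seed recorded in the fingerprint (the fit itself is
#'   deterministic).
#' @return An object of class `xtal_svm` with a `predict()` method
#'   returning probabilities of the positive (second factor level) class.
#' @export
train_classifier <- function(data, y, config = svm_config(), seed = 1L) {
  mat <- feature_matrix(data)
  yf <- factor(y)
  if (nlevels(yf) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (any(!is.finite(mat))) stop("non-finite feature values", call. = FALSE)
  center <- colMeans(mat)
  scale <- apply(mat, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  std <- sweep(sweep(mat, 2L, center), 2L, scale, "/")
  gamma <- if (is.null(config$gamma)) 1 / ncol(std) else config$gamma
  fit <- e1071::svm(std, yf, type = "C-classification",
                    kernel = e1071_kernel(config$kernel),
                    cost = config$cost, gamma = gamma,
                    degree = config$degree, scale = FALSE)
  dv_att <- attr(stats::predict(fit, std, decision.values = TRUE),
                 "decision.values")
  dv <- dv_att[, 1L]
  # orient the decision value towards the positive (second) level
  pos <- levels(yf)[[2L]]
  flip <- !startsWith(colnames(dv_att)[[1L]], paste0(pos, "/"))
  if (flip) dv <- -dv
  ybin <- as.integer(yf == pos)
  platt <- suppressWarnings(
    stats::glm(ybin ~ dv, family = stats::binomial())$coefficients)
  if (anyNA(platt)) platt <- c(0, 1) # degenerate dv: fall back to identity
  model <- list(fit = fit, platt = platt, flip = flip,
                center = center, scale = scale,
                feature_ids = colnames(mat), levels = levels(yf),
                config = config, seed = seed)
  model$fingerprint <- model_fingerprint(model)
  structure(model, class = "xtal_svm")
}

model_fingerprint <- function(model) {
  sv <- model$fit$SV
  paste0(
    format(sum(model$fit$coefs * seq_len(nrow(sv))), digits = 15), ":",
    format(sum(sv^2), digits = 15), ":",
    format(model$fit$rho, digits = 15), ":", length(model$feature_ids))
}

#' Predict crystallization-step probabilities from a trained classifier
#'
#' @param object An `xtal_svm` model.
#' @param newdata Feature tibble or matrix containing the model's feature
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]` for the positive
#'   class.
#' @export
predict.xtal_svm <- function(object, newdata, ...) {
  mat <- feature_matrix(newdata)
  missing <- setdiff(object$feature_ids, colnames(mat))
  if (length(missing) > 0L) {
    stop("newdata is missing feature(s): ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  mat <- mat[, object$feature_ids, drop = FALSE]
  std <- sweep(sweep(mat, 2L, object$center), 2L, object$scale, "/")
  dv <- attr(stats::predict(object$fit, std, decision.values = TRUE),
             "decision.values")[, 1L]
  if (object$flip) dv <- -dv
  p <- stats::plogis(object$platt[[1L]] + object$platt[[2L]] * dv)
  pmin(pmax(unname(p), 1e-6), 1 - 1e-6)
}

#' @export
print.xtal_svm <- function(x, ...) {
  cat("<xtal_svm> ", x$config$kernel, " kernel, C = ", x$config$cost,
      ", ", length(x$feature_ids), " features, ",
      nrow(x$fit$SV), " support vectors\n", sep = "")
  invisible(x)
}

#' Kernel and parameter grid search
#'
#' Evaluates every (kernel, C, gamma) combination by stratified k-fold
#' out-of-fold AUC and returns the best configuration (ties broken by grid
#' order) together with the full grid table.
#'
#' @param data Feature tibble or matrix.
#' @param y Binary labels.
#' @param kernels Kernels to try (default all three).
#' @param cost_grid,gamma_grid Numeric grids (defaults: powers of 4 over
#'   2^-5..2^15 and 2^-15..2^3).
#' @param folds CV folds (default 5).
#' @param seed Fold-split seed.
#' @return A list of class `xtal_grid`: `best` (an [svm_config()]),
#'   `best_auc`, and `grid` (tibble kernel, cost, gamma, auc).
#' @export
grid_search <- function(data, y, kernels = c("RBF", "POLY", "SIG"),
                        cost_grid = 4^(-2:8) / 2,
                        gamma_grid = 4^(-7:2) / 2,
                        folds = 5L, seed = 1L) {
  mat <- feature_matrix(data)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      kernel = kernels, stringsAsFactors = FALSE)
  grid <- grid[c("kernel", "cost", "gamma")]
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(kernel = grid$kernel[[i]], cost = grid$cost[[i]],
                      gamma = grid$gamma[[i]])
    subset_cv_auc(mat, y, colnames(mat), folds, seed, cfg)
  }, numeric(1))
  best <- which.max(aucs)
  structure(list(
    best = svm_config(kernel = grid$kernel[[best]], cost = grid$cost[[best]],
                      gamma = grid$gamma[[best]]),
    best_auc = aucs[[best]],
    grid = tibble::as_tibble(cbind(grid, auc = aucs))
  ), class = "xtal_grid")
}

# ---- stacking --------------------------------------------------------------

check_tasks <- function(x, what) {
  if (!setequal(names(x), TASKS)) {
    stop(what, " must be named with the five tasks ",
         paste(TASKS, collapse = ", "), call. = FALSE)
  }
  x[TASKS]
}

#' Train the five first-level task classifiers
#'
#' One probability-output classifier per pipeline step (CLF, MF, PF, CF,
#' CRYS), each on its own labeled rows and selected feature subset.
#'
#' @param data Feature tibble with an `id` column (the full candidate table
#'   or any table containing every selected feature).
#' @param labels Named list (per task) of data frames with columns `id` and
#'   `label` (0/1), or a single tibble with columns `id`, `task`, `label`.
#' @param selected Named list (per task) of selected feature-id vectors.
#' @param config An [svm_config()] (shared) or named per-task list.
#' @param seed Seed.
#' @return Named list of five `xtal_svm` models, class `xtal_level1`.
#' @export
train_level1 <- function(data, labels, selected, config = svm_config(),
                         seed = 1L) {
  labels <- normalize_labels(labels)
  selected <- check_tasks(selected, "selected")
  configs <- if (inherits(config, "svm_config")) {
    stats::setNames(rep(list(config), 5L), TASKS)
  } else check_tasks(config, "config")
  models <- lapply(TASKS, function(task) {
    lab <- labels[[task]]
    rows <- match(lab$id, data$id)
    if (anyNA(rows)) stop("labels for task ", task,
                          " reference unknown protein ids", call. = FALSE)
    train_classifier(data[rows, selected[[task]], drop = FALSE],
                     lab$label, config = configs[[task]], seed = seed)
  })
  structure(stats::setNames(models, TASKS), class = "xtal_level1")
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    labels <- split(labels[c("id", "label")], labels$task)
  }
  check_tasks(labels, "labels")
}

#' Level-1 probability meta-features
#'
#' The five-column table of first-level task probabilities used as input by
#' the second-level models. In `direct` mode each full model scores every
#' row. In `oof` mode (training) each row's meta-features come from models
#' refit with that row's fold held out, so no level-2 training row is
#' scored by a model that saw it.
#'
#' @param level1 An `xtal_level1` model list (direct mode), or, in oof
#'   mode, the training inputs: see `data`, `labels`, `selected`.
#' @param data Feature tibble with `id`.
#' @param mode `"direct"` or `"oof"`.
#' @param labels,selected,config,seed Training inputs (oof mode only);
#'   `labels` as in [train_level1()]. Rows of `data` without a label for
#'   some task are scored by the fold-1 model of that task.
#' @param folds Folds for oof mode (default 5).
#' @return Tibble with `id` and one probability column per task; in oof
#'   mode also an attribute `fold_id` (named list per task).
#' @export
stack_meta_features <- function(level1, data, mode = c("direct", "oof"),
                                labels = NULL, selected = NULL,
                                config = svm_config(), folds = 5L,
                                seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "direct") {
    level1 <- check_tasks(level1, "level1")
    probs <- lapply(level1, function(m) predict(m, data))
    return(tibble::as_tibble(c(list(id = data$id), probs)))
  }
  if (is.null(labels) || is.null(selected)) {
    stop("oof mode needs labels and selected feature subsets", call. = FALSE)
  }
  labels <- normalize_labels(labels)
  selected <- check_tasks(selected, "selected")
  out <- list(id = data$id)
  fold_ids <- list()
  for (task in TASKS) {
    lab <- labels[[task]]
    rows <- match(lab$id, data$id)
    fold_id <- stratified_folds(lab$label, folds, seed)
    fold_ids[[task]] <- stats::setNames(fold_id, lab$id)
    p <- rep(NA_real_, nrow(data))
    for (f in seq_len(folds)) {
      train_rows <- rows[fold_id != f]
      model <- train_classifier(
        data[train_rows, selected[[task]], drop = FALSE],
        lab$label[fold_id != f], config = config, seed = seed)
      score_rows <- rows[fold_id == f]
      p[score_rows] <- predict(model,
                               data[score_rows, selected[[task]],
                                    drop = FALSE])
    }
    if (anyNA(p)) {
      # rows with no label for this task: score with the fold-1 model
      model <- train_classifier(
        data[rows[fold_id != 1L], selected[[task]], drop = FALSE],
        lab$label[fold_id != 1L], config = config, seed = seed)
      p[is.na(p)] <- predict(model,
                             data[is.na(p), selected[[task]], drop = FALSE])
    }
    out[[task]] <- p
  }
  meta <- tibble::as_tibble(out)
  attr(meta, "fold_id") <- fold_ids
  meta
}

#' Train the five second-level task classifiers
#'
#' Each second-level model takes the 5-vector of first-level task
#' probabilities as input; train on out-of-fold meta-features to avoid
#' leaking first-level training rows.
#'
#' @param meta Meta-feature tibble from [stack_meta_features()] (columns
#'   `id` + the five tasks).
#' @param labels As in [train_level1()].
#' @param config Level-2 classifier configuration; defaults to a linear
#'   (degree-1 polynomial) kernel - the low-variance combiner standard for
#'   stacked generalization over a handful of probability inputs.
#' @param seed As in [train_level1()].
#' @return Named list of five `xtal_svm` models, class `xtal_level2`.
#' @export
train_level2 <- function(meta, labels,
                         config = svm_config("POLY", degree = 1L),
                         seed = 1L) {
  labels <- normalize_labels(labels)
  models <- lapply(TASKS, function(task) {
    lab <- labels[[task]]
    rows <- match(lab$id, meta$id)
    if (anyNA(rows)) stop("labels for task ", task,
                          " reference unknown ids", call. = FALSE)
    train_classifier(meta[rows, TASKS], lab$label, config = config,
                     seed = seed)
  })
  structure(stats::setNames(models, TASKS), class = "xtal_level2")
}

#' Train the full two-level stacked predictor
#'
#' Convenience wrapper: first-level models per task on their selected
#' features, out-of-fold meta-features, then second-level models on the
#' five level-1 probabilities.
#'
#' @inheritParams train_level1
#' @param config2 Level-2 classifier configuration (default: linear
#'   degree-1 polynomial kernel).
#' @param folds Folds for the out-of-fold meta-features.
#' @param registry Feature registry fingerprint to embed.
#' @return A list of class `xtal_stack` with elements `level1`, `level2`,
#'   `selected`, `tasks`, `registry_fingerprint`.
#' @export
train_stacked <- function(data, labels, selected, config = svm_config(),
                          config2 = svm_config("POLY", degree = 1L),
                          folds = 5L, seed = 1L,
                          registry = feature_registry()) {
  level1 <- train_level1(data, labels, selected, config = config,
                         seed = seed)
  meta <- stack_meta_features(NULL, data, mode = "oof", labels = labels,
                              selected = selected, config = config,
                              folds = folds, seed = seed)
  level2 <- train_level2(meta, labels, config = config2, seed = seed)
  structure(list(level1 = level1, level2 = level2,
                 selected = check_tasks(selected, "selected"),
                 tasks = TASKS,
                 registry_fingerprint = registry_fingerprint(registry)),
            class = "xtal_stack")
}

registry_fingerprint <- function(registry) {
  paste0("xtalprop-registry-", nrow(registry), "-",
         sum(nchar(registry$feature_id)))
}

#' Predict with a stacked model
#'
#' Scores a feature table with the five first-level models, feeds the
#' probabilities to the second-level models, and tiers each protein by its
#' second-level crystallizability (CRYS) score.
#'
#' @param object An `xtal_stack` model.
#' @param newdata Feature tibble with `id` (must contain every selected
#'   feature column).
#' @param ... Unused.
#' @return Tibble: `id`, five level-2 probability columns (one per task),
#'   and `tier`.
#' @export
predict.xtal_stack <- function(object, newdata, ...) {
  meta <- stack_meta_features(object$level1, newdata, mode = "direct")
  probs <- lapply(object$level2, function(m) predict(m, meta[TASKS]))
  out <- tibble::as_tibble(c(list(id = newdata$id), probs))
  out$tier <- classify_difficulty(out$CRYS)
  out
}

#' @export
print.xtal_stack <- function(x, ...) {
  cat("<xtal_stack> two-level predictor over tasks ",
      paste(x$tasks, collapse = ", "), "\n", sep = "")
  cat("  level-1 feature subset sizes: ",
      paste(vapply(x$selected, length, integer(1)), collapse = "/"), "\n",
      sep = "")
  invisible(x)
}

#' Compare first-level and second-level out-of-fold performance
#'
#' For each task: the first-level AUC is computed from the out-of-fold
#' level-1 probabilities; the second-level AUC is the pooled out-of-fold
#' AUC of a classifier on the five level-1 probability columns,
#' cross-validated with the same fold structure. This is the per-task
#' quantity on which stacking is expected to improve when the tasks share
#' a latent factor.
#'
#' @inheritParams train_level1
#' @param config2 Level-2 classifier configuration (default: linear
#'   degree-1 polynomial kernel).
#' @param folds Folds (default 5).
#' @return Tibble with columns `task`, `level1_auc`, `level2_auc`.
#' @export
stacking_comparison <- function(data, labels, selected,
                                config = svm_config(),
                                config2 = svm_config("POLY", degree = 1L),
                                folds = 5L, seed = 1L) {
  labels <- normalize_labels(labels)
  selected <- check_tasks(selected, "selected")
  meta <- stack_meta_features(NULL, data, mode = "oof", labels = labels,
                              selected = selected, config = config,
                              folds = folds, seed = seed)
  rows <- lapply(TASKS, function(task) {
    lab <- labels[[task]]
    at <- match(lab$id, meta$id)
    l1 <- roc_auc(meta[[task]][at], lab$label)
    cv <- cross_validate(meta[at, TASKS], lab$label, folds = folds,
                         seed = seed, config = config2)
    tibble::tibble(task = task, level1_auc = l1, level2_auc = cv$auc)
  })
  dplyr::bind_rows(rows)
}

# ---- difficulty tiers ------------------------------------------------------

TIER_LEVELS <- c("Optimal", "Suboptimal", "Average", "Difficult",
                 "Very difficult")

#' Map crystallizability scores to difficulty tiers
#'
#' Boundary-inclusive bins on the probability score: Optimal (>= 0.6),
#' Suboptimal ([0.55, 0.6)), Average ([0.45, 0.55)), Difficult
#' ([0.2, 0.45)), Very difficult (< 0.2).
#'
#' @param score Numeric scores in `[0, 1]` (vectorized).
#' @return Ordered factor with levels Optimal > Suboptimal > Average >
#'   Difficult > Very difficult.
#' @export
classify_difficulty <- function(score) {
  if (any(is.na(score) | score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  tier <- dplyr::case_when(
    score >= 0.6 ~ "Optimal",
    score >= 0.55 ~ "Suboptimal",
    score >= 0.45 ~ "Average",
    score >= 0.2 ~ "Difficult",
    TRUE ~ "Very difficult"
  )
  factor(tier, levels = TIER_LEVELS, ordered = TRUE)
}
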