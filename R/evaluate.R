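# Performance evaluation: the six scalar measures (accuracy, MCC,
# sensitivity, specificity, precision, AUC), ROC curves, the stratified
# cross-validation harness, inter-task output correlations, and
# per-feature contribution measures (t-test significance, single-feature
# AUC).

#' Confusion-matrix performance measures
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any zero denominator yields 0 for that measure and sets `degenerate`.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `mcc`, `degenerate`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts", call. = FALSE)
  if (sum(counts) < 1) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0 || (tp + fp) == 0 ||
    mcc_den == 0
  tibble::tibble(
    accuracy = (tp + tn) / sum(counts),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    degenerate = degenerate
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with half credit for ties; equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (positives = 1 / `TRUE` / second factor
#'   level); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- binarize_labels(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

binarize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  f <- factor(labels)
  if (nlevels(f) > 2L) stop("labels must be binary", call. = FALSE)
  as.integer(f) - 1L
}

#' Empirical ROC curve
#'
#' @param scores,labels As in [roc_auc()].
#' @return Tibble with `threshold`, `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), FPR non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  y <- binarize_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # collapse tied scores into single operating points
  last <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / max(sum(y == 0L), 1L)),
    tpr = c(0, tp / max(sum(y == 1L), 1L))
  )
}

#' Stratified cross-validation of a classifier
#'
#' Splits the rows into stratified folds, trains on each training portion
#' and scores the held-out fold, so every row is scored exactly once
#' out-of-fold. Per-fold threshold metrics (at probability 0.5) and the
#' pooled AUC over the concatenated out-of-fold scores are reported.
#'
#' @param data Feature tibble or matrix.
#' @param y Binary labels.
#' @param folds Number of folds (default 5); every class needs at least
#'   `folds` rows.
#' @param seed Fold-split seed.
#' @param config [svm_config()] for the package classifier.
#' @param trainer Optional custom trainer `function(data, y)` returning an
#'   object whose `predict(object, data)` gives scores; defaults to
#'   [train_classifier()].
#' @return A list of class `xtal_cv`: `fold_metrics` (tibble), `auc`
#'   (pooled out-of-fold AUC), `scores`, `labels`, `fold_id`, `roc`.
#' @export
cross_validate <- function(data, y, folds = 5L, seed = 1L,
                           config = svm_config(), trainer = NULL) {
  mat <- feature_matrix(data)
  yb <- binarize_labels(y)
  if (min(table(yb)) < folds) {
    stop("each class needs at least ", folds, " rows for ", folds,
         "-fold cross-validation", call. = FALSE)
  }
  if (is.null(trainer)) {
    trainer <- function(d, yy) train_classifier(d, yy, config = config,
                                                seed = seed)
  }
  fold_id <- stratified_folds(yb, folds, seed)
  scores <- numeric(length(yb))
  fold_rows <- list()
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- tryCatch(
      trainer(mat[!test, , drop = FALSE], yb[!test]),
      error = function(e) stop("cross-validation failed in fold ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    scores[test] <- predict(model, mat[test, , drop = FALSE])
    pred <- as.integer(scores[test] >= 0.5)
    truth <- yb[test]
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n = sum(test)),
      confusion_metrics(tp = sum(pred == 1L & truth == 1L),
                        fp = sum(pred == 1L & truth == 0L),
                        tn = sum(pred == 0L & truth == 0L),
                        fn = sum(pred == 0L & truth == 1L)))
  }
  structure(list(
    fold_metrics = dplyr::bind_rows(fold_rows),
    auc = roc_auc(scores, yb),
    scores = scores, labels = yb, fold_id = fold_id,
    roc = roc_curve(scores, yb)
  ), class = "xtal_cv")
}

#' @export
print.xtal_cv <- function(x, ...) {
  cat("<xtal_cv> ", max(x$fold_id), "-fold cross-validation, pooled AUC ",
      sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Inter-task output correlation matrix
#'
#' Pearson correlations between the five first-level task probability
#' columns, quantifying how strongly the predicted propensities of any two
#' pipeline steps co-vary across proteins.
#'
#' @param x Either an `xtal_stack`/`xtal_level1` model (scored on
#'   `data`) or a meta-feature tibble with the five task columns.
#' @param data Feature tibble (required when `x` is a model).
#' @return 5x5 symmetric correlation matrix with unit diagonal;
#'   zero-variance columns are flagged in `attr(, "degenerate")`.
#' @export
output_correlation_matrix <- function(x, data = NULL) {
  meta <- if (is.data.frame(x)) {
    x
  } else {
    level1 <- if (inherits(x, "xtal_stack")) x$level1 else x
    stack_meta_features(level1, data, mode = "direct")
  }
  m <- as.matrix(meta[TASKS])
  if (nrow(m) < 3L) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  degenerate <- names(sds)[sds == 0]
  cc <- suppressWarnings(stats::cor(m))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "degenerate") <- degenerate
  cc
}

#' Per-feature significance of class separation
#'
#' Two-sample unequal-variance (Welch) t-test of every feature between the
#' two label classes; returns `-log10(p)` per feature, ranked. Features
#' with degenerate variance in both classes get p = 1.
#'
#' @param data Feature tibble or matrix.
#' @param y Binary labels (both classes with at least 2 rows).
#' @return Tibble `feature_id`, `neg_log10_p`, `rank` (1 = most
#'   significant), in registry/column order.
#' @export
feature_significance <- function(data, y) {
  mat <- feature_matrix(data)
  yb <- binarize_labels(y)
  if (min(table(yb)) < 2L) {
    stop("both classes need at least 2 rows", call. = FALSE)
  }
  g1 <- mat[yb == 1L, , drop = FALSE]
  g0 <- mat[yb == 0L, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2L, stats::var); v0 <- apply(g0, 2L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1 # zero variance in both classes
  out <- tibble::tibble(
    feature_id = colnames(mat),
    neg_log10_p = unname(-log10(pmax(p, .Machine$double.xmin)))
  )
  out$rank <- rank(-out$neg_log10_p, ties.method = "first")
  out
}

#' Single-feature discriminative power
#'
#' AUC of each feature used alone as a prediction score; the
#' orientation-corrected value `max(AUC, 1 - AUC)` is reported alongside
#' the raw AUC.
#'
#' @inheritParams feature_significance
#' @return Tibble `feature_id`, `auc` (raw), `auc_oriented`, `rank`
#'   (1 = most discriminative by oriented AUC).
#' @export
single_feature_auc <- function(data, y) {
  mat <- feature_matrix(data)
  yb <- binarize_labels(y)
  aucs <- apply(mat, 2L, roc_auc, labels = yb)
  out <- tibble::tibble(
    feature_id = colnames(mat),
    auc = unname(aucs),
    auc_oriented = pmax(unname(aucs), 1 - unname(aucs))
  )
  out$rank <- rank(-out$auc_oriented, ties.method = "first")
  out
}
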