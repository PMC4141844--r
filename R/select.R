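# Feature ranking and selection: plug-in mutual information on
# equal-frequency terciles, greedy mRMR (difference criterion), the one-step
# and two-step mRMR stages over the full registry, and the IFS/FFS wrapper
# stages scored by cross-validated AUC of the package classifier.

#' mRMR/selection configuration
#'
#' @param k_one_step Features kept by the one-step mRMR stage (default 300).
#' @param k_per_block Features kept from each AAindex block in the first
#'   step of the two-step strategy (default 100).
#' @param k_two_step Features kept by the second step (default 300).
#' @param folds Stratified cross-validation folds used by the wrapper
#'   stages (default 5).
#' @param ffs_tol Minimum cross-validated AUC improvement for forward
#'   selection to accept another feature (default 1e-4).
#' @return A list of class `mrmr_config`.
#' @export
mrmr_config <- function(k_one_step = 300L, k_per_block = 100L,
                        k_two_step = 300L, folds = 5L, ffs_tol = 1e-4) {
  stopifnot(k_one_step > 0L, k_per_block > 0L, k_two_step > 0L, folds >= 2L)
  structure(list(k_one_step = as.integer(k_one_step),
                 k_per_block = as.integer(k_per_block),
                 k_two_step = as.integer(k_two_step),
                 folds = as.integer(folds), ffs_tol = ffs_tol),
            class = "mrmr_config")
}

# equal-frequency tercile codes (1..3); ties broken by value then original
# index so the coding is invariant under monotone transforms. A constant
# vector collapses to a single bin.
discretize_terciles <- function(x) {
  n <- length(x)
  if (length(unique(x)) == 1L) return(rep(1L, n))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(3 * r / n))
}

# plug-in MI (bits) between two small-alphabet integer codes
mi_codes <- function(a, b, na = max(a), nb = max(b)) {
  n <- length(a)
  joint <- tabulate((a - 1L) * nb + b, nbins = na * nb) / n
  pa <- tabulate(a, nbins = na) / n
  pb <- tabulate(b, nbins = nb) / n
  # joint is laid out with b varying fastest
  joint_m <- matrix(joint, nrow = nb, ncol = na)
  pm <- t(joint_m)
  terms <- pm * log2(pm / outer(pa, pb, "*"))
  sum(terms[pm > 0 & outer(pa, pb, "*") > 0])
}

#' Mutual information between a feature and binary labels
#'
#' The feature is discretized into equal-frequency terciles (ties broken by
#' value then index) and the plug-in mutual information of the discrete
#' joint distribution is returned in bits (log base 2). A constant feature
#' occupies a single bin and has MI 0.
#'
#' @param x Numeric feature vector.
#' @param y Binary labels (any two-valued vector) of the same length.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  a <- discretize_terciles(x)
  b <- as.integer(factor(y))
  mi_codes(a, b, na = 3L, nb = max(b))
}

# tercile-code matrix for all feature columns
discretize_matrix <- function(mat) {
  apply(mat, 2L, discretize_terciles)
}

# MI (bits) of every column of code matrix D (codes 1..3) with code vector g
mi_vs_all <- function(D, g, ng = max(g)) {
  n <- nrow(D)
  pg <- tabulate(g, nbins = ng) / n
  pc <- vapply(1:3, function(c) colSums(D == c), numeric(ncol(D))) / n # p x 3
  mi <- numeric(ncol(D))
  for (l in seq_len(ng)) {
    rows <- g == l
    if (!any(rows)) next
    sub <- D[rows, , drop = FALSE]
    for (c in 1:3) {
      plc <- colSums(sub == c) / n
      denom <- pg[l] * pc[, c]
      term <- plc * log2(plc / denom)
      term[plc == 0 | denom == 0] <- 0
      mi <- mi + term
    }
  }
  pmax(mi, 0)
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance ranking under the difference
#' criterion: the first feature maximizes relevance `I(f; y)`; each
#' subsequent feature maximizes `I(f; y) - mean over selected g of
#' I(f; g)`. All mutual informations are computed on equal-frequency
#' tercile codes. Ties are broken by column (registry) order. Deterministic
#' given the data.
#'
#' @param data Tibble or data frame of features (an `id` column, if
#'   present, is ignored).
#' @param y Binary labels, one per row.
#' @param k Number of features to rank (default: all).
#' @return A tibble of class `xtal_ranking` with columns `rank`,
#'   `feature_id`, `score` (the criterion value when selected) and
#'   `relevance`.
#' @export
mrmr_rank <- function(data, y, k = NULL) {
  mat <- feature_matrix(data)
  p <- ncol(mat)
  if (anyNA(y)) stop("labels contain NA", call. = FALSE)
  if (length(y) != nrow(mat)) {
    stop("length(y) must equal the number of rows", call. = FALSE)
  }
  if (is.null(k)) k <- p
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  k <- min(k, p)
  D <- discretize_matrix(mat)
  ycode <- as.integer(factor(y))
  rel <- mi_vs_all(D, ycode, ng = max(ycode))

  selected <- integer(0)
  red_sum <- numeric(p)
  scores <- numeric(k)
  remaining <- rep(TRUE, p)
  for (round in seq_len(k)) {
    crit <- if (round == 1L) rel else rel - red_sum / (round - 1L)
    crit[!remaining] <- -Inf
    pick <- which.max(crit) # which.max takes the first maximum: column order
    selected <- c(selected, pick)
    scores[round] <- crit[pick]
    remaining[pick] <- FALSE
    if (round < k) {
      red_sum <- red_sum + mi_vs_all(D, D[, pick], ng = 3L)
    }
  }
  tibble::tibble(rank = seq_len(k),
                 feature_id = colnames(mat)[selected],
                 score = scores,
                 relevance = rel[selected]) |>
    structure(class = c("xtal_ranking", class(tibble::tibble())))
}

#' One-step mRMR selection over the full registry
#'
#' Ranks all 2,924 candidate features jointly and keeps the top
#' `k_one_step` (default 300).
#'
#' @param data Feature tibble whose columns match the feature registry.
#' @param y Binary labels.
#' @param config An [mrmr_config()] list.
#' @param registry Feature registry (default: the canonical one). Used to
#'   check the column set.
#' @return An `xtal_ranking` tibble of `k_one_step` rows.
#' @export
one_step_select <- function(data, y, config = mrmr_config(),
                            registry = feature_registry()) {
  check_registry_columns(data, registry)
  mrmr_rank(data, y, k = config$k_one_step)
}

#' Two-step mRMR selection over the full registry
#'
#' Stage 1 ranks each of the three 544-feature AAindex blocks separately
#' and keeps `k_per_block` (default 100) from each, pooling 300 AAindex
#' features. Stage 2 ranks the pool together with the 1,292 non-AAindex
#' features (1,592 candidates) and keeps `k_two_step` (default 300).
#'
#' @inheritParams one_step_select
#' @return An `xtal_ranking` tibble of `k_two_step` rows with the stage-1
#'   pool in `attr(, "stage1_pool")`.
#' @export
two_step_select <- function(data, y, config = mrmr_config(),
                            registry = feature_registry()) {
  check_registry_columns(data, registry)
  aaindex_blocks <- c("aaindex_seq", "aaindex_exposed", "aaindex_buried")
  pool <- unlist(lapply(aaindex_blocks, function(b) {
    ids <- registry$feature_id[registry$block == b]
    mrmr_rank(data[ids], y, k = config$k_per_block)$feature_id
  }))
  non_aaindex <- registry$feature_id[!registry$block %in% aaindex_blocks]
  candidates <- c(pool, non_aaindex)
  out <- mrmr_rank(data[candidates], y, k = config$k_two_step)
  attr(out, "stage1_pool") <- pool
  attr(out, "n_candidates") <- length(candidates)
  out
}

check_registry_columns <- function(data, registry) {
  cols <- setdiff(names(data), c("id", "label"))
  if (!setequal(cols, registry$feature_id)) {
    stop("feature columns do not match the registry (",
         length(cols), " columns vs ", nrow(registry), " registry features)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- wrapper stages --------------------------------------------------------

# out-of-fold AUC of the package classifier on a feature subset
subset_cv_auc <- function(mat, y, ids, folds, seed, config) {
  fold_id <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- train_classifier(mat[!test, ids, drop = FALSE], y[!test],
                              config = config, seed = seed)
    scores[test] <- predict(model, mat[test, ids, drop = FALSE])
  }
  roc_auc(scores, y)
}

#' Incremental feature selection
#'
#' Evaluates growing prefixes of an mRMR ranking by the out-of-fold AUC of
#' the package SVM classifier, and returns the prefix whose AUC is maximal
#' (smallest prefix on ties) together with the full trajectory.
#'
#' @param data Feature tibble (or matrix) containing at least the ranked
#'   features.
#' @param y Binary labels.
#' @param ranking An `xtal_ranking` tibble (or character vector of feature
#'   ids in rank order).
#' @param max_size Largest prefix evaluated (default: all ranked features).
#' @param folds Stratified CV folds (default 5).
#' @param seed Seed for the fold split (default 1).
#' @param svm SVM configuration for the wrapper classifier
#'   (default [svm_config()]).
#' @return A list of class `xtal_selection`: `selected` (feature ids),
#'   `auc` (the maximum), `trajectory` (tibble `size`, `auc`), `method`.
#' @export
ifs <- function(data, y, ranking, max_size = NULL, folds = 5L, seed = 1L,
                svm = svm_config()) {
  ids <- if (is.character(ranking)) ranking else ranking$feature_id
  if (length(ids) == 0L) stop("empty ranking", call. = FALSE)
  if (is.null(max_size)) max_size <- length(ids)
  max_size <- min(max_size, length(ids))
  mat <- feature_matrix(data)
  aucs <- vapply(seq_len(max_size), function(s) {
    subset_cv_auc(mat, y, ids[seq_len(s)], folds, seed, svm)
  }, numeric(1))
  best <- which.max(aucs) # first maximum = smallest prefix on ties
  structure(list(selected = ids[seq_len(best)],
                 auc = aucs[best],
                 trajectory = tibble::tibble(size = seq_len(max_size),
                                             auc = aucs),
                 method = "ifs"),
            class = "xtal_selection")
}

#' Forward feature selection
#'
#' Greedy wrapper selection: each round tries every remaining candidate and
#' keeps the single feature whose addition maximizes the out-of-fold AUC of
#' the package SVM classifier; stops when no addition improves the best AUC
#' by more than `tol`.
#'
#' @inheritParams ifs
#' @param candidates Character vector of candidate feature ids (e.g. an
#'   mRMR-selected subset).
#' @param tol Minimum AUC improvement to accept a round (default 1e-4).
#' @param max_rounds Optional cap on the number of accepted rounds.
#' @return A list of class `xtal_selection`: `selected`, `auc`,
#'   `trajectory` (tibble `size`, `feature_id`, `auc` per accepted round),
#'   `method`.
#' @export
ffs <- function(data, y, candidates, folds = 5L, seed = 1L, tol = 1e-4,
                svm = svm_config(), max_rounds = NULL) {
  if (is.data.frame(candidates)) candidates <- candidates$feature_id
  if (length(candidates) == 0L) stop("no candidate features", call. = FALSE)
  if (is.null(max_rounds)) max_rounds <- length(candidates)
  mat <- feature_matrix(data)
  selected <- character(0)
  best_auc <- -Inf
  rounds <- tibble::tibble(size = integer(), feature_id = character(),
                           auc = numeric())
  repeat {
    if (length(selected) >= max_rounds) break
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    aucs <- vapply(remaining, function(id) {
      subset_cv_auc(mat, y, c(selected, id), folds, seed, svm)
    }, numeric(1))
    pick <- which.max(aucs)
    if (aucs[pick] <= best_auc + tol && length(selected) > 0L) break
    selected <- c(selected, remaining[pick])
    best_auc <- aucs[pick]
    rounds <- dplyr::bind_rows(rounds, tibble::tibble(
      size = length(selected), feature_id = remaining[pick],
      auc = best_auc))
  }
  structure(list(selected = selected, auc = best_auc, trajectory = rounds,
                 method = "ffs"),
            class = "xtal_selection")
}

#' @export
print.xtal_selection <- function(x, ...) {
  cat("<xtal_selection> ", toupper(x$method), ": ", length(x$selected),
      " features, cross-validated AUC ", sprintf("%.4f", x$auc), "\n",
      sep = "")
  invisible(x)
}
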