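# Performance measures, ROC/AUC oracles, the cross-validation harness and
# feature-contribution analyses.

test_that("confusion metrics match the defining formulas", {
  perfect <- confusion_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_false(perfect$degenerate)

  m <- confusion_metrics(tp = 2, fp = 1, tn = 3, fn = 0)
  expect_equal(m$mcc, 6 / sqrt(72))
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$precision, 2 / 3)

  degenerate <- confusion_metrics(tp = 0, fp = 0, tn = 4, fn = 2)
  expect_equal(degenerate$precision, 0)
  expect_true(degenerate$degenerate)
  expect_error(confusion_metrics(tp = -1, fp = 0, tn = 1, fn = 0),
               "negative")
})

test_that("AUC equals brute-force pair counting with tie half-credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    expect_equal(roc_auc(scores, labels),
                 as.numeric(suppressMessages(
                   pROC::auc(labels, scores, direction = "<"))))
  }
})

test_that("ROC curves run from (0,0) to (1,1) with monotone FPR", {
  set.seed(2)
  scores <- rnorm(40); labels <- rep(0:1, 20)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$fpr[[1]], 0)
  expect_equal(roc$tpr[[1]], 0)
  expect_equal(roc$fpr[[nrow(roc)]], 1)
  expect_equal(roc$tpr[[nrow(roc)]], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  # trapezoidal area equals the rank AUC
  area <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  expect_equal(area, roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("cross-validation scores every row exactly once, stratified", {
  sim <- simulate_planted(n = 103, p = 6, k = 2, delta = 1, tasks = 1,
                          seed = 20)
  y <- sim$labels$label
  cv <- cross_validate(sim$features, y, folds = 5, seed = 2)
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  sizes <- table(cv$fold_id)
  expect_lte(max(sizes) - min(sizes), 2L) # near-equal within each stratum
  expect_equal(nrow(cv$fold_metrics), 5L)
  expect_equal(sum(cv$fold_metrics$n), 103L)
  # a perfect oracle trainer gives pooled AUC 1
  oracle_trainer <- function(d, yy) {
    structure(list(), class = "oracle_model")
  }
  assign("predict.oracle_model",
         function(object, newdata, ...) newdata[, 1], envir = globalenv())
  on.exit(rm("predict.oracle_model", envir = globalenv()), add = TRUE)
  perfect <- tibble::tibble(s = as.numeric(y), noise = rnorm(103))
  cvp <- cross_validate(perfect, y, folds = 5, seed = 1,
                        trainer = oracle_trainer)
  expect_equal(cvp$auc, 1)
  expect_error(cross_validate(sim$features[1:6, ], y[1:6], folds = 5),
               "at least 5")
})

test_that("task output correlations are symmetric with unit diagonal", {
  sim <- simulate_planted(n = 60, p = 25, k = 5, delta = 1, rho = 0.8,
                          tasks = 5, seed = 13)
  lv1 <- train_level1(sim$features, sim$labels, sim$truth)
  cc <- output_correlation_matrix(lv1, sim$features)
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc, t(cc), tolerance = 1e-12)
  meta2 <- stack_meta_features(lv1, sim$features[1:2, ])
  expect_error(output_correlation_matrix(meta2), "at least 3")
})

test_that("latent coupling raises the inter-task output correlations", {
  mean_offdiag <- function(rho, s) {
    sim <- simulate_planted(n = 150, p = 25, k = 5, delta = 1, rho = rho,
                            tasks = 5, seed = s)
    lv1 <- train_level1(sim$features, sim$labels, sim$truth)
    cc <- output_correlation_matrix(lv1, sim$features)
    mean(cc[upper.tri(cc)])
  }
  seeds <- 1:10
  high <- vapply(seeds, mean_offdiag, numeric(1), rho = 0.8)
  null <- vapply(seeds, mean_offdiag, numeric(1), rho = 0)
  expect_gt(mean(high), mean(null))
})

test_that("t-test significance separates shifted features from null", {
  set.seed(44)
  n <- 200
  tbl <- tibble::tibble(shifted = c(rnorm(n / 2), rnorm(n / 2, 5)),
                        flat = rnorm(n))
  y <- rep(0:1, each = n / 2)
  sig <- feature_significance(tbl, y)
  expect_equal(nrow(sig), 2L)
  expect_gt(sig$neg_log10_p[sig$feature_id == "shifted"], 10)
  expect_equal(sig$rank[sig$feature_id == "shifted"], 1L)

  # permuted labels: mostly insignificant
  meds <- vapply(1:10, function(s) {
    set.seed(s)
    mat <- tibble::as_tibble(as.data.frame(matrix(rnorm(100 * 20), 100)))
    median(feature_significance(mat, rbinom(100, 1, 0.5))$neg_log10_p)
  }, numeric(1))
  expect_lt(median(meds), 1)
  # agreement with stats::t.test
  tt <- stats::t.test(tbl$flat[y == 1], tbl$flat[y == 0])
  expect_equal(sig$neg_log10_p[sig$feature_id == "flat"],
               -log10(tt$p.value), tolerance = 1e-8)
})

test_that("single-feature AUC ranks match significance on planted data", {
  set.seed(7)
  n <- 500
  tbl <- tibble::tibble(sep = c(rnorm(n / 2), rnorm(n / 2, 3)),
                        noise = rnorm(n))
  y <- rep(0:1, each = n / 2)
  sfa <- single_feature_auc(tbl, y)
  expect_gt(sfa$auc[sfa$feature_id == "sep"], 0.95)
  expect_true(all(sfa$auc_oriented >= 0.5))
  # pure noise stays near 0.5 on average
  null_auc <- vapply(1:10, function(s) {
    set.seed(s)
    single_feature_auc(tibble::tibble(x = rnorm(n)), y)$auc
  }, numeric(1))
  expect_gt(mean(null_auc), 0.43)
  expect_lt(mean(null_auc), 0.57)
  # AUC-based and p-value-based rankings agree on planted signal
  sim <- simulate_planted(n = 200, p = 20, k = 5, delta = 1, tasks = 1,
                          seed = 9)
  yl <- sim$labels$label
  r_auc <- single_feature_auc(sim$features, yl)$rank
  r_sig <- feature_significance(sim$features, yl)$rank
  expect_gt(cor(r_auc, r_sig, method = "spearman"), 0)
})
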