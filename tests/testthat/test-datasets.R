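# Dataset construction: trial filters, class assignment, task label
# composition, redundancy reduction, splits and the simulators.

test_that("trial filters apply the four criteria in order", {
  records <- dplyr::bind_rows(
    # removed: before the window
    make_status_row("t1", "t1.a", "in PDB", "2005-06-01",
                    stop_condition = "in PDB"),
    make_status_row("t1", "t1.b", "expressed", "2008-01-01"),
    # most advanced wins regardless of date
    make_status_row("t2", "t2.a", "expressed", "2008-01-01"),
    make_status_row("t2", "t2.b", "soluble", "2007-01-01"),
    # equal statuses: latest trial kept
    make_status_row("t3", "t3.a", "purified", "2007-05-01"),
    make_status_row("t3", "t3.b", "purified", "2009-05-01"),
    # removed: non-X-ray
    make_status_row("t4", "t4.a", "crystal structure", "2008-01-01",
                    method = "NMR", stop_condition = "crystal structure"),
    make_status_row("t4", "t4.b", "cloned", "2008-02-01"),
    # removed: stop condition not whitelisted
    make_status_row("t5", "t5.a", "soluble", "2008-01-01",
                    stop_condition = "work in progress"),
    make_status_row("t5", "t5.b", "selected", "2008-02-01"))
  out <- filter_trials(records)
  expect_equal(out$status[out$target_id == "t1"], "expressed")
  expect_equal(out$status[out$target_id == "t2"], "soluble")
  expect_equal(out$trial_id[out$target_id == "t3"], "t3.b")
  expect_equal(out$status[out$target_id == "t4"], "cloned")
  expect_equal(out$status[out$target_id == "t5"], "selected")
})

test_that("class assignment follows the five-class status mapping", {
  expect_equal(assign_class("selected"), "CLF")
  expect_equal(assign_class(c("cloned", "expressed")), c("MF", "MF"))
  expect_equal(assign_class(c("soluble", "purified", "purification failed")),
               rep("PF", 3))
  expect_equal(assign_class(c("crystallization failed", "poor diffraction",
                              "crystallized", "diffraction")),
               rep("CF", 4))
  expect_equal(assign_class(c("crystal structure", "structure successful",
                              "in PDB")), rep("CRYS", 3))
  # case-insensitive after trimming
  expect_equal(assign_class("  In PDB "), "CRYS")
  expect_error(assign_class("struck by lightning"), "known statuses")
})

test_that("task datasets follow the per-step label composition", {
  targets <- tibble::tibble(
    id = sprintf("t%02d", 1:30),
    class = rep(c("CLF", "MF", "PF", "CF", "CRYS"), c(10, 10, 5, 3, 2)))
  pf <- build_task_dataset(targets, "PF")
  expect_equal(sum(pf$label == 0), 5L)
  expect_equal(sum(pf$label == 1), 5L)
  expect_equal(attr(pf, "n_excluded"), 20L)

  mf <- build_task_dataset(targets, "MF")
  expect_equal(sum(mf$label == 0), 20L)
  expect_equal(sum(mf$label == 1), 10L)

  crys <- build_task_dataset(targets, "CRYS")
  expect_equal(sum(crys$label == 0), 28L)
  expect_equal(sum(crys$label == 1), 2L)

  clf <- build_task_dataset(targets, "CLF")
  expect_equal(sum(clf$label == 0), 10L)
  expect_equal(sum(clf$label == 1), 20L)

  cf <- build_task_dataset(targets, "CF")
  expect_equal(sum(cf$label == 0), 3L)
  expect_equal(sum(cf$label == 1), 2L)

  # every target is positive, negative or excluded
  for (task in c("CLF", "MF", "PF", "CF", "CRYS")) {
    ds <- build_task_dataset(targets, task)
    expect_equal(nrow(ds) + attr(ds, "n_excluded"), 30L)
  }
  expect_error(build_task_dataset(targets[targets$class == "CLF", ], "CLF"),
               "empty")
})

test_that("greedy redundancy reduction clusters by global identity", {
  twins <- tibble::tibble(id = c("a", "b"),
                          sequence = rep("MKLVINSGGHILK", 2),
                          length = 13L)
  expect_equal(nrow(reduce_redundancy(twins, 0.4)), 1L)

  distinct <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("MKLVINSGGHILKWWPQRV", "DDEEDDEEDDCCYYDDEE"),
    length = c(19L, 18L))
  expect_equal(nrow(reduce_redundancy(distinct, 0.4)), 2L)

  # representative is the longest member of its cluster
  family <- tibble::tibble(
    id = c("short", "long"),
    sequence = c("MKLVINSGGHILK", "MKLVINSGGHILKMKLV"),
    length = c(13L, 17L))
  expect_equal(reduce_redundancy(family, 0.4)$id, "long")

  # grouped: reduction happens within each class only
  grouped <- tibble::tibble(
    id = c("x1", "x2"), sequence = rep("MKLVINSGGHILK", 2),
    length = 13L, class = c("PF", "CRYS"))
  expect_equal(nrow(reduce_redundancy(grouped, 0.4, by = "class")), 2L)
})

test_that("the 6-way split is stratified, seeded and non-overlapping", {
  data <- tibble::tibble(id = sprintf("p%03d", 1:600),
                         label = rep(0:1, c(480, 120)))
  sp <- split_train_test(data, seed = 4)
  expect_equal(nrow(sp$train), 500L)
  expect_equal(nrow(sp$test), 100L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  # stratification: test keeps the 1:4 class ratio
  expect_equal(sum(sp$test$label == 1), 20L)
  sp2 <- split_train_test(data, seed = 4)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(split_train_test(data[1:4, ], seed = 1), "at least 6")
})

test_that("the cross-set identity filter drops near-duplicates of training", {
  train <- tibble::tibble(id = "tr", sequence = "MKLVINSGGHILKWWPQRV")
  test <- tibble::tibble(
    id = c("same", "far"),
    sequence = c("MKLVINSGGHILKWWPQRV", "DDEEDDEEDDCCYYDDEE"))
  kept <- cross_set_filter(train, test, threshold = 0.25)
  expect_equal(kept$id, "far")
})

test_that("sequence simulation respects bounds, seed and composition", {
  pr <- simulate_sequences(100, c(50, 300), seed = 10)
  expect_equal(nrow(pr), 100L)
  expect_true(all(pr$length >= 50 & pr$length <= 300))
  expect_identical(pr, simulate_sequences(100, c(50, 300), seed = 10))
  # uniform composition: each frequency within 3 binomial sigmas of 0.05
  chars <- strsplit(paste(simulate_sequences(500, c(200, 200),
                                             seed = 2)$sequence,
                          collapse = ""), "")[[1]]
  n <- length(chars)
  freq <- table(factor(chars, levels = AA_ALPHABET)) / n
  sigma <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freq - 0.05) < 3 * sigma))
})

test_that("status-record simulation plants recoverable classes", {
  st <- simulate_status_records(400, seed = 5)
  truth <- attr(st, "truth")
  fin <- filter_trials(st)
  got <- assign_class(fin$status)
  agree <- mean(got == truth$class[match(fin$target_id, truth$target_id)])
  expect_gte(agree, 0.99)
  # decoy trials exist and are removed by the filters
  expect_true(any(st$stop_date < as.Date("2006-01-01")))
  expect_true(any(st$method != "X-ray"))
  expect_true(all(fin$stop_date >= as.Date("2006-01-01")))
  # single-class mixture maps every target to that class
  pure <- simulate_status_records(50, mixture = c(CLF = 1, MF = 0, PF = 0,
                                                  CF = 0, CRYS = 0),
                                  seed = 6)
  fin_pure <- filter_trials(pure)
  expect_true(all(assign_class(fin_pure$status) == "CLF"))
})

test_that("planted feature tables honor the null and the seed", {
  sim <- simulate_planted(n = 50, p = 10, k = 2, delta = 1, rho = 0.3,
                          seed = 42)
  sim2 <- simulate_planted(n = 50, p = 10, k = 2, delta = 1, rho = 0.3,
                           seed = 42)
  expect_identical(sim$features, sim2$features)
  expect_identical(sim$labels, sim2$labels)
  expect_equal(dim(sim$features), c(50L, 11L))
  expect_length(sim$truth, 5L)
  # features remain unit-variance after latent mixing
  v <- apply(as.matrix(sim$features[-1]), 2, var)
  expect_true(all(v > 0.4 & v < 1.8))
  expect_error(simulate_planted(n = 10, p = 3, k = 5), "k <= p")
})

test_that("null planted data yield chance-level classifiers", {
  aucs <- vapply(1:10, function(s) {
    sim <- simulate_planted(n = 100, p = 6, k = 2, delta = 0, rho = 0,
                            tasks = 1, seed = s)
    cross_validate(sim$features, sim$labels$label, folds = 5,
                   seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
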