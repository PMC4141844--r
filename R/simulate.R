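# Synthetic-data generators: random protein sequences, status-record
# tables covering the X-ray status vocabulary (with decoy trials that the
# dataset filters must remove), and labeled feature tables with a planted
# informative-feature signal and a shared latent factor inducing
# inter-task output correlations.

#' Simulate random protein sequences
#'
#' i.i.d. sequences with lengths uniform in `length_range` and residues
#' drawn from `composition` (uniform over the 20 amino acids by default).
#'
#' @param n Number of sequences.
#' @param length_range Integer vector `c(min, max)` (default 50..300).
#' @param composition Named residue probability vector over [AA_ALPHABET]
#'   (normalized internally).
#' @param seed Seed.
#' @return Protein tibble (`id`, `sequence`, `length`).
#' @export
simulate_sequences <- function(n, length_range = c(50L, 300L),
                               composition = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  composition <- composition[AA_ALPHABET] / sum(composition[AA_ALPHABET])
  lens <- sample(seq.int(length_range[[1L]], length_range[[2L]]), n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
          collapse = "")
  }, character(1))
  new_protein_tbl(sprintf("syn%04d", seq_len(n)), seqs)
}

# in-pipeline statuses preceding each final status (for trial trajectories)
status_trajectory <- function(final) {
  chain <- c("selected", "cloned", "expressed", "soluble", "purified",
             "crystallized", "diffraction", "crystal structure", "in pdb")
  at <- match(final, chain)
  if (!is.na(at)) return(chain[seq_len(at)])
  before <- c("purification failed" = "soluble",
              "crystallization failed" = "purified",
              "poor diffraction" = "crystallized",
              "structure successful" = "diffraction")
  c(chain[seq_len(match(before[[final]], chain))], final)
}

FINAL_STATUS_BY_CLASS <- list(
  CLF = "selected",
  MF = c("cloned", "expressed"),
  PF = c("soluble", "purified", "purification failed"),
  CF = c("crystallization failed", "poor diffraction", "crystallized",
         "diffraction"),
  CRYS = c("crystal structure", "structure successful", "in pdb")
)

#' Simulate a status-record table with known classes
#'
#' Each target gets a trial trajectory consistent with a class drawn from
#' `mixture`: successive in-window X-ray trials up to a class-defining
#' final status, plus (with probability `decoy_prob` each) an
#' out-of-window 2005 trial and a non-X-ray trial carrying a more advanced
#' status - decoys that [filter_trials()] must remove for the planted class
#' to be recovered. The planted truth is attached as
#' `attr(, "truth")` (tibble `target_id`, `class`).
#'
#' @param n_targets Number of targets.
#' @param mixture Named class probabilities over CLF/MF/PF/CF/CRYS
#'   (default: the heavily failure-skewed composition typical of
#'   structural-genomics registries).
#' @param decoy_prob Probability of each decoy trial (default 0.3).
#' @param seed Seed.
#' @return Status-record tibble in the [read_status_records()] layout.
#' @export
simulate_status_records <- function(n_targets,
                                    mixture = c(CLF = 0.25, MF = 0.25,
                                                PF = 0.2, CF = 0.15,
                                                CRYS = 0.15),
                                    decoy_prob = 0.3, seed = 1L) {
  set.seed(seed)
  mixture <- mixture[TASKS] / sum(mixture[TASKS])
  classes <- sample(TASKS, n_targets, replace = TRUE, prob = mixture)
  rows <- list()
  for (i in seq_len(n_targets)) {
    target <- sprintf("T%05d", i)
    final <- sample(FINAL_STATUS_BY_CLASS[[classes[[i]]]], 1L)
    traj <- status_trajectory(final)
    n_tr <- length(traj)
    dates <- sort(as.Date("2006-01-01") + sample.int(1820L, n_tr))
    stop_cond <- if (final %in% c("in pdb", "crystal structure")) {
      final
    } else {
      "current status: work stopped"
    }
    tr <- tibble::tibble(
      target_id = target,
      trial_id = sprintf("%s.%d", target, seq_len(n_tr)),
      status = traj, stop_date = dates, method = "X-ray",
      stop_condition = stop_cond)
    decoys <- list()
    if (stats::runif(1) < decoy_prob) {
      # pre-window trial with a more advanced status
      decoys <- c(decoys, list(tibble::tibble(
        target_id = target, trial_id = paste0(target, ".old"),
        status = "in pdb", stop_date = as.Date("2005-06-01"),
        method = "X-ray", stop_condition = "in pdb")))
    }
    if (stats::runif(1) < decoy_prob) {
      # non-X-ray trial with a more advanced status
      decoys <- c(decoys, list(tibble::tibble(
        target_id = target, trial_id = paste0(target, ".nmr"),
        status = "crystal structure",
        stop_date = as.Date("2008-06-01"),
        method = "NMR", stop_condition = "crystal structure")))
    }
    rows[[i]] <- dplyr::bind_rows(c(list(tr), decoys))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- tibble::tibble(
    target_id = sprintf("T%05d", seq_len(n_targets)), class = classes)
  out
}

#' Simulate a labeled feature table with planted signal
#'
#' `p` unit-variance Gaussian features per protein plus a shared latent
#' factor `z`. For each of the five tasks, `k` informative features
#' (disjoint across tasks while `5 * k <= p`) carry effect `delta` each on
#' the task's logit. With `rho > 0` the latent factor is mixed into every
#' informative feature (`x = (e + rho * z) / sqrt(1 + rho^2)`, preserving
#' unit variance) and enters each logit directly scaled by `2 * rho`, so
#' the five tasks' classifiers produce correlated outputs and each task's
#' label carries signal that the other tasks' probability outputs can
#' recover - the regime in which second-level stacking is informative.
#' Labels are Bernoulli draws from the logistic model.
#'
#' @param n Number of proteins.
#' @param p Number of features.
#' @param k Informative features per task.
#' @param delta Per-feature effect size in standardized units (default 1).
#' @param rho Latent-factor coupling in `[0, 1]` (default 0; 0 makes the
#'   five tasks independent).
#' @param tasks Number of tasks to label (default 5, named CLF..CRYS).
#' @param seed Seed.
#' @return List: `features` (tibble `id` + `f0001..`), `labels` (tibble
#'   `id`, `task`, `label`), `truth` (named list of informative feature
#'   ids per task), `latent` (the latent factor).
#' @export
simulate_planted <- function(n, p, k, delta = 1, rho = 0, tasks = 5L,
                             seed = 1L) {
  stopifnot(k <= p, delta >= 0, rho >= 0, rho <= 1)
  set.seed(seed)
  task_names <- TASKS[seq_len(tasks)]
  x <- matrix(stats::rnorm(n * p), n, p)
  ids <- sprintf("f%04d", seq_len(p))
  colnames(x) <- ids
  z <- stats::rnorm(n)
  truth <- list()
  labels <- list()
  for (t in seq_along(task_names)) {
    informative <- if (tasks * k <= p) {
      ids[seq.int((t - 1L) * k + 1L, t * k)]
    } else {
      set.seed(seed + 1000L * t)
      sample(ids, k)
    }
    truth[[task_names[[t]]]] <- informative
    if (rho > 0) {
      x[, informative] <- (x[, informative, drop = FALSE] + rho * z) /
        sqrt(1 + rho^2)
    }
    logit <- as.vector(x[, informative, drop = FALSE] %*%
                         rep(delta, k)) + 2 * rho * z
    labels[[t]] <- tibble::tibble(
      id = sprintf("prot%05d", seq_len(n)),
      task = task_names[[t]],
      label = stats::rbinom(n, 1L, stats::plogis(logit)))
  }
  features <- tibble::as_tibble(as.data.frame(x))
  features <- tibble::add_column(features,
                                 id = sprintf("prot%05d", seq_len(n)),
                                 .before = 1L)
  list(features = features, labels = dplyr::bind_rows(labels),
       truth = truth, latent = z)
}
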