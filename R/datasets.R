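# Construction of the five task datasets from experimental status records:
# trial filters, 5-class assignment, per-task positive/negative label
# composition, CD-HIT-style redundancy reduction, and the 6-way
# training/test split.

# X-ray status vocabulary with the total precedence order used by the
# "most advanced status" rule (higher rank = further along the pipeline).
STATUS_PRECEDENCE <- c(
  "selected" = 1, "cloned" = 2, "expressed" = 3, "soluble" = 4,
  "purified" = 5, "purification failed" = 6, "crystallization failed" = 7,
  "poor diffraction" = 8, "crystallized" = 9, "diffraction" = 10,
  "structure successful" = 11, "crystal structure" = 12, "in pdb" = 13
)

STATUS_CLASS <- c(
  "selected" = "CLF",
  "cloned" = "MF", "expressed" = "MF",
  "soluble" = "PF", "purified" = "PF", "purification failed" = "PF",
  "crystallization failed" = "CF", "poor diffraction" = "CF",
  # crystal obtained but no solved structure: stalls at the final step
  "crystallized" = "CF", "diffraction" = "CF",
  "crystal structure" = "CRYS", "structure successful" = "CRYS",
  "in pdb" = "CRYS"
)

STOP_WHITELIST <- c("current status: work stopped", "in pdb",
                    "crystal structure")

norm_status <- function(x) tolower(trimws(x))

#' Trial filter criteria
#'
#' @param date_window Two dates: trials outside `[start, end]` are removed
#'   (default 2006-01-01 to 2010-12-31).
#' @param stop_whitelist Accepted `stop_condition` values (matched
#'   case-insensitively after trimming).
#' @param method Required experimental method (default `"X-ray"`; matched
#'   case-insensitively as a prefix, so "X-ray crystallography" passes).
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(date_window = as.Date(c("2006-01-01",
                                                    "2010-12-31")),
                            stop_whitelist = STOP_WHITELIST,
                            method = "X-ray") {
  stopifnot(length(date_window) == 2L, date_window[[1L]] < date_window[[2L]])
  structure(list(date_window = date_window,
                 stop_whitelist = norm_status(stop_whitelist),
                 method = method),
            class = "filter_criteria")
}

#' Filter experimental trials and collapse to one final status per target
#'
#' Applies the four dataset-construction criteria in order: (1) keep trials
#' whose stop condition is in the whitelist ("current status: work
#' stopped", "in PDB", "crystal structure"); (2) keep trials inside the
#' date window; (3) keep X-ray trials; (4) collapse each target to its most
#' advanced status (per the fixed precedence chain selected < cloned <
#' expressed < soluble < purified < ... < in PDB), keeping the latest trial
#' among equal statuses.
#'
#' @param records Status-record tibble ([read_status_records()] layout).
#' @param criteria A [filter_criteria()] list.
#' @return Tibble with one row per surviving target: `target_id`,
#'   `trial_id`, `status` (normalized to lower case), `stop_date`.
#' @export
filter_trials <- function(records, criteria = filter_criteria()) {
  out <- records |>
    dplyr::mutate(status = norm_status(.data$status)) |>
    dplyr::filter(
      norm_status(.data$stop_condition) %in% criteria$stop_whitelist,
      .data$stop_date >= criteria$date_window[[1L]],
      .data$stop_date <= criteria$date_window[[2L]],
      startsWith(tolower(.data$method), tolower(criteria$method))
    )
  unknown <- setdiff(unique(out$status), names(STATUS_PRECEDENCE))
  if (length(unknown) > 0L) {
    stop("unknown status value(s): ", paste(unknown, collapse = ", "),
         "; known statuses: ",
         paste(names(STATUS_PRECEDENCE), collapse = ", "), call. = FALSE)
  }
  out |>
    dplyr::mutate(.rank = STATUS_PRECEDENCE[.data$status]) |>
    dplyr::group_by(.data$target_id) |>
    dplyr::filter(.data$.rank == max(.data$.rank)) |>
    dplyr::arrange(dplyr::desc(.data$stop_date), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("target_id", "trial_id", "status", "stop_date")
}

#' Map a final status to its experimental-progress class
#'
#' The five classes mark the pipeline step at which a target stalled:
#' CLF (cloning failed: "selected"), MF (material production failed:
#' "cloned"/"expressed"), PF (purification failed: "soluble"/"purified"/
#' "purification failed"), CF (crystallization failed: "crystallization
#' failed"/"poor diffraction", plus "crystallized"/"diffraction" - crystal
#' obtained but no solved structure), CRYS (solved: "crystal structure"/
#' "structure successful"/"in PDB"). Vectorized; matching is
#' case-insensitive after trimming.
#'
#' @param status Character vector of final statuses.
#' @return Character vector over {CLF, MF, PF, CF, CRYS}.
#' @export
assign_class <- function(status) {
  s <- norm_status(status)
  unknown <- setdiff(unique(s), names(STATUS_CLASS))
  if (length(unknown) > 0L) {
    stop("unknown status value(s): ", paste(unknown, collapse = ", "),
         "; known statuses: ", paste(names(STATUS_CLASS), collapse = ", "),
         call. = FALSE)
  }
  unname(STATUS_CLASS[s])
}

# per-task label composition; targets in neither set are excluded
TASK_COMPOSITION <- list(
  CLF  = list(neg = "CLF", pos = c("MF", "PF", "CF", "CRYS")),
  MF   = list(neg = c("CLF", "MF"), pos = c("PF", "CF", "CRYS")),
  PF   = list(neg = "PF", pos = c("CF", "CRYS")),
  CF   = list(neg = "CF", pos = "CRYS"),
  CRYS = list(neg = c("CLF", "MF", "PF", "CF"), pos = "CRYS")
)

#' Build a task-specific labeled dataset
#'
#' Applies the per-task positive/negative composition: a target is positive
#' for a step if it passed it and negative if it stalled there; targets
#' whose class is uninformative for the step (e.g. CLF/MF targets for the
#' purification task, which may still be purifiable) are excluded.
#'
#' @param targets Tibble with columns `id` (or `target_id`) and `class`
#'   over {CLF, MF, PF, CF, CRYS}.
#' @param task One of `"CLF"`, `"MF"`, `"PF"`, `"CF"`, `"CRYS"`.
#' @return Tibble `id`, `class`, `label` (1 = passed the step) for the
#'   retained targets; excluded count in `attr(, "n_excluded")`.
#' @export
build_task_dataset <- function(targets, task = TASKS) {
  task <- match.arg(task)
  if (!"id" %in% names(targets) && "target_id" %in% names(targets)) {
    targets <- dplyr::rename(targets, id = "target_id")
  }
  comp <- TASK_COMPOSITION[[task]]
  out <- targets |>
    dplyr::mutate(label = dplyr::case_when(
      .data$class %in% comp$pos ~ 1L,
      .data$class %in% comp$neg ~ 0L,
      TRUE ~ NA_integer_
    ))
  excluded <- sum(is.na(out$label))
  out <- dplyr::filter(out, !is.na(.data$label))
  if (!all(c(0L, 1L) %in% out$label)) {
    stop("task ", task, " has an empty positive or negative set",
         call. = FALSE)
  }
  out <- dplyr::select(out, "id", "class", "label")
  attr(out, "task") <- task
  attr(out, "n_excluded") <- excluded
  out
}

# ---- redundancy reduction --------------------------------------------------

# global pairwise identity (matches / alignment length) in [0, 1]
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Greedy sequence-identity redundancy reduction
#'
#' CD-HIT-style incremental clustering: sequences are visited longest
#' first; a sequence joins the first existing cluster whose representative
#' shares at least `threshold` global pairwise identity (matches over
#' alignment length), otherwise it founds a new cluster. Cluster
#' representatives (each cluster's longest member, the founder) are
#' returned. With `by`, clustering is performed within each group
#' separately.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param threshold Identity threshold in (0, 1] (default 0.4).
#' @param by Optional column name grouping the rows (e.g. `"class"`);
#'   redundancy is then reduced within each group only.
#' @return The representative rows of `proteins`, original order.
#' @export
reduce_redundancy <- function(proteins, threshold = 0.4, by = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!is.null(by)) {
    keep_ids <- unlist(lapply(
      split(seq_len(nrow(proteins)), proteins[[by]]),
      function(rows) reduce_redundancy(proteins[rows, ], threshold)$id))
    return(proteins[proteins$id %in% keep_ids, ])
  }
  ord <- order(-nchar(proteins$sequence))
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      if (pairwise_identity(proteins$sequence[[i]],
                            proteins$sequence[[r]]) >= threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps <- c(reps, i)
  }
  proteins[sort(reps), ]
}

#' Remove test sequences similar to training sequences
#'
#' Cross-set identity filter: drops every test protein whose global
#' pairwise identity to any training protein is at least `threshold`
#' (default 0.25).
#'
#' @param train,test Protein tibbles (`id`, `sequence`).
#' @param threshold Identity cutoff in (0, 1].
#' @return The filtered `test` tibble.
#' @export
cross_set_filter <- function(train, test, threshold = 0.25) {
  keep <- vapply(seq_len(nrow(test)), function(i) {
    for (j in seq_len(nrow(train))) {
      if (pairwise_identity(test$sequence[[i]],
                            train$sequence[[j]]) >= threshold) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  test[keep, ]
}

#' Stratified 6-way training/test split
#'
#' Randomly partitions the rows into six near-equal subsets, stratified by
#' label; five are merged into the training set and the remaining subset is
#' the independent test set. Optionally applies the cross-set identity
#' filter to the test rows.
#'
#' @param data Tibble with a `label` column (and, for the identity filter,
#'   a `sequence` column).
#' @param seed Seed for the random partition.
#' @param identity_filter If `TRUE`, drop test rows with >= `threshold`
#'   identity to any training row.
#' @param threshold Cross-set identity cutoff (default 0.25).
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, seed = 1L, identity_filter = FALSE,
                             threshold = 0.25) {
  if (nrow(data) < 6L) stop("need at least 6 rows to split", call. = FALSE)
  subset_id <- stratified_folds(data$label, 6L, seed)
  train <- data[subset_id != 6L, ]
  test <- data[subset_id == 6L, ]
  if (identity_filter) test <- cross_set_filter(train, test, threshold)
  list(train = train, test = test)
}
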