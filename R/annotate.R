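# Per-residue annotation tracks: secondary structure (H/E/C), disorder
# (D/O) and solvent exposure (E/B). Tracks come either from external
# predictor output files (PSIPRED-style ss2, tabular disorder/accessibility
# calls) or from fast deterministic baseline annotators, so the feature
# encoder never requires an external binary.

#' Baseline annotator parameters
#'
#' @param hydropathy_window Odd window (residues) for the windowed
#'   Kyte-Doolittle mean used by the exposure call. Default 9.
#' @param exposure_threshold Exposure cutoff on the windowed hydropathy
#'   mean: a residue is called exposed when the mean is below this value
#'   (hydrophilic stretches face solvent). Default 0.
#' @param disorder_window Odd window for the disorder-prone residue
#'   fraction. Default 21.
#' @param disorder_threshold Minimum windowed fraction of disorder-prone
#'   residues (D,E,K,R,S,Q,P,G) for a disorder call. Default 0.3.
#' @param ss_window Odd window for the helix/strand propensity means.
#'   Default 9.
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(hydropathy_window = 9L, exposure_threshold = 0,
                            disorder_window = 21L, disorder_threshold = 0.3,
                            ss_window = 9L) {
  for (w in c(hydropathy_window, disorder_window, ss_window)) {
    if (w < 3L || w %% 2L == 0L) {
      stop("annotation windows must be odd and >= 3", call. = FALSE)
    }
  }
  structure(list(hydropathy_window = hydropathy_window,
                 exposure_threshold = exposure_threshold,
                 disorder_window = disorder_window,
                 disorder_threshold = disorder_threshold,
                 ss_window = ss_window),
            class = "baseline_params")
}

# centred moving average with truncated windows at the termini
windowed_mean <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Annotate sequences with the built-in baseline predictors
#'
#' Adds three per-residue tracks to a protein tibble, each a string of the
#' same length as the sequence: `ss` over {H,E,C} (windowed Chou-Fasman
#' helix/strand propensity vs. a fixed coil baseline of 1, ties to coil),
#' `disorder` over {D,O} (windowed fraction of disorder-prone residues),
#' and `exposure` over {E,B} (windowed Kyte-Doolittle hydropathy below the
#' threshold means exposed). Purely deterministic in (sequence, params);
#' reversing a sequence reverses every track.
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param params A [baseline_params()] list.
#' @param overwrite If `FALSE` (default), tracks already present (e.g. from
#'   [parse_annotation()]) are kept and only missing ones are filled in.
#' @return `proteins` with `ss`, `disorder`, `exposure` columns.
#' @export
annotate_baseline <- function(proteins, params = baseline_params(),
                              overwrite = FALSE) {
  one <- function(sequence) {
    chars <- seq_to_chars(sequence)
    kd <- windowed_mean(KD_HYDROPATHY[chars], params$hydropathy_window)
    exposure <- ifelse(kd < params$exposure_threshold, "E", "B")
    h <- windowed_mean(CF_HELIX[chars], params$ss_window)
    e <- windowed_mean(CF_STRAND[chars], params$ss_window)
    ss <- rep("C", length(chars))
    ss[h > e & h > 1] <- "H"
    ss[e > h & e > 1] <- "E"
    dfrac <- windowed_mean(as.numeric(chars %in% DISORDER_PRONE),
                           params$disorder_window)
    disorder <- ifelse(dfrac >= params$disorder_threshold, "D", "O")
    list(ss = paste(ss, collapse = ""),
         disorder = paste(disorder, collapse = ""),
         exposure = paste(exposure, collapse = ""))
  }
  tracks <- purrr::map(proteins$sequence, one)
  for (track in c("ss", "disorder", "exposure")) {
    new <- purrr::map_chr(tracks, track)
    if (overwrite || !track %in% names(proteins)) {
      proteins[[track]] <- new
    } else {
      keep <- !is.na(proteins[[track]])
      proteins[[track]] <- ifelse(keep, proteins[[track]], new)
    }
  }
  proteins
}

#' Parse external per-residue predictor output
#'
#' Attaches one annotation track parsed from an external predictor's output
#' file to a single protein record. Supported kinds:
#' \describe{
#'   \item{`ss2`}{PSIPRED-style vertical format: `index residue state` plus
#'     three per-state probabilities; states mapped to {H,E,C}.}
#'   \item{`disorder_tab`}{two-column `residue mark` table; marks `*`, `D`
#'     or `d` mean disordered, everything else ordered; mapped to {D,O}.}
#'   \item{`acc_tab`}{two-column `residue call` table with `e`/`b` calls;
#'     mapped to {E,B}.}
#' }
#' The file's residue column must match the record's sequence exactly; the
#' first mismatching position is reported otherwise. Tracks not provided
#' remain unset (`NA`) and must be filled by [annotate_baseline()] before
#' encoding.
#'
#' @param proteins Tibble with a single row (or `record_id` to select one).
#' @param kind One of `"ss2"`, `"disorder_tab"`, `"acc_tab"`.
#' @param path Path to the predictor output file.
#' @param record_id Optional id selecting the row of `proteins` to annotate.
#' @return `proteins` with the corresponding track column filled for that
#'   record (other rows get `NA` if the column did not exist).
#' @export
parse_annotation <- function(proteins, kind = c("ss2", "disorder_tab",
                                                "acc_tab"),
                             path, record_id = NULL) {
  kind <- match.arg(kind)
  row <- if (is.null(record_id)) {
    if (nrow(proteins) != 1L) {
      stop("specify record_id when annotating a multi-protein tibble",
           call. = FALSE)
    }
    1L
  } else {
    match(record_id, proteins$id)
  }
  if (is.na(row)) stop("record '", record_id, "' not found", call. = FALSE)
  sequence <- proteins$sequence[[row]]

  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  if (kind == "ss2") {
    # drop the "# PSIPRED ..." style header if numeric index is absent
    fields <- purrr::keep(fields, ~ suppressWarnings(!is.na(as.integer(.x[[1]]))))
    residues <- toupper(purrr::map_chr(fields, 2L))
    states <- toupper(purrr::map_chr(fields, 3L))
    track <- dplyr::recode(states, "G" = "H", "I" = "H", "B" = "E",
                           "T" = "C", "S" = "C", "L" = "C", "-" = "C",
                           .default = states)
    if (!all(track %in% c("H", "E", "C"))) {
      stop("unrecognized secondary-structure state '",
           setdiff(track, c("H", "E", "C"))[[1L]], "'", call. = FALSE)
    }
    column <- "ss"
  } else {
    residues <- toupper(purrr::map_chr(fields, 1L))
    marks <- purrr::map_chr(fields, 2L)
    if (kind == "disorder_tab") {
      track <- ifelse(marks %in% c("*", "D", "d"), "D", "O")
      column <- "disorder"
    } else {
      if (!all(tolower(marks) %in% c("e", "b"))) {
        stop("accessibility calls must be 'e' or 'b'", call. = FALSE)
      }
      track <- toupper(marks)
      column <- "exposure"
    }
  }

  chars <- seq_to_chars(sequence)
  if (length(residues) != length(chars)) {
    stop("annotation length ", length(residues), " does not match sequence ",
         "length ", length(chars), " for record '", proteins$id[[row]], "'",
         call. = FALSE)
  }
  mism <- which(residues != chars)
  if (length(mism) > 0L) {
    stop("annotation residue mismatch at position ", mism[[1L]], " ('",
         residues[[mism[[1L]]]], "' vs '", chars[[mism[[1L]]]], "')",
         call. = FALSE)
  }
  if (!column %in% names(proteins)) proteins[[column]] <- NA_character_
  proteins[[column]][[row]] <- paste(track, collapse = "")
  proteins
}

# validated per-residue tracks for one record; errors on unset tracks
annotation_tracks <- function(protein_row,
                              need = c("ss", "disorder", "exposure")) {
  n <- nchar(protein_row$sequence)
  out <- list()
  for (track in need) {
    value <- protein_row[[track]]
    if (is.null(value) || is.na(value)) {
      stop("annotation track '", track, "' is not set for record '",
           protein_row$id, "'; run annotate_baseline() first", call. = FALSE)
    }
    if (nchar(value) != n) {
      stop("annotation track '", track, "' has length ", nchar(value),
           ", expected ", n, call. = FALSE)
    }
    out[[track]] <- seq_to_chars(value)
  }
  out
}
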