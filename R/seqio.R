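# Reading and writing external artifacts: FASTA sequences, AAindex1 tables,
# experimental status records, feature tables and trained-model bundles.

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the 20 standard one-letter
#' amino-acid codes. Records containing non-standard codes (B, J, O, U, X, Z,
#' gaps, `*`) are an error in strict mode or silently dropped otherwise.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param strict If `TRUE` (default) any non-standard residue aborts with the
#'   offending record and position; if `FALSE` such records are skipped.
#' @return A tibble with columns `id`, `sequence`, `length`, one row per
#'   retained record, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                   seqs[[i]])
    if (bad > 0L) {
      if (strict) {
        stop("non-standard residue '", substr(seqs[[i]], bad, bad),
             "' at position ", bad, " in record '", ids[[i]], "'",
             call. = FALSE)
      }
      keep[[i]] <- FALSE
    }
  }
  new_protein_tbl(ids[keep], seqs[keep])
}

new_protein_tbl <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  tibble::tibble(id = unname(as.character(id)),
                 sequence = unname(sequence),
                 length = nchar(unname(sequence)))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- AAindex ---------------------------------------------------------------

# AAindex1 I-block column order (row 1 then row 2)
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse an AAindex1 flat file
#'
#' Reads the `H`/`I` blocks of the AAindex1 dialect (two rows of ten values
#' per index, `NA` allowed). Missing values are imputed with the mean of the
#' index's available values so every entry covers all 20 amino acids; the
#' imputed entries are recorded in `attr(, "imputed")`.
#'
#' @param path Path to an AAindex1-format flat file.
#' @param expected_count Expected number of entries (default 544, the size
#'   of the snapshot whose count enters the feature-registry arithmetic).
#'   Use `NULL` to accept any count.
#' @return A tibble with columns `index_id` and one column per amino acid
#'   (in [AA_ALPHABET] order).
#' @export
parse_aaindex1 <- function(path, expected_count = 544L) {
  lines <- readLines(path)
  h_at <- grep("^H ", lines)
  if (length(h_at) == 0L) stop("no AAindex entries found in '", path, "'",
                               call. = FALSE)
  ids <- sub("^H\\s+", "", lines[h_at])
  end_at <- c(h_at[-1L] - 1L, length(lines))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = 20,
                 dimnames = list(NULL, AAINDEX_ORDER))
  for (k in seq_along(ids)) {
    block <- lines[h_at[[k]]:end_at[[k]]]
    i_at <- grep("^I ", block)
    if (length(i_at) != 1L || i_at + 2L > length(block)) {
      stop("malformed I-block for index '", ids[[k]], "'", call. = FALSE)
    }
    rows <- block[i_at + 1:2]
    fields <- unlist(strsplit(trimws(rows), "\\s+"))
    if (length(fields) != 20L) {
      stop("malformed I-block for index '", ids[[k]], "': expected 20 ",
           "values, got ", length(fields), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields))
    v[toupper(fields) %in% c("NA", "NA.")] <- NA_real_
    vals[k, ] <- v
  }
  if (anyDuplicated(ids)) {
    stop("duplicate AAindex id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  build_aaindex_tbl(ids, vals[, AA_ALPHABET, drop = FALSE],
                    expected_count = expected_count)
}

build_aaindex_tbl <- function(ids, vals, expected_count = 544L) {
  imputed <- character(0)
  for (k in seq_along(ids)) {
    if (anyNA(vals[k, ])) {
      avail <- vals[k, !is.na(vals[k, ])]
      if (length(avail) == 0L) {
        stop("AAindex entry '", ids[[k]], "' has no values", call. = FALSE)
      }
      vals[k, is.na(vals[k, ])] <- mean(avail)
      imputed <- c(imputed, ids[[k]])
    }
  }
  if (!is.null(expected_count) && length(ids) != expected_count) {
    stop("AAindex table has ", length(ids), " entries, expected ",
         expected_count, " (set expected_count = NULL to accept)",
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- tibble::add_column(out, index_id = ids, .before = 1L)
  attr(out, "imputed") <- imputed
  out
}

aaindex_env <- new.env(parent = emptyenv())

#' The bundled 544-entry AAindex1 snapshot
#'
#' Builds the package's default AAindex table from the `aaindex` dataset
#' shipped with seqinr (544 physicochemical indices, the release size the
#' feature-registry arithmetic assumes: 2924 - 3 x 544 = 1292 non-AAindex
#' features). Missing values are mean-imputed per index. The result is
#' cached for the session.
#'
#' @return A tibble as returned by [parse_aaindex1()]: `index_id` plus 20
#'   amino-acid columns, 544 rows.
#' @export
aaindex_table <- function() {
  if (!is.null(aaindex_env$table)) return(aaindex_env$table)
  aaindex <- NULL # appease R CMD check; loaded just below
  utils::data("aaindex", package = "seqinr", envir = environment())
  ids <- vapply(aaindex, function(e) e$H, character(1))
  three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  vals <- t(vapply(aaindex, function(e) {
    v <- e$I
    stats::setNames(as.numeric(v), three[names(v)])[AA_ALPHABET]
  }, numeric(20)))
  colnames(vals) <- AA_ALPHABET
  tbl <- build_aaindex_tbl(unname(ids), vals, expected_count = 544L)
  aaindex_env$table <- tbl
  tbl
}

# 20 x n_index value matrix from an AAindex tibble
aaindex_matrix <- function(aaindex = aaindex_table()) {
  m <- t(as.matrix(aaindex[, AA_ALPHABET]))
  colnames(m) <- aaindex$index_id
  m
}

# ---- status records --------------------------------------------------------

STATUS_COLUMNS <- c("target_id", "trial_id", "status", "stop_date",
                    "method", "stop_condition")

#' Read experimental status records
#'
#' Reads a TSV of per-trial experimental status annotations (one row per
#' crystallization trial). Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path Path to a TSV file with header columns `target_id`,
#'   `trial_id`, `status`, `stop_date`, `method`, `stop_condition`.
#' @return A tibble with those columns; `stop_date` parsed as `Date`.
#' @export
read_status_records <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(STATUS_COLUMNS, names(tbl))
  if (length(missing) > 0L) {
    stop("status table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(tbl$stop_date, format = "%Y-%m-%d", optional = TRUE)
  bad <- which(is.na(dates) | is.na(tbl$status) | !nzchar(tbl$status))
  if (length(bad) > 0L) {
    stop("unparseable stop_date or empty status at row ", bad[[1L]],
         " ('", tbl$stop_date[[bad[[1L]]]], "')", call. = FALSE)
  }
  dplyr::mutate(tbl[STATUS_COLUMNS], stop_date = dates)
}

#' Write status records to TSV
#' @param records Status-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

# ---- feature tables --------------------------------------------------------

#' Write a feature table to TSV
#'
#' Full-precision TSV with an `id` column followed by one column per
#' feature; round-trips through [read_feature_table()] exactly.
#'
#' @param features Tibble with an `id` column and numeric feature columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- dplyr::mutate(features, dplyr::across(
    dplyr::where(is.numeric),
    ~ vapply(.x, function(v) sprintf("%.17g", v), character(1))
  ))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a feature table from TSV
#' @param path Path written by [write_feature_table()] (or any TSV with an
#'   `id` column and numeric feature columns).
#' @return A tibble; all feature values must be finite.
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (col in setdiff(names(tbl), "id")) {
    # base strtod parsing round-trips %.17g output exactly
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  mat <- as.matrix(tbl[setdiff(names(tbl), "id")])
  if (any(!is.finite(mat))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  tbl
}

feature_matrix <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    return(features)
  }
  cols <- setdiff(names(features), c("id", "label"))
  m <- as.matrix(features[cols])
  rownames(m) <- if ("id" %in% names(features)) features$id else NULL
  storage.mode(m) <- "double"
  m
}

# ---- model bundles ---------------------------------------------------------

MODEL_BUNDLE_FORMAT <- 1L

#' Save a trained model bundle
#'
#' Wraps any trained object of this package (a single classifier or a
#' stacked model) with format-version metadata so that incompatible or
#' corrupted files are rejected on load rather than silently mispredicting.
#'
#' @param model A `xtal_svm` or `xtal_stack` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  bundle <- list(
    format = MODEL_BUNDLE_FORMAT,
    package_version = as.character(utils::packageVersion("xtalprop")),
    class = class(model)[[1L]],
    payload = model
  )
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a trained model bundle
#' @param path Path written by [save_model()].
#' @return The stored model object; predictions are bit-identical to those
#'   of the object that was saved.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model bundle '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(bundle) || is.null(bundle$format) || is.null(bundle$payload)) {
    stop("'", path, "' is not an xtalprop model bundle", call. = FALSE)
  }
  if (bundle$format > MODEL_BUNDLE_FORMAT) {
    stop("model bundle format ", bundle$format, " is newer than this ",
         "version supports (", MODEL_BUNDLE_FORMAT, ")", call. = FALSE)
  }
  bundle$payload
}
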