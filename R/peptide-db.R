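# Activity-annotated bioactive-peptide database.
#
# The database is a tibble with columns sequence, activity, ec50_um,
# source_id and a "version_tag" attribute. Activity labels are free text,
# matched exactly after case-folding and whitespace normalisation.

normalise_activity <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

#' Build a peptide database from a data frame
#'
#' Validates and normalises records: sequences are uppercased and must use
#' the 20 standard residues with length >= 2 (shorter or longer than the
#' typical 2–20 bioactive-peptide range only warns); EC50 values (µM) must
#' be positive when present; duplicate (sequence, activity) rows are
#' collapsed with a warning, keeping the first.
#'
#' @param x Data frame with columns `sequence` and `activity`; optional
#'   `ec50_um` and `source_id`.
#' @param version_tag Free-text version label stored as an attribute.
#' @return A `peptide_db` tibble.
#' @export
#' @examples
#' peptide_db(data.frame(sequence = c("VW", "IPP"),
#'                       activity = "ACE inhibitor",
#'                       ec50_um = c(1.6, 5)))
peptide_db <- function(x, version_tag = "unversioned") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("sequence", "activity"), names(x))
  if (length(missing_cols)) {
    rlang::abort(paste0("peptide database is missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  db <- tibble::as_tibble(x)
  if (!"ec50_um" %in% names(db)) db$ec50_um <- NA_real_
  if (!"source_id" %in% names(db)) db$source_id <- NA_character_
  db <- dplyr::select(db, "sequence", "activity", "ec50_um", "source_id")
  db$sequence <- stringr::str_to_upper(stringr::str_trim(db$sequence))
  db$activity <- normalise_activity(db$activity)
  db$ec50_um <- as.numeric(db$ec50_um)
  db$source_id <- as.character(db$source_id)

  if (any(!nzchar(db$activity))) {
    rlang::abort("every record needs a non-empty activity label.")
  }
  bad_seq <- which(!grepl(paste0("^[", paste(AA_STANDARD, collapse = ""),
                                 "]+$"), db$sequence))
  if (length(bad_seq)) {
    rlang::abort(paste0("invalid peptide sequence(s) in row(s): ",
                        paste(bad_seq, collapse = ", ")))
  }
  bad_ec50 <- which(!is.na(db$ec50_um) & db$ec50_um <= 0)
  if (length(bad_ec50)) {
    rlang::abort(paste0("EC50 must be positive; offending row(s): ",
                        paste(bad_ec50, collapse = ", ")))
  }
  len <- stringr::str_length(db$sequence)
  if (any(len < 2)) {
    rlang::abort(paste0("peptide sequences must have length >= 2; row(s): ",
                        paste(which(len < 2), collapse = ", ")))
  }
  if (any(len > 20)) {
    rlang::warn(paste0(length(which(len > 20)),
                       " peptide(s) longer than the typical 20-residue range."))
  }
  key <- paste(db$sequence, db$activity, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::warn(paste0("collapsed ", sum(duplicated(key)),
                       " duplicate (sequence, activity) record(s)."))
    db <- db[!duplicated(key), ]
  }
  structure(db, class = c("peptide_db", class(tibble::tibble())),
            version_tag = as.character(version_tag))
}

#' Read a peptide database from CSV/TSV or JSON
#'
#' Delimited files must carry a header with at least `sequence` and
#' `activity`; JSON files hold an array of record objects (optionally
#' wrapped as `{version_tag, records}`).
#'
#' @param path File path; format inferred from the extension
#'   (`.json` vs delimited) unless `format` is given.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"json"`.
#' @param version_tag Version label; defaults to the file name (or the
#'   JSON-embedded tag when present).
#' @return A `peptide_db` tibble.
#' @export
read_peptide_db <- function(path, format = c("auto", "csv", "tsv", "json"),
                            version_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(doc) && !is.data.frame(doc) && !is.null(doc$records)) {
      version_tag <- version_tag %||% doc$version_tag
      doc <- doc$records
    }
    x <- tibble::as_tibble(doc)
  } else {
    delim <- if (format == "tsv") "\t" else ","
    x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  }
  peptide_db(x, version_tag = version_tag %||% basename(path))
}

#' Write a peptide database
#'
#' @param db A `peptide_db` tibble.
#' @param path Output path; `.json` writes
#'   `{version_tag, records: [...]}`, anything else a delimited file.
#' @param format As in [read_peptide_db()].
#' @return The path, invisibly. Round-trips: reading the file back
#'   reproduces all records and the version tag.
#' @export
write_peptide_db <- function(db, path,
                             format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(
      list(version_tag = db_version(db),
           records = as.data.frame(db)),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  } else {
    delim <- if (format == "tsv") "\t" else ","
    readr::write_delim(as.data.frame(db), path, delim = delim, na = "")
  }
  invisible(path)
}

#' Database version tag
#' @param db A `peptide_db`.
#' @return Character scalar.
#' @export
db_version <- function(db) {
  as.character(attr(db, "version_tag") %||% "unversioned")
}

#' Restrict a peptide database to one activity class
#'
#' Exact label match after case-folding and whitespace normalisation; an
#' empty result is allowed (the corresponding profile is then flagged not
#' calculable).
#'
#' @param db A `peptide_db`.
#' @param activity Activity label, e.g. `"ACE inhibitor"`.
#' @return A `peptide_db` with only that activity; version tag preserved.
#' @export
filter_by_activity <- function(db, activity) {
  check_string(activity, "activity")
  keep <- db$activity == normalise_activity(activity)
  structure(db[keep, ], class = class(db), version_tag = db_version(db))
}

#' Activity labels present in a database
#' @param db A `peptide_db`.
#' @return Character vector of distinct (normalised) activity labels.
#' @export
db_activities <- function(db) unique(db$activity)

#' Summarise database health and EC50 coverage
#'
#' Report-only check: per activity, the number of records and the fraction
#' carrying an EC50 value. The coverage determines whether the potency
#' statistic B can be non-zero for that activity (with no EC50-annotated
#' record the EC50-weighted sum is empty and B = 0).
#'
#' @param db A data frame of peptide records (validated or not).
#' @return A list with `per_activity` (tibble: activity, n_records,
#'   n_with_ec50, ec50_coverage) and `invalid_sequences` (tibble: row,
#'   sequence) listing records whose sequence leaves the standard alphabet.
#' @export
validate_db <- function(db) {
  stopifnot(is.data.frame(db))
  seqs <- stringr::str_to_upper(stringr::str_trim(as.character(db$sequence)))
  ok <- grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]{2,}$"), seqs)
  ec50 <- if ("ec50_um" %in% names(db)) as.numeric(db$ec50_um) else
    rep(NA_real_, nrow(db))
  per_activity <- tibble::tibble(
    activity = normalise_activity(db$activity),
    has_ec50 = !is.na(ec50) & ec50 > 0
  ) |>
    dplyr::group_by(.data$activity) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_with_ec50 = sum(.data$has_ec50),
      ec50_coverage = mean(.data$has_ec50),
      .groups = "drop"
    )
  list(
    per_activity = per_activity,
    invalid_sequences = tibble::tibble(
      row = which(!ok),
      sequence = as.character(db$sequence)[!ok]
    )
  )
}
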