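# Protein sequence input/output and validation.
#
# Sequences live in an ordinary tibble ("protein tibble") with one row per
# record and columns id, description, residues, n_residues — so they chain
# directly into dplyr verbs. FASTA parsing and writing are delegated to
# Biostrings; validation against the amino-acid alphabet is done here so
# that strict-mode errors can name the offending positions.

#' Build a protein tibble from residue strings
#'
#' @param id Character vector of record identifiers (non-empty, unique).
#' @param residues Character vector of one-letter residue strings. Stored
#'   uppercased with whitespace removed.
#' @param description Optional character vector of free-text descriptions.
#' @param is_fragment Logical; whether each record is a fragment of a larger
#'   chain. Fragments are treated identically in all downstream statistics;
#'   the flag is informational.
#' @return A tibble with columns `id`, `description`, `residues`,
#'   `n_residues`, `is_fragment`.
#' @export
#' @examples
#' protein_tbl("p1", "MKT")
protein_tbl <- function(id, residues, description = "", is_fragment = FALSE) {
  if (length(id) == 0) rlang::abort("no records")
  if (any(!nzchar(id) | is.na(id))) rlang::abort("`id` must be non-empty.")
  if (anyDuplicated(id)) rlang::abort("record ids must be unique.")
  residues <- stringr::str_to_upper(gsub("[[:space:]]", "", residues))
  tibble::tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    residues = residues,
    n_residues = stringr::str_length(residues),
    is_fragment = rep_len(as.logical(is_fragment), length(id))
  )
}

#' Read protein sequences from FASTA
#'
#' Accepts either a file path or literal FASTA text (detected by a leading
#' `>`). Residues are uppercased and whitespace inside records is dropped;
#' record order is preserved.
#'
#' @param source Path to a FASTA file, or a character scalar/vector of FASTA
#'   text.
#' @param mode Validation mode passed to [validate_sequence()]: `"strict"`
#'   (default) rejects any residue outside the 20 standard codes; to skip
#'   validation use `mode = "none"`.
#' @return A protein tibble (see [protein_tbl()]).
#' @export
#' @examples
#' read_fasta(">p1\nMKT\n")
read_fasta <- function(source, mode = c("strict", "permissive", "none")) {
  mode <- match.arg(mode)
  if (length(source) == 0 || all(!nzchar(source))) rlang::abort("no records")
  if (length(source) > 1 || grepl("^[[:space:]]*>", source[1])) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(source, collapse = "\n"), path)
  } else {
    path <- source
    if (!file.exists(path)) {
      rlang::abort(paste0("FASTA file not found: ", path))
    }
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) rlang::abort("no records")
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(
    grepl("[[:space:]]", headers),
    stringr::str_trim(sub("^[^[:space:]]+[[:space:]]+", "", headers)),
    ""
  )
  seqs <- protein_tbl(
    id = id,
    residues = as.character(set),
    description = description,
    is_fragment = grepl("fragment", headers, ignore.case = TRUE)
  )
  if (mode != "none") seqs <- validate_sequence(seqs, mode = mode) else seqs
}

#' Validate residues against the amino-acid alphabet
#'
#' In strict mode any residue outside the 20 standard one-letter codes is an
#' error; the message lists every offending position and character. In
#' permissive mode the ambiguity codes X, B, Z and U are retained — they
#' count towards the chain length `N` but are flagged non-matchable (a
#' database peptide or a cleavage clause can never match them); any other
#' character is still an error.
#'
#' @param x A protein tibble or a single residue string.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return The validated protein tibble, with a list-column `nonstandard`
#'   (integer positions of tolerated ambiguity codes; empty in strict mode).
#' @export
#' @examples
#' validate_sequence("ACDEFGHIKLMNPQRSTVWY")
#' validate_sequence("AXA", mode = "permissive")
validate_sequence <- function(x, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (is.character(x)) x <- protein_tbl("seq", x)
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  allowed <- if (mode == "strict") AA_STANDARD else
    c(AA_STANDARD, AA_PERMISSIVE_EXTRA)
  flagged <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    chars <- residue_chars(x$residues[i])
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      rlang::abort(paste0(
        "invalid residue(s) in record '", x$id[i], "' (", mode, " mode): ",
        paste0("position ", bad, " ('", chars[bad], "')", collapse = ", ")
      ))
    }
    flagged[[i]] <- which(chars %in% AA_PERMISSIVE_EXTRA)
  }
  x$nonstandard <- flagged
  x
}

#' Write protein sequences as FASTA
#'
#' @param seqs A protein tibble.
#' @param path Optional output file path. When `NULL` (default) the FASTA
#'   text is returned as a character scalar.
#' @param width Line width for wrapping residue lines (default 60).
#' @return The path (invisibly) when `path` is given, otherwise the FASTA
#'   text. Round-trips through [read_fasta()]: parsing the output reproduces
#'   ids, descriptions and residues exactly.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 1, width >= 1)
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- ifelse(
    nzchar(seqs$description),
    paste(seqs$id, seqs$description),
    seqs$id
  )
  out <- path %||% tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(set, filepath = out, format = "fasta",
                              width = as.integer(width))
  if (is.null(path)) {
    txt <- paste(readLines(out), collapse = "\n")
    unlink(out)
    paste0(txt, "\n")
  } else {
    invisible(out)
  }
}

#' Fetch a UniProtKB record as FASTA (convenience; needs network)
#'
#' Downloads `https://rest.uniprot.org/uniprotkb/<accession>.fasta` to a
#' user-named path. Purely a convenience for interactive use; nothing in the
#' package requires network access.
#'
#' @param accession UniProtKB accession, e.g. `"H6TQS9"`.
#' @param path Destination FASTA path.
#' @return The path, invisibly.
#' @export
fetch_uniprot_fasta <- function(accession, path) {
  check_string(accession, "accession")
  check_string(path, "path")
  url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".fasta")
  utils::download.file(url, destfile = path, quiet = TRUE, mode = "wb")
  invisible(path)
}
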