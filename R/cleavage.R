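# Protease specificity rules and in-silico digestion.
#
# A cleavage rule is a disjunction of clauses evaluated on every peptide
# bond. Bond i (1-based, i in 1..N-1) joins residues i and i+1; positions
# are named by the standard protease nomenclature P4..P1 (N-terminal side
# of the scissile bond, P1 = residue i) and P1'..P4' (C-terminal side,
# P1' = residue i+1). Each clause may require residues at positions and
# block residues at positions. The pseudo-residue "-" denotes "outside the
# chain", so termini can be required (e.g. dipeptidase rules) or blocked.

POSITION_OFFSETS <- c(
  "P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
  "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L
)

validate_residue_set <- function(set, where) {
  set <- as.character(unlist(set))
  if (length(set) == 0) {
    rlang::abort(paste0("empty residue set in ", where))
  }
  bad <- setdiff(set, c(AA_STANDARD, "-"))
  if (length(bad)) {
    rlang::abort(paste0(
      "invalid residue code(s) in ", where, ": ",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  unique(set)
}

normalise_clause <- function(clause, enzyme_name) {
  known <- c("p1", "p1prime", "require", "block")
  unknown <- setdiff(names(clause), known)
  if (length(unknown)) {
    rlang::abort(paste0(
      "unknown clause field(s) for enzyme '", enzyme_name, "': ",
      paste(unknown, collapse = ", ")
    ))
  }
  where <- paste0("enzyme '", enzyme_name, "'")
  # [[ indexing throughout: $ would partially match p1 against p1prime
  require <- lapply(clause[["require"]] %||% list(), validate_residue_set,
                    where)
  block <- lapply(clause[["block"]] %||% list(), validate_residue_set, where)
  if (!is.null(clause[["p1"]])) {
    require[["P1"]] <- validate_residue_set(clause[["p1"]], where)
  }
  if (!is.null(clause[["p1prime"]])) {
    require[["P1'"]] <- validate_residue_set(clause[["p1prime"]], where)
  }
  badpos <- setdiff(c(names(require), names(block)), names(POSITION_OFFSETS))
  if (length(badpos)) {
    rlang::abort(paste0(
      "unknown position label(s) for enzyme '", enzyme_name, "': ",
      paste(badpos, collapse = ", ")
    ))
  }
  if (length(require) == 0) {
    rlang::abort(paste0(
      "clause for enzyme '", enzyme_name,
      "' must require at least one position (p1, p1prime or require)"
    ))
  }
  list(require = require, block = block)
}

#' Define a protease cleavage rule
#'
#' A rule is one or more clauses; a peptide bond is cut when any clause is
#' satisfied. Each clause is a list with optional fields `p1` (residues
#' required at P1, i.e. immediately N-terminal to the bond), `p1prime`
#' (required at P1'), `require` (named list of position -> residue set that
#' must be present, positions `P4`..`P4'`), and `block` (named list of
#' position -> residue set that must be absent). The token `"-"` in a set
#' refers to positions beyond the chain termini.
#'
#' @param name Enzyme name (unique within a rule set).
#' @param clauses List of clause lists (see Details above). A single clause
#'   may be given directly.
#' @return An object of class `cleavage_rule`.
#' @export
#' @examples
#' trypsin <- cleavage_rule("Trypsin",
#'   list(p1 = c("K", "R"), block = list("P1'" = "P")))
cleavage_rule <- function(name, clauses) {
  check_string(name, "name")
  if (!is.list(clauses)) rlang::abort("`clauses` must be a list.")
  # single bare clause (any named fields) vs unnamed list of clauses
  if (!is.null(names(clauses)) && any(nzchar(names(clauses)))) {
    clauses <- list(clauses)
  }
  if (length(clauses) == 0) rlang::abort("a rule needs at least one clause.")
  structure(
    list(
      enzyme_name = name,
      clauses = lapply(clauses, normalise_clause, enzyme_name = name)
    ),
    class = "cleavage_rule"
  )
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat("<cleavage_rule> ", x$enzyme_name, ": ", length(x$clauses),
      " clause(s)\n", sep = "")
  invisible(x)
}

#' Compile an enzyme rule set from a config document
#'
#' Reads a YAML (or already-parsed list) rule document with fields
#' `version` and `enzymes` (each entry `{name, clauses}`) into a named list
#' of [cleavage_rule()] objects. Compilation is deterministic; duplicate
#' enzyme names, unknown fields and invalid residue codes are errors.
#'
#' @param spec Path to a YAML file, or the equivalent nested list.
#' @return Named list of `cleavage_rule` objects (class `enzyme_rules`),
#'   with the document's version string in attribute `version_tag`.
#' @export
compile_enzyme_rules <- function(spec) {
  doc <- if (is.character(spec)) yaml::read_yaml(spec) else spec
  if (!is.list(doc) || is.null(doc$enzymes)) {
    rlang::abort("rule document must have an `enzymes` field.")
  }
  unknown <- setdiff(names(doc), c("version", "enzymes"))
  if (length(unknown)) {
    rlang::abort(paste0("unknown rule-document field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  nms <- purrr::map_chr(doc$enzymes, function(e) e$name %||% "")
  if (any(!nzchar(nms))) rlang::abort("every enzyme entry needs a `name`.")
  if (anyDuplicated(nms)) {
    rlang::abort(paste0("duplicate enzyme name: ",
                        paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  rules <- purrr::map(doc$enzymes, function(e) {
    extra <- setdiff(names(e), c("name", "clauses"))
    if (length(extra)) {
      rlang::abort(paste0("unknown field(s) for enzyme '", e$name, "': ",
                          paste(extra, collapse = ", ")))
    }
    cleavage_rule(e$name, e$clauses)
  })
  names(rules) <- nms
  structure(rules, class = "enzyme_rules",
            version_tag = as.character(doc$version %||% "unversioned"))
}

#' Load the packaged protease rule file
#'
#' The package ships a versioned YAML rule file covering 33 named
#' proteases, authored from public PeptideCutter/BIOPEP-style specificity
#' conventions. Specificities for several food-science proteases are only
#' loosely documented in the literature, so exact agreement with any given
#' web service's rule set is not guaranteed; see the methods vignette.
#'
#' @param enzymes Optional character vector restricting the returned rules.
#' @return Named list of `cleavage_rule` objects (class `enzyme_rules`).
#' @export
enzyme_rules <- function(enzymes = NULL) {
  path <- system.file("extdata", "protease_rules.yaml", package = "pepsilico")
  rules <- compile_enzyme_rules(path)
  if (is.null(enzymes)) return(rules)
  missing <- setdiff(enzymes, names(rules))
  if (length(missing)) {
    rlang::abort(paste0(
      "unknown enzyme name(s): ", paste(missing, collapse = ", "),
      "; available: ", paste(names(rules), collapse = ", ")
    ))
  }
  structure(rules[enzymes], class = "enzyme_rules",
            version_tag = attr(rules, "version_tag"))
}

# Resolve a protein argument (tibble row or residue string) to a
# list(id, residues, n).
resolve_protein <- function(seq) {
  if (is.character(seq) && length(seq) == 1) {
    seq <- protein_tbl("seq", seq)
  }
  stopifnot(is.data.frame(seq), all(c("id", "residues") %in% names(seq)))
  if (nrow(seq) != 1) {
    rlang::abort("expected exactly one protein record; filter first.")
  }
  list(id = seq$id[1], residues = seq$residues[1],
       n = stringr::str_length(seq$residues[1]))
}

# Evaluate one clause on all bonds of a residue-character vector.
clause_hits <- function(chars, clause) {
  n <- length(chars)
  if (n < 2) return(logical(0))
  bonds <- seq_len(n - 1L)
  ok <- rep(TRUE, n - 1L)
  eval_pos <- function(pos, set, type) {
    idx <- bonds + POSITION_OFFSETS[[pos]]
    inside <- idx >= 1L & idx <= n
    res <- rep(NA_character_, length(idx))
    res[inside] <- chars[idx[inside]]
    present <- inside & res %in% set
    terminal <- !inside & ("-" %in% set)
    if (type == "require") present | terminal else !(present | terminal)
  }
  for (pos in names(clause$require)) {
    ok <- ok & eval_pos(pos, clause$require[[pos]], "require")
  }
  for (pos in names(clause$block)) {
    ok <- ok & eval_pos(pos, clause$block[[pos]], "block")
  }
  ok
}

#' Find cleavage sites of a rule on a protein
#'
#' @param seq A one-row protein tibble or a residue string.
#' @param rule A [cleavage_rule()].
#' @return Strictly increasing integer vector of cut sites; site `i` means
#'   the bond between residues `i` and `i + 1` (1-based) is hydrolyzed.
#'   Empty when no bond satisfies any clause.
#' @export
#' @examples
#' tryp <- cleavage_rule("Trypsin",
#'   list(p1 = c("K", "R"), block = list("P1'" = "P")))
#' find_cut_sites("AAKAAKP", tryp) # 3
find_cut_sites <- function(seq, rule) {
  stopifnot(inherits(rule, "cleavage_rule"))
  p <- resolve_protein(seq)
  chars <- residue_chars(p$residues)
  if (length(chars) < 2) return(integer(0))
  hit <- Reduce(`|`, lapply(rule$clauses, clause_hits, chars = chars))
  which(hit)
}

#' Digest a protein with one or more proteases
#'
#' Multi-enzyme digestion models simultaneous action: the cut-site set is
#' the union over enzymes, and a bond satisfying several clauses or
#' enzymes is still a single cut. Fragments are the maximal runs between
#' consecutive cuts, in 1-based inclusive coordinates; their concatenation
#' always reproduces the chain.
#'
#' @param seq A one-row protein tibble or a residue string.
#' @param rules A `cleavage_rule`, a list of them, or an `enzyme_rules`
#'   subset.
#' @param total_bonds Override for the total peptide-bond count `D` used by
#'   [theoretical_dh()]. Defaults to `N - 1` for a linear chain. Some
#'   published tables are consistent with a different denominator, so it is
#'   configurable rather than guessed.
#' @return An object of class `digestion` with fields `protein_id`,
#'   `enzyme`, `cut_sites`, `fragments` (tibble: protein_id, enzyme, start,
#'   end, sequence), `d_bonds`, `total_bonds`, `n_residues`. Use [tidy()]
#'   for the fragment tibble and [glance()] for the one-row summary.
#' @export
#' @examples
#' tryp <- cleavage_rule("Trypsin",
#'   list(p1 = c("K", "R"), block = list("P1'" = "P")))
#' digest_protein("AAKAAKP", tryp)
digest_protein <- function(seq, rules, total_bonds = NULL) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  if (length(rules) == 0) rlang::abort("at least one cleavage rule needed.")
  stopifnot(all(purrr::map_lgl(rules, inherits, "cleavage_rule")))
  p <- resolve_protein(seq)
  sites <- sort(unique(unlist(
    lapply(rules, function(r) find_cut_sites(seq, r))
  )))
  starts <- c(1L, sites + 1L)
  ends <- c(sites, p$n)
  frags <- tibble::tibble(
    protein_id = p$id,
    enzyme = paste(purrr::map_chr(rules, "enzyme_name"), collapse = " + "),
    start = starts,
    end = ends,
    sequence = stringr::str_sub(p$residues, starts, ends)
  )
  structure(
    list(
      protein_id = p$id,
      enzyme = frags$enzyme[1],
      cut_sites = as.integer(sites),
      fragments = frags,
      d_bonds = length(sites),
      total_bonds = as.integer(total_bonds %||% (p$n - 1L)),
      n_residues = p$n
    ),
    class = "digestion"
  )
}

#' Theoretical degree of hydrolysis
#'
#' \eqn{DH_t = 100 \, d / D} (percent), where `d` is the number of
#' hydrolyzed peptide bonds and `D` the total number of peptide bonds in
#' the chain.
#'
#' @param x A `digestion` object, or the number of hydrolyzed bonds `d`.
#' @param total_bonds Total bond count `D`; for a `digestion` this
#'   overrides the value stored at digestion time.
#' @return Percentage in `[0, 100]`; 0 exactly when there is no cut site.
#' @export
#' @examples
#' theoretical_dh(1, total_bonds = 6) # 16.667
theoretical_dh <- function(x, total_bonds = NULL) {
  if (inherits(x, "digestion")) {
    d <- x$d_bonds
    D <- total_bonds %||% x$total_bonds
  } else {
    d <- x
    D <- total_bonds
    if (is.null(D)) rlang::abort("`total_bonds` is required.")
  }
  if (is.na(D) || D < 1) {
    rlang::abort("total peptide-bond count must be >= 1 (chain too short).")
  }
  100 * d / D
}

#' @export
print.digestion <- function(x, ...) {
  cat("<digestion> ", x$protein_id, " by ", x$enzyme, ": ",
      x$d_bonds, "/", x$total_bonds, " bonds cut (DH_t = ",
      sprintf("%.4f", theoretical_dh(x)), "%), ",
      nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' @rdname digest_protein
#' @param x A `digestion` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.digestion <- function(x, ...) x$fragments

#' @rdname digest_protein
#' @exportS3Method generics::glance
glance.digestion <- function(x, ...) {
  tibble::tibble(
    protein_id = x$protein_id,
    enzyme = x$enzyme,
    n_residues = x$n_residues,
    n_fragments = nrow(x$fragments),
    d_bonds = x$d_bonds,
    total_bonds = x$total_bonds,
    dh_t = theoretical_dh(x)
  )
}
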