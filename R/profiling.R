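# Occurrence/release counting and the profiling statistics.
#
# Conventions (documented in the methods vignette):
# * Occurrence counting includes overlapping matches, and every database
#   record is counted independently — a dipeptide inside a matched
#   tripeptide counts for both records. `count_overlaps = FALSE` switches
#   to non-overlapping counting for comparison with services that differ.
# * A released fragment must equal a database peptide exactly; containment
#   is not release.
# * W is NA (rendered "-") only when A = 0; when A > 0 but nothing is
#   released, W = 0. Likewise V is NA only when B = 0.

#' Count occurrences of database peptides in the intact chain
#'
#' @param seq A one-row protein tibble or residue string.
#' @param db A `peptide_db` (typically already restricted with
#'   [filter_by_activity()]).
#' @param count_overlaps Count overlapping occurrences of the same peptide
#'   (default `TRUE`).
#' @return A tibble with one row per database record: `sequence`,
#'   `activity`, `ec50_um`, `positions` (list-column of 1-based match start
#'   positions) and `a_i` (occurrence count). The total `a` for an activity
#'   is `sum(a_i)`.
#' @export
#' @examples
#' db <- peptide_db(data.frame(sequence = "GP", activity = "x"))
#' count_occurrences("GPAGP", db)$a_i # 2
count_occurrences <- function(seq, db, count_overlaps = TRUE) {
  p <- resolve_protein(seq)
  positions <- purrr::map(db$sequence, function(pep) {
    m <- stringi::stri_locate_all_fixed(p$residues, pep,
                                        overlap = isTRUE(count_overlaps))[[1]]
    if (nrow(m) == 1 && is.na(m[1, 1])) integer(0) else as.integer(m[, 1])
  })
  tibble::tibble(
    sequence = db$sequence,
    activity = db$activity,
    ec50_um = db$ec50_um,
    positions = positions,
    a_i = purrr::map_int(positions, length)
  )
}

#' Count database peptides released as digestion fragments
#'
#' A peptide is released when a digestion fragment equals it exactly;
#' multiplicity is counted (two identical fragments are two releases).
#'
#' @param result A `digestion` object (or its [tidy()] fragment tibble).
#' @param db A `peptide_db`.
#' @return A tibble with one row per database record: `sequence`,
#'   `activity`, `ec50_um`, `d_i`. The total `d` is `sum(d_i)`.
#' @export
count_released <- function(result, db) {
  frag <- if (inherits(result, "digestion")) result$fragments else result
  stopifnot(is.data.frame(frag), "sequence" %in% names(frag))
  counts <- table(frag$sequence)
  tibble::tibble(
    sequence = db$sequence,
    activity = db$activity,
    ec50_um = db$ec50_um,
    d_i = as.integer(ifelse(is.na(match(db$sequence, names(counts))), 0L,
                            counts[db$sequence]))
  )
}

#' Occurrence and release frequencies
#'
#' \eqn{A = a/N}, \eqn{A_E = d/N} and the relative release
#' \eqn{W = A_E / A}. `W` is `NA` when `A = 0` (no encrypted fragment to
#' release) and 0 when `A > 0` but nothing is released. With `n = 1` the
#' function also serves to combine already-normalised frequencies: feeding
#' published (A, A_E) pairs reproduces the corresponding W.
#'
#' @param a Occurrence count (or frequency when `n = 1`).
#' @param d Release count (or frequency when `n = 1`).
#' @param n Number of residues in the protein chain.
#' @return A one-row tibble (vectorised over `a`/`d`) with `A`, `A_E`, `W`.
#' @export
#' @examples
#' compute_frequencies(a = 0.5827, d = 0.0874, n = 1)$W # 0.14999...
compute_frequencies <- function(a, d, n) {
  stopifnot(all(n >= 1), all(a >= 0), all(d >= 0))
  if (any(d > a)) {
    rlang::abort("released count d cannot exceed occurrence count a.")
  }
  A <- a / n
  A_E <- d / n
  tibble::tibble(A = A, A_E = A_E,
                 W = ifelse(A > 0, A_E / A, NA_real_))
}

#' EC50-weighted potency statistics
#'
#' \eqn{B = \frac{1}{N} \sum_{i} a_i / EC_{50,i}} in \eqn{\mu M^{-1}},
#' summing over the database peptides that carry an EC50; `B_E` is the same
#' sum with the released counts `d_i`; \eqn{V = B_E / B} when `B > 0`, `NA`
#' otherwise. Records without an EC50 contribute nothing, so `B` is
#' invariant to adding or removing them.
#'
#' @param matches Occurrence tibble from [count_occurrences()].
#' @param released Release tibble from [count_released()] (same record
#'   order), or `NULL` to compute `B` only.
#' @param n Number of residues in the chain.
#' @return One-row tibble with `B`, `B_E`, `V`.
#' @export
compute_potencies <- function(matches, released = NULL, n) {
  stopifnot(n >= 1)
  weight <- function(count, ec50) {
    keep <- !is.na(ec50)
    if (!any(keep)) return(0)
    sum(count[keep] / ec50[keep]) / n
  }
  B <- weight(matches$a_i, matches$ec50_um)
  B_E <- if (is.null(released)) NA_real_ else {
    if (!identical(released$sequence, matches$sequence)) {
      rlang::abort("`matches` and `released` must list the same records.")
    }
    weight(released$d_i, released$ec50_um)
  }
  tibble::tibble(B = B, B_E = B_E,
                 V = ifelse(B > 0, B_E / B, NA_real_))
}

#' Amino-acid composition
#'
#' Counts and fractions of each residue in the chain (ProtParam-style).
#'
#' @param seq A one-row protein tibble or residue string.
#' @param all_residues Include standard residues absent from the chain
#'   (count 0)? Default `FALSE`.
#' @return Tibble with `residue`, `count`, `fraction`; fractions sum to 1.
#' @export
#' @examples
#' aa_composition("AAKK")
aa_composition <- function(seq, all_residues = FALSE) {
  p <- resolve_protein(seq)
  chars <- residue_chars(p$residues)
  stopifnot(length(chars) >= 1)
  lv <- if (all_residues) union(AA_STANDARD, unique(chars)) else
    sort(unique(chars))
  counts <- table(factor(chars, levels = lv))
  tibble::tibble(
    residue = names(counts),
    count = as.integer(counts),
    fraction = as.numeric(counts) / length(chars)
  )
}

#' Profile one (protein, activity, enzyme) combination
#'
#' Orchestrates the pipeline: restrict the database to the activity, count
#' occurrences in the intact chain, digest, count exact releases, and
#' compute A, A_E, W, B, B_E, V and DH_t. When the database holds no
#' record for the activity the row is flagged not calculable (all-zero
#' counts, NA frequencies).
#'
#' @param seq A one-row protein tibble or residue string.
#' @param db A `peptide_db`.
#' @param activity Activity label.
#' @param rule A [cleavage_rule()] (or list of rules digesting together).
#' @param total_bonds Optional override of the bond denominator `D` for
#'   DH_t (default `N - 1`).
#' @param count_overlaps Passed to [count_occurrences()].
#' @return A one-row `activity_profile` tibble with columns `protein_id`,
#'   `activity`, `enzyme`, `n_residues`, `a`, `d`, `A`, `A_E`, `W`, `B`,
#'   `B_E`, `V`, `dh_t`, `calculable`.
#' @export
build_profile <- function(seq, db, activity, rule, total_bonds = NULL,
                          count_overlaps = TRUE) {
  p <- resolve_protein(seq)
  sub <- filter_by_activity(db, activity)
  dig <- digest_protein(seq, rule, total_bonds = total_bonds)
  if (nrow(sub) == 0) {
    row <- tibble::tibble(
      protein_id = p$id, activity = normalise_activity(activity),
      enzyme = dig$enzyme, n_residues = p$n,
      a = 0L, d = 0L, A = NA_real_, A_E = NA_real_, W = NA_real_,
      B = NA_real_, B_E = NA_real_, V = NA_real_,
      dh_t = theoretical_dh(dig), calculable = FALSE
    )
  } else {
    occ <- count_occurrences(seq, sub, count_overlaps = count_overlaps)
    rel <- count_released(dig, sub)
    freq <- compute_frequencies(sum(occ$a_i), sum(rel$d_i), p$n)
    pot <- compute_potencies(occ, rel, p$n)
    row <- tibble::tibble(
      protein_id = p$id, activity = sub$activity[1], enzyme = dig$enzyme,
      n_residues = p$n, a = sum(occ$a_i), d = sum(rel$d_i),
      A = freq$A, A_E = freq$A_E, W = freq$W,
      B = pot$B, B_E = pot$B_E, V = pot$V,
      dh_t = theoretical_dh(dig), calculable = TRUE
    )
  }
  class(row) <- c("activity_profile", class(tibble::tibble()))
  row
}

#' Profile a protein across activities and enzymes
#'
#' @param seq A one-row protein tibble or residue string.
#' @param db A `peptide_db`.
#' @param rules An `enzyme_rules` set / list of [cleavage_rule()]s; each
#'   enzyme digests separately (one profile row per enzyme and activity).
#' @param activities Activity labels to profile (default: all in `db`).
#' @param ... Passed to [build_profile()] (`total_bonds`,
#'   `count_overlaps`).
#' @return An `activity_profile` tibble, one row per (activity, enzyme).
#' @export
profile_protein <- function(seq, db, rules, activities = NULL, ...) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  if (length(rules) == 0) rlang::abort("at least one cleavage rule needed.")
  activities <- activities %||% db_activities(db)
  if (length(activities) == 0) rlang::abort("no activities to profile.")
  rows <- purrr::map(activities, function(act) {
    purrr::map(rules, function(r) build_profile(seq, db, act, r, ...)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(rows) <- c("activity_profile", class(tibble::tibble()))
  rows
}

#' Rank enzymes by a profiling statistic
#'
#' Stable descending order by the chosen statistic, ties broken by enzyme
#' name; rows with an undefined statistic (NA) are kept last and excluded
#' from the max/min sets. Ties at the extremes are reported as sets via
#' the `is_max`/`is_min` flags, mirroring how profiling studies list
#' several co-minimal proteases.
#'
#' @param profiles An `activity_profile` tibble sharing one protein and
#'   one activity.
#' @param key One of `"A"`, `"A_E"`, `"W"`, `"B"`, `"V"`, `"dh_t"`.
#' @return The profiles reordered, with logical columns `is_max` and
#'   `is_min`.
#' @export
rank_enzymes <- function(profiles, key = c("A_E", "A", "W", "B", "V",
                                           "dh_t")) {
  key <- match.arg(key)
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    rlang::abort("`profiles` must be a non-empty profile tibble.")
  }
  if (dplyr::n_distinct(profiles$protein_id) > 1 ||
      dplyr::n_distinct(profiles$activity) > 1) {
    rlang::abort("rank_enzymes() expects one protein and one activity.")
  }
  v <- profiles[[key]]
  ord <- order(-xtfrm(v), profiles$enzyme, na.last = TRUE)
  out <- profiles[ord, ]
  vv <- out[[key]]
  finite <- !is.na(vv)
  out$is_max <- finite & vv == suppressWarnings(max(vv, na.rm = TRUE))
  out$is_min <- finite & vv == suppressWarnings(min(vv, na.rm = TRUE))
  if (!any(finite)) {
    out$is_max <- FALSE
    out$is_min <- FALSE
  }
  class(out) <- c("activity_profile", class(tibble::tibble()))
  out
}

#' Summarise an activity profile by activity class
#'
#' One row per (protein, activity): the enzyme count and the maxima of
#' the release statistics across enzymes.
#'
#' @param x An `activity_profile` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.activity_profile <- function(x, ...) {
  x |>
    dplyr::group_by(.data$protein_id, .data$activity) |>
    dplyr::summarise(
      n_enzymes = dplyr::n(),
      A = max(.data$A, na.rm = FALSE),
      max_A_E = suppressWarnings(max(.data$A_E, na.rm = TRUE)),
      max_W = suppressWarnings(max(.data$W, na.rm = TRUE)),
      max_V = suppressWarnings(max(.data$V, na.rm = TRUE)),
      .groups = "drop"
    )
}
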