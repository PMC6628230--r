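# Brute-force reference implementations.
#
# These internal routines recompute matching, cleavage and the profiling
# statistics with plain per-position loops and direct window inspection.
# They deliberately share no code with the production paths (vectorised
# clause engine, stringi matching) and exist as the independent route in
# dual-route tests and for generating the worked-example expectations.

# All start positions (1-based) where `peptide` occurs in `residues`,
# overlaps included, by checking every window explicitly.
naive_match_positions <- function(residues, peptide) {
  n <- nchar(residues)
  m <- nchar(peptide)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - m + 1L)) {
    if (substr(residues, s, s + m - 1L) == peptide) hits <- c(hits, s)
  }
  hits
}

# Cut sites of a compiled rule by evaluating every bond's full context
# window one position at a time.
naive_cut_sites <- function(residues, rule) {
  stopifnot(inherits(rule, "cleavage_rule"))
  n <- nchar(residues)
  if (n < 2) return(integer(0))
  at <- function(idx) {
    if (idx < 1 || idx > n) "-" else substr(residues, idx, idx)
  }
  sites <- integer(0)
  for (i in seq_len(n - 1L)) {
    bond_cut <- FALSE
    for (clause in rule$clauses) {
      ok <- TRUE
      for (pos in names(clause$require)) {
        r <- at(i + POSITION_OFFSETS[[pos]])
        if (!(r %in% clause$require[[pos]])) { ok <- FALSE; break }
      }
      if (ok) {
        for (pos in names(clause$block)) {
          r <- at(i + POSITION_OFFSETS[[pos]])
          if (r %in% clause$block[[pos]]) { ok <- FALSE; break }
        }
      }
      if (ok) { bond_cut <- TRUE; break }
    }
    if (bond_cut) sites <- c(sites, i)
  }
  sites
}

# Fragments between consecutive cut sites.
naive_fragments <- function(residues, sites) {
  n <- nchar(residues)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  vapply(seq_along(starts),
         function(k) substr(residues, starts[k], ends[k]),
         character(1))
}

# Full profile row for one (protein, activity, rule) by first principles.
naive_profile <- function(residues, db, activity, rule, total_bonds = NULL) {
  act <- stringr::str_squish(tolower(activity))
  sub <- db[stringr::str_squish(tolower(db$activity)) == act, , drop = FALSE]
  n <- nchar(residues)
  sites <- naive_cut_sites(residues, rule)
  frags <- naive_fragments(residues, sites)
  D <- if (is.null(total_bonds)) n - 1L else total_bonds
  if (nrow(sub) == 0) {
    return(list(a = 0L, d = 0L, A = NA_real_, A_E = NA_real_, W = NA_real_,
                B = NA_real_, B_E = NA_real_, V = NA_real_,
                dh_t = 100 * length(sites) / D, calculable = FALSE))
  }
  a_i <- integer(nrow(sub))
  d_i <- integer(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    a_i[r] <- length(naive_match_positions(residues, sub$sequence[r]))
    d_i[r] <- sum(frags == sub$sequence[r])
  }
  a <- sum(a_i); d <- sum(d_i)
  A <- a / n; A_E <- d / n
  ec50 <- as.numeric(sub$ec50_um)
  keep <- !is.na(ec50)
  B <- if (any(keep)) sum(a_i[keep] / ec50[keep]) / n else 0
  B_E <- if (any(keep)) sum(d_i[keep] / ec50[keep]) / n else 0
  list(
    a = a, d = d, A = A, A_E = A_E,
    W = if (A > 0) A_E / A else NA_real_,
    B = B, B_E = B_E,
    V = if (B > 0) B_E / B else NA_real_,
    dh_t = 100 * length(sites) / D, calculable = TRUE
  )
}
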