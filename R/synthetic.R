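# Seeded synthetic data: protein backgrounds, planted peptides, peptide
# databases, and a fully hand-checkable worked example. Everything is
# deterministic under a seed and leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

MAX_SAMPLING_ATTEMPTS <- 10000L

forbidden_sequences <- function(forbidden) {
  if (is.null(forbidden)) return(character(0))
  if (is.data.frame(forbidden)) return(unique(forbidden$sequence))
  unique(stringr::str_to_upper(as.character(forbidden)))
}

#' Generate a random protein background
#'
#' Draws residues i.i.d. from the given frequencies, then removes any
#' occurrence of the forbidden peptides by resampling just the violating
#' windows (not the whole chain), bounded at 10000 rounds. The result is a
#' clean background into which known peptides can be planted with
#' [plant_peptides()] so that their occurrence count is exact by
#' construction.
#'
#' @param length Chain length `N` (>= 2).
#' @param freqs Named numeric vector of residue frequencies over the
#'   standard alphabet (default uniform). Normalised internally.
#' @param forbidden A `peptide_db` or character vector of peptides that
#'   must not occur (all shorter than `length`).
#' @param seed Integer seed; identical seeds give identical chains.
#' @param id Record id for the returned protein tibble.
#' @return A one-row protein tibble.
#' @export
#' @examples
#' gen_background(50, forbidden = "WW", seed = 7)
gen_background <- function(length, freqs = NULL, forbidden = NULL,
                           seed = NULL, id = "synthetic_background") {
  stopifnot(length >= 2)
  if (is.null(freqs)) {
    freqs <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (is.null(names(freqs)) || !all(names(freqs) %in% AA_STANDARD)) {
    rlang::abort("`freqs` must be named with standard residue codes.")
  }
  freqs <- freqs / sum(freqs)
  avoid <- forbidden_sequences(forbidden)
  if (any(nchar(avoid) >= length)) {
    rlang::abort("forbidden peptides must be shorter than the chain.")
  }
  with_seed(seed, {
    chars <- sample(names(freqs), length, replace = TRUE, prob = freqs)
    if (length(avoid)) {
      violating <- function(chars) {
        s <- paste(chars, collapse = "")
        loc <- stringi::stri_locate_all_fixed(s, avoid, overlap = TRUE)
        hits <- integer(0)
        for (k in seq_along(loc)) {
          m <- loc[[k]]
          if (!is.na(m[1, 1])) {
            hits <- c(hits, unlist(lapply(m[, 1], function(x)
              seq(x, x + nchar(avoid[k]) - 1L))))
          }
        }
        unique(hits)
      }
      best <- Inf
      stalled <- 0L
      for (attempt in seq_len(MAX_SAMPLING_ATTEMPTS)) {
        hits <- violating(chars)
        if (length(hits) == 0) break
        # pathological sets (e.g. all dipeptides) never shrink the
        # violation set; give up once resampling stops making progress
        if (length(hits) < best) {
          best <- length(hits)
          stalled <- 0L
        } else {
          stalled <- stalled + 1L
        }
        if (stalled >= 200L || attempt == MAX_SAMPLING_ATTEMPTS) {
          rlang::abort(paste0(
            "could not build a background avoiding the forbidden peptides; ",
            "use a longer alphabet, fewer/shorter forbidden peptides, ",
            "or a longer chain."
          ))
        }
        chars[hits] <- sample(names(freqs), length(hits), replace = TRUE,
                              prob = freqs)
      }
    }
    protein_tbl(id, paste(chars, collapse = ""))
  })
}

#' Plant exact copies of a peptide into a clean background
#'
#' Overwrites `k` non-overlapping windows with the peptide, then verifies
#' post-hoc that the total occurrence count in the result is exactly `k`
#' (splicing can create accidental extra matches across window borders;
#' the placement is re-drawn when that happens).
#'
#' @param background A one-row protein tibble whose chain contains no
#'   occurrence of `peptide`.
#' @param peptide Peptide to plant (standard residues, length >= 1).
#' @param k Number of copies (0 returns the background unchanged).
#' @param seed Integer seed for the placement draw.
#' @param positions Optional explicit 1-based start positions (must be
#'   non-overlapping); overrides the random draw.
#' @return A list with `seq` (the modified protein tibble) and `positions`
#'   (sorted start positions of the planted copies).
#' @export
plant_peptides <- function(background, peptide, k, seed = NULL,
                           positions = NULL) {
  p <- resolve_protein(background)
  peptide <- stringr::str_to_upper(peptide)
  m <- nchar(peptide)
  stopifnot(m >= 1, k >= 0)
  if (k == 0) return(list(seq = background, positions = integer(0)))
  if (k * m > p$n) {
    rlang::abort("cannot place k copies: k * length(peptide) exceeds N.")
  }
  if (length(naive_match_positions(p$residues, peptide)) > 0) {
    rlang::abort("background already contains the peptide; use a clean one.")
  }
  place <- function(pos) {
    chars <- residue_chars(p$residues)
    for (s in pos) {
      chars[seq(s, s + m - 1L)] <- residue_chars(peptide)
    }
    paste(chars, collapse = "")
  }
  if (!is.null(positions)) {
    positions <- sort(as.integer(positions))
    stopifnot(length(positions) == k, all(positions >= 1),
              all(positions + m - 1L <= p$n))
    if (any(diff(positions) < m)) {
      rlang::abort("explicit positions overlap.")
    }
    out <- place(positions)
    if (length(naive_match_positions(out, peptide)) != k) {
      rlang::abort("these positions splice extra copies; choose others.")
    }
    return(list(seq = protein_tbl(p$id, out), positions = positions))
  }
  with_seed(seed, {
    for (attempt in seq_len(MAX_SAMPLING_ATTEMPTS)) {
      cand <- sort(sample(seq_len(p$n - m + 1L), k))
      if (k > 1 && any(diff(cand) < m)) next
      out <- place(cand)
      if (length(naive_match_positions(out, peptide)) == k) {
        return(list(seq = protein_tbl(p$id, out), positions = cand))
      }
    }
    rlang::abort("could not place the copies without splice artifacts.")
  })
}

#' Generate a synthetic activity-annotated peptide database
#'
#' Random peptides with lengths drawn uniformly in `length_range`,
#' activities cycled over `activities`, and EC50 values (µM) drawn
#' lognormal for a `ec50_coverage` fraction of records. (sequence,
#' activity) pairs are unique by construction.
#'
#' @param n_records Number of records (>= 1).
#' @param length_range Integer range of peptide lengths, default `c(2, 4)`.
#' @param activities Character vector of activity labels.
#' @param ec50_meanlog,ec50_sdlog Lognormal parameters on the log-µM scale
#'   (defaults meanlog 2, sdlog 1.5: median ~7 µM with a long right tail,
#'   the shape typical of inhibitory-peptide EC50 collections).
#' @param ec50_coverage Fraction of records carrying an EC50 in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `peptide_db` tibble (version tag records the seed).
#' @export
gen_peptide_db <- function(n_records, length_range = c(2L, 4L),
                           activities = c("ACE inhibitor",
                                          "dipeptidyl peptidase IV inhibitor"),
                           ec50_meanlog = 2, ec50_sdlog = 1.5,
                           ec50_coverage = 0.5, seed = NULL) {
  stopifnot(n_records >= 1, length(activities) >= 1)
  if (is.na(ec50_coverage) || ec50_coverage < 0 || ec50_coverage > 1) {
    rlang::abort("`ec50_coverage` must be in [0, 1].")
  }
  with_seed(seed, {
    act <- rep_len(activities, n_records)
    seqs <- character(0)
    seen <- character(0)
    while (length(seqs) < n_records) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      s <- paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
      key <- paste(s, act[length(seqs) + 1L])
      if (!key %in% seen) {
        seqs <- c(seqs, s)
        seen <- c(seen, key)
      }
    }
    n_ec50 <- round(ec50_coverage * n_records)
    has_ec50 <- rep(FALSE, n_records)
    if (n_ec50 > 0) has_ec50[sample(n_records, n_ec50)] <- TRUE
    ec50 <- rep(NA_real_, n_records)
    ec50[has_ec50] <- stats::rlnorm(n_ec50, ec50_meanlog, ec50_sdlog)
    peptide_db(
      tibble::tibble(
        sequence = seqs,
        activity = act,
        ec50_um = ec50,
        source_id = paste0("SYN", sprintf("%04d", seq_len(n_records)))
      ),
      version_tag = paste0("synthetic-seed-", seed %||% "none")
    )
  })
}

#' Typical RubisCO large-chain residue frequencies
#'
#' Approximate amino-acid composition of plant RubisCO large subunits,
#' usable as `freqs` in [gen_background()] to generate realistic
#' RubisCO-like backgrounds instead of uniform ones.
#'
#' @return Named numeric vector over the 20 standard residues (sums to 1).
#' @export
rbcl_residue_freqs <- function() {
  f <- c(
    A = 0.087, C = 0.009, D = 0.051, E = 0.062, F = 0.042,
    G = 0.089, H = 0.028, I = 0.045, K = 0.058, L = 0.088,
    M = 0.023, N = 0.038, P = 0.048, Q = 0.031, R = 0.055,
    S = 0.046, T = 0.058, V = 0.069, W = 0.017, Y = 0.056
  )
  f / sum(f)
}

#' The packaged synthetic RubisCO-like reference fragment
#'
#' A fixed 200-residue chain generated once from typical plant RubisCO
#' large-chain amino-acid composition at a fixed seed and committed with
#' the package. It is a synthetic stand-in, not a database sequence; it
#' exists so the full pipeline (33-protease rule file, bundled miniature
#' peptide database) can run end-to-end offline on a realistic input.
#'
#' @return A one-row protein tibble (N = 200).
#' @export
synthetic_rubisco_standin <- function() {
  read_fasta(system.file("extdata", "synthetic_H6TQS9_standin.fasta",
                         package = "pepsilico"))
}

#' A tiny fully hand-checkable worked example
#'
#' A fixed 40-residue chain, a six-record database over three activity
#' classes (one with EC50 annotations so V is defined, one without so
#' B = 0 and V is absent), and two proteases (one cutting nothing, giving
#' a DH_t = 0 row). The expected profile rows are computed at call time by
#' the independent brute-force reference implementation, never by the
#' production pipeline, so comparing the two is a genuine dual-route
#' check.
#'
#' @return A list with `seq` (protein tibble), `db` (`peptide_db`),
#'   `rules` (named list of [cleavage_rule()]), and `expected`
#'   (tibble of profile rows in [build_profile()] column order).
#' @export
make_worked_example <- function() {
  # tryptic fragments by design:
  # MGPR | VWK | AHIKPPGK | GPGVK | VWK | TIPPEDFR | NQSTVWGPG
  seq <- protein_tbl(
    "toy40",
    "MGPRVWKAHIKPPGKGPGVKVWKTIPPEDFRNQSTVWGPG",
    description = "synthetic worked example"
  )
  db <- peptide_db(
    tibble::tibble(
      sequence = c("VWK", "IPP", "KP", "GP", "PG", "AH"),
      activity = c("ACE inhibitor", "ACE inhibitor", "ACE inhibitor",
                   "dipeptidyl peptidase IV inhibitor",
                   "dipeptidyl peptidase IV inhibitor",
                   "antioxidative"),
      ec50_um = c(2, 5, NA, NA, NA, 12.5),
      source_id = paste0("WE", 1:6)
    ),
    version_tag = "worked-example-1"
  )
  rules <- list(
    Tryptic = cleavage_rule(
      "Tryptic", list(p1 = c("K", "R"), block = list("P1'" = "P"))),
    PostC = cleavage_rule("PostC", list(p1 = "C"))
  )
  expected <- purrr::map(db_activities(db), function(act) {
    purrr::map(rules, function(r) {
      e <- naive_profile(seq$residues, db, act, r)
      tibble::tibble(
        protein_id = seq$id, activity = act, enzyme = r$enzyme_name,
        n_residues = seq$n_residues,
        a = e$a, d = e$d, A = e$A, A_E = e$A_E, W = e$W,
        B = e$B, B_E = e$B_E, V = e$V, dh_t = e$dh_t,
        calculable = e$calculable
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  list(seq = seq, db = db, rules = rules, expected = expected)
}
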