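# Shared constants and small numeric helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes used for strict sequence
#' validation and for matching against the peptide database.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Ambiguity/non-standard codes tolerated in permissive mode. They count
# towards chain length N but can never take part in a peptide match or
# satisfy a cleavage clause.
AA_PERMISSIVE_EXTRA <- c("X", "B", "Z", "U")

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.00005 -> 0.0001), matching the
#' convention used when rendering profile tables. `round()` in R rounds
#' half to even, which would print 0.149950 as 0.1499 rather than 0.1500.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 4).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.149991, 4) # 0.1500
round_half_up <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# Format a statistic for table rendering: NA -> "-", else fixed decimals.
format_stat <- function(x, digits = 4) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  out[is.na(x)] <- "-"
  out
}

# Split a residue string into single characters.
residue_chars <- function(residues) {
  if (!nzchar(residues)) return(character(0))
  stringr::str_split(residues, "")[[1]]
}

# Validate that a scalar is a single non-empty string.
check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    rlang::abort(paste0("`", what, "` must be a single non-empty string."))
  }
  invisible(x)
}
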