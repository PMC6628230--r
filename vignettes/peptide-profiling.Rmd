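---
title: "In silico bioactive peptide profiling: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico bioactive peptide profiling: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsilico)
```

## The model

`pepsilico` treats in-silico proteolysis as a deterministic, complete
digestion: a protease is a set of clauses over the residues flanking each
peptide bond, and every bond satisfying any clause is hydrolyzed. For a
chain of `N` residues there are `N - 1` bonds; bond `i` (1-based) joins
residues `i` and `i + 1`, with the protease nomenclature `P4..P1` on the
N-terminal side (`P1` = residue `i`) and `P1'..P4'` on the C-terminal
side. Fragments are the maximal runs between consecutive cuts, so their
concatenation always reproduces the chain — an invariant the test suite
checks on every randomized instance. Digestion by several enzymes at once
is modelled as the union of their cut sites (simultaneous action); a bond
matched by several clauses is still one cut. Sequential digestion,
missed-cleavage enumeration and kinetic/partial hydrolysis are out of
scope: pH and condition variants enter only as distinct named rule sets
(e.g. "Pepsin" vs "Pepsin (pH > 2)").

Matching against the peptide database happens on two routes:

* **Occurrence** (`count_occurrences()`): every position at which a
  database peptide occurs in the intact chain, overlaps included, each
  record counted independently — a dipeptide inside a matched tripeptide
  counts for both records. This is the only convention under which
  `A = a/N` is well defined per record set; services differ here, so
  `count_overlaps = FALSE` switches to non-overlapping counting.
* **Release** (`count_released()`): a peptide is released only when a
  digestion fragment equals it *exactly*. Containment is not release —
  a fragment that merely contains an active peptide would need further
  hydrolysis to act.

From the totals `a` and `d` the statistics follow their definitions:
`A = a/N`, `A_E = d/N`, `W = A_E/A`, `B = (1/N) Σ aᵢ/EC₅₀ᵢ` (µM⁻¹, over
EC50-annotated records only), `B_E` likewise with `dᵢ`, `V = B_E/B`, and
`DH_t = 100·d_bonds/D`. Release is a subset of occurrence
(`dᵢ ≤ aᵢ`), so `A_E ≤ A`, `B_E ≤ B`, `W ∈ [0, 1]` and `V ∈ [0, 1]`
whenever defined.

## Conventions and degenerate inputs

* **Undefined vs zero.** `W` is `NA` only when `A = 0` (nothing encrypted
  to release); if `A > 0` but the protease liberates nothing, `W = 0`.
  `V` is `NA` only when `B = 0`, which happens exactly when no matching
  record carries an EC50. Rendered tables print `-` for `NA`. An activity
  with no database records at all yields a row flagged
  `calculable = FALSE` and is omitted from rendered tables.
* **Rounding.** Rendered tables round half away from zero at 4 decimals
  (`round_half_up()`); base `round()` rounds half to even, which would
  print 0.14999… · 4dp as 0.1499 where profiling tables conventionally
  print 0.1500. Full precision is kept internally and in the JSON output.
* **Coordinates.** 1-based inclusive, the R/Bioconductor idiom; cut site
  `i` is the bond after residue `i`. (A 0-based half-open convention
  encodes the same arithmetic; 1-based was chosen to match IRanges-style
  expectations of R users.)
* **Chain length.** `N` is taken verbatim from the record, fragments
  included — a fragment flag changes no downstream arithmetic. `DH_t`'s
  denominator `D` defaults to `N - 1`, the bond count of a linear chain,
  but is exposed (`total_bonds`) because published tables sometimes imply
  a different denominator (see Limits).
* **Degenerate chains.** A single-residue chain has no bonds: digestion
  returns one fragment and `theoretical_dh()` refuses the zero
  denominator. Strict validation rejects any residue outside the 20
  standard codes, naming every offending position; permissive mode keeps
  X/B/Z/U, which count toward `N` but can never match a database peptide
  (databases are standard-alphabet only) nor satisfy a clause.
* **Ranking ties.** `rank_enzymes()` orders descending by the chosen
  statistic with lexicographic enzyme-name tie-break, and reports the
  extremes as *sets* (`is_max`/`is_min`), since profiling studies
  routinely list several co-minimal proteases. `NA` rows sort last and
  join neither set.

## The rule file

Specificity rules are data (`inst/extdata/protease_rules.yaml`,
versioned): per enzyme, clauses with required and blocked residues at
positions `P4..P4'`, plus the pseudo-residue `"-"` meaning "beyond the
chain terminus" — which is how a strict dipeptidase (Xaa-Pro dipeptidase)
is expressed: it requires both `P2` and `P2'` to lie outside the chain,
so it can only ever cut a free dipeptide. The shipped file covers 33
proteases authored from public PeptideCutter/BIOPEP-style conventions;
for sparsely documented food-science enzymes (V-protease, proteinase P1
/ lactocepin, ginger protease, endopeptidase II) the closest literature
description was used. These are documented approximations: profiling
web services do not publish their exact internal rule sets, so
bond-level agreement with any given service is not guaranteed, and all
correctness tests therefore use synthetic rules whose behaviour is fully
specified here.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable offline
with known ground truth:

* `gen_background(length, freqs, forbidden, seed)` draws residues i.i.d.
  (uniform by default; `rbcl_residue_freqs()` gives a realistic RubisCO
  large-chain composition) and removes occurrences of forbidden peptides
  by resampling only the violating windows, bounded at 10,000 rounds with
  stall detection for impossible sets (e.g. all 400 dipeptides).
* `plant_peptides()` overwrites `k` non-overlapping windows and verifies
  post hoc that the occurrence count is exactly `k` — splicing can create
  accidental extra copies across window borders, in which case the
  placement is re-drawn. This makes `A = k/N` exact by construction.
* `gen_peptide_db()` draws EC50s lognormal on the µM scale (defaults
  meanlog 2, sdlog 1.5: median ≈ 7 µM with a long right tail, the shape
  typical of inhibitory-peptide EC50 collections) for a configurable
  coverage fraction; coverage 0 forces `B = 0` everywhere, mirroring
  activity classes whose records carry no potency annotation.

Everything is bit-reproducible under a seed and leaves the caller's RNG
state untouched. What the generator does *not* emulate: residue
autocorrelation and domain structure of real proteins, homology between
database peptides and the chain, and any correlation between peptide
sequence and EC50. Passing tests on synthetic data therefore demonstrate
the correctness of the counting and algebra, not the biological
representativeness of any particular profile.

The committed reference input
(`inst/extdata/synthetic_H6TQS9_standin.fasta`) is a synthetic
200-residue chain generated once from the RubisCO composition at a fixed
seed (42) — a labelled stand-in for a real RubisCO large-chain fragment,
used so the 33-protease rule file and the bundled nine-activity database
can exercise the full pipeline offline.

## Verification strategy

Two independent routes are kept throughout. The production code uses a
vectorised clause engine and `stringi` fixed-pattern search; the
reference implementation (`R/naive-oracle.R`) re-derives cut sites,
match positions and every statistic with plain per-position loops and
shares no code with the production path. The worked example
(`make_worked_example()`: N = 40, six records, three activities, one
zero-cutting enzyme) has its expectations computed by the reference
route, and its rendered tables are committed as golden files. The test
suite runs the dual-route comparison on 220 seeded random instances
(chains of 10–60 residues, databases of up to 12 peptides, randomized
context-window rules), plus the invariant suite (fragment concatenation,
`A_E ≤ A`, `W·A = A_E`, `V ∈ [0,1]`, `DH_t ∈ [0,100]`, union
monotonicity) and exact planted-copy recovery. These sizes keep the
default test run in tens of seconds while covering every clause-engine
code path (terminal tokens, blockers, multi-clause disjunction).

## Known limits

* **Absolute profile values are database-bound.** `A`, `A_E`, `B`, `V`
  for a real protein depend on the exact snapshot of the peptide
  database used — public collections grow continuously — and the bundled
  miniature database is a labelled synthetic emulation, not a snapshot.
  What *is* reproducible from published tables alone are the internal
  identities: feeding published `(A, A_E)` pairs through
  `compute_frequencies()` reproduces the published `W` at 4-decimal
  rounding, which the acceptance checks do for six published pairs.
* **DH_t depends on the rule set and a denominator convention.**
  Published DH_t tables for a 200-residue fragment are consistent with
  an integer cut count over 205 bonds rather than 199; the package does
  not guess at the discrepancy but exposes `total_bonds`. With the
  shipped rules on the packaged stand-in, the restrictive-specificity
  zero class (thrombin, endopeptidase II, Xaa-Pro dipeptidase, chymosin)
  reproduces DH_t = 0 robustly; value-level agreement for permissive
  enzymes (e.g. pepsin at pH > 2) additionally requires the service's
  exact unpublished rule set and the real sequence, and is not achieved
  by the authored approximations — the acceptance suite states this
  expectation faithfully and records the discrepancy rather than hiding
  it. Ginger protease (zingipain), authored with the literature
  P2-proline convention, cuts a Pro-containing chain and so does not
  reproduce a published zero; a narrower rule would be unsupported
  speculation.
* **Enzyme-independent A.** `A` depends only on the protein and the
  database, so the package reports one `A` per (protein, activity) on
  every enzyme row; small per-protease variation of `A` seen in some
  published tables is a reporting artifact of the originating service
  and is deliberately not emulated.
* **No kinetics.** Complete digestion at every matching bond is an
  idealisation; real hydrolysates contain missed cleavages and
  intermediate fragments, so in-vitro release is bounded above by the
  in-silico prediction.
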