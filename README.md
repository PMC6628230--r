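# pepsilico

In-silico profiling of bioactive peptides encrypted in a protein chain.

Food and plant proteins — RubisCO large chains, caseins, muscle proteins —
carry short "encrypted" peptides that become physiologically active
(ACE-inhibitory, DPP-IV-inhibitory, antioxidative, ...) once a protease
liberates them. `pepsilico` simulates that process end to end: it digests a
protein with declarative protease-specificity rules, matches both the
intact chain and the released fragments against an activity-annotated
peptide database, and computes the standard profiling statistics used in
BIOPEP-style screening studies.

For a chain of *N* residues and one activity class:

- **A = a / N** — frequency of occurrence: *a* counts every occurrence of
  every database peptide of that activity in the intact chain (overlaps
  included, each record counted independently).
- **A_E = d / N** — frequency of release: *d* counts the digestion
  fragments that equal a database peptide exactly.
- **W = A_E / A** — the fraction of the encrypted potential a protease
  actually liberates (undefined when A = 0).
- **B = (1/N) Σᵢ aᵢ / EC₅₀ᵢ** (µM⁻¹) — EC50-weighted potential activity
  over the records that carry an EC50; **B_E** is the released analogue
  and **V = B_E / B** the released share (undefined when B = 0).
- **DH_t = 100 · d_bonds / D** (%) — theoretical degree of hydrolysis:
  hydrolyzed peptide bonds over total bonds (*D* defaults to N − 1 and is
  configurable).

Cleavage rules are data, not code: a YAML file gives each protease one or
more clauses over the P4…P4′ context window (required residues, blocked
residues, chain-terminus tokens). The package ships a versioned rule file
for 33 named proteases authored from public PeptideCutter/BIOPEP-style
conventions, a miniature synthetic peptide database spanning nine activity
classes, and a seeded synthetic-data generator (clean backgrounds, planted
peptide copies, lognormal EC50s) so every stage is testable offline. A
committed synthetic 200-residue RubisCO-like fragment
(`inst/extdata/synthetic_H6TQS9_standin.fasta`, composition-matched
stand-in, not a database sequence) serves as the default realistic input.

## Worked example

The package carries a 40-residue fully hand-checkable example: six
database records over three activities, a tryptic protease and one that
cuts nothing.

```r
library(pepsilico)

we <- make_worked_example()
prof <- profile_protein(we$seq, we$db, we$rules)
cat(render_activity_table(dplyr::filter(prof, activity == "ace inhibitor")),
    sep = "\n")
#> Proteases	A	AE	W	B	V
#> Tryptic	0.1000	0.0500	0.5000	0.0300	0.8333
#> PostC	0.1000	0.0000	0.0000	0.0300	0.0000
```

Reading the tryptic row: the chain holds 4 ACE-inhibitor occurrences
(A = 4/40 = 0.1000); tryptic digestion liberates 2 of them as exact
fragments (A_E = 0.0500), i.e. half of the encrypted potential
(W = 0.5000); weighting occurrences by 1/EC50 gives B = 0.0300 µM⁻¹ of
which 83.33 % (V) sits in released fragments. The inert protease releases
nothing: A_E = W = 0, V = 0, and its DH_t row is 0.

```r
d <- digest_protein(we$seq, we$rules$Tryptic)
glance(d)
#> # A tibble: 1 × 7
#>   protein_id enzyme  n_residues n_fragments d_bonds total_bonds  dh_t
#>   <chr>      <chr>        <int>       <int>   <int>       <int> <dbl>
#> 1 toy40      Tryptic         40           7       6          39  15.4
```

The full pipeline over a FASTA file, a database CSV and a rule file —
writing one table per activity, a DH_t table, JSON profiles and a run
log — is one call (`run_profile(fasta, db, rules, out_dir = "results")`),
also exposed as a thin command-line wrapper in `inst/cli/pepsilico.R`
(subcommands `profile`, `digest`, `synth`, `validate-db`).

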