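Package: pepsilico
Title: In Silico Profiling of Bioactive Peptides Released by Proteolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in-silico screening of bioactive peptides encrypted in
    food and plant proteins. Digests a protein chain with declarative protease
    specificity rules (P1/P1' residues plus positional context), matches the
    intact chain and the released fragments against an activity-annotated
    peptide database, and computes the standard peptide-profiling statistics:
    frequency of occurrence (A), frequency of release (A_E), relative release
    (W), EC50-weighted potential activity (B) and its released share (V), and
    the theoretical degree of hydrolysis (DH_t). Includes a seeded synthetic
    data generator (random protein backgrounds with planted peptides,
    databases with lognormal EC50 values), publication-style table rendering, and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
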