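# Shared test fixtures, all built in code.

trypsin_rule <- function() {
  cleavage_rule("Trypsin", list(p1 = c("K", "R"), block = list("P1'" = "P")))
}

cut_all_rule <- function() {
  cleavage_rule("CutAll", list(p1 = AA_STANDARD))
}

no_cut_rule <- function(name = "Inert") {
  # requires a residue at P1 that can never follow itself in the test seqs
  cleavage_rule(name, list(p1 = "C", p1prime = "C"))
}

random_residues <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# A random clause engine stress rule: 1-2 clauses with random require/block
# positions over the full P4..P4' window.
random_rule <- function(name = "Rnd") {
  positions <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")
  mk_clause <- function() {
    req_pos <- unique(c("P1", sample(positions, sample(0:2, 1))))
    req <- lapply(req_pos, function(p) sample(AA_STANDARD, sample(2:8, 1)))
    names(req) <- req_pos
    blk_pos <- sample(setdiff(positions, req_pos), sample(0:2, 1))
    blk <- lapply(blk_pos, function(p) sample(c(AA_STANDARD, "-"),
                                              sample(1:4, 1)))
    names(blk) <- blk_pos
    if (length(blk)) list(require = req, block = blk) else
      list(require = req)
  }
  cleavage_rule(name, replicate(sample(1:2, 1), mk_clause(),
                                simplify = FALSE))
}

random_db <- function(n_peptides, activities = c("a1", "a2")) {
  seqs <- unique(replicate(n_peptides, random_residues(sample(2:4, 1))))
  peptide_db(data.frame(
    sequence = seqs,
    activity = sample(activities, length(seqs), replace = TRUE),
    ec50_um = ifelse(runif(length(seqs)) < 0.5,
                     round(runif(length(seqs), 0.5, 50), 2), NA)
  ))
}

# Published ACE-inhibitor release frequencies (per-protease A_E) used as a
# ranking fixture.
ace_release_tbl <- function() {
  tibble::tibble(
    protein_id = "rubisco",
    activity = "ace inhibitor",
    enzyme = c(
      "Chymotrypsin A", "Trypsin", "Pepsin", "Proteinase K",
      "Pancreatic elastase", "V-protease", "Thermolysin",
      "Chymotrypsin C", "Plasmin", "Cathepsin G", "Chymase", "Papain",
      "Ficin", "Leukocyte elastase", "Metridin", "Pancreatic elastase II",
      "Bromelain", "Oligopeptidase B", "Calpain 2",
      "Glycyl endopeptidase", "Oligopeptidase F",
      "Proteinase P1 (lactocepin)", "Pepsin (pH > 2)", "Coccolysin",
      "Subtilisin", "V-8 protease (Glutamyl endopeptidase)"
    ),
    A_E = c(
      0.0485, 0.0097, 0.0194, 0.0777, 0.0437, 0.0049, 0.0777, 0.0631,
      0.0097, 0.0388, 0.0388, 0.0631, 0.0680, 0.0485, 0.0388, 0.0194,
      0.0340, 0.0097, 0.0874, 0.0049, 0.0194, 0.0243, 0.0777, 0.0680,
      0.0534, 0.0049
    )
  )
}
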