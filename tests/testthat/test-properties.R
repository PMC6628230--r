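# Property-style invariants under a fixed seed: the production matcher and
# clause engine against the independent brute-force reference, and the
# algebraic identities tying the statistics together.

test_that("clause engine equals brute-force context evaluation", {
  set.seed(401)
  for (i in 1:60) {
    s <- random_residues(sample(2:50, 1))
    rule <- random_rule()
    expect_identical(find_cut_sites(s, rule),
                     as.integer(pepsilico:::naive_cut_sites(s, rule)))
  }
})

test_that("fragments always tile the chain and unions are monotone", {
  set.seed(402)
  for (i in 1:40) {
    s <- random_residues(sample(2:60, 1))
    r1 <- random_rule("R1")
    r2 <- random_rule("R2")
    d1 <- digest_protein(s, r1)
    d12 <- digest_protein(s, list(r1, r2))
    expect_equal(paste(d1$fragments$sequence, collapse = ""), s)
    expect_equal(paste(d12$fragments$sequence, collapse = ""), s)
    expect_equal(d1$d_bonds, length(d1$cut_sites))
    expect_equal(nrow(d1$fragments), d1$d_bonds + 1)
    # simultaneous digestion never removes cuts
    expect_gte(d12$d_bonds, d1$d_bonds)
    expect_true(all(d1$cut_sites %in% d12$cut_sites))
    dh <- theoretical_dh(d12)
    expect_gte(dh, 0)
    expect_lte(dh, 100)
  }
  expect_equal(theoretical_dh(digest_protein(random_residues(30),
                                             cut_all_rule())), 100)
})

test_that("production match counts equal the all-substrings scan", {
  set.seed(403)
  for (i in 1:60) {
    s <- random_residues(sample(10:60, 1))
    db <- random_db(sample(1:12, 1))
    occ <- count_occurrences(s, db)
    rel <- count_released(digest_protein(s, random_rule()), db)
    for (r in seq_len(nrow(db))) {
      expect_identical(
        occ$positions[[r]],
        as.integer(pepsilico:::naive_match_positions(s, db$sequence[r]))
      )
    }
    expect_true(all(rel$d_i <= occ$a_i))
  }
})

test_that("profile identities hold on random instances", {
  set.seed(404)
  for (i in 1:30) {
    s <- random_residues(sample(20:60, 1))
    db <- random_db(sample(2:10, 1))
    act <- sample(db_activities(db), 1)
    prof <- build_profile(s, db, act, random_rule())
    n <- prof$n_residues
    expect_equal(prof$A * n, round(prof$A * n), tolerance = 1e-9)
    expect_equal(prof$A_E * n, round(prof$A_E * n), tolerance = 1e-9)
    expect_lte(prof$A_E, prof$A)
    if (!is.na(prof$W)) expect_equal(prof$W * prof$A, prof$A_E)
    if (!is.na(prof$V)) {
      expect_gte(prof$V, 0)
      expect_lte(prof$V, 1)
    }
    expect_lte(prof$B_E, prof$B + 1e-15)
  }
})

test_that("planted-copy recovery gives A = k/N and A_E = j/N exactly", {
  # j of the k copies are preceded by G; cutting after G and after W
  # liberates exactly those j as "VW" fragments
  release_rule <- cleavage_rule("PostGW", list(p1 = c("G", "W")))
  for (k in c(1, 3, 5)) {
    for (j in 0:k) {
      body <- paste0(c(rep("GVW", j), rep("AVW", k - j), "HH"),
                     collapse = "")
      db <- peptide_db(data.frame(sequence = "VW", activity = "x"))
      n <- nchar(body)
      prof <- build_profile(body, db, "x", release_rule)
      expect_equal(prof$a, k)
      expect_equal(prof$A, k / n)
      expect_equal(prof$d, j)
      expect_equal(prof$A_E, j / n)
    }
  }
  # and with randomly planted copies in a clean background
  bg <- gen_background(90, forbidden = "VW", seed = 31)
  pl <- plant_peptides(bg, "VW", k = 4, seed = 32)
  db <- peptide_db(data.frame(sequence = "VW", activity = "x"))
  prof <- build_profile(pl$seq, db, "x", no_cut_rule())
  expect_equal(prof$A, 4 / 90)
  expect_equal(prof$A_E, 0)
})

test_that("potency ignores records without EC50", {
  set.seed(405)
  s <- random_residues(50)
  db_full <- random_db(8, activities = "x")
  db_annotated <- peptide_db(as.data.frame(db_full[!is.na(db_full$ec50_um), ]))
  if (nrow(db_annotated) > 0) {
    rule <- random_rule()
    b_full <- build_profile(s, db_full, "x", rule)$B
    b_ann <- build_profile(s, db_annotated, "x", rule)$B
    expect_equal(b_full, b_ann)
  }
})
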