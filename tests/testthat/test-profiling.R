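test_that("occurrence counting includes overlaps and counts per record", {
  db <- peptide_db(data.frame(sequence = "GP", activity = "x"))
  occ <- count_occurrences("GPAGP", db)
  expect_equal(occ$positions[[1]], c(1L, 4L))
  expect_equal(occ$a_i, 2L)

  # overlapping occurrences of the same peptide
  aa <- peptide_db(data.frame(sequence = "AA", activity = "x"))
  expect_equal(count_occurrences("AAAA", aa)$a_i, 3L)
  expect_equal(count_occurrences("AAAA", aa, count_overlaps = FALSE)$a_i, 2L)

  # nested records both count
  nested <- peptide_db(data.frame(sequence = c("VW", "VWK"),
                                  activity = "x"))
  expect_equal(count_occurrences("AVWKA", nested)$a_i, c(1L, 1L))

  empty <- filter_by_activity(db, "absent")
  expect_equal(nrow(count_occurrences("GPAGP", empty)), 0)
})

test_that("release counting is exact fragment equality with multiplicity", {
  db <- peptide_db(data.frame(sequence = c("AAK", "VW"), activity = "x"))
  d <- digest_protein("AAKAAKP", trypsin_rule())
  rel <- count_released(d, db)
  expect_equal(rel$d_i, c(1L, 0L))

  frags <- tibble::tibble(sequence = c("VW", "AAK", "VW"))
  expect_equal(count_released(frags, db)$d_i, c(1L, 2L))

  # peptide present in the chain but never liberated
  gp <- peptide_db(data.frame(sequence = "KA", activity = "x"))
  expect_equal(count_released(d, gp)$d_i, 0L)
  expect_equal(count_occurrences("AAKAAKP", gp)$a_i, 1L)
})

test_that("frequency and potency formulas match their definitions", {
  f <- compute_frequencies(a = 6, d = 3, n = 40)
  expect_equal(f$A, 0.15)
  expect_equal(f$A_E, 0.075)
  expect_equal(f$W, 0.5)
  expect_true(is.na(compute_frequencies(0, 0, 10)$W))
  expect_equal(compute_frequencies(4, 0, 10)$W, 0)
  expect_error(compute_frequencies(1, 2, 10), "exceed")

  m <- tibble::tibble(sequence = "VW", a_i = 2L, ec50_um = 5)
  r <- tibble::tibble(sequence = "VW", d_i = 2L, ec50_um = 5)
  pot <- compute_potencies(m, r, n = 10)
  expect_equal(pot$B, 0.04)
  expect_equal(pot$V, 1)

  none <- tibble::tibble(sequence = "VW", a_i = 2L, ec50_um = NA_real_)
  pot0 <- compute_potencies(none, dplyr::mutate(none, d_i = 0L), n = 10)
  expect_equal(pot0$B, 0)
  expect_true(is.na(pot0$V))
})

test_that("amino-acid composition fractions sum to one", {
  comp <- aa_composition("AAKK")
  expect_equal(comp$fraction[comp$residue == "A"], 0.5)
  expect_equal(comp$fraction[comp$residue == "K"], 0.5)
  expect_equal(aa_composition("M")$fraction, 1)
  standin <- synthetic_rubisco_standin()
  expect_equal(sum(aa_composition(standin)$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(aa_composition(standin)$count), 200L)
})

test_that("profiles flag activities absent from the database", {
  we <- make_worked_example()
  row <- build_profile(we$seq, we$db, "opioid", we$rules$Tryptic)
  expect_false(row$calculable)
  expect_equal(row$a, 0L)
  expect_true(is.na(row$A))
  expect_gt(row$dh_t, 0)
})

test_that("enzyme ranking reports extremes as sets with name tie-breaks", {
  tbl <- ace_release_tbl()
  ranked <- rank_enzymes(tbl, key = "A_E")
  expect_equal(ranked$enzyme[1], "Calpain 2")
  expect_equal(ranked$A_E[1], 0.0874)
  expect_equal(ranked$enzyme[ranked$is_max], "Calpain 2")
  expect_setequal(
    ranked$enzyme[ranked$is_min],
    c("Glycyl endopeptidase", "V-protease",
      "V-8 protease (Glutamyl endopeptidase)")
  )
  expect_equal(ranked$A_E[ranked$is_min], rep(0.0049, 3))
  # ties ordered lexicographically
  mins <- ranked$enzyme[ranked$is_min]
  expect_equal(mins, sort(mins))

  single <- rank_enzymes(tbl[1, ], key = "A_E")
  expect_true(single$is_max && single$is_min)
  expect_error(rank_enzymes(tbl[0, ]), "non-empty")
})
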