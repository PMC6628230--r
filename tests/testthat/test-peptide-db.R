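test_that("database loading validates records and collapses duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sequence,activity,ec50_um,source_id",
    "VW,ACE inhibitor,1.6,S1",
    "IPP,ACE inhibitor,,S2",
    "LY,antioxidative,12,S3"
  ), path)
  db <- read_peptide_db(path)
  expect_equal(nrow(db), 3)
  expect_equal(sum(is.na(db$ec50_um)), 1)
  expect_equal(db_version(db), basename(path))

  expect_warning(
    dup <- peptide_db(data.frame(
      sequence = c("VW", "VW"), activity = "ACE inhibitor",
      ec50_um = c(1.6, 1.6))),
    "duplicate"
  )
  expect_equal(nrow(dup), 1)

  expect_error(
    peptide_db(data.frame(sequence = "VW", activity = "x", ec50_um = -1)),
    "row\\(s\\): 1"
  )
  expect_error(peptide_db(data.frame(sequence = "VW")), "activity")
  expect_error(peptide_db(data.frame(sequence = "V1W", activity = "x")),
               "invalid peptide")
})

test_that("activity filtering is an exact-label partition of the records", {
  db <- peptide_db(data.frame(
    sequence = c("VW", "IPP", "LY"),
    activity = c("ACE inhibitor", "ace  inhibitor", "antioxidative"),
    ec50_um = c(1.6, 5, NA)
  ))
  ace <- filter_by_activity(db, "ACE Inhibitor")
  expect_equal(nrow(ace), 2)
  expect_equal(ace$ec50_um, c(1.6, 5))
  expect_equal(nrow(filter_by_activity(db, "no such label")), 0)

  sizes <- vapply(db_activities(db),
                  function(a) nrow(filter_by_activity(db, a)), integer(1))
  expect_equal(sum(sizes), nrow(db))
})

test_that("the health report gives per-activity EC50 coverage", {
  db <- data.frame(
    sequence = c("VW", "IPP", "GG1", "LY"),
    activity = c("ACE inhibitor", "ACE inhibitor", "ACE inhibitor",
                 "antioxidative"),
    ec50_um = c(1.6, NA, NA, NA)
  )
  rep <- validate_db(db)
  ace <- rep$per_activity[rep$per_activity$activity == "ace inhibitor", ]
  expect_equal(ace$n_records, 3)
  expect_equal(ace$n_with_ec50, 1)
  anti <- rep$per_activity[rep$per_activity$activity == "antioxidative", ]
  expect_equal(anti$ec50_coverage, 0)
  expect_equal(rep$invalid_sequences$sequence, "GG1")
})

test_that("CSV and JSON serialisation round-trip records and version tag", {
  db <- peptide_db(data.frame(
    sequence = c("VW", "IPP", "LY"),
    activity = c("ACE inhibitor", "ACE inhibitor", "antioxidative"),
    ec50_um = c(1.6, NA, 12)
  ), version_tag = "rt-1")
  for (ext in c(".csv", ".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_peptide_db(db, path)
    back <- read_peptide_db(path, version_tag = "rt-1")
    expect_equal(as.data.frame(back), as.data.frame(db), ignore_attr = TRUE)
    expect_equal(db_version(back), "rt-1")
  }
  # JSON embeds the tag itself
  path <- withr::local_tempfile(fileext = ".json")
  write_peptide_db(db, path)
  expect_equal(db_version(read_peptide_db(path)), "rt-1")
})

test_that("the bundled miniature database covers nine activity classes", {
  db <- read_peptide_db(system.file("extdata", "synthetic_peptide_db.csv",
                                    package = "pepsilico"))
  expect_length(db_activities(db), 9)
  cov <- validate_db(db)$per_activity
  expect_true(cov$ec50_coverage[cov$activity == "ace inhibitor"] > 0)
  expect_true(any(cov$ec50_coverage == 0))
})
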