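test_that("table rendering rounds half-up and prints '-' for absent values", {
  prof <- tibble::tibble(
    protein_id = "p", activity = "x", enzyme = c("E1", "E2"),
    n_residues = 40L, a = c(3L, 3L), d = c(2L, 0L),
    A = c(0.075, 0.075), A_E = c(0.05, 0), W = c(0.149991, 0),
    B = c(0, 0), B_E = c(0, 0), V = c(NA_real_, NA_real_),
    dh_t = c(16.6667, 0), calculable = TRUE
  )
  lines <- render_activity_table(prof)
  expect_equal(lines[1], "Proteases\tA\tAE\tW\tB\tV")
  # rounding is half-up at 4 decimals; absent V renders "-"
  expect_equal(lines[2], "E1\t0.0750\t0.0500\t0.1500\t0.0000\t-")
  expect_match(lines[3], "\t-$")

  dh <- render_dh_table(prof)
  expect_equal(dh[1], "Proteases\tDHt")
  expect_equal(dh[2], "E1\t16.6667")

  none <- dplyr::mutate(prof, calculable = FALSE)
  expect_warning(out <- render_activity_table(none), "nothing to render")
  expect_length(out, 0)
  expect_error(render_activity_table(dplyr::mutate(prof,
                                                   activity = c("x", "y"))),
               "one activity")
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.149991, 4), 0.1500)
  expect_equal(round_half_up(0.00005, 4), 0.0001)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.00005, 4), -0.0001)
  expect_equal(round_half_up(70.73170, 4), 70.7317)
})

test_that("run_profile writes stable reports that round-trip", {
  we_dir <- system.file("extdata", "worked_example", package = "pepsilico")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res1 <- run_profile(
    fasta = file.path(we_dir, "protein.fasta"),
    db = file.path(we_dir, "peptides.csv"),
    rules = file.path(we_dir, "rules.yaml"),
    out_dir = out1
  )
  res2 <- run_profile(
    fasta = file.path(we_dir, "protein.fasta"),
    db = file.path(we_dir, "peptides.csv"),
    rules = file.path(we_dir, "rules.yaml"),
    out_dir = out2
  )
  # byte-identical reruns
  for (f in basename(res1$files)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # JSON round-trips through the reader
  back <- read_profiles_json(file.path(out1, "profiles.json"))
  expect_equal(as.data.frame(back), as.data.frame(res1$profiles),
               ignore_attr = TRUE)

  # activity selection restricts the emitted tables
  out3 <- withr::local_tempdir()
  res3 <- run_profile(
    fasta = file.path(we_dir, "protein.fasta"),
    db = file.path(we_dir, "peptides.csv"),
    rules = file.path(we_dir, "rules.yaml"),
    out_dir = out3, activities = "ACE inhibitor"
  )
  expect_length(grep("^table_", basename(res3$files)), 2) # activity + DH_t
  expect_error(
    run_profile(
      fasta = file.path(we_dir, "protein.fasta"),
      db = file.path(we_dir, "peptides.csv"),
      rules = file.path(we_dir, "rules.yaml"),
      out_dir = withr::local_tempdir(), enzymes = "Nonexistase"
    ),
    "available"
  )
})

test_that("plot builders return ggplot objects", {
  we <- make_worked_example()
  prof <- profile_protein(we$seq, we$db, we$rules)
  expect_s3_class(autoplot(prof, statistic = "A"), "ggplot")
  d <- digest_protein(we$seq, we$rules$Tryptic)
  expect_s3_class(autoplot(d), "ggplot")
})

test_that("the command-line wrapper ships with the package", {
  cli <- system.file("cli", "pepsilico.R", package = "pepsilico")
  expect_true(nzchar(cli))
  expect_match(readLines(cli, n = 2)[1], "Rscript")
})
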