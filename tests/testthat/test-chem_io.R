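test_that("SMILES parsing yields normalized records with explicit hydrogens", {
  m <- parse_smiles("Nc1ccccc1")[[1]]
  expect_s3_class(m, "amine_mol")
  expect_true(is.na(m$error))
  expect_equal(sum(m$atoms$element != "H"), 7)
  expect_equal(sum(m$atoms$element == "H"), 7)
  expect_true(all(m$atoms$charge == 0))
  expect_equal(sum(m$atoms$aromatic), 6)

  tol <- parse_smiles("Cc1ccccc1N", id = "otol")[[1]]
  expect_equal(tol$id, "otol")
  expect_equal(sum(tol$atoms$element != "H"), 8)
})

test_that("malformed entries become error records, the run continues", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("Nc1ccccc1 aniline", "not_a_smiles bad", "Cc1ccccc1N otol"), f)
  mols <- parse_structures(f, "smiles")
  expect_length(mols, 3)
  expect_true(is.na(mols[[1]]$error))
  expect_equal(mols[[2]]$error, "parse error")
  expect_true(is.na(mols[[3]]$error))
  expect_equal(vapply(mols, `[[`, "", "id"), c("aniline", "bad", "otol"))
})

test_that("empty input gives an empty list with a warning", {
  f <- tempfile(fileext = ".smi")
  writeLines(character(0), f)
  expect_warning(mols <- parse_structures(f, "smiles"), "empty")
  expect_length(mols, 0)
})

test_that("salts are stripped to the largest organic fragment", {
  salt <- parse_smiles("Nc1ccccc1.Cl")[[1]]
  free <- parse_smiles("Nc1ccccc1")[[1]]
  expect_equal(salt$n_fragments_stripped, 1L)
  expect_equal(salt$smiles, free$smiles)
  expect_equal(nrow(salt$atoms), nrow(free$atoms))
})

test_that("parsing round-trips structure identity for the reference panel", {
  for (smi in reference_set()$smiles) {
    m1 <- parse_smiles(smi)[[1]]
    expect_true(is.na(m1$error), info = smi)
    m2 <- parse_smiles(m1$smiles)[[1]]
    expect_equal(m1$smiles, m2$smiles, info = smi)
    expect_equal(nrow(m1$atoms), nrow(m2$atoms), info = smi)
    expect_equal(sort(m1$atoms$charge), sort(m2$atoms$charge), info = smi)
  }
})

test_that("SDF input is read entry by entry", {
  f <- tempfile(fileext = ".sdf")
  sdf <- nitrenium:::.ob_run(c("-ismi", "-osdf", "-h"),
                             input = c("Nc1ccccc1", "Cc1ccccc1N"))
  writeLines(sdf, f)
  mols <- parse_structures(f, "sdf")
  expect_length(mols, 2)
  expect_equal(sum(mols[[1]]$atoms$element != "H"), 7)
  expect_equal(sum(mols[[2]]$atoms$element != "H"), 8)
})

test_that("the CSV report uses the closed remark vocabulary and one decimal", {
  rows <- tibble::tibble(
    id = c("aniline", "x", "y"),
    ddE = c(0.04, NA, NA),
    prediction = c("nonmutagenic", "inconclusive", "inconclusive"),
    remark = c("", "NaN", "no aromatic amine"))
  f <- tempfile(fileext = ".csv")
  write_report(rows, f)
  out <- readLines(f)
  expect_equal(out[1], "id,ddE_kcal_per_mol,prediction,remark")
  expect_equal(out[2], "aniline,0.0,nonmutagenic,")
  expect_equal(out[3], "x,,inconclusive,NaN")
  expect_equal(out[4], "y,,inconclusive,no aromatic amine")
  expect_equal(length(out) - 1, nrow(rows))  # no silent drops
})

test_that("report writing validates its input", {
  expect_error(write_report(data.frame(id = 1), tempfile()), "columns")
})
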