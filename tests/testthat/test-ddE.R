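test_that("the sign rule classifies with a nonmutagenic boundary", {
  expect_equal(classify(-5.6), "mutagenic")
  expect_equal(classify(24.1), "nonmutagenic")
  expect_equal(classify(0.0), "nonmutagenic")      # boundary convention
  expect_equal(classify(0.4, cutoff = 2.5), "mutagenic")
  expect_equal(classify(2.5, cutoff = 2.5), "nonmutagenic")
  expect_true(is.na(classify(NA_real_)))
  expect_equal(classify(c(-1, 1)), c("mutagenic", "nonmutagenic"))
})

test_that("ddE is the scripted double difference, exactly", {
  eng <- mock_engine_table(MOCK_TBL)
  ref <- reference_energies(eng)
  expect_equal(ref$E_PhNH2, 20.0)
  expect_equal(ref$E_PhNHplus, 246.0)
  r <- compute_ddE(parse_smiles("Cc1ccccc1N", id = "otol")[[1]], ref, eng)
  # (232 + 20) - (13 + 246) = -7
  expect_equal(r$ddE, -7)
  expect_equal(r$prediction, "mutagenic")
  expect_equal(r$remark, "")
})

test_that("aniline scores exactly zero against its own reference", {
  eng <- mock_engine_table(MOCK_TBL)
  ref <- reference_energies(eng)
  r <- compute_ddE(parse_smiles("Nc1ccccc1", id = "aniline")[[1]], ref, eng)
  expect_identical(r$ddE, 0)
  expect_equal(r$prediction, "nonmutagenic")
})

test_that("the aniline reference is cached per engine fingerprint", {
  eng <- mock_engine_table(MOCK_TBL)
  ref1 <- reference_energies(eng)
  n1 <- eng$calls$n
  ref2 <- reference_energies(eng)
  expect_identical(eng$calls$n, n1)          # second call did no engine work
  expect_identical(ref1, ref2)
  reference_energies(eng, refresh = TRUE)
  expect_gt(eng$calls$n, n1)                 # refresh recomputes
  eng2 <- mock_engine_table(MOCK_TBL)        # new fingerprint, cold cache
  reference_energies(eng2)
  expect_gt(eng2$calls$n, 0)
})

test_that("an engine that stabilizes the cation below the neutral is rejected", {
  eng <- mock_engine_table(list("C6H7N1/0" = 20, "C6H6N1/1" = 10))
  expect_error(reference_energies(eng), "more stable")
})

test_that("failures surface as remarks, never as errors", {
  eng <- mock_engine_table(MOCK_TBL)
  ref <- reference_energies(eng)

  # cation SCF failure -> NaN
  eng_nocat <- mock_engine_table(list("C6H7N1/0" = 20, "C6H6N1/1" = 246,
                                      "C7H9N1/0" = 13))
  ref2 <- reference_energies(eng_nocat)
  r <- compute_ddE(parse_smiles("Cc1ccccc1N")[[1]], ref2, eng_nocat)
  expect_true(is.na(r$ddE))
  expect_equal(r$remark, "NaN")
  expect_equal(r$prediction, "inconclusive")

  # no aromatic amine
  r2 <- compute_ddE(parse_smiles("CCN")[[1]], ref, eng)
  expect_equal(r2$remark, "no aromatic amine")

  # ineligible (two amine sites)
  r3 <- compute_ddE(parse_smiles("Nc1ccc(N)cc1")[[1]], ref, eng)
  expect_equal(r3$remark, "ineligible:v")
  expect_true(is.na(r3$ddE))

  # parse error propagates to the row
  r4 <- compute_ddE(parse_smiles("not_a_smiles")[[1]], ref, eng)
  expect_equal(r4$remark, "parse error")
})

test_that("ring opening during optimization is detected and reported", {
  # engine that returns a sane energy but tears one ring bond apart
  breaker <- engine_mock(function(z, xyz, charge) {
    if (charge == 0) return(list(hf = 20, xyz = xyz, converged = TRUE))
    bad <- xyz
    bad[2, ] <- bad[2, ] + c(5, 0, 0)
    list(hf = 240, xyz = bad, converged = TRUE)
  }, fingerprint = "mock-breaker")
  # reference with a well-behaved engine, scoring with the breaker
  eng <- mock_engine_table(MOCK_TBL)
  ref <- reference_energies(eng)
  r <- compute_ddE(parse_smiles("Cc1ccccc1N")[[1]], ref, breaker)
  expect_equal(r$remark, "aromatic ring opening")
  expect_equal(r$prediction, "inconclusive")
})

test_that("forcing scores ineligible compounds and keeps the failure visible", {
  tbl <- c(MOCK_TBL, list("C6H8N2/0" = 30, "C6H7N2/1" = 250))
  eng <- mock_engine_table(tbl)
  ref <- reference_energies(eng)
  r <- compute_ddE(parse_smiles("Nc1ccc(N)cc1")[[1]], ref, eng, force = TRUE)
  expect_equal(r$ddE, (250 + 20) - (30 + 246))
  expect_equal(r$remark, "ineligible:v")
})

test_that("the optional equivocal band labels borderline scores", {
  eng <- mock_engine_table(MOCK_TBL)
  ref <- reference_energies(eng)
  r <- compute_ddE(parse_smiles("Cc1ccccc1N")[[1]], ref, eng,
                   equivocal_band = 10)
  expect_equal(r$prediction, "equivocal")   # |-7| < 10
  r2 <- compute_ddE(parse_smiles("Cc1ccccc1N")[[1]], ref, eng,
                    equivocal_band = 5)
  expect_equal(r2$prediction, "mutagenic")
})

test_that("predict_ddE returns one row per input and a tidy summary", {
  eng <- mock_engine_table(MOCK_TBL)
  res <- predict_ddE(c("Nc1ccccc1", "Cc1ccccc1N", "bad_smiles", "CCN"),
                     engine = eng)
  expect_s3_class(res, "ddE_tbl")
  expect_equal(nrow(res), 4)
  expect_equal(res$prediction,
               c("nonmutagenic", "mutagenic", "inconclusive", "inconclusive"))
  g <- glance(res)
  expect_equal(g$n, 4)
  expect_equal(g$n_scored, 2)
  expect_equal(g$coverage, 50)
  # data-frame input with ids
  res2 <- predict_ddE(data.frame(smiles = "Nc1ccccc1", id = "ani"),
                      engine = eng)
  expect_equal(res2$id, "ani")
})
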