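mol <- function(smi) parse_smiles(smi)[[1]]

test_that("primary aromatic amine sites match the substructure definition", {
  cases <- list(
    list("Nc1ccccc1", 1),          # aniline: the defining case
    list("CNc1ccccc1", 0),         # N-methylaniline: secondary amine
    list("Nc1ccc(N)cc1", 2),       # benzene-1,4-diamine: two sites
    list("NC1CCCCC1", 0),          # cyclohexylamine: no aromatic carbon
    list("NCc1ccccc1", 0),         # benzylamine: carbon is not aromatic
    list("Nc1ccc(cc1)S(N)(=O)=O", 1)  # sulfanilamide: SO2NH2 N excluded
  )
  for (cs in cases) {
    expect_equal(nrow(find_primary_aromatic_amines(mol(cs[[1]]))), cs[[2]],
                 info = cs[[1]])
  }
  s <- find_primary_aromatic_amines(mol("Nc1ccccc1"))
  m <- mol("Nc1ccccc1")
  expect_equal(m$atoms$element[s$n_idx], "N")
  expect_true(m$atoms$aromatic[s$c_idx])
})

test_that("each eligibility criterion is detected, and all failures reported", {
  expect_true(check_eligibility(mol("Nc1ccccc1"))$eligible)

  nitro <- check_eligibility(mol("Nc1ccc(cc1)[N+](=O)[O-]"))
  expect_equal(nitro$failed_criteria[[1]], "vi")
  nitro2 <- check_eligibility(mol("Nc1ccc(cc1)N(=O)=O"))
  expect_equal(nitro2$failed_criteria[[1]], "vi")

  ppd <- check_eligibility(mol("Nc1ccc(N)cc1"))
  expect_equal(ppd$failed_criteria[[1]], "v")
  expect_equal(ppd$n_amine_sites, 2)

  anilinium <- check_eligibility(mol("[NH3+]c1ccccc1"))
  expect_true("i" %in% anilinium$failed_criteria[[1]])

  # long alkyl chain: heavy and floppy; both ii and iv must be reported
  big <- check_eligibility(mol(paste0("Nc1ccc(cc1)", strrep("C", 32))))
  expect_true(big$mw >= 500)
  expect_setequal(big$failed_criteria[[1]], c("ii", "iv"))

  two_sc <- check_eligibility(mol("FC(Cl)C(F)(Cl)Br"))
  expect_equal(two_sc$n_stereocenters, 2)
  expect_true("iii" %in% two_sc$failed_criteria[[1]])

  one_sc <- check_eligibility(mol("CC(O)c1ccc(N)cc1"))
  expect_equal(one_sc$n_stereocenters, 1)
  expect_false("iii" %in% one_sc$failed_criteria[[1]])
})

test_that("rotatable bonds follow the stated convention", {
  expect_equal(check_eligibility(mol("Nc1ccccc1"))$n_rotatable, 0L)
  # acetanilide: the amide C-N bond is excluded, the N-ring bond counts
  expect_equal(check_eligibility(mol("CC(=O)Nc1ccccc1"))$n_rotatable, 1L)
  # butylbenzene: ring-C1, C1-C2, C2-C3 (terminal CH3 bond excluded)
  expect_equal(check_eligibility(mol("CCCCc1ccccc1"))$n_rotatable, 3L)
})

test_that("eligibility is idempotent and order-independent", {
  m <- mol("Cc1ccccc1N")
  r1 <- check_eligibility(m)
  r2 <- check_eligibility(m)
  expect_identical(r1, r2)
})

test_that("all 23 reference panel compounds are eligible", {
  for (smi in reference_set()$smiles) {
    e <- check_eligibility(mol(smi))
    expect_true(e$eligible, info = smi)
    expect_equal(e$n_amine_sites, 1, info = smi)
  }
})
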