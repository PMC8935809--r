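test_that("rigid molecules collapse to a singleton ensemble", {
  ens <- enumerate_conformers(parse_smiles("Nc1ccccc1")[[1]])
  expect_s3_class(ens, "conf_ensemble")
  expect_length(ens$xyz, 1)   # amine pyramidalization variants deduplicate
  expect_equal(nrow(ens$xyz[[1]]), 14)  # C6H7N with explicit hydrogens
  expect_equal(nrow(ens$mol3d$atoms), 14)
})

test_that("flexible molecules give a windowed, sorted, deduplicated ensemble", {
  ens <- enumerate_conformers(parse_smiles("CCCCc1ccc(N)cc1")[[1]])
  expect_gte(length(ens$xyz), 3)
  expect_equal(ens$energies, sort(ens$energies))
  expect_true(all(ens$energies - ens$energies[1] <= ens$window + 1e-9))
  heavy <- ens$mol3d$atoms$element != "H"
  r <- nitrenium:::.kabsch_rmsd(ens$xyz[[1]][heavy, ], ens$xyz[[2]][heavy, ])
  expect_gte(r, 0.4)   # members are mutually distinct
})

test_that("the ensemble is bit-identical across runs with the same seed", {
  m <- parse_smiles("COc1ccc(N)cc1")[[1]]
  e1 <- enumerate_conformers(m, seed = 20220321)
  e2 <- enumerate_conformers(m, seed = 20220321)
  expect_identical(e1$energies, e2$energies)
  expect_identical(e1$xyz, e2$xyz)
})

test_that("the search minimum is robust to the embedding seed", {
  m <- parse_smiles("CCCCc1ccc(N)cc1")[[1]]
  e1 <- enumerate_conformers(m, seed = 1)
  e2 <- enumerate_conformers(m, seed = 2)
  expect_lt(abs(e1$energies[1] - e2$energies[1]), 1.0)
})

test_that("for near-rigid molecules the selected AM1 energy is seed-insensitive", {
  eng <- engine_am1()
  m <- parse_smiles("Cc1ccccc1N")[[1]]   # one (methyl) rotatable unit only
  hfs <- vapply(c(11, 22), function(s) {
    ens <- enumerate_conformers(m, seed = s)
    low <- select_lowest(ens)
    optimize_species(eng, ens$mol3d$atoms$z, low$xyz, 0)$hf
  }, numeric(1))
  expect_lt(abs(hfs[1] - hfs[2]), 0.1)
})

test_that("select_lowest picks the minimum and breaks ties by generation order", {
  fake <- structure(list(mol3d = NULL,
                         xyz = list("a", "b", "c"),
                         energies = c(3.1, 0.0, 1.2),
                         window = 7, seed = 1), class = "conf_ensemble")
  expect_equal(select_lowest(fake)$index, 2)
  fake$energies <- c(5.5)
  fake$xyz <- list("only")
  expect_equal(select_lowest(fake)$index, 1)
  fake$energies <- c(1.0, 1.0 + 1e-9, 2.0)
  fake$xyz <- list("a", "b", "c")
  expect_equal(select_lowest(fake)$index, 1)
})

test_that("unembeddable input raises the dedicated condition", {
  m <- parse_smiles("Nc1ccccc1")[[1]]
  m$smiles <- "this_is_not_a_smiles"
  expect_error(enumerate_conformers(m), class = "nitrenium_embed_error")
})
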