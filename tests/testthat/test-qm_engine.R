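# The bundled engine is checked against published AM1 heats of formation
# (the independent reference for an AM1 implementation) and against the
# symmetries any quantum-chemical energy must obey.

embed <- function(smi) {
  ens <- enumerate_conformers(parse_smiles(smi)[[1]])
  list(z = ens$mol3d$atoms$z, xyz = ens$xyz[[1]], mol3d = ens$mol3d)
}

test_that("optimized heats of formation match published AM1 values", {
  eng <- engine_am1()
  cases <- list(                      # literature AM1 heats of formation
    list("C", -8.79, 0.2),            # methane
    list("N", -7.3, 0.2),             # ammonia
    list("O", -59.24, 0.2),           # water
    list("c1ccccc1", 22.0, 0.5)       # benzene
  )
  for (cs in cases) {
    m <- embed(cs[[1]])
    r <- optimize_species(eng, m$z, m$xyz, 0)
    expect_true(r$converged, info = cs[[1]])
    expect_lt(abs(r$hf - cs[[2]]), cs[[3]])
  }
})

test_that("the energy is invariant to translation, rotation, and atom order", {
  m <- embed("Cc1ccccc1N")
  e0 <- .am1_energy(m$z, m$xyz, 0)$hf
  # translation
  e1 <- .am1_energy(m$z, m$xyz + matrix(c(3.1, -1.7, 0.9),
                                        nrow(m$xyz), 3, byrow = TRUE), 0)$hf
  expect_lt(abs(e1 - e0), 1e-4)
  # rotation
  th <- 0.7; rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                          c(0, 0, 1))
  e2 <- .am1_energy(m$z, m$xyz %*% rot, 0)$hf
  expect_lt(abs(e2 - e0), 1e-4)
  # atom permutation
  p <- rev(seq_along(m$z))
  e3 <- .am1_energy(m$z[p], m$xyz[p, ], 0)$hf
  expect_lt(abs(e3 - e0), 1e-4)
})

test_that("removing an amine hydrogen at +1 charge costs ionization-scale energy", {
  eng <- engine_am1()
  m <- embed("Nc1ccccc1")
  rn <- optimize_species(eng, m$z, m$xyz, 0)
  site <- find_primary_aromatic_amines(m$mol3d)
  cand <- build_nitrenium_candidates(m$mol3d, rn$xyz, site)[[1]]
  rc <- optimize_species(eng, cand$z, cand$xyz, 1)
  expect_true(rn$converged && rc$converged)
  expect_gt(rc$hf - rn$hf, 150)   # cation formation is strongly endothermic
})

test_that("engine failures are reported, not thrown", {
  eng <- engine_am1()
  r <- optimize_species(eng, c(53L, 1L), rbind(c(0, 0, 0), c(1.6, 0, 0)), 0)
  expect_false(r$converged)       # iodine is outside the parameter set
  expect_true(is.na(r$hf))
})

test_that("ring integrity is judged from re-perceived connectivity", {
  eng <- engine_am1()
  m <- embed("c1ccccc1")
  r <- optimize_species(eng, m$z, m$xyz, 0)
  expect_true(check_ring_integrity(m$mol3d, r$xyz))
  # stretch one aromatic ring bond to 2.8 angstrom
  b <- m$mol3d$bonds
  arb <- b[b$aromatic & b$in_ring, ][1, ]
  bad <- r$xyz
  dir <- bad[arb$j, ] - bad[arb$i, ]
  bad[arb$j, ] <- bad[arb$i, ] + dir / sqrt(sum(dir^2)) * 2.8
  expect_false(check_ring_integrity(m$mol3d, bad))
  # acyclic molecules pass vacuously
  m2 <- embed("CCN")
  expect_true(check_ring_integrity(m2$mol3d, m2$xyz * 3))
})

test_that("the mock adapter makes downstream modules testable without QM", {
  eng <- engine_mock(function(z, xyz, charge) 42.0)
  r <- optimize_species(eng, c(6L, 1L), rbind(c(0, 0, 0), c(1.1, 0, 0)), 0)
  expect_equal(r$hf, 42)
  expect_true(r$converged)
  eng2 <- engine_mock(function(z, xyz, charge) NA_real_)
  expect_false(optimize_species(eng2, 6L, rbind(c(0, 0, 0)), 0)$converged)
})

test_that("MOPAC decks are written and outputs parsed (adapter contract)", {
  deck <- write_mopac_deck(c(7L, 1L, 1L, 1L),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(0, 0, 1)), charge = 1)
  expect_match(deck[1], "^AM1 SINGLET CHARGE=\\+1")
  expect_length(deck, 3 + 4)
  expect_match(deck[4], "^N\\s+0\\.0+\\s+1\\s")

  out <- c(" some banner",
           "          FINAL HEAT OF FORMATION =         -8.78963 KCAL/MOL",
           "", "          CARTESIAN COORDINATES", "",
           "     1    C        0.000000    0.000000    0.000000",
           "     2    H        1.100000    0.000000    0.000000",
           "", " DONE")
  p <- parse_mopac_output(out)
  expect_true(p$converged)
  expect_equal(p$hf, -8.78963)
  expect_equal(dim(p$xyz), c(2, 3))

  bad <- c("garbled", "UNABLE TO ACHIEVE SELF-CONSISTENCE", "no result")
  expect_false(parse_mopac_output(bad)$converged)
  expect_false(parse_mopac_output("")$converged)
})
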