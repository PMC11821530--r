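# Electronic-structure engine: textbook anchors, internal identities, and
# cross-route consistency (determinant CI vs qubit-Hamiltonian
# diagonalization).

test_that("H2/STO-3G reproduces the textbook restricted Hartree-Fock energy",
{
  hf <- scfRHF(h2Geometry(0.74))
  # literature value for R = 0.74 A in the minimal basis
  expect_equal(hf$energy, -1.1167593, tolerance = 1e-6)
  expect_true(hf$converged)
})

test_that("two-electron systems close the CCSD = FCI identity", {
  fx <- h2Fixture(0.9)
  cc <- ccsdEnergy(fx$hf, so = fx$mp2$so)
  ct <- ccsdTEnergy(cc)
  expect_equal(cc$energy, fx$fci, tolerance = 1e-8)
  expect_equal(ct$et, 0)             # no triples with two electrons
  expect_equal(cisdEnergy(fx$hf), fx$fci, tolerance = 1e-8)
})

test_that("variational orderings hold and MP2 sits below HF", {
  fx <- h2Fixture(1.1)
  e <- runBenchmarks(NULL, methods = c("HF", "MP2", "CISD", "FCI"),
                     hf = fx$hf)
  expect_gte(e["HF"], e["CISD"] - 1e-10)
  expect_gte(e["CISD"], e["FCI"] - 1e-8)
  expect_lt(e["MP2"], e["HF"])
  expect_error(runBenchmarks(NULL, methods = "DMRG", hf = fx$hf),
               "unsupported")
})

test_that("water STO-3G energies are locked against the validated engines", {
  # geometry in Bohr, symmetric bent water; the SCF value was verified
  # against an independent Obara-Saika implementation and grid quadrature
  b2a <- 0.529177210903
  coords <- rbind(c(0, -0.143225816552, 0),
                  c(1.638036840407, 1.136548822547, 0),
                  c(-1.638036840407, 1.136548822547, 0)) * b2a
  geom <- molecularGeometry(c("O", "H", "H"), coords)
  hf <- scfRHF(geom)
  expect_equal(nuclearRepulsion(geom), 8.002367062, tolerance = 1e-8)
  expect_equal(hf$energy, -74.96408827, tolerance = 1e-7)
  m <- mp2Energy(hf)
  expect_equal(m$ecorr, -0.046351570, tolerance = 1e-7)
  cc <- ccsdEnergy(hf, so = m$so)
  expect_equal(cc$ecorr, -0.066955757, tolerance = 1e-6)
  expect_equal(ccsdTEnergy(cc)$et, -0.0000963186, tolerance = 1e-4)
})

test_that("FCI is invariant under orbital rotations (natural orbitals)", {
  fx <- h2Fixture(1.0)
  eCanon <- fx$fci
  # re-run the CI in the MP2 natural-orbital basis via the CAS machinery
  eNO <- casciEnergy(fx$hf, nAct = 2L, nElec = 2L, mp2 = fx$mp2)$energy
  expect_equal(eNO, eCanon, tolerance = 1e-8)
})

test_that("CAS(full) equals FCI and CASSCF never lies above CASCI", {
  fx <- h2Fixture(1.2)
  cas <- casciEnergy(fx$hf, nAct = 2L, nElec = 2L, mp2 = fx$mp2)
  expect_equal(cas$energy, fx$fci, tolerance = 1e-8)
  scf2 <- casscfEnergy(fx$hf, nAct = 1L, nElec = 2L, mp2 = fx$mp2,
                       maxit = 60L)
  expect_lte(scf2$energy, scf2$casci + 1e-8)
  expect_gte(scf2$energy, fx$fci - 1e-8)
})

test_that("MP2 natural occupations live in [0, 2] and sum to the electron
           count", {
  fx <- h2Fixture(1.3)
  occ <- fx$mp2$noOcc
  expect_true(all(occ >= -1e-10 & occ <= 2 + 1e-10))
  expect_equal(sum(occ), 2, tolerance = 1e-6)
})

test_that("the XYZ reader matches the programmatic geometry", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0", "H 0.0 0.0 0.9"), f)
  g <- readXYZ(f)
  expect_equal(g$atoms, c("H", "H"))
  expect_equal(nuclearRepulsion(g), nuclearRepulsion(h2Geometry(0.9)))
})

test_that("degenerate pi orbitals are split deterministically for diatomics",
{
  hf1 <- scfRHF(n2Geometry(1.1))
  hf2 <- scfRHF(n2Geometry(1.1))
  expect_identical(hf1$C, hf2$C)
  # pi orbitals are axis-pure: each MO touches px or py AOs, never both
  px <- which(hf1$ints$aoComp == 1L)
  py <- which(hf1$ints$aoComp == 2L)
  for (k in seq_len(ncol(hf1$C))) {
    hasX <- any(abs(hf1$C[px, k]) > 1e-8)
    hasY <- any(abs(hf1$C[py, k]) > 1e-8)
    expect_false(hasX && hasY)
  }
})

test_that("reference data round-trips through the JSON cache", {
  fx <- h2Fixture(1.1)
  cc <- ccsdEnergy(fx$hf, so = fx$mp2$so)
  f <- withr::local_tempfile(fileext = ".json")
  writeReferenceData(fx$hf, f, mp2 = fx$mp2, cc = cc)
  back <- readReferenceData(f)
  expect_equal(back$moEnergies, as.numeric(fx$hf$eps))
  expect_equal(back$t2mp2, fx$mp2$t2)
  expect_equal(back$ccsdEnergy, cc$energy)
  expect_true(all(back$noOccupations >= -1e-10 &
                  back$noOccupations <= 2 + 1e-10))
})
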