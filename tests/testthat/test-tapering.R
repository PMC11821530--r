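# Z2-symmetry tapering: generator discovery, sector fixing, spectral
# preservation.

test_that("single-qubit Z Hamiltonians expose their own symmetry", {
  H <- pauliSum("Z", 1)
  gens <- findSymmetryGenerators(H)
  expect_equal(pauliStrings(gens), "Z")
})

test_that("every generator commutes with every Hamiltonian term", {
  fx <- h2Fixture(0.9)
  gens <- findSymmetryGenerators(fx$qb$H)
  expect_true(all(pauliCommutes(fx$qb$H, gens, outer = TRUE)))
})

test_that("H2 tapers 4 -> 1 with the ground energy preserved", {
  fx <- h2Fixture(0.9)
  expect_equal(nQubits(fx$taper$H), 1L)
  expect_equal(groundEnergyExact(fx$taper$H), fx$fci, tolerance = 1e-8)
  expect_lte(nTerms(fx$taper$H), nTerms(fx$qb$H))
})

test_that("sector spectra of planted-symmetry Hamiltonians tile the full
           spectrum", {
  # build a 4-qubit Hamiltonian commuting with ZZII and IIZZ by symmetrizing
  set.seed(8)
  raw <- randomPauliSum(4, 30, 61)
  gens <- pauliSum(c("ZZII", "IIZZ"), 1)
  keep <- rowSums(pauliCommutes(raw, gens, outer = TRUE)) == 2L
  H <- raw[which(keep)]
  full <- sort(eigen(kronPauliSum(H), symmetric = TRUE)$values)
  pooled <- c()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    rot <- CSVQE:::.stabilizerRotations(gens, values = c(s1, s2))
    Hr <- applyCliffordRotations(H, rot$rotations)
    Hp <- CSVQE:::.projectQubits(Hr, rot$targets, rot$zEigenvalues)
    pooled <- c(pooled, eigen(kronPauliSum(Hp), symmetric = TRUE)$values)
  }
  expect_equal(sort(pooled), full, tolerance = 1e-8)
})

test_that("tapering with zero generators returns the Hamiltonian unchanged",
{
  H <- pauliSum(c("X", "Z"), c(1, 0.5))
  gens <- findSymmetryGenerators(H)
  expect_equal(nTerms(gens), 0L)
  sector <- new("SymmetrySector", generators = gens,
                eigenvalues = numeric(0),
                rotations = pauliSum(nQubits = 1L),
                targetQubits = integer(0))
  expect_equal(nTerms(taperHamiltonian(H, sector) - H), 0L)
})

test_that("non-commuting generators are rejected", {
  H <- pauliSum(c("XX", "ZZ"), c(1, 1))
  badGens <- pauliSum("XI", 1)
  sector <- selectSector(pauliSum("ZZ", 1), c(1L, 0L))
  expect_error(taperHamiltonian(pauliSum("XI", 1), sector),
               "contract violation")
})

test_that("sector eigenvalues follow the reference occupation parity", {
  # single-Z generator: eigenvalue is the plain occupation sign
  secZ <- selectSector(pauliSum("ZIII", 1), c(1L, 1L, 0L, 0L))
  expect_equal(secZ@eigenvalues, -1)
  expect_equal(selectSector(pauliSum("ZIII", 1), rep(0L, 4))@eigenvalues, 1)
  # multi-qubit generator: the stored value is the rotated-frame Z
  # eigenvalue; verify it against the rotated reference statevector
  gens <- pauliSum(c("ZIII", "IZZI"), 1)
  occ <- c(1L, 1L, 0L, 0L)
  sec <- selectSector(gens, occ)
  v <- complex(length.out = 16)
  v[bitsToMask(which(occ == 1L) - 1L) + 1L] <- 1 + 0i
  vr <- CSVQE:::.rotateState(v, sec@rotations)
  for (i in seq_along(sec@targetQubits)) {
    zq <- rep("I", 4L)
    zq[sec@targetQubits[i] + 1L] <- "Z"
    expect_equal(pauliExpectation(pauliSum(paste(zq, collapse = ""), 1), vr),
                 sec@eigenvalues[i], tolerance = 1e-10)
  }
})

test_that("the tapered register hosts the projected reference state", {
  fx <- h2Fixture(0.9)
  ref <- projectedReference(fx$qb$hfOccupation, fx$taper$sector)
  expect_equal(length(ref), 2^nQubits(fx$taper$H))
  e <- pauliExpectation(fx$taper$H, ref)
  expect_equal(e, fx$hf$energy, tolerance = 1e-8)
})
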