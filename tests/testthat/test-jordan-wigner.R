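# Jordan-Wigner mapping: spectral equivalence with determinant CI, the
# trace identity, and excitation-generator structure.

test_that("the qubit Hamiltonian is isospectral with determinant FCI (H2)", {
  fx <- h2Fixture(0.9)
  expect_equal(nQubits(fx$qb$H), 4L)
  expect_equal(groundEnergyExact(fx$qb$H), fx$fci, tolerance = 1e-8)
})

test_that("the Hartree-Fock determinant energy is reproduced on qubits", {
  fx <- h2Fixture(0.9)
  occ <- fx$qb$hfOccupation
  v <- complex(length.out = 2^4)
  v[bitsToMask(which(occ == 1L) - 1L) + 1L] <- 1 + 0i
  expect_equal(pauliExpectation(fx$qb$H, v), fx$hf$energy,
               tolerance = 1e-10)
})

test_that("the identity coefficient equals the trace mean", {
  fx <- h2Fixture(0.8)
  M <- kronPauliSum(fx$qb$H)
  expect_equal(Re(identityCoeff(fx$qb$H)), Re(sum(diag(M))) / nrow(M),
               tolerance = 1e-10)
})

test_that("term count and l1 norm are invariant under rigid motions", {
  hfA <- scfRHF(h2Geometry(0.9))
  HA <- buildQubitHamiltonian(h2Geometry(0.9), hf = hfA)$H
  # same molecule, translated and rotated off-axis
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  base <- rbind(c(0, 0, 0), c(0, 0, 0.9)) %*% t(R)
  geomB <- molecularGeometry(c("H", "H"), sweep(base, 2, c(1, -2, 0.5),
                                                `+`))
  hfB <- scfRHF(geomB)
  HB <- buildQubitHamiltonian(geomB, hf = hfB)$H
  expect_equal(nTerms(HA), nTerms(HB))
  expect_equal(l1Norm(HA), l1Norm(HB), tolerance = 1e-8)
})

test_that("the MP2 excitation generator of H2 is the 8-string double", {
  fx <- h2Fixture(0.9)
  g <- excitationGenerator(fx$hf, "MP2", mp2 = fx$mp2)
  expect_equal(nTerms(g), 8L)
  # anti-Hermitian: purely imaginary coefficients
  expect_true(all(abs(Re(coeffs(g))) < 1e-12))
  M <- kronPauliSum(g)
  expect_lt(max(abs(M + Conj(t(M)))), 1e-10)
})

test_that("zero amplitudes produce an empty generator", {
  fx <- h2Fixture(0.9)
  fake <- list(so = fx$mp2$so, t2 = fx$mp2$t2 * 0)
  g <- excitationGenerator(fx$hf, "MP2", mp2 = fake)
  expect_equal(nTerms(g), 0L)
})

test_that("CCSD guide includes singles and is configurable", {
  fx <- h2Fixture(1.1)
  cc <- ccsdEnergy(fx$hf, so = fx$mp2$so)
  gFull <- excitationGenerator(fx$hf, "CCSD", cc = cc)
  gNoS <- excitationGenerator(fx$hf, "CCSD", cc = cc,
                              includeSingles = FALSE)
  expect_gte(nTerms(gFull), nTerms(gNoS))
})
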