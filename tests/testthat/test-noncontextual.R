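# Noncontextual decomposition and its classical objective.

test_that("both split strategies reconstruct the Hamiltonian exactly", {
  for (s in 1:4) {
    H <- randomPauliSum(4, 14, s + 100)
    for (strat in c("diagonal", "magnitude")) {
      sp <- selectNoncontextual(H, strategy = strat)
      expect_equal(nTerms(sp$Hnc + sp$Hctx - H), 0L)
      if (nTerms(sp$Hnc) > 0L) expect_true(isNoncontextual(sp$Hnc))
    }
  }
})

test_that("the classical objective solves 3X + 4Z exactly", {
  res <- noncontextualEnergy(pauliSum(c("X", "Z"), c(3, 4)),
                             strategy = "magnitude")
  expect_equal(res$energy, -5, tolerance = 1e-12)
  expect_equal(sum(res$model@r^2), 1, tolerance = 1e-12)
})

test_that("anticommuting-clique triples reach the closed-form minimum", {
  res <- noncontextualEnergy(pauliSum(c("X", "Y", "Z"), c(1, 2, 3)),
                             strategy = "magnitude")
  expect_equal(res$energy, -sqrt(14), tolerance = 1e-10)
})

test_that("diagonal Hamiltonians are solved exactly by both strategies", {
  set.seed(5)
  H <- pauliSum(c("ZZI", "ZIZ", "IZZ", "ZII", "IIZ"),
                stats::runif(5, -2, 2))
  exact <- groundEnergyExact(H)
  expect_equal(noncontextualEnergy(H, strategy = "diagonal")$energy, exact,
               tolerance = 1e-10)
  expect_equal(noncontextualEnergy(H, strategy = "magnitude")$energy, exact,
               tolerance = 1e-10)
})

test_that("the magnitude model matches exact diagonalization of Hnc on
           random fixtures", {
  for (s in 1:6) {
    H <- randomPauliSum(4, 12, s)
    sp <- selectNoncontextual(H, strategy = "magnitude")
    mo <- solveNoncontextual(sp)
    eg <- groundEnergyExact(sp$Hnc)
    expect_equal(mo@energy, eg, tolerance = 1e-8)
    # clique representatives pairwise anticommute
    reps <- mo@cliqueReps
    if (nTerms(reps) >= 2L) {
      cm <- pauliCommutes(reps, reps, outer = TRUE)
      diag(cm) <- FALSE
      expect_false(any(cm))
    }
  }
})

test_that("symmetry-element values multiply consistently", {
  H <- randomPauliSum(4, 12, 3)
  mo <- solveNoncontextual(selectNoncontextual(H, strategy = "magnitude"))
  gens <- mo@generators
  k <- nTerms(gens)
  if (k >= 2L) {
    v1 <- symmetryElementValue(mo, gens@x[1L], gens@z[1L])
    v2 <- symmetryElementValue(mo, gens@x[2L], gens@z[2L])
    pr <- pauliProduct(gens[1L], gens[2L], canonical = FALSE)
    v12 <- symmetryElementValue(mo, pr@x[1L], pr@z[1L])
    expect_equal(v12 * Re(pr@coeff[1L]), v1 * v2)
  }
})

test_that("the diagonal model is deterministic and HF-consistent at the
           equilibrium-like geometry", {
  fx <- h2Fixture(0.9)
  mo1 <- solveNoncontextual(selectNoncontextual(fx$taper$H))
  mo2 <- solveNoncontextual(selectNoncontextual(fx$taper$H))
  expect_identical(mo1@q, mo2@q)
  expect_lte(mo1@energy, fx$hf$energy + 1e-10)
})
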