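# Stabilizer selection and subspace projection.

test_that("projection endpoints are exact: full recovery and the classical
           constant", {
  for (s in c(101L, 104L)) {
    H <- randomPauliSum(4, 14, s)
    sp <- selectNoncontextual(H, strategy = "magnitude")
    mo <- solveNoncontextual(sp)
    need <- 4L - nTerms(mo@generators)
    if (need > 1L || length(mo@cliques) == 0L) next
    chF <- selectStabilizers(mo, 4L, H, strategy = "weight",
                             sector = "model")
    prF <- projectToSubspace(H, chF, mo)
    expect_equal(nTerms(prF$H - H), 0L)
    ch0 <- selectStabilizers(mo, 0L, H, strategy = "weight",
                             sector = "model")
    pr0 <- projectToSubspace(H, ch0, mo)
    prNC <- projectToSubspace(sp$Hnc, ch0, mo)
    expect_equal(Re(identityCoeff(prNC$H)), mo@energy, tolerance = 1e-7)
  }
})

test_that("the weight greedy is nested so scores shrink with the subspace",
{
  H <- randomPauliSum(5, 20, 31)
  mo <- solveNoncontextual(selectNoncontextual(H, strategy = "magnitude"))
  guide <- randomPauliSum(5, 15, 32)
  k <- nTerms(mo@generators)
  scores <- c()
  for (nq in 5L:(5L - min(k, 3L))) {
    ch <- selectStabilizers(mo, nq, guide, strategy = "weight",
                            sector = "model")
    scores <- c(scores, ch$score)
  }
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("greedy selection matches exhaustive search on a tiny instance", {
  # diagonal model on 4 qubits, 2-term guide; brute-force over all pairs of
  # independent Z-parity stabilizers
  H <- pauliSum(c("ZIII", "IZII", "IIZI", "IIIZ", "ZZII", "IIZZ"),
                c(0.9, -0.4, 0.3, -0.2, 0.15, 0.1))
  mo <- solveNoncontextual(selectNoncontextual(H, strategy = "diagonal"))
  guide <- pauliSum(c("XXII", "IIYY"), c(0.7i, 0.3i))
  ch <- selectStabilizers(mo, 2L, guide, strategy = "weight",
                          sector = "model")
  best <- -Inf
  for (a in 1:15) for (b in 1:15) {
    if (bitwXor(a, b) == 0L) next
    keep <- vapply(seq_len(nTerms(guide)), function(t) {
      xa <- guide@x[t]
      bitParity(bitwAnd(xa, a)) == 0L && bitParity(bitwAnd(xa, b)) == 0L
    }, logical(1))
    best <- max(best, sum(Mod(coeffs(guide))[keep]))
  }
  expect_equal(ch$score, best, tolerance = 1e-12)
})

test_that("significance selection protects the heaviest excitation space
           and the reference sector hosts the reference state", {
  fx <- h2Fixture(0.9)
  gTap <- taperOperator(excitationGenerator(fx$hf, "MP2", mp2 = fx$mp2),
                        fx$taper$sector)
  mo <- solveNoncontextual(selectNoncontextual(fx$taper$H))
  n <- nQubits(fx$taper$H)
  ch <- selectStabilizers(mo, n, gTap,
                          reference = fx$taper$hfOccupation)
  expect_equal(nTerms(ch$stabilizers), 0L)
  expect_equal(ch$score, l1Norm(gTap), tolerance = 1e-12)
})

test_that("projection replay reproduces the main projection", {
  H <- randomPauliSum(4, 16, 201)
  mo <- solveNoncontextual(selectNoncontextual(H, strategy = "diagonal"))
  guide <- randomPauliSum(4, 8, 202)
  ch <- selectStabilizers(mo, 2L, guide, sector = "model")
  pr <- projectToSubspace(H, ch, mo)
  again <- replayProjection(H, pr$record)
  expect_equal(nTerms(pr$H - again), 0L)
})

test_that("contextual subspaces interpolate between the classical constant
           and FCI for H2", {
  fx <- h2Fixture(1.1)
  gTap <- taperOperator(excitationGenerator(fx$hf, "MP2", mp2 = fx$mp2),
                        fx$taper$sector)
  n <- nQubits(fx$taper$H)    # 1 qubit after tapering
  cs <- contextualSubspace(fx$taper$H, gTap, n,
                           reference = fx$taper$hfOccupation)
  expect_equal(csddEnergy(cs$H), fx$fci, tolerance = 1e-8)
  cs0 <- contextualSubspace(fx$taper$H, gTap, 0L,
                            reference = fx$taper$hfOccupation)
  expect_equal(csddEnergy(cs0$H), fx$hf$energy, tolerance = 1e-8)
})

test_that("general-angle Pauli rotations conjugate exactly", {
  H <- randomPauliSum(3, 10, 77)
  P <- pauliTerm("XYZ")
  th <- 0.37
  Hr <- applyPauliRotation(H, P@x, P@z, th)
  U <- cos(th) * diag(8) + 1i * sin(th) * kronPauli("XYZ")
  dense <- U %*% kronPauliSum(H) %*% Conj(t(U))
  expect_lt(max(abs(kronPauliSum(Hr) - dense)), 1e-10)
})
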