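# QWC grouping, shot estimation, measurement-error mitigation, tiling.

test_that("all-Z Hamiltonians need one group and the 3-term example two", {
  gp1 <- qwcPartition(pauliSum(c("ZI", "IZ", "ZZ"), 1))
  expect_equal(length(gp1$groups), 1L)
  gp2 <- qwcPartition(pauliSum(c("ZI", "IZ", "XX"), 1))
  expect_equal(length(gp2$groups), 2L)
})

test_that("every group is internally qubit-wise commuting", {
  H <- randomPauliSum(4, 25, 55)
  gp <- qwcPartition(H)
  for (g in gp$groups) {
    sub <- H[g]
    cm <- pauliQWCommutes(sub, sub, outer = TRUE)
    expect_true(all(cm))
  }
  expect_equal(sort(unlist(gp$groups)),
               which(!(H@x == 0L & H@z == 0L)))
})

test_that("the shot estimator is unbiased in the infinite-shot limit", {
  set.seed(2)
  H <- randomPauliSum(3, 8, 77)
  circ <- addGate(addGate(quantumCircuit(3), "H", 0), "CNOT", c(0, 1))
  exact <- pauliExpectation(H, applyCircuit(circ))
  est <- estimateEnergy(H, circ, shots = Inf)
  expect_equal(est$energy, exact, tolerance = 1e-10)
  # identity-only Hamiltonian: constant with zero spread
  Hid <- pauliSum("III", 2.5)
  estId <- estimateEnergy(Hid, circ, shots = 100L)
  expect_equal(estId$energy, 2.5)
  expect_equal(estId$stderr, 0)
})

test_that("sampling error shrinks like one over root shots", {
  set.seed(3)
  H <- randomPauliSum(3, 8, 78)
  circ <- addGate(addGate(quantumCircuit(3), "H", 0), "CNOT", c(1, 2))
  exact <- pauliExpectation(H, applyCircuit(circ))
  errLo <- abs(estimateEnergy(H, circ, shots = 200L, seed = 11)$energy -
               exact)
  seHi <- estimateEnergy(H, circ, shots = 20000L, seed = 11)$stderr
  seLo <- estimateEnergy(H, circ, shots = 200L, seed = 11)$stderr
  expect_gt(seLo / seHi, 5)   # sqrt(100) = 10 up to sampling noise
})

test_that("measurement-error mitigation inverts the confusion channel", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  # identity confusion leaves distributions alone
  pid <- memApply(c(0.3, 0.7), diag(2))
  expect_equal(pid$counts, c(0.3, 0.7))
  # true |0> distorted then recovered
  pm <- applyReadoutConfusion(c(1, 0), A)
  expect_equal(pm, c(0.9, 0.1))
  rec <- memApply(pm, A)
  expect_equal(rec$counts, c(1, 0), tolerance = 1e-10)
  # two-qubit joint element is the product of marginals
  A2 <- list(matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE),
             matrix(c(0.85, 0.15, 0.25, 0.75), 2, byrow = TRUE))
  p00 <- c(1, 0, 0, 0)
  pj <- applyReadoutConfusion(p00, A2)
  expect_equal(pj[4L], A2[[1L]][1L, 2L] * A2[[2L]][1L, 2L])
  # round trip on a generic distribution
  set.seed(5)
  p <- stats::runif(4); p <- p / sum(p)
  back <- memApply(applyReadoutConfusion(p, A2), A2)$counts
  expect_equal(back, p, tolerance = 1e-10)
  expect_error(memApply(c(0.5, 0.5), matrix(0.5, 2, 2)), "singular")
})

test_that("tiling reproduces the device capacities for 5-qubit clusters", {
  expect_equal(length(tileAssignments(5, deviceTopology("heavy-hex-27"))),
               5L)
  expect_equal(length(tileAssignments(5, deviceTopology("heavy-hex-16"))),
               3L)
  tiles <- tileAssignments(5, deviceTopology("heavy-hex-27"))
  expect_equal(anyDuplicated(unlist(tiles)), 0L)
})

test_that("tile averaging tightens the estimate roughly like one over
           tiles", {
  H <- pauliSum(c("ZI", "XX"), c(0.5, 0.3))
  circ <- addGate(addGate(quantumCircuit(2), "H", 0), "CNOT", c(0, 1))
  nm <- noiseModel(p1 = 1e-3, p2 = 5e-3,
                   readout = matrix(c(0.98, 0.02, 0.03, 0.97), 2,
                                    byrow = TRUE))
  t1 <- tiledEstimate(H, circ, list(1), nm, shots = 400L, seed = 7)
  t9 <- tiledEstimate(H, circ, as.list(1:9), nm, shots = 400L, seed = 7)
  exact <- pauliExpectation(H, applyCircuit(circ))
  expect_lt(abs(t9$energy - exact), 0.2)
  expect_true(is.na(t1$stderr) || t1$stderr >= 0)
  expect_true(t9$stderr >= 0)
})
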