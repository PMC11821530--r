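# Zero-noise extrapolation machinery.

test_that("amplified circuits keep the unitary for every lambda", {
  circ <- quantumCircuit(3)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "CNOT", c(0, 1))
  circ <- addGate(circ, "Ry", 2, 0.4)
  circ <- addGate(circ, "CNOT", c(1, 2))
  U0 <- circuitUnitary(circ)
  for (lam in 1:3) {
    amp <- zneAmplify(circ, lam)
    expect_lt(CSVQE:::unitaryDistance(circuitUnitary(amp), U0), 1e-10)
  }
  expect_error(zneAmplify(circ, 0L), "lambda")
})

test_that("gate counts follow 2*lambda CNOT and 3*lambda + 2 singles", {
  circ <- addGate(quantumCircuit(2), "CNOT", c(0, 1))
  for (lam in 1:4) {
    amp <- zneAmplify(circ, lam)
    n2 <- sum(vapply(amp@gates, function(g) g$name == "CNOT", logical(1)))
    expect_equal(n2, 2L * lam)
    expect_equal(gateCount(amp) - n2, 3L * lam + 2L)
  }
})

test_that("gain factors behave as the error-event ratio predicts", {
  circ <- addGate(quantumCircuit(2), "CNOT", c(0, 1))
  nm0 <- noiseModel(p1 = 0, p2 = 1e-3)
  expect_equal(gainFactor(circ, 1L, nm0), 1)
  for (lam in 2:4) expect_equal(gainFactor(circ, lam, nm0), lam)
  nm1 <- noiseModel(p1 = 3e-4, p2 = 1e-3)
  gs <- vapply(1:4, function(l) gainFactor(circ, l, nm1), numeric(1))
  expect_true(all(diff(gs) > 0))
  expect_lt(gs[3L], 3)   # single-qubit overhead grows sub-proportionally
})

test_that("the weighted intercept recovers exact linear data", {
  ex <- suppressWarnings(
    zneExtrapolate(data.frame(G = c(1, 2, 3), E = c(-1.0, -0.9, -0.8))))
  expect_equal(ex$energy, -1.1, tolerance = 1e-10)
  flat <- suppressWarnings(
    zneExtrapolate(data.frame(G = c(1, 2, 3), E = rep(-0.7, 3))))
  expect_equal(flat$energy, -0.7, tolerance = 1e-10)
  expect_error(zneExtrapolate(data.frame(G = 1, E = 1), order = 1L),
               "at least")
})

test_that("extrapolation pulls a noisy estimate towards the exact energy", {
  H <- pauliSum(c("ZZ", "XI", "IX"), c(-1, 0.3, 0.3))
  circ <- quantumCircuit(2)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "CNOT", c(0, 1))
  circ <- addGate(circ, "Ry", 1, 0.35)
  exact <- pauliExpectation(H, applyCircuit(circ))
  nm <- noiseModel(p1 = 2e-3, p2 = 1.5e-2,
                   readout = matrix(c(0.97, 0.03, 0.05, 0.95), 2,
                                    byrow = TRUE))
  raw <- estimateEnergy(H, circ, noise = nm, shots = 20000L, seed = 31)
  zz <- zneEstimate(H, circ, nm, lambdas = 1:3, shots = 20000L, seed = 31)
  expect_lt(abs(zz$energy - exact), abs(raw$energy - exact) + 2e-3)
  expect_true(all(diff(zz$table$G) > 0))
})

test_that("noise models serialize through JSON", {
  nm <- noiseModel(1e-3, 5e-3,
                   readout = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                   seed = 7L)
  f <- withr::local_tempfile(fileext = ".json")
  writeNoiseModel(nm, f)
  nm2 <- readNoiseModel(f)
  expect_equal(nm2$p1, nm$p1)
  expect_equal(nm2$p2, nm$p2)
  expect_equal(nm2$readout, nm$readout)
})
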