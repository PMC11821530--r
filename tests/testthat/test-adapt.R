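# Adaptive ansatz construction and gradients.

test_that("commuting pool elements score zero and the textbook case scores
           two", {
  psi <- c(1, 1) / sqrt(2)
  expect_equal(poolGradient(pauliSum("Z", 1), psi,
                            pauliTerm("Y")@x, pauliTerm("Y")@z), 2)
  # [H, P] = 0
  expect_equal(poolGradient(pauliSum("Z", 1), psi,
                            pauliTerm("Z")@x, pauliTerm("Z")@z), 0)
})

test_that("pool gradients agree with central finite differences", {
  set.seed(4)
  H <- randomPauliSum(4, 20, 44)
  pool <- randomPauliSum(4, 6, 45)
  ref <- complex(real = stats::rnorm(16), imaginary = stats::rnorm(16))
  ref <- ref / sqrt(sum(Mod(ref)^2))
  for (t in seq_len(nTerms(pool))) {
    g <- poolGradient(H, ref, pool@x[t], pool@z[t])
    h <- 1e-5
    ops <- list(x = pool@x[t], z = pool@z[t])
    fd <- (pauliExpectation(H, CSVQE:::.ansatzState(ref, ops, h)) -
           pauliExpectation(H, CSVQE:::.ansatzState(ref, ops, -h))) / (2 * h)
    expect_lt(abs(g - fd), 1e-6)
  }
})

test_that("adjoint and parameter-shift gradients coincide", {
  set.seed(5)
  H <- randomPauliSum(4, 15, 46)
  pool <- randomPauliSum(4, 5, 47)
  ref <- complex(real = stats::rnorm(16)); ref <- ref / sqrt(sum(Mod(ref)^2))
  ops <- list(x = pool@x[1:3], z = pool@z[1:3])
  th <- c(0.3, -0.2, 0.15)
  op <- pauliMatvecOperator(H)
  ag <- CSVQE:::.ansatzEnergyGrad(function(v) op$matvec(v), ref, ops, th)
  ps <- parameterShiftGradient(H, ref, ops, th)
  expect_lt(max(abs(ag$grad - ps)), 1e-10)
})

test_that("a single-qubit problem converges in one cycle from |+>", {
  res <- adaptRun(pauliSum("Z", 1), pauliSum("Y", 1),
                  reference = c(1, 1) / sqrt(2))
  expect_equal(res$energy, -1, tolerance = 1e-8)
  expect_true(length(res$trace) >= 1L)
})

test_that("the energy trace is non-increasing in noiseless runs", {
  fx <- h2Fixture(1.2)
  pool <- buildQubitPool(fx$hf, sector = fx$taper$sector)
  ref <- projectedReference(fx$qb$hfOccupation, fx$taper$sector)
  res <- adaptRun(fx$taper$H, pool, reference = ref, maxCycles = 6L)
  if (length(res$trace) >= 2L) {
    expect_true(all(diff(res$trace) <= 1e-8))
  }
  expect_equal(res$energy, fx$fci, tolerance = 1e-6)
})

test_that("the circuit graph counts two-qubit gates as edge weights", {
  circ <- quantumCircuit(4)
  circ <- addGate(circ, "CNOT", c(0, 1))
  circ <- addGate(circ, "CNOT", c(1, 2))
  circ <- addGate(circ, "CNOT", c(1, 2))
  circ <- addGate(circ, "CNOT", c(2, 3))
  gc <- circuitGraph(circ)
  expect_equal(totalWeight(gc), 4)
  expect_equal(nrow(gc$edges), 3L)
  expect_equal(gc$edges$w[gc$edges$u == 1L & gc$edges$v == 2L], 2)
})

test_that("bias arithmetic follows the penalty formula and edge cases", {
  ring4 <- deviceTopology("ring-4")
  line8 <- deviceTopology("line-8")
  circ <- quantumCircuit(4)
  for (p in list(c(0, 1), c(1, 2), c(2, 3), c(3, 0))) {
    circ <- addGate(circ, "CNOT", p)
  }
  gc <- circuitGraph(circ)
  expect_equal(biasFactor(gc, ring4), 1)              # embeds at d = 0
  expect_equal(biasFactor(gc, line8, maxDepth = 0L), 0)
  # deleting one node removes weight 2 of 4: (1 - 0.5)^b
  expect_equal(biasFactor(gc, line8, maxDepth = 2L, bias = 2), 0.25)
  # non-increasing in b for s/W in (0, 1)
  b1 <- biasFactor(gc, line8, maxDepth = 2L, bias = 1)
  b3 <- biasFactor(gc, line8, maxDepth = 2L, bias = 3)
  expect_lte(b3, b1)
})

test_that("hardware-aware scoring never selects a zero-bias operator while
           a positive-score one exists", {
  set.seed(9)
  H <- randomPauliSum(3, 12, 71)
  pool <- pauliSum(c("XYI", "IXY", "XIY"), 1)
  res <- adaptRun(H, pool, target = deviceTopology("line-3"),
                  maxCycles = 2L)
  # every selected operator admitted an embedding within depth D
  for (k in seq_along(res$theta)) {
    expect_true(bitCount(bitwOr(res$ops$x[k], res$ops$z[k])) >= 1L)
  }
  expect_true(length(res$theta) >= 1L)
})
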