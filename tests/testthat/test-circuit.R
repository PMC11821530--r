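# Circuit IR, Pauli-exponential compilation, routing.

test_that("compiled Pauli exponentials match the matrix exponential", {
  set.seed(1)
  for (s in c("Z", "Y", "XX", "ZY", "XYZ", "IYXZ")) {
    th <- stats::runif(1, -1, 1)
    ps <- pauliTerm(s)
    circ <- compileExponential(ps@x, ps@z, th, nchar(s))
    d <- 2^nchar(s)
    exact <- cos(th) * diag(d) + 1i * sin(th) * kronPauli(s)
    expect_lt(CSVQE:::unitaryDistance(circuitUnitary(circ), exact), 1e-10)
  }
})

test_that("zero-angle exponentials compile to the identity action", {
  ps <- pauliTerm("XZ")
  circ <- compileExponential(ps@x, ps@z, 0, 2L)
  expect_lt(CSVQE:::unitaryDistance(circuitUnitary(circ), diag(4) + 0i),
            1e-12)
  expect_equal(gateCount(compileExponential(0L, 0L, 0.3, 2L)), 0L)
})

test_that("single-Z exponential is one Rz", {
  ps <- pauliTerm("Z")
  circ <- compileExponential(ps@x, ps@z, 0.4, 1L)
  expect_equal(gateCount(circ), 1L)
  expect_equal(circ@gates[[1L]]$name, "Rz")
})

test_that("statevector gates agree with dense unitaries", {
  set.seed(6)
  circ <- quantumCircuit(3)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "Ry", 1, 0.3)
  circ <- addGate(circ, "CNOT", c(0, 2))
  circ <- addGate(circ, "CPhase", c(1, 2), 0.8)
  circ <- addGate(circ, "SWAP", c(0, 1))
  circ <- addGate(circ, "Rz", 2, -0.5)
  circ <- addGate(circ, "X", 1)
  U <- circuitUnitary(circ)
  expect_lt(max(abs(U %*% Conj(t(U)) - diag(8))), 1e-10)
  v0 <- complex(real = stats::rnorm(8), imaginary = stats::rnorm(8))
  v0 <- v0 / sqrt(sum(Mod(v0)^2))
  expect_lt(max(Mod(applyCircuit(circ, v0) - U %*% v0)), 1e-10)
})

test_that("QASM export covers the gate set and counts lines", {
  circ <- addGate(addGate(quantumCircuit(2), "H", 0), "CNOT", c(0, 1))
  qasm <- exportQASM(circ)
  expect_equal(length(qasm), 3L + 2L)
  expect_match(qasm[4L], "^h q\\[0\\];$")
  expect_match(qasm[5L], "^cx q\\[0\\],q\\[1\\];$")
})

test_that("routing conforms to the device and expands SWAPs as 3 CNOTs", {
  circ <- addGate(quantumCircuit(3), "CNOT", c(0, 2))
  # identity placement forces a SWAP; automatic placement would instead
  # embed the coupling graph and avoid it
  rt <- routeCircuit(circ, deviceTopology("line-3"),
                     initialMapping = c(0L, 1L, 2L))
  dev <- deviceTopology("line-3")
  ek <- paste(dev$edges$u, dev$edges$v)
  for (g in rt$circuit@gates) {
    if (length(g$qubits) == 2L) {
      key <- paste(min(g$qubits), max(g$qubits))
      expect_true(key %in% ek)
    }
  }
  expect_equal(rt$cnotCount, 4L)   # one inserted SWAP (3) + the gate itself
  # already-conformant circuits are untouched
  circ2 <- addGate(quantumCircuit(3), "CNOT", c(0, 1))
  rt2 <- routeCircuit(circ2, deviceTopology("line-3"))
  expect_equal(rt2$cnotCount, 1L)
  # automatic placement resolves the non-adjacent pair without SWAPs
  rt3 <- routeCircuit(circ, deviceTopology("line-3"))
  expect_equal(rt3$cnotCount, 1L)
})

test_that("routed circuits implement the original unitary up to the final
           permutation", {
  circ <- quantumCircuit(3)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "CNOT", c(0, 2))
  circ <- addGate(circ, "Ry", 1, 0.4)
  rt <- routeCircuit(circ, deviceTopology("line-3"),
                     initialMapping = c(0L, 1L, 2L))
  U0 <- circuitUnitary(circ)
  Ur <- circuitUnitary(rt$circuit)
  # permutation matrix from the final logical->physical mapping
  d <- 8L
  P <- matrix(0, d, d)
  for (b in 0:(d - 1L)) {
    bits <- bitwAnd(bitwShiftR(b, 0:2), 1L)
    tgt <- sum(bits * 2^rt$mapping)
    P[tgt + 1L, b + 1L] <- 1
  }
  expect_lt(CSVQE:::unitaryDistance(Ur, P %*% U0), 1e-10)
})

test_that("the peephole pass cancels inverse pairs", {
  circ <- quantumCircuit(2)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "H", 0)
  circ <- addGate(circ, "CNOT", c(0, 1))
  circ <- addGate(circ, "CNOT", c(0, 1))
  circ <- addGate(circ, "Rz", 1, 0.3)
  circ <- addGate(circ, "Rz", 1, -0.3)
  out <- CSVQE:::.peephole(circ)
  expect_equal(gateCount(out), 0L)
})
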