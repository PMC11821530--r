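#' @include AllClasses.R pauli.R
NULL

#' Build an empty quantum circuit
#' @param nQubits register width
#' @return [QuantumCircuit-class]
#' @export
quantumCircuit <- function(nQubits) {
  new("QuantumCircuit", nQubits = as.integer(nQubits), gates = list())
}

#' Append a gate
#'
#' @param circ QuantumCircuit
#' @param name one of H, X, Rx, Ry, Rz, CNOT, CPhase, SWAP, PauliRot
#' @param qubits 0-based qubit indices (control first for CNOT/CPhase)
#' @param angle rotation angle where applicable
#' @param pauli for PauliRot: list(x =, z =) masks of the Hermitian Pauli
#' @return QuantumCircuit
#' @export
addGate <- function(circ, name, qubits, angle = NA_real_, pauli = NULL) {
  circ@gates[[length(circ@gates) + 1L]] <-
    list(name = name, qubits = as.integer(qubits), angle = angle,
         pauli = pauli)
  circ
}

#' Number of gates / two-qubit gates
#' @param circ QuantumCircuit
#' @return integer count
#' @export
gateCount <- function(circ) length(circ@gates)

#' @rdname gateCount
#' @export
twoQubitGateCount <- function(circ) {
  sum(vapply(circ@gates, function(g)
    g$name %in% c("CNOT", "CPhase", "SWAP"), logical(1)))
}

setMethod("show", "QuantumCircuit", function(object) {
  cat(sprintf("QuantumCircuit on %d qubit(s): %d gates (%d two-qubit)\n",
              object@nQubits, gateCount(object),
              twoQubitGateCount(object)))
})

# ---------------------------------------------------------------------------
# Statevector simulation (little-endian: qubit j <-> bit 2^j)
# ---------------------------------------------------------------------------

## apply a single-qubit unitary u (2x2) on qubit q
.apply1q <- function(v, u, q) {
  d <- length(v)
  idx <- 0:(d - 1L)
  b <- bitwShiftL(1L, q)
  lo <- which(bitwAnd(idx, b) == 0L)        # 1-based positions with bit 0
  hi <- lo + b
  v0 <- v[lo]; v1 <- v[hi]
  v[lo] <- u[1L, 1L] * v0 + u[1L, 2L] * v1
  v[hi] <- u[2L, 1L] * v0 + u[2L, 2L] * v1
  v
}

.gateMatrix <- function(name, angle) {
  switch(name,
    H = matrix(c(1, 1, 1, -1), 2) / sqrt(2),
    X = matrix(c(0, 1, 1, 0), 2),
    Rx = {
      c0 <- cos(angle / 2); s0 <- sin(angle / 2)
      matrix(c(c0, -1i * s0, -1i * s0, c0), 2)
    },
    Ry = {
      c0 <- cos(angle / 2); s0 <- sin(angle / 2)
      matrix(c(c0, s0, -s0, c0), 2)
    },
    Rz = diag(c(exp(-1i * angle / 2), exp(1i * angle / 2))),
    stop("unknown single-qubit gate ", name))
}

#' Apply a circuit to a statevector
#'
#' @param circ QuantumCircuit
#' @param v complex statevector of length 2^nQubits; default
#'   \eqn{|0...0\rangle}
#' @return statevector
#' @export
applyCircuit <- function(circ, v = NULL) {
  n <- circ@nQubits
  d <- 2^n
  if (is.null(v)) {
    v <- complex(length.out = d)
    v[1L] <- 1 + 0i
  }
  idx <- 0:(d - 1L)
  for (g in circ@gates) {
    v <- .applyGateVec(v, g, idx)
  }
  v
}

.applyGateVec <- function(v, g, idx) {
  q <- g$qubits
  switch(g$name,
    H = , X = , Rx = , Ry = , Rz =
      .apply1q(v, .gateMatrix(g$name, g$angle), q[1L]),
    CNOT = {
      cb <- bitwShiftL(1L, q[1L]); tb <- bitwShiftL(1L, q[2L])
      sel <- which(bitwAnd(idx, cb) != 0L)
      part <- v[sel]
      tgt <- bitwXor(idx[sel], tb) + 1L
      v[tgt] <- part
      v
    },
    CPhase = {
      cb <- bitwShiftL(1L, q[1L]); tb <- bitwShiftL(1L, q[2L])
      sel <- bitwAnd(idx, cb) != 0L & bitwAnd(idx, tb) != 0L
      v[sel] <- v[sel] * exp(1i * g$angle)
      v
    },
    SWAP = {
      b1 <- bitwShiftL(1L, q[1L]); b2 <- bitwShiftL(1L, q[2L])
      a1 <- bitwAnd(idx, b1) != 0L; a2 <- bitwAnd(idx, b2) != 0L
      sel <- which(a1 & !a2)
      tgt <- bitwXor(idx[sel], bitwOr(b1, b2)) + 1L
      tmp <- v[sel]
      v[sel] <- v[tgt]
      v[tgt] <- tmp
      v
    },
    PauliRot = {
      # e^{i theta P} v = cos(theta) v + i sin(theta) P v
      ps <- newPauliSum(g$pauli$x, g$pauli$z, complex(real = 1),
                        as.integer(log2(length(v))))
      cos(g$angle) * v + 1i * sin(g$angle) * pauliApply(ps, v)
    },
    stop("unknown gate ", g$name))
}

#' Dense unitary of a circuit (small registers)
#' @param circ QuantumCircuit (nQubits <= 10)
#' @return complex matrix 2^n x 2^n
#' @export
circuitUnitary <- function(circ) {
  n <- circ@nQubits
  if (n > 10L) stop("dense unitary limited to 10 qubits")
  d <- 2^n
  U <- matrix(0i, d, d)
  for (c0 in seq_len(d)) {
    v <- complex(length.out = d)
    v[c0] <- 1 + 0i
    U[, c0] <- applyCircuit(circ, v)
  }
  U
}

## max |U1 - phase*U2| over the optimal global phase
unitaryDistance <- function(U1, U2) {
  ip <- sum(Conj(U2) * U1)   # phase of U1 relative to U2
  if (abs(ip) < 1e-14) return(max(abs(U1 - U2)))
  ph <- ip / abs(ip)
  max(abs(U1 - ph * U2))
}

# ---------------------------------------------------------------------------
# Pauli-exponential compilation
# ---------------------------------------------------------------------------

#' Compile a Pauli exponential to elementary gates
#'
#' Builds the standard basis-change + CNOT-ladder + Rz realization of
#' \eqn{e^{i\theta P}} for a single Pauli string P (phase convention:
#' \eqn{R_z(\phi) = e^{-i\phi Z/2}}, so the ladder carries
#' \eqn{R_z(-2\theta)}).  The identity string returns an empty circuit.
#'
#' @param x,z masks of P
#' @param theta angle
#' @param nQubits register width
#' @return QuantumCircuit whose unitary equals \eqn{e^{i\theta P}} up to
#'   global phase
#' @export
compileExponential <- function(x, z, theta, nQubits) {
  circ <- quantumCircuit(nQubits)
  sup <- which(bitwAnd(bitwOr(x, z), bitwShiftL(1L, 0:(nQubits - 1L))) != 0L) - 1L
  if (length(sup) == 0L) return(circ)
  basis <- list()
  for (q in sup) {
    b <- bitwShiftL(1L, q)
    hasX <- bitwAnd(x, b) != 0L; hasZ <- bitwAnd(z, b) != 0L
    if (hasX && !hasZ) {
      circ <- addGate(circ, "H", q); basis[[length(basis) + 1L]] <- c("H", q)
    } else if (hasX && hasZ) {
      circ <- addGate(circ, "Rx", q, pi / 2)
      basis[[length(basis) + 1L]] <- c("RxInv", q)
    }
  }
  if (length(sup) > 1L) {
    for (i in seq_len(length(sup) - 1L)) {
      circ <- addGate(circ, "CNOT", c(sup[i], sup[i + 1L]))
    }
  }
  circ <- addGate(circ, "Rz", sup[length(sup)], -2 * theta)
  if (length(sup) > 1L) {
    for (i in rev(seq_len(length(sup) - 1L))) {
      circ <- addGate(circ, "CNOT", c(sup[i], sup[i + 1L]))
    }
  }
  for (bset in rev(basis)) {
    q <- as.integer(bset[2L])
    if (bset[1L] == "H") circ <- addGate(circ, "H", q)
    else circ <- addGate(circ, "Rx", q, -pi / 2)
  }
  circ
}

#' Export a circuit as OpenQASM 2.0
#' @param circ QuantumCircuit
#' @param file optional path; when missing the text is returned
#' @return character vector of QASM lines (invisibly when writing to file)
#' @export
exportQASM <- function(circ, file = NULL) {
  lines <- c("OPENQASM 2.0;", "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", circ@nQubits))
  for (g in circ@gates) {
    q <- g$qubits
    lines <- c(lines, switch(g$name,
      H = sprintf("h q[%d];", q[1L]),
      X = sprintf("x q[%d];", q[1L]),
      Rx = sprintf("rx(%.12g) q[%d];", g$angle, q[1L]),
      Ry = sprintf("ry(%.12g) q[%d];", g$angle, q[1L]),
      Rz = sprintf("rz(%.12g) q[%d];", g$angle, q[1L]),
      CNOT = sprintf("cx q[%d],q[%d];", q[1L], q[2L]),
      CPhase = sprintf("cp(%.12g) q[%d],q[%d];", g$angle, q[1L], q[2L]),
      SWAP = sprintf("swap q[%d],q[%d];", q[1L], q[2L]),
      stop("cannot export gate ", g$name)))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
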