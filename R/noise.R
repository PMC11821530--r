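#' @include circuit.R
NULL

#' Gate-located depolarizing + readout noise model
#'
#' Single- and two-qubit depolarizing channels attached to every gate, plus
#' terminal per-qubit readout confusion matrices \eqn{A^{(k)}} with
#' \eqn{A_{ij}} the probability of preparing \eqn{|i\rangle} and measuring
#' \eqn{|j\rangle}.  There is no idle decoherence channel, so
#' dynamical-decoupling sequences would act trivially under this model and
#' are not represented.
#'
#' @param p1,p2 single-/two-qubit depolarizing rates in [0, 1)
#' @param readout single 2x2 confusion matrix (rows sum to 1) shared by all
#'   qubits, or a list with one matrix per qubit
#' @param seed integer seed used by samplers
#' @return noiseModel list object
#' @export
noiseModel <- function(p1 = 0, p2 = 0, readout = NULL, seed = 1L) {
  if (p1 < 0 || p1 >= 1 || p2 < 0 || p2 >= 1)
    stop("depolarizing rates must lie in [0, 1)")
  if (!is.null(readout)) {
    ros <- if (is.matrix(readout)) list(readout) else readout
    for (A in ros) {
      if (any(abs(rowSums(A) - 1) > 1e-10))
        stop("readout confusion rows must sum to 1")
    }
  }
  structure(list(p1 = p1, p2 = p2, readout = readout,
                 seed = as.integer(seed)), class = "noiseModel")
}

#' @export
print.noiseModel <- function(x, ...) {
  cat(sprintf("noiseModel: p1=%g p2=%g readout=%s\n", x$p1, x$p2,
              if (is.null(x$readout)) "ideal" else "confused"))
  invisible(x)
}

## read/write noise models as JSON
#' Serialize a noise model
#' @param nm noiseModel
#' @param file path
#' @return file path invisibly
#' @export
writeNoiseModel <- function(nm, file) {
  obj <- list(p1 = nm$p1, p2 = nm$p2, seed = nm$seed)
  if (!is.null(nm$readout)) {
    ros <- if (is.matrix(nm$readout)) list(nm$readout) else nm$readout
    obj$readout <- lapply(ros, function(A) as.vector(t(A)))
  }
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeNoiseModel
#' @export
readNoiseModel <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  readout <- NULL
  if (!is.null(obj$readout)) {
    rolist <- obj$readout
    if (!is.list(rolist)) rolist <- list(rolist)
    readout <- lapply(rolist, function(v) matrix(unlist(v), 2, 2,
                                                 byrow = TRUE))
    if (length(readout) == 1L) readout <- readout[[1L]]
  }
  noiseModel(obj$p1, obj$p2, readout, obj$seed %||% 1L)
}

# ---------------------------------------------------------------------------
# Density-matrix simulation with gate-located depolarizing noise
# ---------------------------------------------------------------------------

## dense unitary of one gate on the full register
.gateUnitary <- function(g, n) {
  circ <- quantumCircuit(n)
  circ@gates <- list(g)
  circuitUnitary(circ)
}

## depolarizing channel on the given qubits
.depolarize <- function(rho, qubits, p, n) {
  if (p <= 0) return(rho)
  paulis <- c("X", "Y", "Z")
  if (length(qubits) == 1L) {
    acc <- matrix(0i, nrow(rho), ncol(rho))
    for (s in paulis) {
      str <- rep("I", n); str[qubits + 1L] <- s
      P <- pauliMatrix(pauliTerm(paste(str, collapse = "")))
      acc <- acc + P %*% rho %*% P
    }
    return((1 - p) * rho + p / 3 * acc)
  }
  acc <- matrix(0i, nrow(rho), ncol(rho))
  cnt <- 0L
  for (s1 in c("I", paulis)) for (s2 in c("I", paulis)) {
    if (s1 == "I" && s2 == "I") next
    str <- rep("I", n); str[qubits[1L] + 1L] <- s1
    str[qubits[2L] + 1L] <- s2
    P <- pauliMatrix(pauliTerm(paste(str, collapse = "")))
    acc <- acc + P %*% rho %*% P
    cnt <- cnt + 1L
  }
  (1 - p) * rho + p / cnt * acc
}

#' Simulate a circuit as a density matrix under depolarizing noise
#'
#' @param circ QuantumCircuit (<= 8 qubits)
#' @param noise noiseModel or NULL for the ideal channel
#' @param rho optional input density matrix (default \eqn{|0..0\rangle})
#' @return density matrix 2^n x 2^n
#' @export
simulateDensityMatrix <- function(circ, noise = NULL, rho = NULL) {
  n <- circ@nQubits
  if (n > 8L) stop("density-matrix simulation limited to 8 qubits")
  d <- 2^n
  if (is.null(rho)) {
    rho <- matrix(0i, d, d)
    rho[1L, 1L] <- 1 + 0i
  }
  for (g in circ@gates) {
    U <- .gateUnitary(g, n)
    rho <- U %*% rho %*% Conj(t(U))
    if (!is.null(noise)) {
      q <- g$qubits
      rho <- if (length(q) == 1L) .depolarize(rho, q, noise$p1, n)
             else .depolarize(rho, q, noise$p2, n)
    }
  }
  rho
}

#' Apply per-qubit readout confusion to a probability vector
#'
#' @param p probability vector over bitstrings (length 2^n, little-endian)
#' @param readout confusion matrix or list of per-qubit matrices
#' @return distorted probability vector
#' @export
applyReadoutConfusion <- function(p, readout) {
  n <- as.integer(round(log2(length(p))))
  ros <- if (is.matrix(readout)) rep(list(readout), n) else readout
  idx <- 0:(length(p) - 1L)
  for (q in seq_len(n) - 1L) {
    A <- ros[[q + 1L]]
    b <- bitwShiftL(1L, q)
    lo <- which(bitwAnd(idx, b) == 0L)
    hi <- lo + b
    p0 <- p[lo]; p1 <- p[hi]
    # measured j gets sum_i A[i+1, j+1] p_i
    p[lo] <- A[1L, 1L] * p0 + A[2L, 1L] * p1
    p[hi] <- A[1L, 2L] * p0 + A[2L, 2L] * p1
  }
  p
}
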