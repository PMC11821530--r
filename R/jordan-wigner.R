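#' @include ccsd.R pauli.R
NULL

# Jordan-Wigner mapping.  Spin orbital (p, sigma) with spatial index p
# (0-based) and sigma in {0 alpha, 1 beta} occupies qubit 2p + sigma
# (interleaved convention); the JW chain acts on lower-indexed qubits.
# a_k   = 1/2 (X_k + i Y_k) Z_{k-1} ... Z_0
# a^+_k = 1/2 (X_k - i Y_k) Z_{k-1} ... Z_0

## vectorised product of ladder operators.
## qubits: nterms x nops matrix (0-based); daggers: logical vector length
## nops; coeff: numeric/complex length nterms.  Returns PauliSum.
.ladderProductPauli <- function(qubits, daggers, coeff, nQubits) {
  nops <- ncol(qubits)
  nterms <- nrow(qubits)
  bit <- matrix(bitwShiftL(1L, qubits), nterms, nops)
  chain <- matrix(bitwShiftL(1L, qubits) - 1L, nterms, nops)
  combos <- as.matrix(expand.grid(rep(list(0:1), nops)))
  xs <- zs <- integer(0); cf <- complex(0)
  outX <- vector("list", nrow(combos))
  outZ <- vector("list", nrow(combos))
  outC <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cc <- combos[ci, ]
    x <- integer(nterms); z <- integer(nterms)
    p <- integer(nterms)               # phase exponent of i, mod 4
    fac <- rep(complex(real = 1), nterms)
    for (k in seq_len(nops)) {
      x2 <- bit[, k]
      z2 <- if (cc[k] == 1L) bitwOr(chain[, k], bit[, k]) else chain[, k]
      # phase of W(x1,z1) * W(x2,z2)
      x3 <- bitwXor(x, x2); z3 <- bitwXor(z, z2)
      p <- (p + bitCount(bitwAnd(x, z)) + bitCount(bitwAnd(x2, z2)) -
            bitCount(bitwAnd(x3, z3)) + 2L * bitCount(bitwAnd(z, x2))) %% 4L
      x <- x3; z <- z3
      cfac <- if (cc[k] == 1L) {
        if (daggers[k]) -0.5i else 0.5i
      } else 0.5 + 0i
      fac <- fac * cfac
    }
    ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[p + 1L]
    outX[[ci]] <- x; outZ[[ci]] <- z
    outC[[ci]] <- coeff * fac * ph
  }
  canonicalize(newPauliSum(unlist(outX), unlist(outZ),
                           unlist(outC), nQubits))
}

#' Jordan-Wigner qubit Hamiltonian from MO integrals
#'
#' @param h one-electron MO integrals (M x M, Hartree)
#' @param g two-electron MO integrals, chemists' (pq|rs)
#' @param enuc nuclear repulsion constant
#' @return Hermitian PauliSum on 2M qubits
#' @export
jwHamiltonian <- function(h, g, enuc = 0) {
  M <- nrow(h)
  nq <- 2L * M
  # one-body
  idx <- which(abs(h) > 1e-14, arr.ind = TRUE)
  terms <- NULL
  acc <- list()
  if (nrow(idx)) {
    for (sigma in 0:1) {
      q <- cbind(2L * (idx[, 1L] - 1L) + sigma, 2L * (idx[, 2L] - 1L) + sigma)
      acc[[length(acc) + 1L]] <-
        .ladderProductPauli(q, c(TRUE, FALSE), h[idx], nq)
    }
  }
  # two-body: 1/2 sum (pq|rs) a^+_{p s1} a^+_{r s2} a_{s s2} a_{q s1}
  gv <- as.vector(g)
  nz <- which(abs(gv) > 1e-14)
  ind <- arrayInd(nz, dim(g))
  for (s1 in 0:1) for (s2 in 0:1) {
    q <- cbind(2L * (ind[, 1L] - 1L) + s1,
               2L * (ind[, 3L] - 1L) + s2,
               2L * (ind[, 4L] - 1L) + s2,
               2L * (ind[, 2L] - 1L) + s1)
    acc[[length(acc) + 1L]] <-
      .ladderProductPauli(q, c(TRUE, TRUE, FALSE, FALSE), 0.5 * gv[nz], nq)
  }
  xs <- unlist(lapply(acc, function(a) a@x))
  zs <- unlist(lapply(acc, function(a) a@z))
  cf <- unlist(lapply(acc, function(a) a@coeff))
  H <- canonicalize(newPauliSum(c(xs, 0L), c(zs, 0L),
                                c(cf, complex(real = enuc)), nq))
  # Hermitian by construction: drop numerically spurious imaginary parts
  newPauliSum(H@x, H@z, complex(real = Re(H@coeff)), nq)
}

#' Molecular qubit Hamiltonian
#'
#' Runs SCF at the given geometry and maps the second-quantized Hamiltonian
#' in the canonical MO basis onto qubits via the Jordan-Wigner transformation
#' (interleaved spin ordering).
#'
#' @param geom [molecularGeometry()]
#' @param hf optional converged [scfRHF()] result to reuse
#' @return list: H (PauliSum on 2M qubits), hf, hfOccupation (0/1 vector per
#'   qubit in the Hartree-Fock determinant)
#' @export
buildQubitHamiltonian <- function(geom, hf = NULL) {
  if (is.null(hf)) hf <- scfRHF(geom)
  h <- moOne(hf$ints, hf$C)
  g <- moERI(hf$ints$eri, hf$C)
  H <- jwHamiltonian(h, g, hf$ints$enuc)
  occ <- integer(2L * hf$ints$nbf)
  occ[seq_len(2L * hf$nocc)] <- 1L
  list(H = H, hf = hf, hfOccupation = occ)
}

#' Coupled-cluster excitation generator on qubits
#'
#' Jordan-Wigner image of the anti-Hermitian cluster generator
#' \eqn{T - T^\dagger} with T the singles (+doubles) excitation operator.
#' The MP2 guide uses doubles amplitudes only; the CCSD guide uses t1 + t2.
#'
#' @param hf converged [scfRHF()]
#' @param source "MP2" or "CCSD"
#' @param mp2,cc optional precomputed [mp2Energy()] / [ccsdEnergy()] results
#' @param includeSingles logical; include t1 (CCSD only)
#' @return anti-Hermitian PauliSum (imaginary coefficients) on 2M qubits
#' @export
excitationGenerator <- function(hf, source = c("MP2", "CCSD"), mp2 = NULL,
                                cc = NULL, includeSingles = TRUE) {
  source <- match.arg(source)
  if (source == "MP2") {
    if (is.null(mp2)) mp2 <- mp2Energy(hf)
    so <- mp2$so; t1 <- NULL; t2 <- mp2$t2
  } else {
    if (is.null(cc)) cc <- ccsdEnergy(hf)
    so <- cc$so; t1 <- if (includeSingles) cc$t1 else NULL; t2 <- cc$t2
  }
  no <- so$nocc; nv <- so$nvirt
  nq <- so$nso
  qubitOf <- so$perm - 1L   # permuted position -> interleaved qubit (0-based)
  acc <- list()
  if (!is.null(t1)) {
    nzi <- which(abs(t1) > 1e-12, arr.ind = TRUE)
    if (nrow(nzi)) {
      qa <- qubitOf[no + nzi[, 2L]]; qi <- qubitOf[nzi[, 1L]]
      # T: t_ia a^+_a a_i ; generator T - T^+
      acc[[length(acc) + 1L]] <-
        .ladderProductPauli(cbind(qa, qi), c(TRUE, FALSE), t1[nzi], nq)
      acc[[length(acc) + 1L]] <-
        .ladderProductPauli(cbind(qi, qa), c(TRUE, FALSE), -t1[nzi], nq)
    }
  }
  nz <- which(abs(t2) > 1e-12)
  if (length(nz)) {
    ind <- arrayInd(nz, dim(t2))
    qi <- qubitOf[ind[, 1L]]; qj <- qubitOf[ind[, 2L]]
    qa <- qubitOf[no + ind[, 3L]]; qb <- qubitOf[no + ind[, 4L]]
    amp <- 0.25 * t2[nz]
    # T2 = 1/4 sum t_ijab a^+_a a^+_b a_j a_i
    acc[[length(acc) + 1L]] <-
      .ladderProductPauli(cbind(qa, qb, qj, qi),
                          c(TRUE, TRUE, FALSE, FALSE), amp, nq)
    acc[[length(acc) + 1L]] <-
      .ladderProductPauli(cbind(qi, qj, qb, qa),
                          c(TRUE, TRUE, FALSE, FALSE), -amp, nq)
  }
  if (length(acc) == 0L) return(pauliSum(nQubits = nq))
  xs <- unlist(lapply(acc, function(a) a@x))
  zs <- unlist(lapply(acc, function(a) a@z))
  cf <- unlist(lapply(acc, function(a) a@coeff))
  G <- canonicalize(newPauliSum(xs, zs, cf, nq))
  # anti-Hermitian: real parts are numerical noise
  canonicalize(newPauliSum(G@x, G@z, complex(imaginary = Im(G@coeff)), nq))
}
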