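#' @include graphs.R stabilizers.R jordan-wigner.R
NULL

# Adaptive ansatz construction (qubit-ADAPT with coupled-cluster pools),
# optionally biased towards a hardware topology through approximate
# subgraph-isomorphism scoring.

#' Qubit pool of coupled-cluster excitations
#'
#' Builds the singles+doubles excitation generator with unit amplitudes,
#' maps it through Jordan-Wigner, optionally replays tapering/projection
#' records, and splits the image into individual Pauli strings (the
#' qubit-ADAPT pool).  Strings that project to the identity are dropped.
#'
#' @param hf converged [scfRHF()]
#' @param sector optional [SymmetrySector-class] to taper with
#' @param record optional projection record from [projectToSubspace()]
#' @param includeSingles logical
#' @return PauliSum whose terms (unit coefficients) are the pool operators
#' @export
buildQubitPool <- function(hf, sector = NULL, record = NULL,
                           includeSingles = TRUE) {
  so <- spinOrbitalData(hf)
  no <- so$nocc; nv <- so$nvirt
  # antisymmetrized unit amplitudes (a symmetric array would cancel out of
  # the antisymmetrized double-excitation sum identically)
  t2 <- array(0, c(no, no, nv, nv))
  for (i in seq_len(no - 1L)) for (j in (i + 1L):no)
    for (a in seq_len(nv - 1L)) for (b in (a + 1L):nv) {
      t2[i, j, a, b] <- 1; t2[j, i, a, b] <- -1
      t2[i, j, b, a] <- -1; t2[j, i, b, a] <- 1
    }
  fake <- list(so = so, t1 = if (includeSingles) matrix(1, no, nv) else NULL,
               t2 = t2)
  gen <- excitationGenerator(hf, "CCSD", cc = fake,
                             includeSingles = includeSingles)
  if (!is.null(sector)) gen <- taperOperator(gen, sector)
  if (!is.null(record)) gen <- replayProjection(gen, record)
  sel <- which(!(gen@x == 0L & gen@z == 0L))
  newPauliSum(gen@x[sel], gen@z[sel],
              rep(complex(real = 1), length(sel)), gen@nQubits)
}

#' Energy-gradient score of a pool element
#'
#' \eqn{\partial_\theta \langle\psi| e^{-i\theta P} H e^{i\theta P}
#' |\psi\rangle|_{\theta=0} = \langle\psi| i[H, P] |\psi\rangle
#' = -2\,\mathrm{Im}\langle\psi|HP|\psi\rangle}.  With \code{Hpsi}
#' precomputed the per-element cost is one Pauli application.
#'
#' @param H PauliSum (used when \code{Hpsi} missing)
#' @param psi statevector
#' @param px,pz masks of the pool Pauli P
#' @param Hpsi optional precomputed H|psi>
#' @return real gradient
#' @export
poolGradient <- function(H, psi, px, pz, Hpsi = NULL) {
  n <- as.integer(round(log2(length(psi))))
  if (is.null(Hpsi)) Hpsi <- pauliApply(H, psi)
  P <- newPauliSum(px, pz, complex(real = 1), n)
  -2 * Im(sum(Conj(Hpsi) * pauliApply(P, psi)))
}

## ansatz state: reference statevector + ordered PauliRot applications
.ansatzState <- function(ref, ops, theta) {
  v <- ref
  n <- as.integer(round(log2(length(ref))))
  for (k in seq_along(theta)) {
    P <- newPauliSum(ops$x[k], ops$z[k], complex(real = 1), n)
    v <- cos(theta[k]) * v + 1i * sin(theta[k]) * pauliApply(P, v)
  }
  v
}

## analytic gradient by adjoint sweep; returns list(energy, grad)
.ansatzEnergyGrad <- function(mvH, ref, ops, theta) {
  n <- as.integer(round(log2(length(ref))))
  N <- length(theta)
  psis <- vector("list", N + 1L)
  psis[[1L]] <- ref
  for (k in seq_len(N)) {
    P <- newPauliSum(ops$x[k], ops$z[k], complex(real = 1), n)
    psis[[k + 1L]] <- cos(theta[k]) * psis[[k]] +
      1i * sin(theta[k]) * pauliApply(P, psis[[k]])
  }
  psi <- psis[[N + 1L]]
  lam <- mvH(psi)
  energy <- Re(sum(Conj(psi) * lam))
  grad <- numeric(N)
  phi <- lam
  for (k in rev(seq_len(N))) {
    P <- newPauliSum(ops$x[k], ops$z[k], complex(real = 1), n)
    # d/dtheta_k e^{i theta P} = iP e^{i theta P}
    grad[k] <- 2 * Re(sum(Conj(phi) * (1i * pauliApply(P, psis[[k + 1L]]))))
    # pull phi back through U_k^dagger = e^{-i theta P}
    phi <- cos(theta[k]) * phi - 1i * sin(theta[k]) * pauliApply(P, phi)
  }
  list(energy = energy, grad = grad)
}

#' Parameter-shift gradient of an ansatz energy
#'
#' The hardware evaluation path: for generators with \eqn{P^2 = I},
#' \eqn{\partial_{\theta_k} E = E(\theta_k + \pi/4) - E(\theta_k - \pi/4)}.
#'
#' @param H PauliSum
#' @param ref reference statevector
#' @param ops list(x =, z =) mask vectors of the ansatz generators
#' @param theta parameter vector
#' @return numeric gradient vector
#' @export
parameterShiftGradient <- function(H, ref, ops, theta) {
  vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + pi / 4
    tm <- theta; tm[k] <- tm[k] - pi / 4
    pauliExpectation(H, .ansatzState(ref, ops, tp)) -
      pauliExpectation(H, .ansatzState(ref, ops, tm))
  }, numeric(1))
}

#' Adaptive ansatz construction (hardware-aware qubit-ADAPT)
#'
#' Iterates: score every pool element by the magnitude of its energy
#' gradient (optionally multiplied by the hardware [biasFactor()] of the
#' would-be circuit), append the best, re-optimize all parameters by BFGS
#' on the exact statevector, repeat until the pool-gradient l1-norm falls
#' below \code{gradTol} or \code{maxCycles} is hit.  On a zero-gradient
#' plateau all parameters are perturbed once (fixed seed) and scoring is
#' retried before declaring convergence.
#'
#' @param H PauliSum on the reduced register
#' @param pool PauliSum of pool operators (see [buildQubitPool()])
#' @param reference reference statevector (default Hartree-Fock-like basis
#'   state |0...0> unless given)
#' @param target optional weightedGraph; enables hardware-aware scoring
#' @param maxDepth,bias bias configuration (Algorithm-2 depth D and
#'   strength b)
#' @param maxCycles,gradTol stopping controls
#' @param seed seed for the plateau perturbation
#' @return list: ops (masks), theta, energy, trace (per-cycle energies),
#'   gradL1 (per-cycle pool-gradient l1-norms), circuit (compiled
#'   QuantumCircuit)
#' @export
adaptRun <- function(H, pool, reference = NULL, target = NULL,
                     maxDepth = 2L, bias = 1, maxCycles = 50L,
                     gradTol = 1e-3, seed = 1L) {
  n <- H@nQubits
  d <- 2^n
  if (is.null(reference)) {
    reference <- complex(length.out = d)
    reference[1L] <- 1 + 0i
  }
  op <- pauliMatvecOperator(H)
  mvH <- function(v) op$matvec(v)
  ops <- list(x = integer(0), z = integer(0))
  theta <- numeric(0)
  trace <- numeric(0); gradL1 <- numeric(0)
  poolStr <- pauliStrings(pool)
  cnotCost <- vapply(seq_len(nTerms(pool)), function(t) {
    s <- bitCount(bitwOr(pool@x[t], pool@z[t]))
    max(0L, 2L * (s - 1L))
  }, integer(1))
  perturbed <- FALSE
  for (cyc in seq_len(maxCycles + 1L)) {
    psi <- .ansatzState(reference, ops, theta)
    Hpsi <- mvH(psi)
    energy <- Re(sum(Conj(psi) * Hpsi))
    grads <- vapply(seq_len(nTerms(pool)), function(t)
      poolGradient(H, psi, pool@x[t], pool@z[t], Hpsi = Hpsi), numeric(1))
    l1 <- sum(abs(grads))
    if (l1 < gradTol) {
      if (!perturbed && length(theta)) {
        set.seed(as.integer(seed))
        theta <- theta + 1e-3 * stats::rnorm(length(theta))
        perturbed <- TRUE
        next
      }
      break
    }
    if (cyc > maxCycles) break
    gradL1 <- c(gradL1, l1)
    # score: |gradient| x bias factor (lazy, in descending-|grad| order)
    ordg <- order(-abs(grads), cnotCost, poolStr)
    bestScore <- -Inf; bestIdx <- NA_integer_
    for (t in ordg) {
      if (abs(grads[t]) <= bestScore) break
      fac <- 1
      if (!is.null(target)) {
        cand <- .compiledAnsatz(n, ops, theta, pool@x[t], pool@z[t])
        fac <- biasFactor(circuitGraph(cand), target,
                          maxDepth = maxDepth, bias = bias)
      }
      sc <- abs(grads[t]) * fac
      if (sc > bestScore + 1e-15) {
        bestScore <- sc; bestIdx <- t
      }
    }
    if (!is.finite(bestScore)) break
    if (bestScore <= 0) bestIdx <- ordg[1L]  # no embedding anywhere: fall
                                             # back to the plain gradient
    ops$x <- c(ops$x, pool@x[bestIdx])
    ops$z <- c(ops$z, pool@z[bestIdx])
    theta <- c(theta, 0)
    fit <- stats::optim(theta, fn = function(th)
      .ansatzEnergyGrad(mvH, reference, ops, th)$energy,
      gr = function(th) .ansatzEnergyGrad(mvH, reference, ops, th)$grad,
      method = "BFGS",
      control = list(maxit = 200L, reltol = 1e-12))
    theta <- fit$par
    trace <- c(trace, fit$value)
  }
  circ <- .compiledAnsatz(n, ops, theta)
  list(ops = ops, theta = theta,
       energy = if (length(trace)) trace[length(trace)] else
         Re(sum(Conj(reference) * mvH(reference))),
       trace = trace, gradL1 = gradL1, circuit = circ)
}

## compile reference-preparing ansatz circuit (PauliRot gates expanded)
.compiledAnsatz <- function(n, ops, theta, extraX = NULL, extraZ = NULL) {
  circ <- quantumCircuit(n)
  for (k in seq_along(theta)) {
    sub <- compileExponential(ops$x[k], ops$z[k], theta[k], n)
    circ@gates <- c(circ@gates, sub@gates)
  }
  if (!is.null(extraX)) {
    sub <- compileExponential(extraX, extraZ, 0.1, n)
    circ@gates <- c(circ@gates, sub@gates)
  }
  circ
}
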