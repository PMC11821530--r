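#' @include noncontextual.R
NULL

# Contextual-subspace stabilizer selection and projection.  Stabilizers are
# drawn from the span of the noncontextual symmetry generators G (eigenvalues
# fixed by the classical ground assignment q); when the requested reduction
# exceeds |G|, the anticommuting-clique degree of freedom supplies one more
# stabilizer: a sequence of exact (non-Clifford) Pauli rotations maps
# sum_i r_i A_i onto a single clique representative, which is then enforced
# with eigenvalue +1.

## fast Walsh-Hadamard transform of a length-2^k vector
.fwht <- function(v) {
  n <- length(v)
  h <- 1L
  while (h < n) {
    idx <- seq(0L, n - 1L)
    sel <- bitwAnd(idx, h) == 0L
    a <- idx[sel] + 1L
    b <- a + h
    va <- v[a]; vb <- v[b]
    v[a] <- va + vb
    v[b] <- va - vb
    h <- h * 2L
  }
  v
}

#' Select contextual-subspace stabilizers
#'
#' Chooses k = nQubits - nq independent stabilizers from the span of the
#' noncontextual symmetry generators, scored against a guide operator (the
#' Jordan-Wigner image of the MP2 or CCSD excitation generator).  A guide
#' term survives the subsequent projection only when it commutes with every
#' chosen stabilizer, so the selection maximizes the retained guide weight.
#'
#' Strategies:
#' \describe{
#'   \item{significance}{(default; requires the diagonal noncontextual
#'     model) guide terms are grouped by X-mask and visited in decreasing
#'     weight; the retained X-space is grown greedily up to rank nq, always
#'     protecting the heaviest excitations exactly.  The stabilizers are the
#'     Z-parity operators orthogonal to that space.}
#'   \item{weight}{nested greedy over the whole generator span, each step
#'     adding the span element that maximizes the total retained guide
#'     l1-norm (evaluated for all 2^|G| candidates at once with a
#'     Walsh-Hadamard transform).  Nested: the choice for nq is a prefix of
#'     the choice for nq' < nq.}
#'   \item{weight-refine}{the weight greedy followed by coordinate-ascent
#'     refinement (each chosen stabilizer re-optimized with the others
#'     fixed).}
#' }
#'
#' Sector fixing: \code{sector = "reference"} (default) takes stabilizer
#' eigenvalues as parities of a reference computational-basis occupation
#' (the Hartree-Fock determinant), so the reference state survives the
#' projection; \code{"model"} uses the noncontextual ground assignment q.
#'
#' @param model [NoncontextualModel-class]
#' @param nq target qubit count
#' @param guide PauliSum on the same register (tapered excitation generator)
#' @param strategy "significance", "weight" or "weight-refine"
#' @param sector "reference" or "model"
#' @param reference integer 0/1 occupation per qubit (required for
#'   \code{sector = "reference"})
#' @return list: stabilizers (PauliSum), eigenvalues, score (retained guide
#'   l1), useClique (logical), cliqueIndex
#' @export
selectStabilizers <- function(model, nq, guide,
                              strategy = c("significance", "weight",
                                           "weight-refine"),
                              sector = c("reference", "model"),
                              reference = NULL) {
  strategy <- match.arg(strategy)
  sector <- match.arg(sector)
  gens <- model@generators
  n <- gens@nQubits
  k <- nTerms(gens)
  if (nq < 0L || nq > n) stop("nq outside [0, nQubits]")
  need <- n - nq
  if (strategy == "significance") {
    if (any(gens@x != 0L))
      stop("significance selection requires Z-type generators ",
           "(the diagonal noncontextual model)")
    ch <- .significanceStabilizers(n, nq, guide)
  } else {
    ch <- .weightStabilizers(model, nq, guide,
                             refine = (strategy == "weight-refine"))
  }
  stab <- ch$stabilizers
  ev <- ch$eigenvaluesModel
  if (sector == "reference") {
    if (is.null(reference))
      stop("sector = \'reference\' needs a reference occupation")
    if (any(stab@x != 0L))
      stop("reference-sector fixing requires Z-type stabilizers")
    refMask <- bitsToMask(which(reference == 1L) - 1L)
    ev <- 1 - 2 * bitParity(bitwAnd(stab@z, refMask))
  }
  list(stabilizers = stab, eigenvalues = as.numeric(ev), score = ch$score,
       useClique = ch$useClique, cliqueIndex = ch$cliqueIndex)
}

## significance strategy: grow the retained X-mask space from the heaviest
## guide excitations; stabilizers = Z-parities orthogonal to it
.significanceStabilizers <- function(n, nq, guide) {
  agg <- rowsum(Mod(guide@coeff), guide@x)
  xs <- as.integer(rownames(agg)); ws <- agg[, 1L]
  o <- order(-ws, xs)
  basis <- NULL
  if (nq > 0L) {
    for (xm in xs[o]) {
      if (xm == 0L) next
      cand <- rbind(basis, .maskBitMatrix(xm, n))
      if (gf2Rref(cand)$rank > nq) next
      basis <- cand
      if (gf2Rref(basis)$rank == nq) break
    }
    # the guide X-space may not span nq dimensions (parity constraints);
    # pad with coordinate directions so exactly n - nq parities remain
    if (!is.null(basis) && gf2Rref(basis)$rank < nq) {
      for (q in seq_len(n)) {
        unit <- integer(n); unit[q] <- 1L
        cand <- rbind(basis, unit)
        if (gf2Rref(cand)$rank > gf2Rref(basis)$rank) basis <- cand
        if (gf2Rref(basis)$rank == nq) break
      }
    }
  }
  W <- if (is.null(basis)) diag(1L, n) else gf2Kernel(gf2Rref(basis)$mat)
  zm <- .bitsMatrixToMask(W)
  zm <- zm[zm != 0L]
  k <- length(zm)
  if (k != n - nq)
    stop("significance search produced ", k, " stabilizers, expected ",
         n - nq, " (guide too sparse for this register)")
  retained <- if (is.null(basis)) guide@x == 0L else {
    vapply(seq_len(nTerms(guide)), function(t) {
      a <- gf2SolveRow(basis, .maskBitMatrix(guide@x[t], n)[1L, ])
      !is.null(a)
    }, logical(1))
  }
  list(stabilizers = newPauliSum(rep(0L, k), zm,
                                 rep(complex(real = 1), k), n),
       eigenvaluesModel = rep(1, k),   # overwritten by sector fixing
       score = sum(Mod(guide@coeff)[retained]),
       useClique = FALSE, cliqueIndex = NA_integer_)
}

## weight strategy: WHT-scored greedy over the generator span (+ optional
## clique stabilizer when the span cannot supply the requested reduction)
.weightStabilizers <- function(model, nq, guide, refine = FALSE) {
  gens <- model@generators
  n <- gens@nQubits
  k <- nTerms(gens)
  need <- n - nq
  useClique <- FALSE
  if (need > k) {
    if (need > k + 1L || length(model@cliques) == 0L)
      stop("requested reduction exceeds the stabilizer supply (|G| = ",
           k, ", need ", need, ")")
    useClique <- TRUE
    need <- need - 1L
  }
  if (need == 0L && !useClique) {
    return(list(stabilizers = pauliSum(nQubits = n),
                eigenvaluesModel = numeric(0), score = l1Norm(guide),
                useClique = FALSE, cliqueIndex = NA_integer_))
  }
  nt <- nTerms(guide)
  pat <- integer(nt)
  for (i in seq_len(k)) {
    anti <- bitParity(bitwAnd(guide@x, gens@z[i])) !=
            bitParity(bitwAnd(guide@z, gens@x[i]))
    pat <- pat + bitwShiftL(as.integer(anti), i - 1L)
  }
  w <- Mod(guide@coeff)
  wVec <- numeric(2^k)
  agg <- rowsum(w, pat)
  wVec[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  chosen <- integer(0)
  spanOf <- function(sel) {
    s <- 0L
    for (a in sel) s <- unique(as.integer(outer(s, c(0L, a), bitwXor)))
    s
  }
  scoreGiven <- function(sel) {
    keep <- rep(TRUE, length(wVec))
    pi0 <- 0:(2^k - 1L)
    for (a in sel) keep <- keep & (bitParity(bitwAnd(pi0, a)) == 0L)
    sum(wVec[keep])
  }
  stepBest <- function(sel) {
    wr <- wVec
    pi0 <- 0:(2^k - 1L)
    for (a in sel) wr[bitParity(bitwAnd(pi0, a)) == 1L] <- 0
    Wh <- .fwht(wr)
    sc <- (sum(wr) + Wh) / 2
    sc[spanOf(sel) + 1L] <- -Inf
    best <- which.max(sc)   # ties: smallest generator-combination index
    list(a = best - 1L, score = sc[best])
  }
  for (m in seq_len(need)) chosen <- c(chosen, stepBest(chosen)$a)
  if (refine && need > 1L && k <= 16L) {
    repeat {
      improved <- FALSE
      for (j in seq_along(chosen)) {
        st <- stepBest(chosen[-j])
        if (st$score > scoreGiven(chosen) + 1e-12) {
          chosen <- c(chosen[-j], st$a)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  sx <- integer(0); sz <- integer(0); ev <- numeric(0)
  for (a0 in chosen) {
    a <- as.integer(bitwAnd(bitwShiftR(a0, 0:(k - 1L)), 1L))
    pr <- .generatorProduct(gens, a)
    sx <- c(sx, pr$x); sz <- c(sz, pr$z)
    ev <- c(ev, prod(model@q[a == 1L]) * pr$phase)
  }
  list(stabilizers = newPauliSum(sx, sz, rep(complex(real = 1),
                                             length(sx)), n),
       eigenvaluesModel = ev, score = scoreGiven(chosen),
       useClique = useClique,
       cliqueIndex = if (useClique) which.max(abs(model@r)) else
         NA_integer_)
}

#' Apply a general-angle Pauli rotation to a PauliSum
#'
#' Conjugation \eqn{e^{i\theta P} H e^{-i\theta P}}: terms commuting with P
#' pass through; anticommuting terms map to
#' \eqn{\cos(2\theta) Q + i \sin(2\theta) P Q}.
#'
#' @param H PauliSum
#' @param px,pz masks of the Hermitian Pauli P (unit coefficient)
#' @param theta rotation angle
#' @return PauliSum
#' @export
applyPauliRotation <- function(H, px, pz, theta) {
  n <- H@nQubits
  anti <- bitParity(bitwAnd(H@x, pz)) != bitParity(bitwAnd(H@z, px))
  if (!any(anti)) return(H)
  P <- newPauliSum(px, pz, complex(real = 1), n)
  Qa <- H[which(anti)]
  PQ <- pauliProduct(P, Qa, canonical = FALSE)
  out <- newPauliSum(c(H@x[!anti], Qa@x, PQ@x),
                     c(H@z[!anti], Qa@z, PQ@z),
                     c(H@coeff[!anti], cos(2 * theta) * Qa@coeff,
                       1i * sin(2 * theta) * PQ@coeff), n)
  canonicalize(out)
}

## Unitary-partitioning rotation schedule mapping sum_i r_i A_i -> A_target.
## Sequential two-plane rotations; returns list of (px, pz, theta).
.upRotationSchedule <- function(model, target) {
  reps <- model@cliqueReps
  r <- model@r
  m <- length(r)
  rot <- list()
  rcur <- r
  for (j in seq_len(m)) {
    if (j == target || abs(rcur[j]) < 1e-14) next
    # plane rotation (target, j): generator P = i A_j A_target
    # (unit-coefficient representatives; reps carry Hamiltonian coefficients)
    n <- reps@nQubits
    Aj <- newPauliSum(reps@x[j], reps@z[j], complex(real = 1), n)
    At <- newPauliSum(reps@x[target], reps@z[target], complex(real = 1), n)
    PR <- pauliProduct(Aj, At, canonical = FALSE)
    ph <- 1i * PR@coeff[1L]
    if (abs(Im(ph)) > 1e-12) stop("clique representatives not anticommuting")
    # with P = sign * W: rotation by theta maps
    # r_t A_t + r_j A_j -> (c r_t + s' r_j) A_t + (c r_j - s' r_t) A_j
    sgn <- Re(ph)
    theta <- 0.5 * atan2(rcur[j] * sgn, rcur[target])
    # choose theta halved because conjugation doubles the angle
    rot[[length(rot) + 1L]] <- list(px = PR@x[1L], pz = PR@z[1L],
                                    theta = theta)
    rt <- rcur[target]; rj <- rcur[j]
    c2 <- cos(2 * theta); s2 <- sin(2 * theta) * sgn
    rcur[target] <- c2 * rt + s2 * rj
    rcur[j] <- c2 * rj - s2 * rt
  }
  list(rotations = rot, finalR = rcur)
}

#' Project a Hamiltonian into a contextual subspace
#'
#' Enforces the chosen stabilizers with their noncontextual eigenvalues:
#' optional unitary-partitioning rotations (for the clique stabilizer), then
#' Clifford reduction of every stabilizer to a single-qubit Z, sign
#' substitution, and qubit removal.  Terms anticommuting with a stabilizer
#' are annihilated by the projector.
#'
#' @param H PauliSum (the tapered Hamiltonian)
#' @param choice result of [selectStabilizers()]
#' @param model [NoncontextualModel-class]
#' @return list: H (reduced PauliSum), record (rotation bookkeeping allowing
#'   replay on other operators via [replayProjection()])
#' @export
projectToSubspace <- function(H, choice, model) {
  n <- H@nQubits
  record <- list(up = list(), cliffords = NULL, targets = integer(0),
                 eigenvalues = numeric(0), nIn = n)
  stab <- choice$stabilizers
  ev <- choice$eigenvalues
  if (choice$useClique) {
    sched <- .upRotationSchedule(model, choice$cliqueIndex)
    for (ro in sched$rotations) {
      H <- applyPauliRotation(H, ro$px, ro$pz, ro$theta)
    }
    record$up <- sched$rotations
    At <- model@cliqueReps[choice$cliqueIndex]
    stab <- newPauliSum(c(stab@x, At@x), c(stab@z, At@z),
                        rep(complex(real = 1), nTerms(stab) + 1L), n)
    sgn <- sign(sched$finalR[choice$cliqueIndex])
    ev <- c(ev, sgn)
  }
  if (nTerms(stab) == 0L) {
    return(list(H = H, record = record))
  }
  rot <- .stabilizerRotations(stab, values = ev)
  Hr <- applyCliffordRotations(H, rot$rotations)
  Hp <- .projectQubits(Hr, rot$targets, rot$zEigenvalues)
  record$cliffords <- rot$rotations
  record$targets <- rot$targets
  record$eigenvalues <- rot$zEigenvalues
  list(H = Hp, record = record)
}

#' Replay a subspace projection on another operator
#'
#' Applies the rotations and qubit removals recorded by
#' [projectToSubspace()] to an arbitrary operator on the original register
#' (terms anticommuting with a fixed stabilizer are dropped).
#'
#' @param op PauliSum
#' @param record the \code{record} element returned by [projectToSubspace()]
#' @return PauliSum on the reduced register
#' @export
replayProjection <- function(op, record) {
  for (ro in record$up) op <- applyPauliRotation(op, ro$px, ro$pz, ro$theta)
  if (!is.null(record$cliffords))
    op <- applyCliffordRotations(op, record$cliffords)
  if (length(record$targets))
    op <- .projectQubits(op, record$targets, record$eigenvalues)
  op
}

#' Taper an arbitrary operator with a previously fixed sector
#'
#' Same mechanics as [taperHamiltonian()] without the termwise commutation
#' contract: operator terms that anticommute with a sector stabilizer are
#' projected away (used for excitation-generator guides).
#'
#' @param op PauliSum
#' @param sector [SymmetrySector-class]
#' @return PauliSum on the reduced register
#' @export
taperOperator <- function(op, sector) {
  if (nTerms(sector@generators) == 0L) return(op)
  opr <- applyCliffordRotations(op, sector@rotations)
  .projectQubits(opr, sector@targetQubits, sector@eigenvalues)
}

#' Exact (direct-diagonalization) energy of a reduced Hamiltonian
#'
#' The noise-free ceiling of contextual-subspace VQE: the lowest eigenvalue
#' of the projected Hamiltonian.
#'
#' @param Hred PauliSum on the reduced register
#' @param v0 optional start vector for the iterative eigensolver (a
#'   projected reference state accelerates convergence on large registers)
#' @return energy (Hartree)
#' @export
csddEnergy <- function(Hred, v0 = NULL) {
  if (Hred@nQubits == 0L) return(Re(identityCoeff(Hred)))
  groundEnergyExact(Hred, v0 = v0)
}

#' One-call contextual-subspace reduction
#'
#' Splits off the noncontextual component, selects stabilizers against the
#' guide, and projects the Hamiltonian to \code{nq} qubits.
#'
#' @param H tapered PauliSum
#' @param guide tapered excitation-generator PauliSum (MP2 or CCSD)
#' @param nq target qubit count
#' @param model optional precomputed [NoncontextualModel-class]
#' @param reference 0/1 occupation per qubit for the reference sector
#'   (Hartree-Fock determinant); required for \code{sector = "reference"}
#' @param strategy,sector passed to [selectStabilizers()]
#' @param ncStrategy noncontextual split strategy (see
#'   [selectNoncontextual()])
#' @return list: H (reduced PauliSum), choice, record, model
#' @export
contextualSubspace <- function(H, guide, nq, model = NULL, reference = NULL,
                               strategy = "significance",
                               sector = "reference",
                               ncStrategy = "diagonal") {
  if (is.null(model)) {
    model <- solveNoncontextual(selectNoncontextual(H, strategy = ncStrategy))
  }
  choice <- selectStabilizers(model, nq, guide, strategy = strategy,
                              sector = sector, reference = reference)
  pr <- projectToSubspace(H, choice, model)
  list(H = pr$H, choice = choice, record = pr$record, model = model)
}
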