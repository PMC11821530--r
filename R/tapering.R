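#' @include pauli.R
NULL

# Z2-symmetry qubit tapering through stabilizer subspace projection: find the
# kernel of the Hamiltonian's binary symplectic matrix over GF(2), fix the
# symmetry sector from a reference computational-basis state, rotate each
# generator onto a distinct single-qubit Z with pi/2 Clifford rotations, and
# project that qubit out.

#' Find Z2 symmetry generators of a PauliSum
#'
#' Returns a maximal independent set of Pauli operators (excluding identity)
#' that commute with every term of \code{H}, found as the GF(2) kernel of the
#' binary symplectic matrix.  The basis is reduced so that as many generators
#' as possible are Z-type, and ordered deterministically.
#'
#' @param H PauliSum
#' @return PauliSum whose terms (unit coefficient) are the generators
#' @export
findSymmetryGenerators <- function(H) {
  n <- H@nQubits
  # constraint per term t: x_t . z_g + z_t . x_g = 0 (mod 2)
  # unknown vector (z_g | x_g); matrix rows (x_t | z_t)
  rows <- cbind(.maskBitMatrix(H@x, n), .maskBitMatrix(H@z, n))
  ker <- gf2Kernel(rows)
  if (nrow(ker) == 0L) return(pauliSum(nQubits = n))
  zg <- ker[, seq_len(n), drop = FALSE]
  xg <- ker[, n + seq_len(n), drop = FALSE]
  # prefer Z-type: eliminate X parts across generators where possible
  ord <- order(rowSums(xg))
  zg <- zg[ord, , drop = FALSE]; xg <- xg[ord, , drop = FALSE]
  # Gaussian sweep on the x-block to zero X-support of later generators
  nr <- nrow(xg)
  for (r in seq_len(nr)) {
    piv <- which(xg[r, ] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L]
    for (r2 in seq_len(nr)) {
      if (r2 != r && xg[r2, piv] == 1L) {
        xg[r2, ] <- (xg[r2, ] + xg[r, ]) %% 2L
        zg[r2, ] <- (zg[r2, ] + zg[r, ]) %% 2L
      }
    }
  }
  xm <- .bitsMatrixToMask(xg)
  zm <- .bitsMatrixToMask(zg)
  keep <- !(xm == 0L & zm == 0L)
  o <- order(xm[keep] != 0L, zm[keep], xm[keep])
  newPauliSum(xm[keep][o], zm[keep][o],
              rep(complex(real = 1), sum(keep)), n)
}

## mask vector -> 0/1 matrix (terms x n)
.maskBitMatrix <- function(m, n) {
  out <- matrix(0L, length(m), n)
  for (j in seq_len(n)) {
    out[, j] <- bitwAnd(bitwShiftR(m, j - 1L), 1L)
  }
  out
}

.bitsMatrixToMask <- function(B) {
  n <- ncol(B)
  as.integer(B %*% bitwShiftL(1L, 0:(n - 1L)))
}

#' Select the symmetry sector of a reference determinant
#'
#' Computes the eigenvalue of each (Z-type) generator in the computational
#' basis state given by \code{occupation} (1 = occupied under the JW
#' convention) and assembles the Clifford rotations that reduce each
#' generator to a distinct single-qubit Z.  The stored eigenvalues are those
#' of the rotated single-qubit Z stabilizers, ready for projection.
#'
#' @param generators PauliSum from [findSymmetryGenerators()]
#' @param occupation integer 0/1 vector, one entry per qubit
#' @return [SymmetrySector-class]
#' @export
selectSector <- function(generators, occupation) {
  n <- generators@nQubits
  occMask <- bitsToMask(which(occupation == 1L) - 1L)
  k <- nTerms(generators)
  eig <- numeric(k)
  for (t in seq_len(k)) {
    if (generators@x[t] != 0L)
      stop("sector selection requires Z-type generators; generator ", t,
           " has X support (its expectation vanishes in a basis state)")
    eig[t] <- 1 - 2 * bitParity(bitwAnd(generators@z[t], occMask))
  }
  rot <- .stabilizerRotations(generators, values = eig)
  new("SymmetrySector", generators = rot$gens,
      eigenvalues = rot$zEigenvalues,
      rotations = rot$rotations, targetQubits = rot$targets)
}

## Build rotations e^{i pi/4 P} mapping each stabilizer onto a distinct
## single-qubit Z.  Each generator is first transformed into the current
## rotated frame (where earlier generators are single-qubit Zs), its support
## on earlier target qubits is cleared by multiplying with those Zs (folding
## their eigenvalues into its own), and the remainder is reduced with at most
## two fresh rotations.  Tracks the eigenvalue of every resulting Z.
.stabilizerRotations <- function(gens, values = NULL) {
  n <- gens@nQubits
  k <- nTerms(gens)
  vals <- if (is.null(values)) rep(1, k) else values
  zEig <- numeric(k)
  rotX <- integer(0); rotZ <- integer(0)
  targets <- integer(0)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (t in seq_len(k)) {
    curx <- gens@x[t]; curz <- gens@z[t]
    v <- vals[t]
    # transform into the current frame
    for (ri in seq_along(rotX)) {
      res <- .applyRotationTerm(newPauliSum(curx, curz, complex(real = 1), n),
                                rotX[ri], rotZ[ri])
      v <- v * Re(res@coeff[1L])
      curx <- res@x[1L]; curz <- res@z[1L]
    }
    # clear support on established target qubits (component is I or Z there
    # because the transformed stabilizers still commute)
    for (s in seq_len(t - 1L)) {
      b <- bitwShiftL(1L, targets[s])
      if (bitwAnd(curx, b) != 0L)
        stop("stabilizer set is not mutually commuting")
      if (bitwAnd(curz, b) != 0L) {
        pr <- pauliProduct(newPauliSum(curx, curz, complex(real = 1), n),
                           newPauliSum(0L, b, complex(real = 1), n),
                           canonical = FALSE)
        phi <- Re(pr@coeff[1L])
        v <- v * zEig[s] * phi
        curx <- pr@x[1L]; curz <- pr@z[1L]
      }
    }
    sup <- bitwOr(curx, curz)
    if (sup == 0L) stop("stabilizer ", t, " is dependent on earlier ones")
    if (curx == 0L && bitCount(curz) == 1L) {
      # already a single-qubit Z: no rotation needed
      zEig[t] <- v
      targets <- c(targets, which(bitwAnd(curz, bits) != 0L) - 1L)
      next
    }
    avail <- setdiff(which(bitwAnd(sup, bits) != 0L) - 1L, targets)
    if (length(avail) == 0L) stop("no free qubit to host stabilizer ", t)
    xsup <- intersect(which(bitwAnd(curx, bits) != 0L) - 1L, avail)
    q <- if (length(xsup)) xsup[1L] else avail[1L]
    zb <- bitwShiftL(1L, q)
    applyRot <- function(bx, bz) {
      pr <- pauliProduct(newPauliSum(curx, curz, complex(real = 1), n),
                         newPauliSum(bx, bz, complex(real = 1), n),
                         canonical = FALSE)
      rotX <<- c(rotX, pr@x[1L]); rotZ <<- c(rotZ, pr@z[1L])
      res <- .applyRotationTerm(newPauliSum(curx, curz, complex(real = 1), n),
                                pr@x[1L], pr@z[1L])
      v <<- v * Re(res@coeff[1L])
      curx <<- res@x[1L]; curz <<- res@z[1L]
    }
    if (bitwAnd(curx, zb) == 0L) applyRot(zb, zb)   # g -> +-Y_q
    if (!(curx == 0L && curz == zb)) applyRot(0L, zb)  # g -> +-Z_q
    if (!(curx == 0L && curz == zb))
      stop("stabilizer failed to reduce to a single Z")
    zEig[t] <- v
    targets <- c(targets, q)
  }
  list(gens = gens,
       rotations = newPauliSum(rotX, rotZ,
                               rep(complex(real = 1), length(rotX)), n),
       targets = targets, zEigenvalues = zEig)
}

## apply e^{i pi/4 P} . Q . e^{-i pi/4 P}: Q if [P,Q]=0 else i P Q
.applyRotationTerm <- function(Q, px, pz) {
  anti <- bitParity(bitwAnd(Q@x, pz)) != bitParity(bitwAnd(Q@z, px))
  if (!any(anti)) return(Q)
  P <- newPauliSum(px, pz, complex(real = 1), Q@nQubits)
  rotated <- 1i * pauliProduct(P, Q[which(anti)], canonical = FALSE)
  out <- newPauliSum(c(Q@x[!anti], rotated@x), c(Q@z[!anti], rotated@z),
                     c(Q@coeff[!anti], rotated@coeff), Q@nQubits)
  out
}

#' Apply a sequence of pi/2 Clifford rotations to a PauliSum
#' @param H PauliSum
#' @param rotations PauliSum; each term P effects \eqn{e^{i\pi/4 P}}
#' @return rotated PauliSum
#' @export
applyCliffordRotations <- function(H, rotations) {
  for (t in seq_len(nTerms(rotations))) {
    H <- .applyRotationTerm(H, rotations@x[t], rotations@z[t])
  }
  canonicalize(H)
}

#' Taper qubits from a Hamiltonian
#'
#' Rotates every sector generator onto its target single-qubit Z, replaces
#' that Z by the sector eigenvalue, and drops the qubit.  Terms anticommuting
#' with a stabilizer are annihilated by the projection (they vanish exactly
#' for true symmetries).
#'
#' @param H PauliSum
#' @param sector [SymmetrySector-class] from [selectSector()]
#' @return PauliSum on n - k qubits
#' @export
taperHamiltonian <- function(H, sector) {
  k <- nTerms(sector@generators)
  if (k == 0L) return(H)
  gen <- sector@generators
  cm <- pauliCommutes(H, gen, outer = TRUE)
  if (!all(cm))
    stop("contract violation: sector generator does not commute with H")
  Hr <- applyCliffordRotations(H, sector@rotations)
  .projectQubits(Hr, sector@targetQubits, sector@eigenvalues)
}

## fix qubits q (0-based) of H to eigenvalues s (+-1 for Z_q) and remove them;
## terms with X/Y on a fixed qubit are dropped (projector annihilates them)
.projectQubits <- function(H, qubits, s) {
  n <- H@nQubits
  keepQ <- setdiff(0:(n - 1L), qubits)
  fixMask <- bitsToMask(qubits)
  drop <- bitwAnd(H@x, fixMask) != 0L
  x <- H@x[!drop]; z <- H@z[!drop]; cf <- H@coeff[!drop]
  # sign from Z eigenvalues
  for (i in seq_along(qubits)) {
    b <- bitwShiftL(1L, qubits[i])
    hit <- bitwAnd(z, b) != 0L
    cf[hit] <- cf[hit] * s[i]
    z[hit] <- bitwXor(z[hit], b)
  }
  # compress remaining qubits
  nx <- integer(length(x)); nz <- integer(length(z))
  for (j in seq_along(keepQ)) {
    b <- bitwShiftL(1L, keepQ[j]); nb <- bitwShiftL(1L, j - 1L)
    nx <- nx + nb * (bitwAnd(x, b) != 0L)
    nz <- nz + nb * (bitwAnd(z, b) != 0L)
  }
  canonicalize(newPauliSum(as.integer(nx), as.integer(nz), cf,
                           length(keepQ)))
}

#' Taper a molecular qubit Hamiltonian in the Hartree-Fock sector
#'
#' Convenience wrapper: find symmetry generators, fix the sector from the
#' Hartree-Fock occupation, taper.
#'
#' @param qb result of [buildQubitHamiltonian()]
#' @return list: H (tapered PauliSum), sector, generators, hfOccupation
#'   (reference occupation restricted to the kept qubits)
#' @export
taperMolecularHamiltonian <- function(qb) {
  gens <- findSymmetryGenerators(qb$H)
  sector <- selectSector(gens, qb$hfOccupation)
  Ht <- taperHamiltonian(qb$H, sector)
  keepQ <- setdiff(0:(qb$H@nQubits - 1L), sector@targetQubits)
  list(H = Ht, sector = sector, generators = gens,
       hfOccupation = qb$hfOccupation[keepQ + 1L])
}
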