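#' @include integrals.R
NULL

## Coulomb/exchange builds from the AO ERI tensor
.buildJK <- function(eri, D) {
  nbf <- dim(eri)[1L]
  em <- matrix(eri, nbf * nbf, nbf * nbf)
  J <- matrix(em %*% as.vector(D), nbf, nbf)
  # K_pq = sum_rs (pr|qs) D_rs
  ex <- aperm(eri, c(1L, 3L, 2L, 4L))
  K <- matrix(matrix(ex, nbf * nbf, nbf * nbf) %*% as.vector(D), nbf, nbf)
  list(J = J, K = K)
}

#' Restricted (open-shell) Hartree-Fock
#'
#' Closed-shell RHF with DIIS acceleration; for singlets this is the ROHF
#' solution.  Optionally warm-started from previous-geometry orbitals, which
#' keeps the SCF solution on a continuous branch along a dissociation scan.
#'
#' @param geom [molecularGeometry()]
#' @param ints optional precomputed [aoIntegrals()] result
#' @param guessC optional MO coefficient matrix used as the initial guess
#' @param maxiter,conv iteration cap and energy/density convergence threshold
#' @param levelShift virtual-orbital level shift (Hartree) applied while the
#'   DIIS error is large; helps stretched geometries
#' @param damp density damping factor for the opening iterations (cold starts
#'   only); steers the SCF away from the symmetry-broken saddle that the bare
#'   core guess produces for multiply bonded diatomics
#' @param dampIters number of damped iterations before DIIS takes over
#' @return list with energy (total, Hartree), C (MO coefficients, AO x MO),
#'   eps (canonical MO energies), D (density), ints, nocc, converged
#' @examples
#' hf <- scfRHF(h2Geometry(0.74))
#' hf$energy
#' @export
scfRHF <- function(geom, ints = NULL, guessC = NULL, maxiter = 200L,
                   conv = 1e-10, levelShift = 0, damp = 0.7,
                   dampIters = if (is.null(guessC)) 60L else 0L) {
  if (is.null(ints)) ints <- aoIntegrals(geom)
  nelec <- ints$nelec
  if (nelec %% 2L != 0L)
    stop("restricted SCF requires an even electron count")
  nocc <- nelec %/% 2L
  S <- ints$S
  Hcore <- ints$T + ints$V
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  occD <- function(C) 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  if (is.null(guessC)) {
    Fo <- t(X) %*% Hcore %*% X
    ev <- eigen(Fo, symmetric = TRUE)
    C <- X %*% ev$vectors[, order(ev$values)]
  } else {
    C <- guessC
  }
  D <- occD(C)
  eold <- Inf
  fockList <- list(); errList <- list()
  energy <- NA_real_; converged <- FALSE
  for (it in seq_len(maxiter)) {
    jk <- .buildJK(ints$eri, D)
    F <- Hcore + jk$J - 0.5 * jk$K
    energy <- 0.5 * sum(D * (Hcore + F)) + ints$enuc
    err <- F %*% D %*% S - S %*% D %*% F
    err <- t(X) %*% err %*% X
    errNorm <- max(abs(err))
    # DIIS over the last 8 Fock matrices (held off while damping)
    if (it > dampIters) {
      fockList <- c(fockList, list(F)); errList <- c(errList, list(err))
      if (length(fockList) > 8L) {
        fockList <- fockList[-1L]; errList <- errList[-1L]
      }
    }
    m <- length(fockList)
    Fd <- F
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (aI in seq_len(m)) for (bI in seq_len(m))
        B[aI, bI] <- sum(errList[[aI]] * errList[[bI]])
      B[m + 1L, seq_len(m)] <- B[seq_len(m), m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fd <- Reduce(`+`, Map(`*`, fockList, cf))
      }
    }
    Fo <- t(X) %*% Fd %*% X
    if (errNorm > 1e-2 && levelShift > 0) {
      # shift virtuals in the current MO basis
      Cv <- C[, (nocc + 1L):ncol(C), drop = FALSE]
      Pv <- S %*% tcrossprod(Cv) %*% S
      Fo <- Fo + levelShift * t(X) %*% Pv %*% X
    }
    ev <- eigen(Fo, symmetric = TRUE)
    o <- order(ev$values)
    C <- X %*% ev$vectors[, o]
    eps <- ev$values[o]
    Dn <- occD(C)
    if (it <= dampIters) Dn <- damp * D + (1 - damp) * Dn
    dD <- max(abs(Dn - D))
    D <- Dn
    if (abs(energy - eold) < conv && dD < sqrt(conv) && errNorm < 1e-6) {
      converged <- TRUE
      break
    }
    eold <- energy
  }
  if (!converged)
    warning(sprintf("SCF not fully converged (dE=%.2e)", abs(energy - eold)))
  # canonical orbital energies without level shift
  jk <- .buildJK(ints$eri, D)
  F <- Hcore + jk$J - 0.5 * jk$K
  Fmo <- t(C) %*% F %*% C
  eps <- diag(Fmo)
  energy <- 0.5 * sum(D * (Hcore + F)) + ints$enuc
  sym <- .diatomicSymmetryMOs(F, ints, geom)
  if (!is.null(sym)) {
    C <- sym$C; eps <- sym$eps
    D <- occD(C)
    jk <- .buildJK(ints$eri, D)
    F <- Hcore + jk$J - 0.5 * jk$K
    energy <- 0.5 * sum(D * (Hcore + F)) + ints$enuc
  } else {
    C <- .purifyDegenerate(C, eps, ints)
  }
  list(energy = energy, C = C, eps = eps, D = D, ints = ints, nocc = nocc,
       converged = converged)
}

## Symmetry-adapted canonical orbitals for homonuclear diatomics.  The
## converged Fock matrix is re-diagonalized blockwise in a basis of
## symmetry-adapted linear combinations (sigma_g, sigma_u, and the four pi
## blocks), which zeroes symmetry-violating SCF noise exactly.  The resulting
## MO integrals then vanish identically outside totally symmetric index
## combinations, so the GF(2) kernel of the qubit Hamiltonian exposes the
## full point-group Z2 symmetry content.
.diatomicSymmetryMOs <- function(F, ints, geom) {
  if (length(geom$atoms) != 2L || geom$atoms[1L] != geom$atoms[2L])
    return(NULL)
  if (is.null(ints$aoComp)) return(NULL)
  comp <- ints$aoComp; atomOf <- ints$aoAtom
  nbf <- ints$nbf
  u <- geom$coords[2L, ] - geom$coords[1L, ]
  u <- u / sqrt(sum(u^2))
  # deterministic transverse frame
  t1 <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- t1 - sum(t1 * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2L] * v[3L] - u[3L] * v[2L], u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  # per-atom AO transformation: s kept; p triples -> (p_u, p_v, p_w)
  # assemble SALC matrix W and block labels
  Wcols <- list(); labels <- integer(0)
  sIdx1 <- which(comp == 0L & atomOf == 1L)
  sIdx2 <- which(comp == 0L & atomOf == 2L)
  if (length(sIdx1) != length(sIdx2)) return(NULL)
  pTrip <- function(at) {
    px <- which(comp == 1L & atomOf == at)
    matrix(c(px, px + 1L, px + 2L), nrow = length(px))  # rows: shells
  }
  p1 <- pTrip(1L); p2 <- pTrip(2L)
  addCol <- function(vec, lab) {
    Wcols[[length(Wcols) + 1L]] <<- vec; labels <<- c(labels, lab)
  }
  unit <- function(idx, coefv) {
    out <- numeric(nbf); out[idx] <- coefv; out
  }
  # sigma_g (label 1): s1+s2, p_u(1)-p_u(2); sigma_u (2): s1-s2, p_u(1)+p_u(2)
  for (k in seq_along(sIdx1)) {
    addCol(unit(c(sIdx1[k], sIdx2[k]), c(1, 1)), 1L)
    addCol(unit(c(sIdx1[k], sIdx2[k]), c(1, -1)), 2L)
  }
  for (k in seq_len(nrow(p1))) {
    addCol(unit(c(p1[k, ], p2[k, ]), c(u, -u)), 1L)
    addCol(unit(c(p1[k, ], p2[k, ]), c(u, u)), 2L)
    addCol(unit(c(p1[k, ], p2[k, ]), c(v, v)), 3L)   # pi_u (v)
    addCol(unit(c(p1[k, ], p2[k, ]), c(v, -v)), 4L)  # pi_g (v)
    addCol(unit(c(p1[k, ], p2[k, ]), c(w, w)), 5L)   # pi_u (w)
    addCol(unit(c(p1[k, ], p2[k, ]), c(w, -w)), 6L)  # pi_g (w)
  }
  W <- do.call(cbind, Wcols)
  if (ncol(W) != nbf) return(NULL)
  C <- matrix(0, nbf, nbf); eps <- numeric(nbf)
  pos <- 1L
  for (lab in sort(unique(labels))) {
    sel <- which(labels == lab)
    Wb <- W[, sel, drop = FALSE]
    Sb <- t(Wb) %*% ints$S %*% Wb
    es <- eigen((Sb + t(Sb)) / 2, symmetric = TRUE)
    Xb <- es$vectors %*% diag(1 / sqrt(es$values), nrow = length(sel)) %*%
      t(es$vectors)
    Fb <- Xb %*% t(Wb) %*% F %*% Wb %*% Xb
    ev <- eigen((Fb + t(Fb)) / 2, symmetric = TRUE)
    o <- order(ev$values)
    C[, pos:(pos + length(sel) - 1L)] <- Wb %*% Xb %*% ev$vectors[, o]
    eps[pos:(pos + length(sel) - 1L)] <- ev$values[o]
    pos <- pos + length(sel)
  }
  o <- order(eps)
  C <- C[, o]; eps <- eps[o]
  for (k in seq_len(nbf)) {
    m <- which.max(abs(C[, k]))
    if (C[m, k] < 0) C[, k] <- -C[, k]
  }
  list(C = C, eps = eps)
}

## Deterministic canonical orbitals.  Within each degenerate eigenvalue block
## the SCF eigensolver returns an arbitrary rotation; for linear molecules we
## rotate pi_x / pi_y pairs back onto the Cartesian axes (diagonalising the
## x-character matrix), which keeps the MO integrals sparse and exposes the
## point-group Z2 symmetries to the tapering kernel.  Orbital signs are fixed
## by making the largest-magnitude AO coefficient positive.
.purifyDegenerate <- function(C, eps, ints, tol = 1e-7) {
  if (!is.null(ints$aoComp)) {
    isX <- as.numeric(ints$aoComp == 1L)
    n <- length(eps)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && abs(eps[j + 1L] - eps[i]) < tol) j <- j + 1L
      if (j > i) {
        blk <- i:j
        Cb <- C[, blk, drop = FALSE]
        B <- t(Cb) %*% (isX * Cb)
        ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
        C[, blk] <- Cb %*% ev$vectors[, order(ev$values, decreasing = TRUE)]
      }
      i <- j + 1L
    }
  }
  for (k in seq_len(ncol(C))) {
    m <- which.max(abs(C[, k]))
    if (C[m, k] < 0) C[, k] <- -C[, k]
  }
  C
}

## AO -> MO transform of the ERI tensor, (pq|rs) in MO indices
moERI <- function(eri, C) {
  nbf <- dim(eri)[1L]
  m <- matrix(eri, nbf, nbf^3)
  t1 <- array(crossprod(C, m), c(nbf, nbf, nbf, nbf))
  t1 <- aperm(t1, c(2L, 3L, 4L, 1L))
  t2 <- array(crossprod(C, matrix(t1, nbf, nbf^3)), c(nbf, nbf, nbf, nbf))
  t2 <- aperm(t2, c(2L, 3L, 4L, 1L))
  t3 <- array(crossprod(C, matrix(t2, nbf, nbf^3)), c(nbf, nbf, nbf, nbf))
  t3 <- aperm(t3, c(2L, 3L, 4L, 1L))
  t4 <- array(crossprod(C, matrix(t3, nbf, nbf^3)), c(nbf, nbf, nbf, nbf))
  aperm(t4, c(2L, 3L, 4L, 1L))
}

## one-electron MO integrals
moOne <- function(ints, C) t(C) %*% (ints$T + ints$V) %*% C
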