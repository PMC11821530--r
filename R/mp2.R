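#' @include fci.R
NULL

## minimal einsum for two tensors, e.g. ein("ijab,klab->ijkl", A, B).
## No repeated index within one operand; output indices must come from inputs.
ein <- function(spec, A, B) {
  parts <- strsplit(spec, "->", fixed = TRUE)[[1L]]
  ins <- strsplit(parts[1L], ",", fixed = TRUE)[[1L]]
  la <- strsplit(ins[1L], "")[[1L]]
  lb <- strsplit(ins[2L], "")[[1L]]
  lo <- strsplit(parts[2L], "")[[1L]]
  da <- dim(A) %||% length(A)
  db <- dim(B) %||% length(B)
  contr <- intersect(la, lb)
  contr <- setdiff(contr, lo)
  freeA <- setdiff(la, contr)
  freeB <- setdiff(lb, c(contr, freeA))
  if (!setequal(c(freeA, freeB), lo))
    stop("einsum spec mismatch: ", spec)
  pa <- match(c(freeA, contr), la)
  Ap <- aperm(A, pa)
  dA <- da[pa]
  nfa <- prod(dA[seq_along(freeA)]); nc <- prod(dA[-seq_along(freeA)])
  if (length(freeA) == 0L) { nfa <- 1L; nc <- prod(dA) }
  Am <- matrix(Ap, nfa, nc)
  pb <- match(c(contr, freeB), lb)
  Bp <- aperm(B, pb)
  dB <- db[pb]
  ncb <- prod(dB[seq_along(contr)])
  if (length(contr) == 0L) ncb <- 1L
  Bm <- matrix(Bp, ncb, prod(dB) / ncb)
  Cm <- Am %*% Bm
  dims <- c(dA[seq_along(freeA)], dB[-seq_along(contr)])
  if (length(contr) == 0L) dims <- c(dA, dB)
  out <- array(Cm, dims)
  # permute to requested output order
  cur <- c(freeA, freeB)
  aperm(out, match(lo, cur))
}

## spin-orbital data from a converged RHF: fock diagonal, antisymmetrized
## integrals <pq||rs>, occupied/virtual slicing.  Interleaved ordering
## (alpha0, beta0, alpha1, ...).
spinOrbitalData <- function(hf) {
  M <- hf$ints$nbf
  nso <- 2L * M
  nocc <- 2L * hf$nocc
  g <- moERI(hf$ints$eri, hf$C)    # (pq|rs) spatial
  eps <- rep(hf$eps, each = 2L)
  spat <- rep(seq_len(M), each = 2L)
  spin <- rep(c(0L, 1L), M)
  # <pq|rs> = (pr|qs) delta(sp,sr) delta(sq,ss)
  gso <- array(0, c(nso, nso, nso, nso))
  gchem <- g
  sameSpin <- outer(spin, spin, `==`)
  # build <pq||rs> via spatial lookup
  idx <- seq_len(nso)
  P <- spat[idx]
  dir <- array(0, c(nso, nso, nso, nso))
  exch <- array(0, c(nso, nso, nso, nso))
  # (pr|qs) with spin masks
  dir <- gchem[P, P, P, P]
  dir <- aperm(dir, c(1L, 3L, 2L, 4L))       # now indexed <pq|rs> = (pr|qs)
  m1 <- outer(spin, spin, `==`)              # sp == sr (after aperm: dims p,q,r,s)
  maskD <- ein("pr,qs->pqrs", m1 * 1, m1 * 1)
  dir <- dir * maskD
  exch <- aperm(dir, c(1L, 2L, 4L, 3L))
  gso <- dir - exch
  # reorder so occupied spin orbitals (by orbital energy) come first
  occSel <- order(rep(hf$eps, each = 2L))[seq_len(nocc)]
  oidx <- sort(occSel)
  vidx <- setdiff(idx, oidx)
  perm <- c(oidx, vidx)
  list(nso = nso, nocc = nocc, nvirt = nso - nocc,
       eps = eps[perm], g = gso[perm, perm, perm, perm],
       perm = perm, spat = spat[perm], spin = spin[perm])
}

#' MP2 energy and amplitudes
#'
#' Spin-orbital second-order Moller-Plesset correction on the RHF reference,
#' returning amplitudes (used as the excitation-generator guide for the
#' contextual-subspace stabilizer selection) and the unrelaxed natural-orbital
#' occupation numbers used for CAS active-space selection.
#'
#' @param hf result of [scfRHF()]
#' @param so optional precomputed [spinOrbitalData()]
#' @return list: energy (total), ecorr, t2 (o,o,v,v spin-orbital amplitudes),
#'   noOcc (spatial natural occupations, descending), noCoef (AO x NO
#'   coefficients), so
#' @export
mp2Energy <- function(hf, so = NULL) {
  if (is.null(so)) so <- spinOrbitalData(hf)
  o <- seq_len(so$nocc); v <- so$nocc + seq_len(so$nvirt)
  eo <- so$eps[o]; ev <- so$eps[v]
  Dijab <- outer(eo, eo, `+`)
  Dijab <- outer(Dijab, outer(ev, ev, `+`), `-`)
  g_oovv <- so$g[o, o, v, v, drop = FALSE]
  t2 <- g_oovv / Dijab
  ecorr <- 0.25 * sum(g_oovv * t2)
  # unrelaxed MP2 density (spin-orbital), spatial natural occupations
  no <- so$nocc; nv <- so$nvirt
  rho_oo <- diag(no) - 0.5 * ein("ikab,jkab->ij", t2, t2)
  rho_vv <- 0.5 * ein("ijac,ijbc->ab", t2, t2)
  M <- length(hf$eps)
  rho <- matrix(0, 2L * M, 2L * M)
  rho[o, o] <- rho_oo
  rho[v, v] <- rho_vv
  # undo occupied-first permutation, then sum spin blocks to spatial
  inv <- order(so$perm)
  rho <- rho[inv, inv]
  a <- seq(1L, 2L * M, by = 2L); b <- a + 1L
  rhoSpat <- rho[a, a] + rho[b, b]
  evd <- eigen((rhoSpat + t(rhoSpat)) / 2, symmetric = TRUE)
  ordn <- order(evd$values, decreasing = TRUE)
  noOcc <- evd$values[ordn]
  noCoef <- hf$C %*% evd$vectors[, ordn]
  list(energy = hf$energy + ecorr, ecorr = ecorr, t2 = t2,
       noOcc = noOcc, noCoef = noCoef, so = so)
}
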