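#' @include scf.R
NULL

# Determinant full CI.  The coupling structure between Slater determinants
# (which pairs interact, with which sign and which integral) depends only on
# (norb, nalpha, nbeta); it is computed once, cached, and re-filled with
# integral values per geometry.  This makes a 14400-determinant FCI a
# sparse-matrix fill plus a Lanczos solve.

## all C(norb, nelec) occupation bitmasks, lexicographic
.fciStrings <- function(norb, ne) {
  if (ne == 0L) return(0L)
  cols <- utils::combn(norb, ne)
  as.integer(colSums(matrix(bitwShiftL(1L, cols - 1L), nrow = ne)))
}

## parity of annihilating orbital p (1-based) from mask: (-1)^(#occ below p)
.parityBelow <- function(mask, p) {
  below <- bitwAnd(mask, bitwShiftL(1L, p - 1L) - 1L)
  1L - 2L * bitParity(below)
}

## single-excitation table: I, J (string indices), p, q (1-based orbitals),
## sign;  J = a^dag_q a_p I, p != q
.singleTable <- function(strings, norb) {
  idx <- seq_along(strings)
  lookup <- new.env(parent = emptyenv())
  for (k in idx) lookup[[as.character(strings[k])]] <- k
  out <- vector("list", length(strings))
  for (k in idx) {
    m <- strings[k]
    occ <- which(bitwAnd(m, bitwShiftL(1L, 0:(norb - 1L))) != 0L)
    vir <- setdiff(seq_len(norb), occ)
    rows <- list()
    for (p in occ) for (q in vir) {
      s1 <- .parityBelow(m, p)
      m1 <- bitwXor(m, bitwShiftL(1L, p - 1L))
      s2 <- .parityBelow(m1, q)
      m2 <- bitwOr(m1, bitwShiftL(1L, q - 1L))
      rows[[length(rows) + 1L]] <-
        c(k, lookup[[as.character(m2)]], p, q, s1 * s2)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L || all(vapply(out, is.null, logical(1)))) {
    tab <- matrix(integer(0), 0L, 5L)
  } else {
    tab <- do.call(rbind, out)
  }
  colnames(tab) <- c("I", "J", "p", "q", "s")
  tab
}

## double-excitation table within one spin: I, J, p1<p2 removed, q1<q2 added,
## sign of a^dag_q2 a^dag_q1 a_p1 a_p2  (convention fixed by the JW oracle
## crosscheck in the tests)
.doubleTable <- function(strings, norb) {
  idx <- seq_along(strings)
  lookup <- new.env(parent = emptyenv())
  for (k in idx) lookup[[as.character(strings[k])]] <- k
  out <- list()
  for (k in idx) {
    m <- strings[k]
    occ <- which(bitwAnd(m, bitwShiftL(1L, 0:(norb - 1L))) != 0L)
    vir <- setdiff(seq_len(norb), occ)
    no <- length(occ); nv <- length(vir)
    if (no < 2L || nv < 2L) next
    for (a1 in 1:(no - 1L)) for (a2 in (a1 + 1L):no) {
      p1 <- occ[a1]; p2 <- occ[a2]
      s1 <- .parityBelow(m, p2)
      m1 <- bitwXor(m, bitwShiftL(1L, p2 - 1L))
      s2 <- .parityBelow(m1, p1)
      m2 <- bitwXor(m1, bitwShiftL(1L, p1 - 1L))
      for (b1 in 1:(nv - 1L)) for (b2 in (b1 + 1L):nv) {
        q1 <- vir[b1]; q2 <- vir[b2]
        s3 <- .parityBelow(m2, q1)
        m3 <- bitwOr(m2, bitwShiftL(1L, q1 - 1L))
        s4 <- .parityBelow(m3, q2)
        m4 <- bitwOr(m3, bitwShiftL(1L, q2 - 1L))
        out[[length(out) + 1L]] <-
          c(k, lookup[[as.character(m4)]], p1, p2, q1, q2, s1 * s2 * s3 * s4)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  tab <- do.call(rbind, out)
  colnames(tab) <- c("I", "J", "p1", "p2", "q1", "q2", "s")
  tab
}

## geometry-independent FCI structure, cached by (norb, na, nb)
.fciStructure <- function(norb, na, nb) {
  key <- sprintf("fci_%d_%d_%d", norb, na, nb)
  got <- .csvqe_env[[key]]
  if (!is.null(got)) return(got)
  sa <- .fciStrings(norb, na)
  sb <- .fciStrings(norb, nb)
  Na <- length(sa); Nb <- length(sb)
  occA <- matrix(0, Na, norb)
  for (p in seq_len(norb))
    occA[, p] <- as.numeric(bitwAnd(sa, bitwShiftL(1L, p - 1L)) != 0L)
  occB <- if (na == nb && identical(sa, sb)) occA else {
    m <- matrix(0, Nb, norb)
    for (p in seq_len(norb))
      m[, p] <- as.numeric(bitwAnd(sb, bitwShiftL(1L, p - 1L)) != 0L)
    m
  }
  ssA <- .singleTable(sa, norb)
  ssB <- if (na == nb) ssA else .singleTable(sb, norb)
  ddA <- if (na >= 2L) .doubleTable(sa, norb) else NULL
  ddB <- if (nb >= 2L) { if (na == nb) ddA else .doubleTable(sb, norb) } else NULL

  dets <- function(ia, ib) ia + Na * (ib - 1)   # determinant linear index

  # triplet skeleton: block by block (values filled per geometry)
  blocks <- list()
  # 1. diagonal handled densely, not in triplets
  # 2. alpha singles x beta diagonal
  nA <- nrow(ssA)
  ib <- rep(seq_len(Nb), each = nA)
  ka <- rep(seq_len(nA), times = Nb)
  blocks$aS <- list(i = dets(ssA[ka, "I"], ib), j = dets(ssA[ka, "J"], ib),
                    ka = ka, ib = ib)
  # 3. beta singles x alpha diagonal
  nB <- nrow(ssB)
  ia <- rep(seq_len(Na), each = nB)
  kb <- rep(seq_len(nB), times = Na)
  blocks$bS <- list(i = dets(ia, ssB[kb, "I"]), j = dets(ia, ssB[kb, "J"]),
                    kb = kb, ia = ia)
  # 4. alpha doubles x beta diagonal / beta doubles x alpha diagonal
  if (!is.null(ddA)) {
    nDA <- nrow(ddA)
    ib <- rep(seq_len(Nb), each = nDA)
    kd <- rep(seq_len(nDA), times = Nb)
    blocks$aD <- list(i = dets(ddA[kd, "I"], ib), j = dets(ddA[kd, "J"], ib),
                      kd = kd)
  }
  if (!is.null(ddB)) {
    nDB <- nrow(ddB)
    ia <- rep(seq_len(Na), each = nDB)
    kd <- rep(seq_len(nDB), times = Na)
    blocks$bD <- list(i = dets(ia, ddB[kd, "I"]), j = dets(ia, ddB[kd, "J"]),
                      kd = kd)
  }
  # 5. alpha single x beta single
  ka <- rep(seq_len(nA), times = nB)
  kb <- rep(seq_len(nB), each = nA)
  blocks$SS <- list(i = dets(ssA[ka, "I"], ssB[kb, "I"]),
                    j = dets(ssA[ka, "J"], ssB[kb, "J"]),
                    ka = ka, kb = kb)

  # CSC skeleton: sort triplets once, store permutation
  iAll <- c(blocks$aS$i, blocks$bS$i,
            if (!is.null(blocks$aD)) blocks$aD$i,
            if (!is.null(blocks$bD)) blocks$bD$i, blocks$SS$i)
  jAll <- c(blocks$aS$j, blocks$bS$j,
            if (!is.null(blocks$aD)) blocks$aD$j,
            if (!is.null(blocks$bD)) blocks$bD$j, blocks$SS$j)
  D <- Na * Nb
  ord <- order(jAll * (D + 1) + iAll)
  iSorted <- as.integer(iAll[ord] - 1L)
  pPtr <- c(0L, cumsum(tabulate(jAll, nbins = D)))
  st <- list(norb = norb, na = na, nb = nb, sa = sa, sb = sb,
             Na = Na, Nb = Nb, occA = occA, occB = occB,
             ssA = ssA, ssB = ssB, ddA = ddA, ddB = ddB,
             blocks = blocks, ord = ord, iSorted = iSorted, pPtr = pPtr)
  .csvqe_env[[key]] <- st
  st
}

## spatial-orbital integral helpers for value fill
.fciValues <- function(st, h, g) {
  norb <- st$norb
  # C1[pq, r] = (pq|rr),  X1[pq, r] = (pr|rq)
  pqi <- function(p, q) p + norb * (q - 1L)
  C1 <- matrix(0, norb * norb, norb)
  X1 <- matrix(0, norb * norb, norb)
  for (r in seq_len(norb)) {
    C1[, r] <- as.vector(g[, , r, r])
    X1[, r] <- as.vector(g[, r, r, ])
  }
  Jm <- matrix(0, norb, norb); Km <- matrix(0, norb, norb)
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    Jm[p, q] <- g[p, p, q, q]; Km[p, q] <- g[p, q, q, p]
  }
  hd <- diag(h)
  occA <- st$occA; occB <- st$occB
  # diagonal energies
  ha <- occA %*% hd; hb <- occB %*% hd
  JKa <- 0.5 * rowSums((occA %*% (Jm - Km)) * occA)
  JKb <- 0.5 * rowSums((occB %*% (Jm - Km)) * occB)
  cross <- (occA %*% Jm) %*% t(occB)       # Na x Nb
  diagE <- outer(as.vector(ha + JKa), as.vector(hb + JKb), `+`) + cross

  singleVals <- function(ss, occSame, occOther, flip) {
    p <- ss[, "p"]; q <- ss[, "q"]; s <- ss[, "s"]
    rows <- pqi(p, q)
    base <- h[cbind(p, q)] +
      rowSums(occSame[ss[, "I"], , drop = FALSE] * (C1 - X1)[rows, ,
                                                             drop = FALSE])
    other <- occOther %*% t(C1[rows, , drop = FALSE])  # Nother x nS
    list(base = s * base, other = other * rep(s, each = nrow(other)))
  }
  svA <- singleVals(st$ssA, occA, occB)
  svB <- singleVals(st$ssB, occB, occA)
  doubleVals <- function(dd) {
    p1 <- dd[, "p1"]; p2 <- dd[, "p2"]; q1 <- dd[, "q1"]; q2 <- dd[, "q2"]
    dd[, "s"] * (g[cbind(p1, q1, p2, q2)] - g[cbind(p1, q2, p2, q1)])
  }
  dvA <- if (!is.null(st$ddA)) doubleVals(st$ddA) else NULL
  dvB <- if (!is.null(st$ddB)) doubleVals(st$ddB) else NULL
  # alpha single x beta single
  ssA <- st$ssA; ssB <- st$ssB
  gss <- matrix(g[cbind(rep(ssA[, "p"], times = nrow(ssB)),
                        rep(ssA[, "q"], times = nrow(ssB)),
                        rep(ssB[, "p"], each = nrow(ssA)),
                        rep(ssB[, "q"], each = nrow(ssA)))],
                nrow(ssA), nrow(ssB))
  ssVal <- gss * outer(ssA[, "s"], ssB[, "s"])
  list(diagE = diagE, svA = svA, svB = svB, dvA = dvA, dvB = dvB,
       ssVal = ssVal)
}

## assemble the off-diagonal sparse matrix (values in precomputed CSC order)
.fciSparse <- function(st, vals) {
  b <- st$blocks
  xaS <- vals$svA$base[b$aS$ka] +
    vals$svA$other[cbind(b$aS$ib, b$aS$ka)]
  xbS <- vals$svB$base[b$bS$kb] +
    vals$svB$other[cbind(b$bS$ia, b$bS$kb)]
  xaD <- if (!is.null(b$aD)) vals$dvA[b$aD$kd]
  xbD <- if (!is.null(b$bD)) vals$dvB[b$bD$kd]
  xSS <- vals$ssVal[cbind(b$SS$ka, b$SS$kb)]
  xAll <- c(xaS, xbS, xaD, xbD, xSS)[st$ord]
  D <- st$Na * st$Nb
  new("dgCMatrix", i = st$iSorted, p = st$pPtr, x = xAll,
      Dim = c(D, D))
}

## lowest eigenpair of the CI Hamiltonian given spatial-orbital h and g
## (electronic part; add enuc outside).  hfIndex: determinant to seed Lanczos.
.fciGround <- function(st, h, g, nroots = 1L, vector = FALSE,
                       subspace = NULL) {
  vals <- .fciValues(st, h, g)
  M <- .fciSparse(st, vals)
  dE <- as.vector(vals$diagE)
  if (!is.null(subspace)) {
    M <- M[subspace, subspace, drop = FALSE]
    dE <- dE[subspace]
  }
  D <- length(dE)
  if (D <= 400L) {
    Hd <- as.matrix(M) + diag(dE, nrow = D)
    ev <- eigen(Hd, symmetric = TRUE)
    if (vector) {
      return(list(value = ev$values[D], vector = ev$vectors[, D]))
    }
    return(ev$values[D])
  }
  v0 <- numeric(D)
  v0[which.min(dE)] <- 1
  v0 <- v0 + 1e-3 * cos(1.7 * seq_len(D))
  mv <- function(v) as.vector(M %*% v) + dE * v
  lanczosGround(mv, D, v0 = v0, maxiter = 250L, tol = 1e-12,
                vectors = vector)
}

#' Full configuration interaction energy
#'
#' Determinant FCI in the molecular-orbital basis of a converged SCF.
#'
#' @param hf result of [scfRHF()]
#' @param vector logical, also return the CI vector and determinant strings
#' @return total FCI energy (Hartree), or a list when \code{vector = TRUE}
#' @export
fciEnergy <- function(hf, vector = FALSE) {
  norb <- hf$ints$nbf
  ne <- hf$ints$nelec
  na <- (ne + 1L) %/% 2L; nb <- ne %/% 2L
  st <- .fciStructure(norb, na, nb)
  h <- moOne(hf$ints, hf$C)
  g <- moERI(hf$ints$eri, hf$C)
  res <- .fciGround(st, h, g, vector = vector)
  if (vector) {
    list(energy = res$value + hf$ints$enuc, vector = res$vector, structure = st)
  } else {
    res + hf$ints$enuc
  }
}

#' Configuration interaction with singles and doubles
#'
#' Determinant CISD: the FCI Hamiltonian restricted to determinants at
#' excitation level <= 2 from the Hartree-Fock reference.
#'
#' @param hf result of [scfRHF()]
#' @return total CISD energy (Hartree)
#' @export
cisdEnergy <- function(hf) {
  norb <- hf$ints$nbf
  ne <- hf$ints$nelec
  na <- (ne + 1L) %/% 2L; nb <- ne %/% 2L
  st <- .fciStructure(norb, na, nb)
  refA <- bitwShiftL(1L, na) - 1L
  refB <- bitwShiftL(1L, nb) - 1L
  excA <- na - bitCount(bitwAnd(st$sa, refA))
  excB <- nb - bitCount(bitwAnd(st$sb, refB))
  lev <- outer(excA, excB, `+`)
  sel <- which(as.vector(lev) <= 2L)
  h <- moOne(hf$ints, hf$C)
  g <- moERI(hf$ints$eri, hf$C)
  .fciGround(st, h, g, subspace = sel) + hf$ints$enuc
}
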