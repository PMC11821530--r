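#' @include basis.R
NULL

# McMurchie-Davidson molecular integrals over contracted Cartesian Gaussians,
# s and p shells (all the built-in STO-3G tables need).  All lengths in Bohr,
# energies in Hartree.

## Hermite expansion coefficient E_t^{ij} for one dimension, vectorised over
## primitive pairs.  `a`, `b` exponent vectors, Q = A_d - B_d (scalar).
.hermiteE <- function(i, j, t, Q, a, b) {
  p <- a + b
  if (t < 0L || t > i + j) return(numeric(length(a)))
  if (i == 0L && j == 0L) {
    if (t != 0L) return(numeric(length(a)))
    return(exp(-a * b / p * Q * Q))
  }
  if (i > 0L) {
    xpa <- -b * Q / p
    return(1 / (2 * p) * .hermiteE(i - 1L, j, t - 1L, Q, a, b) +
           xpa * .hermiteE(i - 1L, j, t, Q, a, b) +
           (t + 1) * .hermiteE(i - 1L, j, t + 1L, Q, a, b))
  }
  xpb <- a * Q / p
  1 / (2 * p) * .hermiteE(i, j - 1L, t - 1L, Q, a, b) +
    xpb * .hermiteE(i, j - 1L, t, Q, a, b) +
    (t + 1) * .hermiteE(i, j - 1L, t + 1L, Q, a, b)
}

## Hermite Coulomb integrals R^0_{tuv}(p, PC) for all t+u+v <= L, vectorised
## over rows of PC.  Returns environment-backed memo closure lookup(t,u,v).
.hermiteRTable <- function(L, p, PC) {
  T <- p * rowSums(PC * PC)
  Fm <- boysF(T, L)
  base <- lapply(0:L, function(n) (-2 * p)^n * Fm[, n + 1L])
  memo <- new.env(parent = emptyenv())
  rec <- function(n, t, u, v) {
    if (t < 0L || u < 0L || v < 0L) return(0)
    key <- paste(n, t, u, v)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (t == 0L && u == 0L && v == 0L) {
      base[[n + 1L]]
    } else if (t > 0L) {
      (t - 1) * rec(n + 1L, t - 2L, u, v) + PC[, 1L] * rec(n + 1L, t - 1L, u, v)
    } else if (u > 0L) {
      (u - 1) * rec(n + 1L, t, u - 2L, v) + PC[, 2L] * rec(n + 1L, t, u - 1L, v)
    } else {
      (v - 1) * rec(n + 1L, t, u, v - 2L) + PC[, 3L] * rec(n + 1L, t, u, v - 1L)
    }
    memo[[key]] <- val
    val
  }
  function(t, u, v) rec(0L, t, u, v)
}

## cartesian components of a shell
.shellComps <- function(l) {
  if (l == 0L) list(c(0L, 0L, 0L))
  else list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
}

## per-pair data shared by every integral type
.pairData <- function(sa, sb) {
  na <- length(sa$exps); nb <- length(sb$exps)
  a <- rep(sa$exps, times = nb); b <- rep(sb$exps, each = na)
  ca <- rep(sa$coefs, times = nb); cb <- rep(sb$coefs, each = na)
  p <- a + b
  AB <- sa$center - sb$center
  P <- (outer(a, sa$center) + outer(b, sb$center)) / p
  # E_d[[dim]][[i+1]][[j+1]][[t+1]] vectors over primitive pairs
  lmaxa <- sa$l; lmaxb <- sb$l
  E <- vector("list", 3L)
  for (d in 1:3) {
    Ed <- vector("list", lmaxa + 1L)
    for (i in 0:lmaxa) {
      Ei <- vector("list", lmaxb + 3L)   # extra angular momentum for kinetic
      for (j in 0:(lmaxb + 2L)) {
        Ei[[j + 1L]] <- lapply(0:(i + j), function(t)
          .hermiteE(i, j, t, AB[d], a, b))
      }
      Ed[[i + 1L]] <- Ei
    }
    E[[d]] <- Ed
  }
  list(a = a, b = b, cc = ca * cb, p = p, P = P, E = E)
}

## one-electron integrals: overlap, kinetic, nuclear attraction
oneElectronIntegrals <- function(shells, geom) {
  so <- shellOffsets(shells)
  nbf <- so$nbf
  S <- matrix(0, nbf, nbf); T <- matrix(0, nbf, nbf); V <- matrix(0, nbf, nbf)
  Zs <- .elementZ[geom$atoms]
  centers <- geom$coords * angstrom_to_bohr
  ns <- length(shells)
  for (i in seq_len(ns)) for (j in i:ns) {
    sa <- shells[[i]]; sb <- shells[[j]]
    pd <- .pairData(sa, sb)
    p <- pd$p
    spre <- sqrt(pi / p)
    compA <- .shellComps(sa$l); compB <- .shellComps(sb$l)
    # nuclear Hermite tables per nucleus
    rtabs <- lapply(seq_len(nrow(centers)), function(ic) {
      PC <- pd$P - matrix(centers[ic, ], length(p), 3L, byrow = TRUE)
      .hermiteRTable(sa$l + sb$l, p, PC)
    })
    for (ia in seq_along(compA)) for (jb in seq_along(compB)) {
      la <- compA[[ia]]; lb <- compB[[jb]]
      s1 <- lapply(1:3, function(d)
        pd$E[[d]][[la[d] + 1L]][[lb[d] + 1L]][[1L]] * spre)
      # per-dim overlap with shifted ket angular momentum for kinetic
      sShift <- function(d, dj) {
        jj <- lb[d] + dj
        if (jj < 0L) return(numeric(length(p)))
        pd$E[[d]][[la[d] + 1L]][[jj + 1L]][[1L]] * spre
      }
      tdim <- lapply(1:3, function(d) {
        jj <- lb[d]
        -2 * pd$b^2 * sShift(d, 2L) + pd$b * (2 * jj + 1) * s1[[d]] -
          0.5 * jj * (jj - 1) * sShift(d, -2L)
      })
      sval <- sum(pd$cc * s1[[1L]] * s1[[2L]] * s1[[3L]])
      tval <- sum(pd$cc * (tdim[[1L]] * s1[[2L]] * s1[[3L]] +
                           s1[[1L]] * tdim[[2L]] * s1[[3L]] +
                           s1[[1L]] * s1[[2L]] * tdim[[3L]]))
      # nuclear attraction
      vval <- 0
      for (ic in seq_len(nrow(centers))) {
        rt <- rtabs[[ic]]
        acc <- numeric(length(p))
        for (t in 0:(la[1L] + lb[1L])) for (u in 0:(la[2L] + lb[2L]))
          for (v in 0:(la[3L] + lb[3L])) {
            acc <- acc +
              pd$E[[1L]][[la[1L] + 1L]][[lb[1L] + 1L]][[t + 1L]] *
              pd$E[[2L]][[la[2L] + 1L]][[lb[2L] + 1L]][[u + 1L]] *
              pd$E[[3L]][[la[3L] + 1L]][[lb[3L] + 1L]][[v + 1L]] *
              rt(t, u, v)
          }
        vval <- vval - Zs[ic] * sum(pd$cc * 2 * pi / p * acc)
      }
      r <- so$offsets[i] + ia; c <- so$offsets[j] + jb
      S[r, c] <- S[c, r] <- sval
      T[r, c] <- T[c, r] <- tval
      V[r, c] <- V[c, r] <- vval
    }
  }
  list(S = S, T = T, V = V)
}

## full ERI tensor (chemists' notation (pq|rs)), 8-fold symmetry exploited
twoElectronIntegrals <- function(shells) {
  so <- shellOffsets(shells)
  nbf <- so$nbf
  eri <- array(0, c(nbf, nbf, nbf, nbf))
  ns <- length(shells)
  pairs <- list()
  for (i in seq_len(ns)) for (j in i:ns) {
    pairs[[length(pairs) + 1L]] <- list(i = i, j = j,
                                        pd = .pairData(shells[[i]],
                                                       shells[[j]]))
  }
  np <- length(pairs)
  for (ibra in seq_len(np)) for (iket in ibra:np) {
    bra <- pairs[[ibra]]; ket <- pairs[[iket]]
    sa <- shells[[bra$i]]; sb <- shells[[bra$j]]
    sc <- shells[[ket$i]]; sd <- shells[[ket$j]]
    pdb <- bra$pd; pdk <- ket$pd
    nb <- length(pdb$p); nk <- length(pdk$p)
    ib <- rep(seq_len(nb), times = nk); ik <- rep(seq_len(nk), each = nb)
    p <- pdb$p[ib]; q <- pdk$p[ik]
    alpha <- p * q / (p + q)
    PQ <- pdb$P[ib, , drop = FALSE] - pdk$P[ik, , drop = FALSE]
    Ltot <- sa$l + sb$l + sc$l + sd$l
    rt <- .hermiteRTable(Ltot, alpha, PQ)
    pref <- 2 * pi^2.5 / (p * q * sqrt(p + q)) * pdb$cc[ib] * pdk$cc[ik]
    compA <- .shellComps(sa$l); compB <- .shellComps(sb$l)
    compC <- .shellComps(sc$l); compD <- .shellComps(sd$l)
    for (ca in seq_along(compA)) for (cb in seq_along(compB))
      for (cc in seq_along(compC)) for (cd in seq_along(compD)) {
        la <- compA[[ca]]; lb <- compB[[cb]]
        lc <- compC[[cc]]; ld <- compD[[cd]]
        acc <- numeric(nb * nk)
        for (t in 0:(la[1L] + lb[1L])) for (u in 0:(la[2L] + lb[2L]))
          for (v in 0:(la[3L] + lb[3L])) {
            Eb <- pdb$E[[1L]][[la[1L] + 1L]][[lb[1L] + 1L]][[t + 1L]] *
                  pdb$E[[2L]][[la[2L] + 1L]][[lb[2L] + 1L]][[u + 1L]] *
                  pdb$E[[3L]][[la[3L] + 1L]][[lb[3L] + 1L]][[v + 1L]]
            Eb81 <- Eb[ib]
            for (tt in 0:(lc[1L] + ld[1L])) for (uu in 0:(lc[2L] + ld[2L]))
              for (vv in 0:(lc[3L] + ld[3L])) {
                Ek <- pdk$E[[1L]][[lc[1L] + 1L]][[ld[1L] + 1L]][[tt + 1L]] *
                      pdk$E[[2L]][[lc[2L] + 1L]][[ld[2L] + 1L]][[uu + 1L]] *
                      pdk$E[[3L]][[lc[3L] + 1L]][[ld[3L] + 1L]][[vv + 1L]]
                sgn <- if ((tt + uu + vv) %% 2L == 0L) 1 else -1
                acc <- acc + Eb81 * Ek[ik] * sgn * rt(t + tt, u + uu, v + vv)
              }
          }
        val <- sum(pref * acc)
        pi_ <- so$offsets[bra$i] + ca; pj <- so$offsets[bra$j] + cb
        pk <- so$offsets[ket$i] + cc; pl <- so$offsets[ket$j] + cd
        eri[pi_, pj, pk, pl] <- eri[pj, pi_, pk, pl] <-
          eri[pi_, pj, pl, pk] <- eri[pj, pi_, pl, pk] <-
          eri[pk, pl, pi_, pj] <- eri[pl, pk, pi_, pj] <-
          eri[pk, pl, pj, pi_] <- eri[pl, pk, pj, pi_] <- val
      }
  }
  eri
}

## normalize contracted AOs so diag(S) = 1, returning scale factors
.contractedNorms <- function(S) 1 / sqrt(diag(S))

#' Atomic-orbital integrals for a geometry
#'
#' Computes overlap, kinetic, nuclear-attraction and two-electron repulsion
#' integrals in the contracted, normalized AO basis, plus the nuclear
#' repulsion energy.
#'
#' @param geom a [molecularGeometry()]
#' @return list with S, T, V, eri (chemists' (pq|rs)), enuc, nbf, nelec
#' @export
aoIntegrals <- function(geom) {
  shells <- buildShells(geom)
  one <- oneElectronIntegrals(shells, geom)
  eri <- twoElectronIntegrals(shells)
  nrm <- .contractedNorms(one$S)
  S <- one$S * outer(nrm, nrm)
  T <- one$T * outer(nrm, nrm)
  V <- one$V * outer(nrm, nrm)
  n4 <- outer(outer(nrm, nrm), outer(nrm, nrm))
  eri <- eri * n4
  # AO metadata: component 0 = s, 1/2/3 = px/py/pz
  comp <- integer(0); atomOf <- integer(0)
  for (sh in shells) {
    if (sh$l == 0L) {
      comp <- c(comp, 0L); atomOf <- c(atomOf, sh$atom)
    } else {
      comp <- c(comp, 1L, 2L, 3L); atomOf <- c(atomOf, rep(sh$atom, 3L))
    }
  }
  list(S = S, T = T, V = V, eri = eri, enuc = nuclearRepulsion(geom),
       nbf = nrow(S), nelec = nElectrons(geom),
       aoComp = comp, aoAtom = atomOf)
}
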