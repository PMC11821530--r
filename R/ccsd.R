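#' @include mp2.R
NULL

# Spin-orbital CCSD and perturbative-triples correction, standard
# single-reference amplitude equations with DIIS on the amplitude residuals.

#' Coupled-cluster singles and doubles
#'
#' @param hf result of [scfRHF()]
#' @param so optional [spinOrbitalData()] result
#' @param maxiter,conv amplitude iteration controls (energy convergence,
#'   Hartree)
#' @param diisDim DIIS history length
#' @return list: energy (total), ecorr, t1 (o x v), t2 (o,o,v,v), converged,
#'   so
#' @export
ccsdEnergy <- function(hf, so = NULL, maxiter = 120L, conv = 1e-10,
                       diisDim = 8L) {
  if (is.null(so)) so <- spinOrbitalData(hf)
  no <- so$nocc; nv <- so$nvirt
  o <- seq_len(no); v <- no + seq_len(nv)
  eps <- so$eps
  g <- so$g
  goovv <- g[o, o, v, v, drop = FALSE]
  Dia <- outer(eps[o], eps[v], `-`)
  Dijab <- outer(outer(eps[o], eps[o], `+`),
                 outer(eps[v], eps[v], `+`), `-`)
  t1 <- matrix(0, no, nv)
  t2 <- goovv / Dijab
  # E_corr = 1/4 sum <ij||ab> t2 + 1/2 sum <ij||ab> t1_ia t1_jb
  eccFast <- function(t1, t2) {
    0.25 * sum(goovv * t2) + 0.5 * sum(ein("ijab,jb->ia", goovv, t1) * t1)
  }
  eold <- eccFast(t1, t2)
  hist <- list(); errs <- list()
  converged <- FALSE
  for (it in seq_len(maxiter)) {
    tau1 <- t2 + 0.5 * (ein("ia,jb->ijab", t1, t1) -
                        ein("ib,ja->ijab", t1, t1))
    tau <- t2 + ein("ia,jb->ijab", t1, t1) - ein("ib,ja->ijab", t1, t1)
    Fae <- ein("mf,mafe->ae", t1, g[o, v, v, v]) -
      0.5 * ein("mnaf,mnef->ae", tau1, goovv)
    Fmi <- ein("ne,mnie->mi", t1, g[o, o, o, v]) +
      0.5 * ein("inef,mnef->mi", tau1, goovv)
    Fme <- ein("nf,mnef->me", t1, goovv)
    Wmnij <- g[o, o, o, o] +
      (ein("je,mnie->mnij", t1, g[o, o, o, v]) -
       aperm(ein("je,mnie->mnij", t1, g[o, o, o, v]), c(1L, 2L, 4L, 3L))) +
      0.25 * ein("ijef,mnef->mnij", tau, goovv)
    Wabef <- g[v, v, v, v] -
      (ein("mb,amef->abef", t1, g[v, o, v, v]) -
       aperm(ein("mb,amef->abef", t1, g[v, o, v, v]), c(2L, 1L, 3L, 4L))) +
      0.25 * ein("mnab,mnef->abef", tau, goovv)
    Wmbej <- g[o, v, v, o] +
      ein("jf,mbef->mbej", t1, g[o, v, v, v]) -
      ein("nb,mnej->mbej", t1, g[o, o, v, o]) -
      ein("jnfb,mnef->mbej", 0.5 * t2 + ein("jf,nb->jnfb", t1, t1), goovv)
    # T1 equation
    rhs1 <- ein("ie,ae->ia", t1, Fae) -
      ein("ma,mi->ia", t1, Fmi) +
      ein("imae,me->ia", t2, Fme) -
      ein("nf,naif->ia", t1, g[o, v, o, v]) -
      0.5 * ein("imef,maef->ia", t2, g[o, v, v, v]) -
      0.5 * ein("mnae,nmei->ia", t2, g[o, o, v, o])
    t1n <- rhs1 / Dia
    # T2 equation
    FbeH <- Fae - 0.5 * ein("mb,me->be", t1, Fme)
    FmjH <- Fmi + 0.5 * ein("je,me->mj", t1, Fme)
    P_ab <- function(X) X - aperm(X, c(1L, 2L, 4L, 3L))
    P_ij <- function(X) X - aperm(X, c(2L, 1L, 3L, 4L))
    rhs2 <- goovv +
      P_ab(ein("ijae,be->ijab", t2, FbeH)) -
      P_ij(ein("imab,mj->ijab", t2, FmjH)) +
      0.5 * ein("mnab,mnij->ijab", tau, Wmnij) +
      0.5 * ein("ijef,abef->ijab", tau, Wabef) +
      P_ij(P_ab(ein("imae,mbej->ijab", t2, Wmbej) -
                ein("ie,abej->ijab", t1,
                    ein("ma,mbej->abej", t1, g[o, v, v, o])))) +
      P_ij(ein("ie,abej->ijab", t1, g[v, v, v, o])) -
      P_ab(ein("ma,mbij->ijab", t1, g[o, v, o, o]))
    t2n <- rhs2 / Dijab
    # DIIS on concatenated amplitude updates
    vecNew <- c(t1n, t2n)
    errVec <- vecNew - c(t1, t2)
    hist <- c(hist, list(vecNew)); errs <- c(errs, list(errVec))
    if (length(hist) > diisDim) { hist <- hist[-1L]; errs <- errs[-1L] }
    m <- length(hist)
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (aI in seq_len(m)) for (bI in seq_len(m))
        B[aI, bI] <- sum(errs[[aI]] * errs[[bI]])
      B[m + 1L, seq_len(m)] <- B[seq_len(m), m + 1L] <- -1
      cf <- tryCatch(solve(B, c(rep(0, m), -1))[seq_len(m)],
                     error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        vecNew <- Reduce(`+`, Map(`*`, hist, cf))
      }
    }
    t1 <- matrix(vecNew[seq_len(no * nv)], no, nv)
    t2 <- array(vecNew[-seq_len(no * nv)], c(no, no, nv, nv))
    enew <- eccFast(t1, t2)
    if (abs(enew - eold) < conv && it > 2L) {
      converged <- TRUE
      eold <- enew
      break
    }
    eold <- enew
  }
  if (!converged) warning("CCSD amplitudes not fully converged")
  list(energy = hf$energy + eold, ecorr = eold, t1 = t1, t2 = t2,
       converged = converged, so = so)
}

#' Perturbative triples correction CCSD(T)
#'
#' @param cc result of [ccsdEnergy()]
#' @return list: energy (total CCSD(T)), et (triples correction)
#' @export
ccsdTEnergy <- function(cc) {
  so <- cc$so
  no <- so$nocc; nv <- so$nvirt
  o <- seq_len(no); v <- no + seq_len(nv)
  eps <- so$eps
  g <- so$g
  t1 <- cc$t1; t2 <- cc$t2
  g_vovv <- g[v, o, v, v, drop = FALSE]   # <ei||bc> ordering below
  g_ovoo <- g[o, v, o, o, drop = FALSE]
  goovv <- g[o, o, v, v, drop = FALSE]
  # full o^3 v^3 arrays
  # connected: X_ijkabc = sum_e t2_jkae <ei||bc> - sum_m t2_imbc <ma||jk>
  X1 <- ein("jkae,eibc->jkiabc", t2, g_vovv)   # dims j,k,i,a,b,c
  X1 <- aperm(X1, c(3L, 1L, 2L, 4L, 5L, 6L))    # i,j,k,a,b,c
  X2 <- ein("imbc,majk->ibcajk", t2, g_ovoo)
  X2 <- aperm(X2, c(1L, 5L, 6L, 4L, 2L, 3L))    # i,j,k,a,b,c
  X <- X1 - X2
  Pijk <- function(A) {
    # P(i/jk): A(ijk) - A(jik) - A(kji)... standard: f(ijk)-f(jik)-f(kij)
    A - aperm(A, c(2L, 1L, 3L, 4L, 5L, 6L)) - aperm(A, c(3L, 2L, 1L, 4L, 5L, 6L))
  }
  Pabc <- function(A) {
    A - aperm(A, c(1L, 2L, 3L, 5L, 4L, 6L)) - aperm(A, c(1L, 2L, 3L, 6L, 5L, 4L))
  }
  t3cD <- Pijk(Pabc(X))
  D3 <- outer(outer(outer(eps[o], eps[o], `+`), eps[o], `+`),
              outer(outer(eps[v], eps[v], `+`), eps[v], `+`), `-`)
  Y <- ein("ia,jkbc->ijkabc", t1, goovv)
  t3dD <- Pijk(Pabc(Y))
  et <- sum(t3cD * (t3cD + t3dD) / D3) / 36
  list(energy = cc$energy + et, et = et)
}
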