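#' @include fci.R mp2.R
NULL

# Complete-active-space methods on top of the determinant CI machinery.
# Active orbitals are selected from MP2 natural-orbital occupations: the
# M_act orbitals with occupation farthest from 0 or 2 (maximal
# min(occ, 2 - occ)) are active, ties broken by proximity to the HOMO.

## frozen-core effective integrals for an active orbital window
.activeIntegrals <- function(h, g, core, act) {
  Ecore <- 2 * sum(diag(h)[core])
  if (length(core)) {
    for (i in core) for (j in core)
      Ecore <- Ecore + 2 * g[i, i, j, j] - g[i, j, j, i]
  }
  heff <- h[act, act, drop = FALSE]
  for (i in core) {
    heff <- heff + 2 * g[act, act, i, i] - g[act, i, i, act]
  }
  list(Ecore = Ecore, h = heff, g = g[act, act, act, act, drop = FALSE])
}

#' Select a CAS active space from MP2 natural orbitals
#'
#' @param mp2 result of [mp2Energy()]
#' @param nAct number of active spatial orbitals
#' @param nElec number of active electrons
#' @param nocc number of doubly occupied orbitals in the reference
#' @return list: coef (AO x MO in natural-orbital basis, core..act..virt
#'   ordered), core, act (index sets in that basis), nAlpha, nBeta
#' @export
casSelectActive <- function(mp2, nAct, nElec, nocc) {
  occ <- mp2$noOcc
  M <- length(occ)
  frac <- pmin(occ, 2 - occ)
  homoOcc <- occ[nocc]
  ordSel <- order(-frac, abs(occ - homoOcc), seq_len(M))
  act <- sort(ordSel[seq_len(nAct)])
  nCore <- (sum(round(occ)) - nElec) / 2
  # core = most occupied non-active orbitals
  rest <- setdiff(seq_len(M), act)
  core <- rest[order(-occ[rest])][seq_len(nCore)]
  core <- sort(core)
  list(coef = mp2$noCoef, core = core, act = act,
       nAlpha = (nElec + 1) %/% 2, nBeta = nElec %/% 2)
}

#' CASCI energy
#'
#' Full CI within an active window of (natural) orbitals over a frozen
#' core.
#'
#' @param hf [scfRHF()] result
#' @param nAct,nElec active space size (spatial orbitals, electrons)
#' @param mp2 optional [mp2Energy()] (for natural orbitals); computed when
#'   missing
#' @param coef optional explicit orbital coefficients (AO x MO) overriding
#'   the natural orbitals
#' @return list: energy, space (selection), coef
#' @export
casciEnergy <- function(hf, nAct, nElec, mp2 = NULL, coef = NULL) {
  if (is.null(mp2) && is.null(coef)) mp2 <- mp2Energy(hf)
  sp <- if (is.null(coef)) {
    casSelectActive(mp2, nAct, nElec, hf$nocc)
  } else {
    # fixed orbitals: active = the nAct orbitals around the Fermi level
    nCore <- (hf$ints$nelec - nElec) %/% 2L
    list(coef = coef, core = seq_len(nCore),
         act = nCore + seq_len(nAct),
         nAlpha = (nElec + 1) %/% 2, nBeta = nElec %/% 2)
  }
  C <- sp$coef
  h <- moOne(hf$ints, C)
  g <- moERI(hf$ints$eri, C)
  ai <- .activeIntegrals(h, g, sp$core, sp$act)
  st <- .fciStructure(length(sp$act), sp$nAlpha, sp$nBeta)
  eci <- .fciGround(st, ai$h, ai$g)
  list(energy = eci + ai$Ecore + hf$ints$enuc, space = sp, coef = C)
}

#' CASSCF energy by direct orbital-rotation minimization
#'
#' Optimizes the CASCI energy over orthogonal orbital rotations
#' \eqn{C \exp(\kappa)} (nonredundant core-active, core-virtual and
#' active-virtual parameters) with BFGS and numerical gradients.  Suited to
#' the small systems this package targets.
#'
#' @param hf [scfRHF()] result
#' @param nAct,nElec active space
#' @param mp2 optional [mp2Energy()]
#' @param maxit BFGS iteration cap
#' @return list: energy, casci (initial CASCI), convergence
#' @export
casscfEnergy <- function(hf, nAct, nElec, mp2 = NULL, maxit = 150L) {
  base <- casciEnergy(hf, nAct, nElec, mp2 = mp2)
  sp <- base$space
  M <- ncol(sp$coef)
  virt <- setdiff(seq_len(M), c(sp$core, sp$act))
  pairs <- rbind(
    expand.grid(p = sp$core, q = sp$act),
    expand.grid(p = sp$core, q = virt),
    expand.grid(p = sp$act, q = virt))
  np <- nrow(pairs)
  energyOf <- function(kappa) {
    K <- matrix(0, M, M)
    for (i in seq_len(np)) {
      K[pairs$p[i], pairs$q[i]] <- kappa[i]
      K[pairs$q[i], pairs$p[i]] <- -kappa[i]
    }
    # orthogonal rotation exp(K) via eigen of the skew-symmetric matrix
    U <- as.matrix(Matrix::expm(K))
    C <- sp$coef %*% U
    h <- moOne(hf$ints, C)
    g <- moERI(hf$ints$eri, C)
    ai <- .activeIntegrals(h, g, sp$core, sp$act)
    st <- .fciStructure(length(sp$act), sp$nAlpha, sp$nBeta)
    .fciGround(st, ai$h, ai$g) + ai$Ecore + hf$ints$enuc
  }
  fit <- stats::optim(rep(0, np), energyOf, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(energy = fit$value, casci = base$energy,
       convergence = fit$convergence)
}
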