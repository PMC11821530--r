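#' @include casscf.R stabilizers.R adapt.R zne.R degeneracy.R
NULL

# Dissociation-curve orchestration: continuation-based SCF scans, the
# classical benchmark suite, contextual-subspace energies, onset /
# equilibrium / discontinuity detection, and simulated CS-VQE.

#' Scan context with warm-started SCF
#'
#' Stores converged orbitals along a bond-length scan so every new geometry
#' is warm-started from the nearest solved point, keeping the SCF solution
#' on a continuous branch.
#'
#' @param build function(r) returning a molecularGeometry (default N2)
#' @return environment-backed context for [scfAt()]
#' @export
scanContext <- function(build = n2Geometry) {
  env <- new.env(parent = emptyenv())
  env$build <- build
  env$rs <- numeric(0)
  env$C <- list()
  env$cache <- list()
  class(env) <- "scanContext"
  env
}

#' Converged SCF at a bond length, warm-started from the scan context
#'
#' Cold starts anchor the branch at the smallest requested radius; all
#' later points reuse the nearest stored orbitals.
#'
#' @param ctx [scanContext()]
#' @param r bond length (Angstrom)
#' @param anchor radius used to seed the branch when the context is empty
#' @return [scfRHF()] result
#' @export
scfAt <- function(ctx, r, anchor = 0.8) {
  key <- sprintf("%.6f", r)
  got <- ctx$cache[[key]]
  if (!is.null(got)) return(got)
  if (length(ctx$rs) == 0L && abs(r - anchor) > 0.051) {
    # walk from the anchor towards r in modest steps
    steps <- seq(anchor, r, by = if (r > anchor) 0.05 else -0.05)
    for (s in steps) scfAt(ctx, s, anchor = anchor)
  }
  guess <- NULL
  if (length(ctx$rs)) {
    near <- which.min(abs(ctx$rs - r))
    if (abs(ctx$rs[near] - r) < 0.2) guess <- ctx$C[[near]]
  }
  hf <- suppressWarnings(scfRHF(ctx$build(r), guessC = guess))
  ctx$rs <- c(ctx$rs, r)
  ctx$C[[length(ctx$C) + 1L]] <- hf$C
  if (length(ctx$cache) < 400L) ctx$cache[[key]] <- hf
  hf
}

#' Classical benchmark suite at one geometry
#'
#' @param geom [molecularGeometry()] (ignored when \code{hf} given)
#' @param methods subset of HF, MP2, CISD, CCSD, CCSD(T), CASCI, CASSCF,
#'   FCI
#' @param activeSpace c(nAct, nElec) for the CAS methods
#' @param hf optional converged [scfRHF()]
#' @return named numeric energies (Hartree)
#' @export
runBenchmarks <- function(geom, methods = c("HF", "MP2", "CCSD", "CCSD(T)",
                                            "FCI"),
                          activeSpace = NULL, hf = NULL) {
  known <- c("HF", "MP2", "CISD", "CCSD", "CCSD(T)", "CASCI", "CASSCF",
             "FCI")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unsupported method(s): ", paste(bad, collapse = ", "))
  if (is.null(hf)) hf <- scfRHF(geom)
  out <- c()
  m <- NULL; cc <- NULL
  need <- function(x) x %in% methods
  if (need("HF")) out["HF"] <- hf$energy
  if (any(methods %in% c("MP2", "CCSD", "CCSD(T)", "CASCI", "CASSCF"))) {
    m <- mp2Energy(hf)
  }
  if (need("MP2")) out["MP2"] <- m$energy
  if (need("CISD")) out["CISD"] <- cisdEnergy(hf)
  if (any(methods %in% c("CCSD", "CCSD(T)"))) {
    cc <- suppressWarnings(ccsdEnergy(hf, so = m$so))
  }
  if (need("CCSD")) out["CCSD"] <- cc$energy
  if (need("CCSD(T)")) out["CCSD(T)"] <- ccsdTEnergy(cc)$energy
  if (any(methods %in% c("CASCI", "CASSCF"))) {
    if (is.null(activeSpace)) stop("CAS methods require activeSpace")
    if (need("CASCI"))
      out["CASCI"] <- casciEnergy(hf, activeSpace[1L], activeSpace[2L],
                                  mp2 = m)$energy
    if (need("CASSCF"))
      out["CASSCF"] <- casscfEnergy(hf, activeSpace[1L],
                                    activeSpace[2L], mp2 = m)$energy
  }
  if (need("FCI")) out["FCI"] <- fciEnergy(hf)
  out
}

#' Full contextual-subspace data at one bond length
#'
#' Runs SCF (warm-started), tapering, the noncontextual solve, guide
#' construction, and the subspace projection; exact diagonalization gives
#' the CS-DD energy.
#'
#' @param ctx [scanContext()]
#' @param r bond length
#' @param nq subspace size(s); vector allowed
#' @param guide "MP2" or "CCSD"
#' @param withFCI also compute the FCI energy
#' @return list with hf, fci, taper data, model, and per-nq reduced
#'   Hamiltonians + CS-DD energies
#' @export
csvqePoint <- function(ctx, r, nq = 5L, guide = "MP2", withFCI = TRUE) {
  hf <- scfAt(ctx, r)
  qb <- buildQubitHamiltonian(ctx$build(r), hf = hf)
  tp <- taperMolecularHamiltonian(qb)
  model <- solveNoncontextual(selectNoncontextual(tp$H))
  m <- mp2Energy(hf)
  gen <- if (guide == "MP2") {
    excitationGenerator(hf, "MP2", mp2 = m)
  } else {
    cc <- suppressWarnings(ccsdEnergy(hf, so = m$so))
    excitationGenerator(hf, "CCSD", cc = cc)
  }
  gTap <- taperOperator(gen, tp$sector)
  perNq <- lapply(nq, function(k) {
    cs <- contextualSubspace(tp$H, gTap, k, model = model,
                             reference = tp$hfOccupation)
    list(nq = k, H = cs$H, csdd = csddEnergy(cs$H), choice = cs$choice,
         record = cs$record)
  })
  names(perNq) <- as.character(nq)
  list(r = r, hf = hf, fci = if (withFCI) fciEnergy(hf) else NA_real_,
       taper = tp, model = model, guide = gTap, mp2 = m,
       enc = model@energy, perNq = perNq)
}

#' Scan the dissociation curve
#'
#' One record per grid point: benchmark energies, noncontextual energy,
#' CS-DD energy, degeneracy metric, and (optionally) a simulated noisy
#' CS-VQE estimate.
#'
#' @param grid bond lengths (Angstrom), increasing
#' @param nq subspace size
#' @param guide "MP2" or "CCSD"
#' @param methods benchmark methods per point
#' @param delta degeneracy-metric filter (Hartree)
#' @param ctx optional existing [scanContext()]
#' @return data.frame, one row per bond length
#' @export
runScan <- function(grid = seq(0.8, 2.0, length.out = 10L), nq = 5L,
                    guide = "MP2",
                    methods = c("HF", "MP2", "CCSD", "CCSD(T)", "FCI"),
                    delta = 0.05, ctx = NULL) {
  if (is.null(ctx)) ctx <- scanContext()
  rows <- list()
  for (r in grid) {
    pt <- csvqePoint(ctx, r, nq = nq, guide = guide,
                     withFCI = "FCI" %in% methods)
    bench <- runBenchmarks(NULL, methods = setdiff(methods, "FCI"),
                           hf = pt$hf)
    row <- data.frame(r = r)
    for (nm in names(bench)) row[[nm]] <- bench[[nm]]
    if ("FCI" %in% methods) row$FCI <- pt$fci
    row$Enc <- pt$enc
    row$CSDD <- pt$perNq[[1L]]$csdd
    row$sDelta <- sDelta(pt$hf$eps, delta = delta)
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Smallest subspace reaching a target accuracy
#'
#' Sweeps nq upward until the worst-case CS-DD error over the grid drops
#' below the threshold.
#'
#' @param grid bond lengths
#' @param guide "MP2" or "CCSD"
#' @param threshold accuracy target (Hartree); default 43 meV
#' @param nqMax sweep cap
#' @param ctx optional scan context
#' @return list: nq (smallest passing size, NA when none), maxError (per
#'   nq, eV)
#' @export
minQubitsForAccuracy <- function(grid = seq(0.8, 2.0, length.out = 10L),
                                 guide = "MP2",
                                 threshold = 0.043 / hartree_to_eV,
                                 nqMax = 13L, ctx = NULL) {
  if (is.null(ctx)) ctx <- scanContext()
  pts <- lapply(grid, function(r)
    csvqePoint(ctx, r, nq = integer(0), guide = guide))
  maxErr <- c()
  for (k in seq_len(nqMax)) {
    errs <- vapply(pts, function(pt) {
      cs <- contextualSubspace(pt$taper$H, pt$guide, k, model = pt$model,
                               reference = pt$taper$hfOccupation)
      csddEnergy(cs$H) - pt$fci
    }, numeric(1))
    maxErr[as.character(k)] <- max(errs) * hartree_to_eV
    if (max(errs) <= threshold) {
      return(list(nq = k, maxError = maxErr))
    }
  }
  list(nq = NA_integer_, maxError = maxErr)
}

#' Memoized FCI energy within a scan context
#' @param ctx [scanContext()]
#' @param r bond length
#' @return FCI energy (Hartree)
#' @export
fciAt <- function(ctx, r) {
  key <- sprintf("fci_%.6f", r)
  got <- ctx$cache[[key]]
  if (!is.null(got)) return(got)
  val <- fciEnergy(scfAt(ctx, r))
  ctx$cache[[key]] <- val
  val
}

#' Onset of non-variationality
#'
#' Finds the smallest bond length at which a method's energy dips below
#' FCI: a coarse scan brackets the first sign change of
#' \eqn{E_{method} - E_{FCI}}, then bisection refines it to \code{tol}.
#'
#' @param method "MP2", "CCSD" or "CCSD(T)"
#' @param range scan window (Angstrom)
#' @param coarse coarse grid step
#' @param tol bisection tolerance (Angstrom)
#' @param ctx optional scan context
#' @return list: onset (Angstrom, NA if none), bracket
#' @export
nonvariationalOnset <- function(method = "MP2", range = c(0.8, 2.0),
                                coarse = 0.05, tol = 5e-4, ctx = NULL) {
  if (is.null(ctx)) ctx <- scanContext()
  diffAt <- function(r) {
    hf <- scfAt(ctx, r)
    e <- runBenchmarks(NULL, methods = method, hf = hf)
    unname(e[method]) - fciAt(ctx, r)
  }
  rs <- seq(range[1L], range[2L], by = coarse)
  prev <- diffAt(rs[1L])
  lo <- NA_real_; hi <- NA_real_
  for (i in 2:length(rs)) {
    cur <- diffAt(rs[i])
    if (prev > 0 && cur < 0) {
      lo <- rs[i - 1L]; hi <- rs[i]
      break
    }
    prev <- cur
  }
  if (is.na(lo)) return(list(onset = NA_real_, bracket = c(NA, NA)))
  flo <- diffAt(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- diffAt(mid)
    if (flo > 0 && fm <= 0) {
      hi <- mid
    } else {
      lo <- mid; flo <- fm
    }
  }
  list(onset = (lo + hi) / 2, bracket = c(lo, hi))
}

#' Equilibrium bond length of the FCI curve
#'
#' Coarse scan over the window followed by golden-section refinement of
#' the FCI energy and a final parabolic fit through the three nearest
#' computed points.
#'
#' @param window search window (Angstrom)
#' @param coarse coarse step
#' @param tol refinement tolerance (Angstrom)
#' @param ctx optional scan context
#' @param energyAt optional function(r) overriding the FCI objective
#' @return list: re (Angstrom), energy (Hartree)
#' @export
equilibriumLength <- function(window = c(1.0, 1.4), coarse = 0.02,
                              tol = 5e-4, ctx = NULL, energyAt = NULL) {
  if (is.null(ctx)) ctx <- scanContext()
  seen <- new.env(parent = emptyenv())
  fci <- if (is.null(energyAt)) {
    function(r) fciAt(ctx, r)
  } else energyAt
  fciMemo <- function(r) {
    key <- sprintf("%.6f", r)
    got <- seen[[key]]
    if (!is.null(got)) return(got)
    val <- fci(r)
    seen[[key]] <- val
    val
  }
  rs <- seq(window[1L], window[2L], by = coarse)
  es <- vapply(rs, fciMemo, numeric(1))
  i <- which.min(es)
  lo <- rs[max(1L, i - 1L)]; hi <- rs[min(length(rs), i + 1L)]
  opt <- stats::optimize(fciMemo, c(lo, hi), tol = tol)
  # parabolic polish through the three nearest evaluated points
  pts <- ls(seen)
  rAll <- as.numeric(pts)
  eAll <- vapply(pts, function(k) seen[[k]], numeric(1))
  ordc <- order(abs(rAll - opt$minimum))[1:3]
  co <- stats::coef(stats::lm(eAll[ordc] ~ stats::poly(rAll[ordc], 2,
                                                       raw = TRUE)))
  re <- -co[2L] / (2 * co[3L])
  if (!is.finite(re) || abs(re - opt$minimum) > coarse) re <- opt$minimum
  list(re = unname(re), energy = opt$objective)
}

#' Noncontextual energy curve and discontinuity detection
#'
#' Computes the noncontextual energy on a grid together with the optimal
#' classical configuration.  Candidate discontinuities are intervals where
#' the optimal configuration switches (the energy of a
#' minimum-over-configurations curve is non-smooth exactly there); each is
#' refined by bisection on the configuration change down to
#' \code{resolution} and accepted only when the two competing
#' configurations separate with a slope difference above \code{slopeTol}
#' (switches between degenerate assignments move the labelling without
#' moving the energy).
#'
#' @param grid bond lengths
#' @param resolution final interval width for flagged switches (Angstrom)
#' @param slopeTol minimum slope difference (Hartree/Angstrom) between the
#'   competing configurations for a switch to count as a discontinuity
#' @param ctx optional scan context
#' @return list: curve (data.frame r, Enc, Ehf), jumps (refined switch
#'   positions)
#' @export
noncontextualScan <- function(grid = seq(0.8, 2.0, by = 0.01),
                              resolution = 0.002, slopeTol = 1e-3,
                              ctx = NULL) {
  if (is.null(ctx)) ctx <- scanContext()
  evalAt <- local({
    memo <- new.env(parent = emptyenv())
    function(r) {
      key <- sprintf("%.6f", r)
      got <- memo[[key]]
      if (!is.null(got)) return(got)
      hf <- scfAt(ctx, r)
      qb <- buildQubitHamiltonian(ctx$build(r), hf = hf)
      tp <- taperMolecularHamiltonian(qb)
      mo <- solveNoncontextual(selectNoncontextual(tp$H))
      val <- list(Enc = mo@energy, Ehf = hf$energy,
                  cfg = paste(mo@q, collapse = ""),
                  Hd = tp$H[which(tp$H@x == 0L)], q = mo@q)
      memo[[key]] <- val
      val
    }
  })
  cfgEnergy <- function(Hd, q) {
    mask <- bitsToMask(which(q < 0) - 1L)
    sum(Re(Hd@coeff) * (1 - 2 * bitParity(bitwAnd(Hd@z, mask))))
  }
  vals <- lapply(grid, evalAt)
  es <- vapply(vals, `[[`, numeric(1), "Enc")
  ehf <- vapply(vals, `[[`, numeric(1), "Ehf")
  cfg <- vapply(vals, `[[`, character(1), "cfg")
  switched <- which(cfg[-1L] != cfg[-length(cfg)])
  jumps <- numeric(0)
  for (i in switched) {
    lo <- grid[i]; hi <- grid[i + 1L]
    vlo <- vals[[i]]; vhi <- vals[[i + 1L]]
    clo <- vlo$cfg
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      vm <- evalAt(mid)
      if (vm$cfg == clo) { lo <- mid; vlo <- vm } else { hi <- mid; vhi <- vm }
    }
    # genuine crossing: the two competing configurations separate with a
    # resolvable slope difference; switches between degenerate assignments
    # leave d(r) = E_left(r) - E_right(r) at zero on both sides
    dLo <- cfgEnergy(vlo$Hd, vlo$q) - cfgEnergy(vlo$Hd, vhi$q)
    dHi <- cfgEnergy(vhi$Hd, vlo$q) - cfgEnergy(vhi$Hd, vhi$q)
    if ((dHi - dLo) / (hi - lo) > slopeTol) {
      jumps <- c(jumps, (lo + hi) / 2)
    }
  }
  if (length(jumps) > 1L) {
    jumps <- sort(jumps)
    jumps <- jumps[c(TRUE, diff(jumps) > 5 * resolution)]
  }
  list(curve = data.frame(r = grid, Enc = es, Ehf = ehf), jumps = jumps)
}

#' Statevector of the reference determinant inside a subspace
#'
#' Builds the computational-basis Hartree-Fock state, pushes it through
#' the tapering Cliffords and qubit fixing, then through a projection
#' record, renormalizing at each slice.
#'
#' @param occupation 0/1 occupation per original qubit
#' @param sector [SymmetrySector-class] from tapering
#' @param record optional projection record ([projectToSubspace()])
#' @return complex statevector on the reduced register
#' @export
projectedReference <- function(occupation, sector, record = NULL) {
  n <- length(occupation)
  v <- complex(length.out = 2^n)
  v[bitsToMask(which(occupation == 1L) - 1L) + 1L] <- 1 + 0i
  v <- .rotateState(v, sector@rotations)
  v <- .sliceState(v, sector@targetQubits, sector@eigenvalues)
  if (!is.null(record)) {
    nr <- as.integer(round(log2(length(v))))
    for (ro in record$up) {
      P <- newPauliSum(ro$px, ro$pz, complex(real = 1), nr)
      v <- cos(ro$theta) * v + 1i * sin(ro$theta) * pauliApply(P, v)
    }
    if (!is.null(record$cliffords)) v <- .rotateState(v, record$cliffords)
    if (length(record$targets))
      v <- .sliceState(v, record$targets, record$eigenvalues)
  }
  v
}

## apply e^{i pi/4 P} rotations to a statevector
.rotateState <- function(v, rotations) {
  n <- as.integer(round(log2(length(v))))
  for (t in seq_len(nTerms(rotations))) {
    P <- newPauliSum(rotations@x[t], rotations@z[t], complex(real = 1), n)
    v <- (v + 1i * pauliApply(P, v)) / sqrt(2)
  }
  v
}

## fix qubits to Z eigenvalues and drop them
.sliceState <- function(v, targets, eigenvalues) {
  n <- as.integer(round(log2(length(v))))
  idx <- 0:(length(v) - 1L)
  keepQ <- setdiff(0:(n - 1L), targets)
  sel <- rep(TRUE, length(v))
  for (i in seq_along(targets)) {
    b <- bitwShiftL(1L, targets[i])
    want <- if (eigenvalues[i] > 0) 0L else b
    sel <- sel & (bitwAnd(idx, b) == want)
  }
  sub <- v[sel]
  nrm <- sqrt(sum(Mod(sub)^2))
  if (nrm < 1e-10)
    warning("reference state has (near-)zero weight in the fixed sector")
  else sub <- sub / nrm
  sub
}

#' Variational optimization of an ansatz on a reduced Hamiltonian
#'
#' Exact backend: BFGS on the statevector energy with adjoint gradients.
#' Noisy backend: shot-based estimates (optionally tiled across a device
#' with measurement-error mitigation and ZNE) driven by parameter-shift
#' gradients, stopping on an energy plateau since gradients do not vanish
#' under noise.
#'
#' @param H reduced PauliSum
#' @param ops ansatz generators (list(x =, z =)) from [adaptRun()]
#' @param theta0 initial parameters
#' @param reference reference statevector
#' @param backend "exact" or "noisy"
#' @param noise,shots,seed noisy-backend controls
#' @param maxit iteration cap
#' @param plateau list(tol =, window =) noisy stopping rule
#' @return list: energy, stderr, theta, trace, gradL1
#' @export
runVQE <- function(H, ops, theta0 = NULL, reference = NULL,
                   backend = c("exact", "noisy"), noise = NULL,
                   shots = 5000L, seed = 1L, maxit = 200L,
                   plateau = list(tol = 1e-4, window = 10L)) {
  backend <- match.arg(backend)
  n <- H@nQubits
  d <- 2^n
  if (is.null(reference)) {
    reference <- complex(length.out = d); reference[1L] <- 1 + 0i
  }
  npar <- length(ops$x)
  if (is.null(theta0)) theta0 <- rep(0, npar)
  if (backend == "exact") {
    op <- pauliMatvecOperator(H)
    mvH <- function(v) op$matvec(v)
    if (npar == 0L) {
      e <- Re(sum(Conj(reference) * mvH(reference)))
      return(list(energy = e, stderr = 0, theta = numeric(0),
                  trace = e, gradL1 = 0))
    }
    fit <- stats::optim(theta0,
      fn = function(th) .ansatzEnergyGrad(mvH, reference, ops, th)$energy,
      gr = function(th) .ansatzEnergyGrad(mvH, reference, ops, th)$grad,
      method = "BFGS", control = list(maxit = maxit, reltol = 1e-12))
    gfin <- .ansatzEnergyGrad(mvH, reference, ops, fit$par)
    return(list(energy = fit$value, stderr = 0, theta = fit$par,
                trace = fit$value, gradL1 = sum(abs(gfin$grad))))
  }
  # noisy: gradient descent with parameter-shift on sampled energies
  grouping <- qwcPartition(H)
  energyNoisy <- function(th, sd) {
    circ <- .compiledAnsatz(n, ops, th)
    estimateEnergy(H, circ, grouping, noise = noise, shots = shots,
                   seed = sd, mitigate = !is.null(noise$readout))$energy
  }
  th <- theta0
  trace <- numeric(0); gradL1 <- numeric(0)
  lr <- 0.15
  for (it in seq_len(maxit)) {
    g <- vapply(seq_len(npar), function(k) {
      tp <- th; tp[k] <- tp[k] + pi / 4
      tm <- th; tm[k] <- tm[k] - pi / 4
      energyNoisy(tp, seed + 1000L * it + 2L * k) -
        energyNoisy(tm, seed + 1000L * it + 2L * k + 1L)
    }, numeric(1))
    th <- th - lr * g
    e <- energyNoisy(th, seed + 1000L * it)
    trace <- c(trace, e)
    gradL1 <- c(gradL1, sum(abs(g)))
    w <- plateau$window
    if (length(trace) > w &&
        abs(mean(utils::tail(trace, w)) -
            mean(utils::head(utils::tail(trace, w + 1L), w))) < plateau$tol)
      break
  }
  est <- energyNoisy(th, seed + 999983L)
  list(energy = est, stderr = NA_real_, theta = th, trace = trace,
       gradL1 = gradL1)
}
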