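#' @include noise.R graphs.R
NULL

# Qubit-wise-commuting measurement grouping, shot-based estimation on the
# (noisy) simulator, measurement-error mitigation, and circuit tiling.

#' Partition a Hamiltonian into qubit-wise commuting groups
#'
#' Greedy colouring of the QWC-incompatibility graph (vertices = non-identity
#' terms, edges between terms that fail qubit-wise commutation), visiting
#' vertices by decreasing degree.  Deterministic.
#'
#' @param H PauliSum
#' @param seed accepted for interface stability; the colouring is
#'   deterministic and ignores it
#' @return list: groups (list of term-index vectors), basis (character
#'   measurement basis string per group, qubit 0 leftmost), identityCoeff
#' @export
qwcPartition <- function(H, seed = 1L) {
  n <- H@nQubits
  nonId <- which(!(H@x == 0L & H@z == 0L))
  m <- length(nonId)
  if (m == 0L) {
    return(list(groups = list(), basis = character(0),
                identityCoeff = Re(identityCoeff(H))))
  }
  sub <- H[nonId]
  compat <- pauliQWCommutes(sub, sub, outer = TRUE)
  deg <- rowSums(!compat)
  ord <- order(-deg, seq_len(m))
  color <- integer(m)
  for (v in ord) {
    used <- unique(color[!compat[v, ] & color > 0L])
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    color[v] <- c0
  }
  ncol <- max(color)
  groups <- lapply(seq_len(ncol), function(c0) nonId[color == c0])
  basis <- vapply(seq_len(ncol), function(c0) {
    sel <- which(color == c0)
    xs <- Reduce(bitwOr, sub@x[sel]); zs <- Reduce(bitwOr, sub@z[sel])
    chars <- rep("Z", n)
    for (q in 0:(n - 1L)) {
      b <- bitwShiftL(1L, q)
      hx <- bitwAnd(xs, b) != 0L; hz <- bitwAnd(zs, b) != 0L
      chars[q + 1L] <- if (hx && hz) "Y" else if (hx) "X" else "Z"
    }
    paste(chars, collapse = "")
  }, character(1))
  list(groups = groups, basis = basis,
       identityCoeff = Re(identityCoeff(H)))
}

## measurement-basis rotation circuit for a basis string
.basisRotation <- function(basis) {
  n <- nchar(basis)
  circ <- quantumCircuit(n)
  chars <- strsplit(basis, "")[[1L]]
  for (q in seq_len(n) - 1L) {
    if (chars[q + 1L] == "X") circ <- addGate(circ, "H", q)
    if (chars[q + 1L] == "Y") circ <- addGate(circ, "Rx", q, pi / 2)
  }
  circ
}

#' Shot-based energy estimation with QWC grouping
#'
#' For every QWC group the state-preparation circuit is extended by the
#' measurement-basis rotation, simulated (statevector when \code{noise} is
#' NULL, density matrix otherwise), sampled with \code{shots} shots, and
#' each member term is estimated from the sampled bit parities.  Optional
#' measurement-error mitigation inverts the readout confusion before
#' estimation.
#'
#' @param H PauliSum
#' @param circ state-preparation QuantumCircuit
#' @param grouping result of [qwcPartition()] (recomputed when NULL)
#' @param noise noiseModel or NULL
#' @param shots shots per group (default 5000)
#' @param seed sampling seed
#' @param mitigate logical: apply [memApply()] with the model's readout
#'   matrices
#' @return list: energy, stderr, perGroup (data.frame)
#' @export
estimateEnergy <- function(H, circ, grouping = NULL, noise = NULL,
                           shots = 5000L, seed = 1L, mitigate = FALSE) {
  n <- H@nQubits
  if (is.null(grouping)) grouping <- qwcPartition(H)
  set.seed(as.integer(seed))
  total <- grouping$identityCoeff
  varTot <- 0
  rows <- list()
  for (gi in seq_along(grouping$groups)) {
    rot <- .basisRotation(grouping$basis[gi])
    full <- circ
    full@gates <- c(full@gates, rot@gates)
    if (is.null(noise)) {
      v <- applyCircuit(full)
      p <- Mod(v)^2
    } else {
      rho <- simulateDensityMatrix(full, noise)
      p <- Re(diag(rho))
      if (!is.null(noise$readout)) {
        p <- applyReadoutConfusion(p, noise$readout)
      }
    }
    p <- pmax(p, 0); p <- p / sum(p)
    if (is.finite(shots)) {
      counts <- as.vector(stats::rmultinom(1L, shots, p))
    } else {
      counts <- p
    }
    if (mitigate && !is.null(noise$readout)) {
      counts <- memApply(counts, noise$readout)$counts
    }
    freq <- counts / sum(counts)
    idx <- 0:(2^n - 1L)
    eg <- 0; varg <- 0
    members <- grouping$groups[[gi]]
    signsList <- lapply(members, function(t) {
      zsup <- bitwOr(H@x[t], H@z[t])   # support of the term
      1 - 2 * bitParity(bitwAnd(idx, zsup))
    })
    cs <- Re(H@coeff[members])
    # per-shot group observable for variance
    gObs <- Reduce(`+`, Map(`*`, signsList, cs))
    eg <- sum(freq * gObs)
    if (is.finite(shots)) {
      varg <- sum(freq * (gObs - eg)^2) / shots
    }
    total <- total + eg
    varTot <- varTot + varg
    rows[[gi]] <- data.frame(basis = grouping$basis[gi],
                             nTerms = length(members),
                             value = eg, variance = varg)
  }
  list(energy = total, stderr = sqrt(varTot),
       perGroup = do.call(rbind, rows))
}

#' Measurement-error mitigation by confusion-matrix inversion
#'
#' Applies the inverse of the tensor-product readout transition matrix to a
#' measured distribution; negative quasi-probabilities are clipped to zero
#' and the result renormalized.
#'
#' @param counts numeric vector over bitstrings (length 2^n), counts or
#'   probabilities
#' @param readout confusion matrix or per-qubit list
#' @return list: counts (rectified, same normalization), clipped (mass
#'   removed by clipping)
#' @export
memApply <- function(counts, readout) {
  n <- as.integer(round(log2(length(counts))))
  if (2^n != length(counts)) stop("counts length must be a power of two")
  ros <- if (is.matrix(readout)) rep(list(readout), n) else readout
  tot <- sum(counts)
  p <- counts / tot
  idx <- 0:(length(p) - 1L)
  for (q in seq_len(n) - 1L) {
    A <- ros[[q + 1L]]
    if (abs(det(A)) < 1e-12) stop("singular readout confusion matrix")
    Ainv <- solve(t(A))   # inverse of the measured-from-true map
    b <- bitwShiftL(1L, q)
    lo <- which(bitwAnd(idx, b) == 0L)
    hi <- lo + b
    p0 <- p[lo]; p1 <- p[hi]
    p[lo] <- Ainv[1L, 1L] * p0 + Ainv[1L, 2L] * p1
    p[hi] <- Ainv[2L, 1L] * p0 + Ainv[2L, 2L] * p1
  }
  clipped <- -sum(p[p < 0])
  p[p < 0] <- 0
  p <- p / sum(p)
  list(counts = p * tot, clipped = clipped)
}

#' Tile a circuit register across a device
#'
#' Greedily finds disjoint connected clusters of the device graph that each
#' embed the circuit's coupling graph (VF2), removing used qubits after
#' every hit.
#'
#' @param gc circuit coupling weightedGraph (or integer: a line of that
#'   many qubits)
#' @param device weightedGraph
#' @return list of integer vectors (device qubits per tile)
#' @export
tileAssignments <- function(gc, device) {
  if (is.numeric(gc) && length(gc) == 1L) {
    gc <- deviceTopology(sprintf("line-%d", as.integer(gc)))
  }
  tiles <- list()
  remaining <- device
  pat <- .toIgraph(gc)
  repeat {
    if (length(remaining$nodes) < length(gc$nodes)) break
    tg <- .toIgraph(remaining)
    iso <- igraph::subgraph_isomorphisms(pat, tg, method = "vf2")
    if (length(iso) == 0L) break
    # prefer peripheral placements: pick the embedding whose nodes leave
    # the fewest severed edges to the rest of the device (ties broken
    # lexicographically) so later tiles are not fragmented
    degs <- igraph::degree(tg)
    cost <- vapply(iso, function(mp) {
      nm <- names(mp)
      sum(degs[nm])
    }, numeric(1))
    keyStr <- vapply(iso, function(mp)
      paste(sort(as.integer(names(mp))), collapse = ","), character(1))
    bestI <- order(cost, keyStr)[1L]
    used <- as.integer(names(iso[[bestI]]))
    tiles[[length(tiles) + 1L]] <- used
    keep <- setdiff(remaining$nodes, used)
    e <- remaining$edges[remaining$edges$u %in% keep &
                         remaining$edges$v %in% keep, , drop = FALSE]
    if (nrow(e) == 0L) {
      remaining <- structure(list(nodes = keep,
                                  edges = e), class = "weightedGraph")
    } else {
      remaining <- weightedGraph(e, nodes = keep)
    }
  }
  tiles
}

#' Tiled noisy estimation
#'
#' Runs [estimateEnergy()] once per tile with per-tile noise parameters
#' drawn from the master seed (emulating spatial noise inhomogeneity) and
#' averages, reporting the standard error over tiles.
#'
#' @param H PauliSum
#' @param circ state-preparation circuit
#' @param tiles list from [tileAssignments()] (only its length is used by
#'   the simulator; tiles index independent noise draws)
#' @param baseNoise noiseModel giving the mean noise parameters
#' @param spread relative spread of per-tile rates (default 0.2)
#' @param shots,seed as in [estimateEnergy()]
#' @param mitigate apply measurement-error mitigation per tile
#' @return list: energy (tile mean), stderr (standard error over tiles),
#'   perTile
#' @export
tiledEstimate <- function(H, circ, tiles, baseNoise, spread = 0.2,
                          shots = 5000L, seed = 1L, mitigate = FALSE) {
  nt <- length(tiles)
  if (nt == 0L) stop("no tiles")
  grouping <- qwcPartition(H)
  set.seed(as.integer(seed))
  vals <- numeric(nt)
  for (ti in seq_len(nt)) {
    fac1 <- max(0, 1 + spread * stats::rnorm(1))
    fac2 <- max(0, 1 + spread * stats::rnorm(1))
    ro <- baseNoise$readout
    nm <- noiseModel(min(0.99, baseNoise$p1 * fac1),
                     min(0.99, baseNoise$p2 * fac2), ro, baseNoise$seed)
    est <- estimateEnergy(H, circ, grouping, noise = nm, shots = shots,
                          seed = seed + ti, mitigate = mitigate)
    vals[ti] <- est$energy
  }
  list(energy = mean(vals),
       stderr = if (nt > 1L) stats::sd(vals) / sqrt(nt) else NA_real_,
       perTile = vals)
}
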