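#' @include circuit.R
NULL

# Weighted graphs for circuit coupling structure and device topologies.
# Represented as a plain list(nodes, edges) with edges a data.frame
# (u, v, w); converted to igraph objects for isomorphism queries.

#' Build a weighted graph
#' @param edges data.frame or matrix with columns u, v, w (0-based node
#'   labels; w defaults to 1)
#' @param nodes optional explicit node set (for isolated nodes)
#' @return weightedGraph list object
#' @export
weightedGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) == 2L) edges$w <- 1
  colnames(edges) <- c("u", "v", "w")
  edges$u <- as.integer(edges$u); edges$v <- as.integer(edges$v)
  if (any(edges$u == edges$v)) stop("self-loops not allowed")
  # canonical undirected form, duplicates merged by weight sum
  lo <- pmin(edges$u, edges$v); hi <- pmax(edges$u, edges$v)
  key <- paste(lo, hi)
  agg <- rowsum(edges$w, key)
  first <- !duplicated(key)
  edges <- data.frame(u = lo[first], v = hi[first],
                      w = agg[match(key[first], rownames(agg)), 1L])
  nodes <- sort(unique(c(nodes, edges$u, edges$v)))
  structure(list(nodes = as.integer(nodes), edges = edges),
            class = "weightedGraph")
}

#' @export
print.weightedGraph <- function(x, ...) {
  cat(sprintf("weightedGraph: %d nodes, %d edges, total weight %g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$w)))
  invisible(x)
}

#' Total edge weight
#' @param g weightedGraph
#' @return numeric
#' @export
totalWeight <- function(g) sum(g$edges$w)

.toIgraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$u), to = as.character(g$edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes)))
}

#' Read / write a device topology as an edge-list text file
#'
#' Format: one edge per line, \code{"u v weight"}; '#' comments ignored.
#'
#' @param file path
#' @return weightedGraph
#' @export
readDeviceGraph <- function(file) {
  lines <- trimws(sub("#.*$", "", readLines(file, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  parts <- do.call(rbind, strsplit(lines, "[[:space:]]+"))
  e <- data.frame(u = as.integer(parts[, 1L]), v = as.integer(parts[, 2L]),
                  w = if (ncol(parts) >= 3L) as.numeric(parts[, 3L]) else 1)
  weightedGraph(e)
}

#' @rdname readDeviceGraph
#' @param g weightedGraph to write
#' @export
writeDeviceGraph <- function(g, file) {
  writeLines(c("# u v weight",
               sprintf("%d %d %g", g$edges$u, g$edges$v, g$edges$w)), file)
  invisible(file)
}

#' Bundled device topologies
#'
#' \code{"heavy-hex-16"} and \code{"heavy-hex-27"} are the 16- and 27-qubit
#' heavy-hexagon coupling maps of the Falcon-generation processors;
#' \code{"heavy-hex-127"} is a 127-node heavy-hexagon lattice in the style
#' of the Eagle generation.  \code{"ring-<n>"} and \code{"line-<n>"} are
#' n-cycles and n-paths.
#'
#' @param name topology name
#' @return weightedGraph
#' @export
deviceTopology <- function(name) {
  if (grepl("^ring-[0-9]+$", name)) {
    n <- as.integer(sub("ring-", "", name))
    return(weightedGraph(data.frame(u = 0:(n - 1L),
                                    v = c(1:(n - 1L), 0L), w = 1)))
  }
  if (grepl("^line-[0-9]+$", name)) {
    n <- as.integer(sub("line-", "", name))
    return(weightedGraph(data.frame(u = 0:(n - 2L), v = 1:(n - 1L), w = 1)))
  }
  if (name == "heavy-hex-16") {
    e <- rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 5), c(1, 4), c(4, 7),
               c(5, 8), c(6, 7), c(7, 10), c(8, 9), c(8, 11), c(10, 12),
               c(12, 15), c(12, 13), c(13, 14), c(11, 14))
    return(weightedGraph(data.frame(u = e[, 1L], v = e[, 2L], w = 1)))
  }
  if (name == "heavy-hex-27") {
    e <- rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 5), c(1, 4), c(4, 7),
               c(5, 8), c(6, 7), c(7, 10), c(8, 9), c(8, 11), c(10, 12),
               c(11, 14), c(12, 13), c(12, 15), c(13, 14), c(14, 16),
               c(15, 18), c(16, 19), c(17, 18), c(18, 21), c(19, 20),
               c(19, 22), c(21, 23), c(22, 25), c(23, 24), c(24, 25),
               c(25, 26))
    return(weightedGraph(data.frame(u = e[, 1L], v = e[, 2L], w = 1)))
  }
  if (name == "heavy-hex-127") {
    edges <- list()
    add <- function(u, v) edges[[length(edges) + 1L]] <<- c(u, v)
    rows <- list(0:13, 18:32, 37:51, 56:70, 75:89, 94:108, 113:126)
    for (rw in rows) for (i in seq_len(length(rw) - 1L))
      add(rw[i], rw[i + 1L])
    # vertical connector qubits between rows
    conn <- list(
      list(ids = 14:17, top = c(0, 4, 8, 12), bot = c(18, 22, 26, 30)),
      list(ids = 33:36, top = c(20, 24, 28, 32), bot = c(39, 43, 47, 51)),
      list(ids = 52:55, top = c(37, 41, 45, 49), bot = c(56, 60, 64, 68)),
      list(ids = 71:74, top = c(58, 62, 66, 70), bot = c(77, 81, 85, 89)),
      list(ids = 90:93, top = c(75, 79, 83, 87), bot = c(94, 98, 102, 106)),
      list(ids = 109:112, top = c(96, 100, 104, 108),
           bot = c(114, 118, 122, 126)))
    for (cn in conn) for (i in seq_along(cn$ids)) {
      add(cn$ids[i], cn$top[i]); add(cn$ids[i], cn$bot[i])
    }
    e <- do.call(rbind, edges)
    return(weightedGraph(data.frame(u = e[, 1L], v = e[, 2L], w = 1)))
  }
  stop("unknown topology ", name)
}

#' Coupling graph of a circuit
#'
#' Nodes are the qubits touched by the circuit; the weight of edge (u, v)
#' counts the two-qubit gates acting on that pair.
#'
#' @param circ QuantumCircuit
#' @return weightedGraph (empty edge set allowed)
#' @export
circuitGraph <- function(circ) {
  us <- integer(0); vs <- integer(0)
  touched <- integer(0)
  for (g in circ@gates) {
    touched <- union(touched, g$qubits)
    if (g$name %in% c("CNOT", "CPhase", "SWAP")) {
      us <- c(us, g$qubits[1L]); vs <- c(vs, g$qubits[2L])
    }
  }
  if (length(us) == 0L) {
    return(structure(list(nodes = sort(as.integer(touched)),
                          edges = data.frame(u = integer(0), v = integer(0),
                                             w = numeric(0))),
                     class = "weightedGraph"))
  }
  weightedGraph(data.frame(u = us, v = vs, w = 1), nodes = touched)
}

#' Hardware-aware bias factor
#'
#' Searches for the smallest number d of deleted circuit-graph nodes such
#' that the remainder embeds in the target topology (VF2 subgraph
#' isomorphism).  Size-d subsets are visited in ascending deleted edge
#' weight s(n), and the first success returns
#' \eqn{(1 - s(n)/W)^b}; if no embedding exists for any d <= D the factor
#' is 0.
#'
#' @param gc circuit weightedGraph
#' @param gt target weightedGraph
#' @param maxDepth D, maximum number of deletions considered
#' @param bias b > 0, biasing strength
#' @return value in [0, 1]
#' @export
biasFactor <- function(gc, gt, maxDepth = 2L, bias = 1) {
  if (bias <= 0) stop("bias strength must be positive")
  W <- totalWeight(gc)
  if (nrow(gc$edges) == 0L) return(1)
  target <- .toIgraph(gt)
  embeds <- function(nodesDrop) {
    keep <- setdiff(gc$nodes, nodesDrop)
    e <- gc$edges[!(gc$edges$u %in% nodesDrop) &
                  !(gc$edges$v %in% nodesDrop), , drop = FALSE]
    if (nrow(e) == 0L) return(TRUE)   # edgeless remainder always embeds
    sub <- weightedGraph(e, nodes = keep)
    igraph::subgraph_isomorphic(.toIgraph(sub), target, method = "vf2")
  }
  for (d in 0:maxDepth) {
    if (d == 0L) {
      if (embeds(integer(0))) return(1)
      next
    }
    if (d > length(gc$nodes)) break
    subsets <- utils::combn(gc$nodes, d)
    sN <- apply(subsets, 2L, function(nd)
      sum(gc$edges$w[gc$edges$u %in% nd | gc$edges$v %in% nd]))
    ord <- order(sN, apply(subsets, 2L, paste, collapse = ","))
    for (j in ord) {
      if (embeds(subsets[, j])) {
        return(max(0, (1 - sN[j] / W))^bias)
      }
    }
  }
  0
}

#' Find an n-cycle inside a device graph
#'
#' @param n ring size
#' @param device weightedGraph
#' @return integer vector of device nodes forming the cycle, or NULL when
#'   none exists
#' @export
ringSubgraph <- function(n, device) {
  ring <- deviceTopology(sprintf("ring-%d", n))
  iso <- igraph::subgraph_isomorphisms(.toIgraph(ring), .toIgraph(device),
                                       method = "vf2")
  if (length(iso) == 0L) return(NULL)
  as.integer(names(iso[[1L]]))
}

#' Route a circuit onto a device topology
#'
#' Greedy nearest-neighbour SWAP insertion: every two-qubit gate between
#' non-adjacent physical qubits is preceded by SWAPs along a shortest path
#' (each SWAP compiled as 3 CNOTs on the device).  A peephole pass cancels
#' adjacent inverse pairs (CNOT-CNOT, H-H, Rz(a)Rz(-a)).  Deterministic.
#'
#' @param circ QuantumCircuit (logical qubits 0..n-1)
#' @param device weightedGraph
#' @param initialMapping optional integer vector: device node hosting each
#'   logical qubit.  When missing, a VF2 embedding of the circuit coupling
#'   graph into the device is used if one exists (so conformant circuits
#'   route without SWAPs); otherwise logical qubit i starts on
#'   \code{device$nodes[i+1]}
#' @return list: circuit (routed, in device labels), cnotCount, mapping
#'   (final logical-to-physical assignment)
#' @export
routeCircuit <- function(circ, device, initialMapping = NULL) {
  ig <- .toIgraph(device)
  devNodes <- device$nodes
  n <- circ@nQubits
  if (length(devNodes) < n) stop("device smaller than circuit register")
  phys <- devNodes[seq_len(n)]     # logical -> physical
  if (!is.null(initialMapping)) {
    phys <- as.integer(initialMapping)
  } else {
    gc <- circuitGraph(circ)
    if (nrow(gc$edges) > 0L) {
      iso <- igraph::subgraph_isomorphisms(.toIgraph(gc), ig,
                                           method = "vf2")
      if (length(iso)) {
        mp <- iso[[1L]]
        hosts <- as.integer(names(mp))
        pat <- as.integer(igraph::V(.toIgraph(gc))$name)
        for (k in seq_along(pat)) {
          if (pat[k] + 1L <= n) phys[pat[k] + 1L] <- hosts[k]
        }
        # place untouched logicals on remaining device nodes
        free <- setdiff(devNodes, phys[pat + 1L])
        rest <- setdiff(seq_len(n), pat + 1L)
        phys[rest] <- free[seq_along(rest)]
      }
    }
  }
  dist <- igraph::distances(ig)
  rownames(dist) <- colnames(dist) <- as.character(devNodes)
  adj <- function(a, b) dist[as.character(a), as.character(b)] == 1
  out <- quantumCircuit(max(devNodes) + 1L)
  for (g in circ@gates) {
    if (length(g$qubits) == 1L) {
      out <- addGate(out, g$name, phys[g$qubits[1L] + 1L], g$angle)
      next
    }
    if (g$name == "PauliRot") stop("route after compiling Pauli rotations")
    a <- g$qubits[1L]; b <- g$qubits[2L]
    while (!adj(phys[a + 1L], phys[b + 1L])) {
      path <- igraph::shortest_paths(
        ig, from = as.character(phys[a + 1L]),
        to = as.character(phys[b + 1L]))$vpath[[1L]]
      nxt <- as.integer(names(path))[2L]
      # swap logical a onto `nxt`; any occupant moves to a's old position
      pa <- phys[a + 1L]
      occ <- which(phys == nxt)
      out <- addGate(out, "SWAP", c(pa, nxt))
      phys[a + 1L] <- nxt
      if (length(occ)) phys[occ] <- pa
    }
    out <- addGate(out, g$name, c(phys[a + 1L], phys[b + 1L]), g$angle)
  }
  out <- .peephole(.expandSwaps(out))
  list(circuit = out, cnotCount = sum(vapply(out@gates, function(g)
    g$name == "CNOT", logical(1))), mapping = phys)
}

## replace SWAP with 3 CNOTs
.expandSwaps <- function(circ) {
  out <- quantumCircuit(circ@nQubits)
  for (g in circ@gates) {
    if (g$name == "SWAP") {
      out <- addGate(out, "CNOT", g$qubits)
      out <- addGate(out, "CNOT", rev(g$qubits))
      out <- addGate(out, "CNOT", g$qubits)
    } else {
      out@gates[[length(out@gates) + 1L]] <- g
    }
  }
  out
}

## cancel adjacent inverse pairs until a fixed point
.peephole <- function(circ) {
  repeat {
    gates <- circ@gates
    ng <- length(gates)
    drop <- logical(ng)
    i <- 1L
    changed <- FALSE
    while (i < ng) {
      if (drop[i]) { i <- i + 1L; next }
      # find next non-dropped gate sharing a qubit
      j <- i + 1L
      blocked <- FALSE
      while (j <= ng) {
        if (!drop[j]) {
          if (length(intersect(gates[[i]]$qubits, gates[[j]]$qubits))) break
        }
        j <- j + 1L
      }
      if (j <= ng && !drop[j]) {
        gi <- gates[[i]]; gj <- gates[[j]]
        cancels <- FALSE
        if (gi$name == gj$name && identical(gi$qubits, gj$qubits)) {
          if (gi$name %in% c("H", "X", "CNOT", "SWAP")) cancels <- TRUE
          if (gi$name %in% c("Rz", "Rx", "Ry") &&
              isTRUE(abs(gi$angle + gj$angle) < 1e-12)) cancels <- TRUE
        }
        if (cancels) {
          drop[i] <- drop[j] <- TRUE
          changed <- TRUE
        }
      }
      i <- i + 1L
    }
    circ@gates <- gates[!drop]
    if (!changed) break
  }
  circ
}
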