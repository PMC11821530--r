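#' @include AllGenerics.R utils.R
NULL

# ---------------------------------------------------------------------------
# Construction
# ---------------------------------------------------------------------------

#' Build a PauliSum
#'
#' @param strings character vector of Pauli strings over \{I, X, Y, Z\};
#'   qubit 0 is the leftmost character.  All strings must share one length.
#' @param coeff numeric or complex coefficients (recycled if length 1).
#' @param nQubits register width; inferred from \code{strings} when omitted.
#'   Required when \code{strings} is empty.
#' @param canonical logical; combine duplicate strings and drop negligible
#'   coefficients (default TRUE).
#' @return a [PauliSum-class] object
#' @examples
#' H <- pauliSum(c("XX", "ZZ", "ZI"), c(0.5, -1, 0.25))
#' l1Norm(H)
#' @export
pauliSum <- function(strings = character(0), coeff = numeric(0),
                     nQubits = NULL, canonical = TRUE) {
  if (length(strings)) {
    wid <- unique(nchar(strings))
    if (length(wid) != 1L) stop("all Pauli strings must have equal length")
    if (is.null(nQubits)) nQubits <- wid
    if (wid != nQubits) stop("string length does not match nQubits")
    if (length(coeff) == 1L) coeff <- rep(coeff, length(strings))
    if (length(coeff) != length(strings))
      stop("coeff must match strings in length")
    chars <- strsplit(strings, "", fixed = TRUE)
    pow <- bitwShiftL(1L, 0:(nQubits - 1L))
    xm <- vapply(chars, function(s) sum(pow[s %in% c("X", "Y")]), numeric(1))
    zm <- vapply(chars, function(s) sum(pow[s %in% c("Z", "Y")]), numeric(1))
    bad <- !vapply(chars, function(s) all(s %in% c("I", "X", "Y", "Z")),
                   logical(1))
    if (any(bad)) stop("invalid Pauli character in: ", strings[bad][1L])
    ps <- new("PauliSum", x = as.integer(xm), z = as.integer(zm),
              coeff = as.complex(coeff), nQubits = as.integer(nQubits))
  } else {
    if (is.null(nQubits)) stop("nQubits required for an empty PauliSum")
    ps <- new("PauliSum", x = integer(0), z = integer(0),
              coeff = complex(0), nQubits = as.integer(nQubits))
  }
  if (canonical) canonicalize(ps) else ps
}

#' Single Pauli term
#'
#' @param string Pauli string, qubit 0 leftmost
#' @param coeff coefficient (default 1)
#' @return PauliSum with one term
#' @export
pauliTerm <- function(string, coeff = 1) pauliSum(string, coeff)

## internal fast constructor from masks (no validity-costly checks repeated)
newPauliSum <- function(x, z, coeff, n) {
  new("PauliSum", x = as.integer(x), z = as.integer(z),
      coeff = as.complex(coeff), nQubits = as.integer(n))
}

#' @rdname pauliStrings
#' @export
setMethod("pauliStrings", "PauliSum", function(object) {
  n <- object@nQubits
  if (nTerms(object) == 0L) return(character(0))
  if (n == 0L) return(rep("", nTerms(object)))
  out <- matrix("I", nTerms(object), n)
  for (j in seq_len(n)) {
    b <- bitwShiftL(1L, j - 1L)
    xb <- bitwAnd(object@x, b) != 0L
    zb <- bitwAnd(object@z, b) != 0L
    out[xb & !zb, j] <- "X"
    out[xb & zb, j] <- "Y"
    out[!xb & zb, j] <- "Z"
  }
  apply(out, 1L, paste, collapse = "")
})

setMethod("show", "PauliSum", function(object) {
  cat(sprintf("PauliSum on %d qubit(s), %d term(s), l1-norm %.6g\n",
              object@nQubits, nTerms(object), l1Norm(object)))
  k <- min(nTerms(object), 8L)
  if (k > 0L) {
    s <- pauliStrings(object)[seq_len(k)]
    cf <- object@coeff[seq_len(k)]
    cfs <- ifelse(abs(Im(cf)) < 1e-12, sprintf("%+.6g", Re(cf)),
                  sprintf("%+.4g%+.4gi", Re(cf), Im(cf)))
    cat(paste0("  ", cfs, " * ", s, collapse = "\n"), "\n")
    if (nTerms(object) > k) cat("  ...\n")
  }
})

# ---------------------------------------------------------------------------
# Canonical form and arithmetic
# ---------------------------------------------------------------------------

## duplicate-mask key; exact for nQubits <= 26
.maskKey <- function(ps) ps@x * 2^26 + ps@z

#' Canonicalize a PauliSum
#'
#' Combines duplicate (x, z) masks, drops coefficients with magnitude below
#' \code{tol}, and orders terms by mask.  The represented operator is
#' unchanged.
#'
#' @param ps PauliSum
#' @param tol drop threshold for coefficient magnitudes (default 1e-12)
#' @return canonical PauliSum
#' @export
canonicalize <- function(ps, tol = 1e-12) {
  if (nTerms(ps) == 0L) return(ps)
  key <- .maskKey(ps)
  o <- order(key)
  key <- key[o]
  cf <- ps@coeff[o]
  grp <- cumsum(c(TRUE, diff(key) != 0))
  cre <- rowsum(Re(cf), grp)[, 1L]
  cim <- rowsum(Im(cf), grp)[, 1L]
  keep <- !duplicated(key)
  xs <- ps@x[o][keep]; zs <- ps@z[o][keep]
  cf <- complex(real = cre, imaginary = cim)
  sel <- Mod(cf) > tol
  newPauliSum(xs[sel], zs[sel], cf[sel], ps@nQubits)
}

#' Product of two Pauli operators
#'
#' Full distributive product with exact \eqn{\{\pm 1, \pm i\}} phase
#' bookkeeping from the symplectic representation.
#'
#' @param a,b PauliSum objects on the same register
#' @param canonical canonicalize the result (default TRUE)
#' @return PauliSum of the product \code{a \%*\% b}
#' @export
pauliProduct <- function(a, b, canonical = TRUE) {
  if (a@nQubits != b@nQubits)
    stop("dimension error: operands act on different register widths")
  na <- nTerms(a); nb <- nTerms(b)
  if (na == 0L || nb == 0L) return(pauliSum(nQubits = a@nQubits))
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  x1 <- a@x[ia]; z1 <- a@z[ia]; x2 <- b@x[ib]; z2 <- b@z[ib]
  x3 <- bitwXor(x1, x2); z3 <- bitwXor(z1, z2)
  # phase i^p with p = |x1^z1| + |x2^z2| - |x3^z3| + 2|z1^x2|  (mod 4)
  p <- (bitCount(bitwAnd(x1, z1)) + bitCount(bitwAnd(x2, z2)) -
        bitCount(bitwAnd(x3, z3)) + 2L * bitCount(bitwAnd(z1, x2))) %% 4L
  ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[p + 1L]
  out <- newPauliSum(x3, z3, a@coeff[ia] * b@coeff[ib] * ph, a@nQubits)
  if (canonical) canonicalize(out) else out
}

#' Sum, difference, and scaling of PauliSums
#' @param e1,e2 PauliSum objects (or one scalar for \code{*})
#' @return PauliSum
#' @name PauliSum-arith
#' @aliases +,PauliSum,PauliSum-method
#' @export
setMethod("+", signature("PauliSum", "PauliSum"), function(e1, e2) {
  if (e1@nQubits != e2@nQubits) stop("register width mismatch")
  canonicalize(newPauliSum(c(e1@x, e2@x), c(e1@z, e2@z),
                           c(e1@coeff, e2@coeff), e1@nQubits))
})

#' @rdname PauliSum-arith
#' @export
setMethod("-", signature("PauliSum", "PauliSum"), function(e1, e2) {
  e1 + (-1) * e2
})

#' @rdname PauliSum-arith
#' @export
setMethod("*", signature("numeric", "PauliSum"), function(e1, e2) {
  newPauliSum(e2@x, e2@z, e1 * e2@coeff, e2@nQubits)
})

#' @rdname PauliSum-arith
#' @export
setMethod("*", signature("complex", "PauliSum"), function(e1, e2) {
  newPauliSum(e2@x, e2@z, e1 * e2@coeff, e2@nQubits)
})

#' @rdname PauliSum-arith
#' @export
setMethod("*", signature("PauliSum", "PauliSum"), function(e1, e2) {
  pauliProduct(e1, e2)
})

#' Subset terms of a PauliSum
#' @param x PauliSum
#' @param i index vector over terms
#' @param j,...,drop ignored
#' @return PauliSum with the selected terms
#' @export
setMethod("[", "PauliSum", function(x, i, j, ..., drop = TRUE) {
  newPauliSum(x@x[i], x@z[i], x@coeff[i], x@nQubits)
})

# ---------------------------------------------------------------------------
# Commutation structure
# ---------------------------------------------------------------------------

#' Pairwise commutation tests
#'
#' \code{pauliCommutes} tests full commutation (symplectic form vanishes);
#' \code{pauliQWCommutes} tests qubit-wise commutation (on every qubit the
#' factors are equal or at least one is the identity).  Both are vectorised
#' over the terms of \code{a} and \code{b} elementwise when the term counts
#' match, otherwise all pairs are compared (outer mode).
#'
#' @param a,b PauliSum objects (single- or multi-term)
#' @param outer logical; force the all-pairs matrix result
#' @return logical vector, or matrix (terms of a x terms of b) when
#'   \code{outer = TRUE}
#' @export
pauliCommutes <- function(a, b, outer = FALSE) {
  if (a@nQubits != b@nQubits)
    stop("dimension error: register width mismatch")
  if (!outer && nTerms(a) == nTerms(b)) {
    return(bitParity(bitwAnd(a@x, b@z)) == bitParity(bitwAnd(a@z, b@x)))
  }
  m <- matrix(FALSE, nTerms(a), nTerms(b))
  for (jj in seq_len(nTerms(b))) {
    m[, jj] <- bitParity(bitwAnd(a@x, b@z[jj])) ==
               bitParity(bitwAnd(a@z, b@x[jj]))
  }
  m
}

#' @rdname pauliCommutes
#' @export
pauliQWCommutes <- function(a, b, outer = FALSE) {
  if (a@nQubits != b@nQubits)
    stop("dimension error: register width mismatch")
  qwc1 <- function(x1, z1, x2, z2) {
    # overlap = qubits where both are non-identity; require equal letters there
    s1 <- bitwOr(x1, z1); s2 <- bitwOr(x2, z2)
    ov <- bitwAnd(s1, s2)
    (bitwAnd(bitwXor(x1, x2), ov) == 0L) & (bitwAnd(bitwXor(z1, z2), ov) == 0L)
  }
  if (!outer && nTerms(a) == nTerms(b)) {
    return(qwc1(a@x, a@z, b@x, b@z))
  }
  m <- matrix(FALSE, nTerms(a), nTerms(b))
  for (jj in seq_len(nTerms(b))) {
    m[, jj] <- qwc1(a@x, a@z, b@x[jj], b@z[jj])
  }
  m
}

## anticommutation parity matrix over GF(2): entry 1 iff terms anticommute
.anticommuteMatrix <- function(a, b = a) {
  1L - pauliCommutes(a, b, outer = TRUE) * 1L
}

#' Test a Pauli operator set for noncontextuality
#'
#' A set S is noncontextual when, after removing the elements Z' that commute
#' with all of S, commutation restricted to the remainder is transitive: the
#' remainder splits into classes with intra-class commutation and inter-class
#' anticommutation.  Coefficients are irrelevant.
#'
#' @param ps PauliSum whose terms form the set S (must be nonempty)
#' @return logical
#' @examples
#' isNoncontextual(pauliSum(c("ZI", "IZ", "ZZ"), 1))    # TRUE
#' isNoncontextual(pauliSum(c("XI", "ZI", "XX", "ZZ"), 1))  # FALSE
#' @export
isNoncontextual <- function(ps) {
  m <- nTerms(ps)
  if (m == 0L) stop("noncontextuality is undefined for an empty set")
  A <- .anticommuteMatrix(ps)
  universal <- rowSums(A) == 0L
  rest <- which(!universal)
  if (length(rest) <= 1L) return(TRUE)
  Ar <- A[rest, rest, drop = FALSE]
  # classes = connected components of the COMMUTE graph on `rest`;
  # noncontextual iff each component is fully commuting internally and fully
  # anticommuting with the others, i.e. the commute relation is transitive.
  Cm <- 1L - Ar
  diag(Cm) <- 0L
  lab <- .componentsFromAdjacency(Cm)
  for (l in unique(lab)) {
    idx <- which(lab == l)
    if (any(Ar[idx, idx, drop = FALSE] == 1L)) return(FALSE)
  }
  TRUE
}

## connected components of an undirected 0/1 adjacency matrix (BFS)
.componentsFromAdjacency <- function(adj) {
  n <- nrow(adj)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] == 1L & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# ---------------------------------------------------------------------------
# Norms, matrices, spectra
# ---------------------------------------------------------------------------

#' l1-norm of the coefficient vector
#'
#' \eqn{\Lambda = \sum_i |h_i|}, which governs the VQE sampling overhead
#' \eqn{O(\Lambda^2 / \epsilon^2)}.
#'
#' @param ps PauliSum
#' @param canonical canonicalize first (default TRUE) so duplicate masks do
#'   not inflate the norm
#' @return non-negative real
#' @export
l1Norm <- function(ps, canonical = TRUE) {
  if (canonical) ps <- canonicalize(ps)
  sum(Mod(ps@coeff))
}

#' Dense matrix representation
#'
#' Builds the \eqn{2^n \times 2^n} complex matrix of the operator.  Intended
#' for oracles and small registers (n <= 12).
#'
#' @param ps PauliSum
#' @return complex matrix
#' @export
pauliMatrix <- function(ps) {
  n <- ps@nQubits
  if (n > 14L) stop("dense matrix limited to 14 qubits")
  d <- 2^n
  M <- matrix(0i, d, d)
  r <- 0:(d - 1L)
  for (t in seq_len(nTerms(ps))) {
    xm <- ps@x[t]; zm <- ps@z[t]
    ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[(bitCount(bitwAnd(xm, zm)) %% 4L) + 1L]
    sgn <- 1 - 2 * bitParity(bitwAnd(r, zm))
    rows <- bitwXor(r, xm)
    M[cbind(rows + 1L, r + 1L)] <- M[cbind(rows + 1L, r + 1L)] +
      ps@coeff[t] * ph * sgn
  }
  M
}

## apply PauliSum to a statevector (little-endian basis index)
pauliApply <- function(ps, v) {
  d <- length(v)
  r <- 0:(d - 1L)
  out <- complex(length.out = d)
  for (t in seq_len(nTerms(ps))) {
    xm <- ps@x[t]; zm <- ps@z[t]
    ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[(bitCount(bitwAnd(xm, zm)) %% 4L) + 1L]
    sgn <- 1 - 2 * bitParity(bitwAnd(r, zm))
    amp <- ps@coeff[t] * ph * sgn * v
    idx <- bitwXor(r, xm) + 1L
    out[idx] <- out[idx] + amp
  }
  out
}

## Fast matvec closure: terms are grouped by X-mask; each group contributes
## y[r XOR x] += f_x(r) v(r) with a precomputed diagonal f_x collecting all
## Z-phases and coefficients of the group.  O(#unique-x) vector ops per
## matvec instead of O(#terms).
pauliMatvecOperator <- function(ps) {
  n <- ps@nQubits
  d <- 2^n
  r <- 0:(d - 1L)
  ux <- unique(ps@x)
  fx <- vector("list", length(ux))
  perm <- vector("list", length(ux))
  allReal <- TRUE
  for (k in seq_along(ux)) {
    sel <- which(ps@x == ux[k])
    acc <- complex(length.out = d)
    for (t in sel) {
      zm <- ps@z[t]
      ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[
        (bitCount(bitwAnd(ps@x[t], zm)) %% 4L) + 1L]
      acc <- acc + ps@coeff[t] * ph * (1 - 2 * bitParity(bitwAnd(r, zm)))
    }
    if (any(abs(Im(acc)) > 1e-13)) allReal <- FALSE
    fx[[k]] <- acc
    perm[[k]] <- bitwXor(r, ux[k]) + 1L
  }
  if (allReal) fx <- lapply(fx, Re)
  list(
    matvec = function(v) {
      y <- if (is.complex(v) || !allReal) complex(length.out = d) else
        numeric(d)
      for (k in seq_along(ux)) {
        z <- fx[[k]] * v
        y[perm[[k]]] <- y[perm[[k]]] + z
      }
      y
    },
    real = allReal, dim = d)
}

## real/imaginary sparse split of the matrix representation, for fast
## Hermitian matvecs through the Matrix package
pauliSparseParts <- function(ps) {
  n <- ps@nQubits
  d <- 2^n
  r <- 0:(d - 1L)
  nt <- nTerms(ps)
  ii <- vector("list", nt); jj <- vector("list", nt); vv <- vector("list", nt)
  for (t in seq_len(nt)) {
    xm <- ps@x[t]; zm <- ps@z[t]
    ph <- c(1 + 0i, 1i, -1 + 0i, -1i)[(bitCount(bitwAnd(xm, zm)) %% 4L) + 1L]
    sgn <- 1 - 2 * bitParity(bitwAnd(r, zm))
    ii[[t]] <- bitwXor(r, xm) + 1L
    jj[[t]] <- r + 1L
    vv[[t]] <- ps@coeff[t] * ph * sgn
  }
  ii <- unlist(ii); jj <- unlist(jj); vv <- unlist(vv)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(vv), dims = c(d, d))
  B <- NULL
  if (any(abs(Im(vv)) > 0)) {
    B <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(vv), dims = c(d, d))
  }
  list(A = A, B = B)
}

#' Exact lowest eigenvalue of a PauliSum
#'
#' Dense diagonalization for small registers, Lanczos with full
#' reorthogonalisation on a sparse representation for larger ones.  The
#' operator must be Hermitian.
#'
#' @param ps PauliSum (n <= 16)
#' @param vector logical; also return the ground eigenvector
#' @param v0 optional complex start vector for the iterative branch
#' @return numeric energy, or list(value, vector)
#' @export
groundEnergyExact <- function(ps, vector = FALSE, v0 = NULL) {
  n <- ps@nQubits
  if (n > 16L) stop("exact diagonalization limited to 16 qubits")
  if (nTerms(ps) == 0L) {
    if (vector) return(list(value = 0, vector = c(1, rep(0, 2^n - 1))))
    return(0)
  }
  if (n <= 8L) {
    M <- pauliMatrix(ps)
    if (max(abs(M - Conj(t(M)))) > 1e-9) stop("operator is not Hermitian")
    ev <- eigen(M, symmetric = TRUE)
    if (vector) {
      return(list(value = ev$values[2^n],
                  vector = as.vector(ev$vectors[, 2^n])))
    }
    return(ev$values[2^n])
  }
  op <- pauliMatvecOperator(ps)
  if (op$real && is.null(v0)) v0 <- cos(0.7 * seq_len(2^n))
  if (op$real && !is.null(v0) && is.complex(v0) &&
      all(abs(Im(v0)) < 1e-14)) v0 <- Re(v0)
  res <- lanczosGround(op$matvec, 2^n, v0 = v0, maxiter = min(300L, 2^n),
                       tol = if (n >= 13L) 1e-9 else 1e-11,
                       vectors = vector)
  res
}

#' Expectation value of a PauliSum in a statevector
#' @param ps PauliSum
#' @param v complex statevector of length 2^nQubits
#' @return real expectation (imaginary part dropped for Hermitian operators)
#' @export
pauliExpectation <- function(ps, v) {
  Re(sum(Conj(v) * pauliApply(ps, v)))
}

# ---------------------------------------------------------------------------
# Random fixtures
# ---------------------------------------------------------------------------

#' Seeded random PauliSum fixture
#'
#' Reproducible random Hermitian PauliSum with real coefficients; used by
#' property tests.
#'
#' @param nQubits register width
#' @param nTerms number of terms drawn (may dedupe to fewer)
#' @param seed integer seed
#' @param coefRange coefficients drawn uniformly from \code{[-coefRange,
#'   coefRange]}
#' @return PauliSum
#' @export
randomPauliSum <- function(nQubits, nTerms, seed, coefRange = 1) {
  stopifnot(nQubits >= 1L, nTerms >= 1L)
  set.seed(as.integer(seed))
  lim <- 2^nQubits
  x <- as.integer(floor(stats::runif(nTerms) * lim))
  z <- as.integer(floor(stats::runif(nTerms) * lim))
  cf <- stats::runif(nTerms, -coefRange, coefRange)
  canonicalize(newPauliSum(x, z, cf, nQubits))
}

#' Identity-coefficient of a PauliSum
#' @param ps PauliSum
#' @return complex coefficient of the all-identity term (0 when absent)
#' @export
identityCoeff <- function(ps) {
  idx <- which(ps@x == 0L & ps@z == 0L)
  if (length(idx) == 0L) return(0 + 0i)
  sum(ps@coeff[idx])
}
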