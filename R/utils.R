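# Internal numerical utilities: bit manipulation on qubit masks, GF(2) linear
# algebra, Boys function, Lanczos ground-state solver.

.csvqe_env <- new.env(parent = emptyenv())

# 16-bit popcount lookup table, built on first use.
.popcountTable <- function() {
  tab <- .csvqe_env$pc16
  if (is.null(tab)) {
    b <- 0:65535
    tab <- integer(65536L)
    v <- b
    while (any(v > 0L)) {
      tab <- tab + (v %% 2L)
      v <- v %/% 2L
    }
    .csvqe_env$pc16 <- tab
  }
  tab
}

## popcount of non-negative integers < 2^30 (vectorised)
bitCount <- function(v) {
  tab <- .popcountTable()
  tab[bitwAnd(v, 65535L) + 1L] + tab[bitwShiftR(v, 16L) + 1L]
}

bitParity <- function(v) bitwAnd(bitCount(v), 1L)

## bits set in each mask, as a list of 0-based qubit indices
maskToBits <- function(v, n) {
  lapply(v, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L) - 1L)
}

bitsToMask <- function(bits) {
  if (length(bits) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(bits)))
}

## GF(2) row reduction of a logical/0-1 matrix.  Returns list(mat, pivots, rank)
## with `mat` in reduced row echelon form (zero rows dropped).
gf2Rref <- function(m) {
  m <- matrix(as.integer(m) %% 2L, nrow = nrow(m))
  nr <- nrow(m); nc <- ncol(m)
  pivots <- integer(0)
  r <- 1L
  for (c in seq_len(nc)) {
    if (r > nr) break
    sel <- which(m[r:nr, c] == 1L)
    if (length(sel) == 0L) next
    piv <- r + sel[1L] - 1L
    if (piv != r) m[c(r, piv), ] <- m[c(piv, r), ]
    hit <- which(m[, c] == 1L)
    hit <- hit[hit != r]
    if (length(hit)) m[hit, ] <- (m[hit, , drop = FALSE] +
                                  rep(m[r, ], each = length(hit))) %% 2L
    pivots <- c(pivots, c)
    r <- r + 1L
  }
  rank <- length(pivots)
  list(mat = m[seq_len(rank), , drop = FALSE], pivots = pivots, rank = rank)
}

## Kernel basis (rows) of a 0-1 matrix over GF(2).
gf2Kernel <- function(m) {
  nc <- ncol(m)
  rr <- gf2Rref(m)
  piv <- rr$pivots
  free <- setdiff(seq_len(nc), piv)
  if (length(free) == 0L) return(matrix(integer(0), nrow = 0L, ncol = nc))
  ker <- matrix(0L, nrow = length(free), ncol = nc)
  for (k in seq_along(free)) {
    f <- free[k]
    ker[k, f] <- 1L
    if (rr$rank > 0L) {
      # pivot rows: x_piv = sum over free columns of row entries
      ker[k, piv] <- rr$mat[, f]
    }
  }
  ker %% 2L
}

## Solve x A = b over GF(2) for row vectors (A rows are generators).
## Returns integer vector of coefficients or NULL if unsolvable.
gf2SolveRow <- function(A, b) {
  nr <- nrow(A)
  if (nr == 0L) {
    if (all(b %% 2L == 0L)) return(integer(0)) else return(NULL)
  }
  # elimination on the augmented system A^T x^T = b^T
  M <- cbind(t(A) %% 2L, as.integer(b) %% 2L)
  nv <- nr
  r <- 1L
  piv <- integer(0)
  for (c in seq_len(nv)) {
    if (r > nrow(M)) break
    sel <- which(M[r:nrow(M), c] == 1L)
    if (length(sel) == 0L) next
    p <- r + sel[1L] - 1L
    if (p != r) M[c(r, p), ] <- M[c(p, r), ]
    hit <- which(M[, c] == 1L); hit <- hit[hit != r]
    if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] +
                                  rep(M[r, ], each = length(hit))) %% 2L
    piv <- c(piv, c)
    r <- r + 1L
  }
  if (r <= nrow(M) && any(M[r:nrow(M), nv + 1L] == 1L)) return(NULL)
  x <- integer(nv)
  x[piv] <- M[seq_along(piv), nv + 1L]
  x
}

## Boys function F_m(T), vectorised over T, for m = 0..mmax.
## Returns matrix length(T) x (mmax+1).
boysF <- function(T, mmax) {
  T <- as.numeric(T)
  out <- matrix(0, length(T), mmax + 1L)
  small <- T < 1e-13
  for (m in 0:mmax) {
    fm <- numeric(length(T))
    if (any(!small)) {
      Tb <- T[!small]
      # F_m(T) = Gamma(m+1/2) P(m+1/2, T) / (2 T^{m+1/2})
      fm[!small] <- gamma(m + 0.5) * pgamma(Tb, m + 0.5) / (2 * Tb^(m + 0.5))
    }
    if (any(small)) {
      Ts <- T[small]
      fm[small] <- 1 / (2 * m + 1) - Ts / (2 * m + 3) + Ts^2 / (2 * (2 * m + 5))
    }
    out[, m + 1L] <- fm
  }
  out
}

## Lanczos with full reorthogonalisation for the lowest eigenvalue of a
## Hermitian operator given as a matvec closure.  Deterministic start vector.
lanczosGround <- function(matvec, dim, v0 = NULL, maxiter = 200L, tol = 1e-10,
                          vectors = FALSE) {
  if (is.null(v0)) {
    v0 <- complex(real = cos(0.7 * seq_len(dim)), imaginary = 0)
  }
  v0 <- v0 / sqrt(sum(Mod(v0)^2))
  V <- matrix(if (is.complex(v0)) 0i else 0, dim, min(maxiter, dim))
  alpha <- numeric(0); beta <- numeric(0)
  V[, 1L] <- v0
  prev <- Inf
  for (j in seq_len(ncol(V))) {
    w <- matvec(V[, j])
    a <- Re(sum(Conj(V[, j]) * w))
    alpha <- c(alpha, a)
    w <- w - a * V[, j]
    if (j > 1L) w <- w - beta[j - 1L] * V[, j - 1L]
    # full reorthogonalisation (twice for stability)
    for (rep in 1:2) {
      proj <- crossprod(Conj(V[, seq_len(j), drop = FALSE]), w)
      w <- w - V[, seq_len(j), drop = FALSE] %*% proj
    }
    b <- sqrt(sum(Mod(w)^2))
    Tm <- diag(alpha, nrow = j)
    if (j > 1L) {
      for (k in seq_len(j - 1L)) {
        Tm[k, k + 1L] <- Tm[k + 1L, k] <- beta[k]
      }
    }
    ev <- eigen(Tm, symmetric = TRUE)
    lam <- ev$values[j]
    if (abs(lam - prev) < tol && j > 3L) {
      if (!vectors) return(lam)
      y <- ev$vectors[, j]
      vec <- V[, seq_len(j), drop = FALSE] %*% y
      return(list(value = lam, vector = as.vector(vec)))
    }
    prev <- lam
    if (b < 1e-12) {  # invariant subspace reached
      if (!vectors) return(lam)
      y <- ev$vectors[, j]
      vec <- V[, seq_len(j), drop = FALSE] %*% y
      return(list(value = lam, vector = as.vector(vec)))
    }
    beta <- c(beta, b)
    if (j < ncol(V)) V[, j + 1L] <- w / b
  }
  if (!vectors) return(prev)
  y <- ev$vectors[, ncol(V)]
  list(value = prev, vector = as.vector(V %*% y))
}

## physical constants
hartree_to_eV <- 27.211386245988
angstrom_to_bohr <- 1 / 0.529177210903

`%||%` <- function(a, b) if (is.null(a)) b else a
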