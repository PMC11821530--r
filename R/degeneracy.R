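#' @include utils.R
NULL

#' Molecular-orbital degeneracy detection function
#'
#' For canonical MO energies \eqn{\mu_1, ..., \mu_M} the metric averages,
#' over all index tuples \eqn{j_1 < ... < j_i} at each depth
#' \eqn{i \in [2, D_{max}]}, the kernel
#' \deqn{\frac{\delta\sqrt{\pi}}{2} \,
#'       \mathrm{erf}(x/\delta)/x, \quad
#'       x = \mu_{j_i} - \sum_{k<i} \mu_{j_k},}
#' normalized by \eqn{1/\binom{M}{i}} per depth and \eqn{1/(D_{max}-1)}
#' overall.  The kernel tends to the Kronecker delta \eqn{\delta_{x,0}} as
#' \eqn{\delta \to 0}, so at \eqn{\delta = 0} exact (near-)degeneracies are
#' counted; for \eqn{\delta > 0} near-degeneracies within roughly
#' \eqn{\delta} Hartree contribute.  The value always lies in [0, 1] and is
#' non-decreasing in \eqn{\delta}.
#'
#' Depths \eqn{i \ge 3} compare one level against a *sum* of others; the
#' result then depends on the order of \eqn{\mu}, which is fixed to
#' ascending (the canonical SCF ordering).
#'
#' @param mu numeric vector of MO energies (Hartree); used in ascending
#'   order
#' @param delta filtering parameter, >= 0 (Hartree)
#' @param dMax truncation depth, between 2 and length(mu); default full
#'   depth
#' @return value in [0, 1]
#' @examples
#' sDelta(c(1, 1), delta = 0)        # 1: one exactly degenerate pair
#' sDelta(c(0, 1), delta = 0)        # 0
#' @export
sDelta <- function(mu, delta = 0.05, dMax = length(mu)) {
  M <- length(mu)
  if (delta < 0) stop("delta must be >= 0")
  if (dMax < 2L || dMax > M) stop("dMax must lie in [2, length(mu)]")
  mu <- sort(mu)
  kern <- function(x) {
    out <- numeric(length(x))
    if (delta == 0) {
      out[abs(x) < 1e-12] <- 1
      return(out)
    }
    small <- abs(x) < 1e-12
    out[small] <- 1   # analytic limit of erf(x/d)*d*sqrt(pi)/(2x)
    xs <- x[!small]
    out[!small] <- delta * sqrt(pi) / 2 * .erf(xs / delta) / xs
    out
  }
  total <- 0
  for (i in 2:dMax) {
    combos <- utils::combn(M, i)
    x <- mu[combos[i, ]] - colSums(matrix(mu[combos[-i, , drop = FALSE]],
                                          nrow = i - 1L))
    total <- total + sum(kern(x)) / choose(M, i)
  }
  total / (dMax - 1)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Degeneracy metric along a bond-length scan
#'
#' Evaluates [sDelta()] for each entry of a list of MO-energy vectors and
#' reports interior local maxima.
#'
#' @param muList named list (names = bond lengths) or list of numeric
#'   vectors
#' @param r numeric bond lengths (defaults to parsed names)
#' @param delta,dMax passed to [sDelta()]
#' @return data.frame (r, s, isPeak)
#' @export
degeneracyScan <- function(muList, r = as.numeric(names(muList)),
                           delta = 0.05, dMax = NULL) {
  s <- vapply(muList, function(mu)
    sDelta(mu, delta = delta, dMax = dMax %||% length(mu)), numeric(1))
  n <- length(s)
  isPeak <- rep(FALSE, n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      isPeak[i] <- s[i] > s[i - 1L] && s[i] >= s[i + 1L]
    }
  }
  data.frame(r = r, s = s, isPeak = isPeak)
}
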