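# Dense-matrix oracles used across the suite.

.sigma <- list(
  I = diag(2) + 0i,
  X = matrix(c(0, 1, 1, 0), 2) + 0i,
  Y = matrix(c(0, 1i, -1i, 0), 2),
  Z = diag(c(1, -1)) + 0i)

## dense matrix of a Pauli string by Kronecker products (qubit 0 leftmost in
## the string = lowest bit of the basis index, so it is the LAST kron factor)
kronPauli <- function(string) {
  chars <- strsplit(string, "")[[1L]]
  M <- .sigma[[chars[1L]]]                 # qubit 0 = lowest bit
  for (c0 in chars[-1L]) M <- kronecker(.sigma[[c0]], M)
  M
}

kronPauliSum <- function(ps) {
  ss <- pauliStrings(ps)
  d <- 2^nQubits(ps)
  M <- matrix(0i, d, d)
  for (i in seq_along(ss)) M <- M + coeffs(ps)[i] * kronPauli(ss[i])
  M
}

## shared small-molecule fixtures (computed once per test run)
.fix <- new.env(parent = emptyenv())

h2Fixture <- function(r = 0.74) {
  key <- sprintf("h2_%.3f", r)
  got <- .fix[[key]]
  if (!is.null(got)) return(got)
  hf <- scfRHF(h2Geometry(r))
  out <- list(hf = hf, fci = fciEnergy(hf), mp2 = mp2Energy(hf))
  out$qb <- buildQubitHamiltonian(h2Geometry(r), hf = hf)
  out$taper <- taperMolecularHamiltonian(out$qb)
  .fix[[key]] <- out
  out
}
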