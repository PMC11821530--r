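#' @include pauli.R
NULL

#' Read / write the Pauli-Hamiltonian text format
#'
#' One term per line: \code{"<real> <imag> <pauli-string>"}, with \code{'#'}
#' comments and blank lines ignored.  Qubit 0 is the leftmost character of
#' the string.  \code{writePauliSum} followed by \code{readPauliSum}
#' round-trips bit-exactly on the string form.
#'
#' @param file path to a text file
#' @return \code{readPauliSum}: a [PauliSum-class].
#' @export
readPauliSum <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no Pauli terms found in ", file)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed line: ", lines[bad][1L])
  re <- as.numeric(vapply(parts, `[`, "", 1L))
  im <- as.numeric(vapply(parts, `[`, "", 2L))
  ss <- vapply(parts, `[`, "", 3L)
  pauliSum(ss, complex(real = re, imaginary = im), canonical = FALSE)
}

#' @rdname readPauliSum
#' @param ps PauliSum to write
#' @return \code{writePauliSum}: the file path, invisibly.
#' @export
writePauliSum <- function(ps, file) {
  s <- pauliStrings(ps)
  lines <- sprintf("%.17g %.17g %s", Re(ps@coeff), Im(ps@coeff), s)
  writeLines(c(sprintf("# PauliSum: %d qubits, %d terms", ps@nQubits,
                       nTerms(ps)), lines), file)
  invisible(file)
}
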