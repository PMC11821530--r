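#' @include utils.R
NULL

# STO-3G basis data (exponents / contraction coefficients for normalized
# primitives), elements needed for the shipped examples and tests.
.sto3g <- list(
  H = list(
    list(l = 0L, exps = c(3.42525091, 0.62391373, 0.16885540),
         coefs = c(0.15432897, 0.53532814, 0.44463454))
  ),
  He = list(
    list(l = 0L, exps = c(6.36242139, 1.15892300, 0.31364979),
         coefs = c(0.15432897, 0.53532814, 0.44463454))
  ),
  N = list(
    list(l = 0L, exps = c(99.1061690, 18.0523120, 4.8856602),
         coefs = c(0.15432897, 0.53532814, 0.44463454)),
    list(l = 0L, exps = c(3.7804559, 0.8784966, 0.2857144),
         coefs = c(-0.09996723, 0.39951283, 0.70011547)),
    list(l = 1L, exps = c(3.7804559, 0.8784966, 0.2857144),
         coefs = c(0.15591627, 0.60768372, 0.44317674))
  ),
  O = list(
    list(l = 0L, exps = c(130.7093200, 23.8088610, 6.4436083),
         coefs = c(0.15432897, 0.53532814, 0.44463454)),
    list(l = 0L, exps = c(5.0331513, 1.1695961, 0.3803890),
         coefs = c(-0.09996723, 0.39951283, 0.70011547)),
    list(l = 1L, exps = c(5.0331513, 1.1695961, 0.3803890),
         coefs = c(0.15591627, 0.60768372, 0.44317674))
  )
)

.elementZ <- c(H = 1L, He = 2L, N = 7L, O = 8L)

#' Molecular geometry constructor
#'
#' @param atoms character vector of element symbols (H, He, N, O supported by
#'   the built-in STO-3G tables)
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom
#' @param charge total charge
#' @param multiplicity spin multiplicity 2S+1
#' @param basis basis-set name; only \code{"sto-3g"} is built in
#' @return a \code{molecularGeometry} list object
#' @examples
#' geom <- n2Geometry(1.192)
#' @export
molecularGeometry <- function(atoms, coords, charge = 0L, multiplicity = 1L,
                              basis = "sto-3g") {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) != length(atoms))
    stop("coordinate count must equal atom count")
  if (!all(atoms %in% names(.elementZ)))
    stop("unsupported element; built-in tables cover ",
         paste(names(.elementZ), collapse = ", "))
  if (tolower(basis) != "sto-3g") stop("only the STO-3G basis is built in")
  structure(list(atoms = atoms, coords = coords, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity), basis = "sto-3g"),
            class = "molecularGeometry")
}

#' Dinitrogen at a given bond length
#' @param r interatomic separation in Angstrom
#' @return molecularGeometry for N2 along the z axis
#' @export
n2Geometry <- function(r) {
  molecularGeometry(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, r)))
}

#' Dihydrogen at a given bond length
#' @param r interatomic separation in Angstrom
#' @return molecularGeometry for H2 along the z axis
#' @export
h2Geometry <- function(r) {
  molecularGeometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
}

#' Read an XYZ geometry file
#'
#' Standard XYZ dialect: atom count line, comment line, then
#' \code{element x y z} with coordinates in Angstrom.
#'
#' @param file path
#' @param charge,multiplicity passed through to [molecularGeometry()]
#' @return molecularGeometry
#' @export
readXYZ <- function(file, charge = 0L, multiplicity = 1L) {
  lines <- trimws(readLines(file, warn = FALSE))
  n <- as.integer(lines[1L])
  rows <- strsplit(lines[3:(2L + n)], "[[:space:]]+")
  atoms <- vapply(rows, `[`, "", 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecularGeometry(atoms, coords, charge, multiplicity)
}

## shell list in Bohr units with normalized primitive coefficients
buildShells <- function(geom) {
  shells <- list()
  for (ia in seq_along(geom$atoms)) {
    el <- geom$atoms[ia]
    center <- geom$coords[ia, ] * angstrom_to_bohr
    for (sh in .sto3g[[el]]) {
      a <- sh$exps
      # primitive norms: s (2a/pi)^(3/4); p adds 2 sqrt(a)
      nrm <- (2 * a / pi)^0.75
      if (sh$l == 1L) nrm <- nrm * 2 * sqrt(a)
      shells[[length(shells) + 1L]] <- list(
        l = sh$l, exps = a, coefs = sh$coefs * nrm,
        center = center, atom = ia)
    }
  }
  shells
}

## number of basis functions and shell -> function offsets
shellOffsets <- function(shells) {
  sizes <- vapply(shells, function(s) if (s$l == 0L) 1L else 3L, integer(1))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  list(offsets = off, sizes = sizes, nbf = sum(sizes))
}

nuclearRepulsion <- function(geom) {
  Zs <- unname(.elementZ[geom$atoms])
  xyz <- geom$coords * angstrom_to_bohr
  e <- 0
  n <- length(Zs)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      e <- e + Zs[i] * Zs[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  e
}

nElectrons <- function(geom) {
  unname(sum(.elementZ[geom$atoms]) - geom$charge)
}
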