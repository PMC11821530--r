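#' @include mp2.R ccsd.R
NULL

#' Cache reference wavefunction data as JSON
#'
#' Serializes the per-geometry quantities the contextual-subspace pipeline
#' consumes repeatedly: canonical MO energies, the Hartree-Fock energy,
#' MP2/CCSD amplitudes and the MP2 natural-orbital occupations.  The file
#' is plain JSON so a scan can be resumed without re-running the engine.
#'
#' @param hf converged [scfRHF()]
#' @param file path
#' @param mp2,cc optional precomputed results (computed when missing)
#' @return the file path, invisibly
#' @export
writeReferenceData <- function(hf, file, mp2 = NULL, cc = NULL) {
  if (is.null(mp2)) mp2 <- mp2Energy(hf)
  if (is.null(cc)) cc <- suppressWarnings(ccsdEnergy(hf, so = mp2$so))
  obj <- list(
    moEnergies = as.numeric(hf$eps),
    hfEnergy = hf$energy,
    mp2Energy = mp2$energy,
    ccsdEnergy = cc$energy,
    noOccupations = as.numeric(mp2$noOcc),
    t2mp2 = list(dim = dim(mp2$t2), values = as.numeric(mp2$t2)),
    t1ccsd = list(dim = dim(cc$t1), values = as.numeric(cc$t1)),
    t2ccsd = list(dim = dim(cc$t2), values = as.numeric(cc$t2)))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeReferenceData
#' @return \code{readReferenceData}: a list with the cached fields; the
#'   amplitude entries are restored to their array shapes.
#' @export
readReferenceData <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("t2mp2", "t1ccsd", "t2ccsd")) {
    obj[[nm]] <- array(obj[[nm]]$values, dim = obj[[nm]]$dim)
  }
  obj
}
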