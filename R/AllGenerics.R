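#' @include AllClasses.R
NULL

#' Number of qubits of an object
#' @param object a PauliSum, QuantumCircuit or related object
#' @return integer register width
#' @export
setGeneric("nQubits", function(object) standardGeneric("nQubits"))

#' Number of terms of a PauliSum
#' @param object a PauliSum
#' @return integer term count
#' @export
setGeneric("nTerms", function(object) standardGeneric("nTerms"))

#' Coefficients of a PauliSum
#' @param object a PauliSum
#' @return complex vector, one entry per term
#' @export
setGeneric("coeffs", function(object) standardGeneric("coeffs"))

#' Pauli strings of a PauliSum
#'
#' Text rendering of each term, qubit 0 leftmost.
#' @param object a PauliSum
#' @return character vector such as \code{c("XZIY", "IIZZ")}
#' @export
setGeneric("pauliStrings", function(object) standardGeneric("pauliStrings"))

#' @rdname PauliSum-class
#' @param object PauliSum
#' @export
setMethod("nQubits", "PauliSum", function(object) object@nQubits)

#' @rdname QuantumCircuit-class
#' @param object QuantumCircuit
#' @export
setMethod("nQubits", "QuantumCircuit", function(object) object@nQubits)

#' @rdname PauliSum-class
#' @export
setMethod("nTerms", "PauliSum", function(object) length(object@coeff))

#' @rdname PauliSum-class
#' @export
setMethod("coeffs", "PauliSum", function(object) object@coeff)
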