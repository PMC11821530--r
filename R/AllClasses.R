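#' @import methods
NULL

#' PauliSum: weighted sum of Pauli strings in symplectic form
#'
#' A Hermitian (or general) operator \eqn{H = \sum_i h_i P_i} on a register of
#' \code{nQubits} qubits.  Each Pauli string \eqn{P_i} is stored as a pair of
#' bit-masks: \code{x} flags qubits carrying an X factor and \code{z} those
#' carrying a Z factor; a qubit flagged in both carries Y.  Masks are stored
#' little-endian (qubit \eqn{j} is bit \eqn{2^j}); all text rendering uses
#' explicit strings such as \code{"XZIY"} in which qubit 0 is the *leftmost*
#' character, so no endianness ambiguity can leak out of the internals.
#'
#' The phase convention is \eqn{P = i^{|x \wedge z|} X^x Z^z}, which makes the
#' single-qubit \code{(x=1, z=1)} mask exactly Y.
#'
#' @slot x integer vector of X bit-masks, one per term.
#' @slot z integer vector of Z bit-masks, one per term.
#' @slot coeff complex vector of coefficients (Hartree for chemical
#'   Hamiltonians).
#' @slot nQubits integer, register width (at most 26).
#'
#' @seealso [pauliSum()], [pauliTerm()], [canonicalize()], [l1Norm()],
#'   [groundEnergyExact()]
#' @export
setClass("PauliSum", representation(
  x = "integer", z = "integer", coeff = "complex", nQubits = "integer"
))

setValidity("PauliSum", function(object) {
  n <- object@nQubits
  if (length(n) != 1L || is.na(n) || n < 0L || n > 26L)
    return("nQubits must be a single integer in [0, 26]")
  if (length(object@x) != length(object@z) ||
      length(object@x) != length(object@coeff))
    return("x, z and coeff must have equal length")
  lim <- 2^n
  if (length(object@x) && (any(object@x < 0) || any(object@x >= lim) ||
                           any(object@z < 0) || any(object@z >= lim)))
    return("masks exceed the register width")
  TRUE
})

#' Noncontextual Hamiltonian model
#'
#' The classical (hidden-variable) structure of a noncontextual Pauli
#' Hamiltonian: a symmetry part Z' whose terms commute with the whole set,
#' anticommuting clique representatives \eqn{A_i}, an independent generating
#' set G of the symmetry group, and the optimal classical value assignment
#' \eqn{(q, r)} with \eqn{q \in \{\pm 1\}^{|G|}} and \eqn{\sum_i r_i^2 = 1}.
#'
#' @slot symmetryPart PauliSum of terms commuting with every element.
#' @slot cliqueReps PauliSum holding one representative per anticommuting
#'   clique.
#' @slot cliques list of PauliSum, the full clique contents.
#' @slot generators PauliSum, independent symmetry-group generators (unit
#'   coefficients).
#' @slot q numeric, optimal \eqn{\pm 1} assignment per generator.
#' @slot r numeric, optimal unit vector over cliques.
#' @slot energy numeric, minimum of the classical objective (Hartree).
#' @export
setClass("NoncontextualModel", representation(
  symmetryPart = "PauliSum", cliqueReps = "PauliSum", cliques = "list",
  generators = "PauliSum", q = "numeric", r = "numeric", energy = "numeric"
))

#' Quantum circuit intermediate representation
#'
#' An ordered gate list.  Gate names are from
#' \{H, X, Rx, Ry, Rz, CNOT, CPhase, SWAP, PauliRot\}; \code{PauliRot} is the
#' Pauli-exponential \eqn{e^{i\theta P}} kept symbolic until compilation.
#'
#' @slot nQubits integer register width.
#' @slot gates list of gate records: \code{list(name, qubits, angle, pauli)}.
#' @export
setClass("QuantumCircuit", representation(
  nQubits = "integer", gates = "list"
))

setValidity("QuantumCircuit", function(object) {
  for (g in object@gates) {
    if (!is.character(g$name)) return("gate records need a name")
    if (any(g$qubits >= object@nQubits) || any(g$qubits < 0L))
      return("gate qubit index outside register")
  }
  TRUE
})

#' Symmetry sector of a tapered Hamiltonian
#'
#' Z2-symmetry generators of a Hamiltonian together with the measured
#' eigenvalue of each in a reference computational-basis state, and the
#' Clifford rotations that map each generator onto a distinct single-qubit Z.
#'
#' @slot generators PauliSum (commuting, independent, coefficient +1).
#' @slot eigenvalues numeric vector of \eqn{\pm 1}.
#' @slot rotations PauliSum; rotation generators P of \eqn{e^{i\pi/4 P}}, in
#'   application order.
#' @slot targetQubits integer; qubit each generator collapses onto (0-based).
#' @export
setClass("SymmetrySector", representation(
  generators = "PauliSum", eigenvalues = "numeric",
  rotations = "PauliSum", targetQubits = "integer"
))
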