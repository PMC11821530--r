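Package: CSVQE
Title: Contextual-Subspace Variational Quantum Eigensolver for Molecular
    Potential Energy Curves
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation of the contextual-subspace variational
    quantum eigensolver (CS-VQE) for small-molecule electronic structure,
    entirely on a classical computer.  Provides a symplectic Pauli-operator
    algebra, a built-in STO-3G electronic-structure engine (Hartree-Fock,
    MP2, CISD, CCSD, CCSD(T), CASCI, CASSCF and determinant FCI), the
    Jordan-Wigner mapping, Z2-symmetry qubit tapering, noncontextual
    Hamiltonian decomposition with stabilizer-subspace projection,
    hardware-aware adaptive (ADAPT) ansatz construction, qubit-wise-commuting
    measurement grouping, measurement-error mitigation and zero-noise
    extrapolation on a configurable noisy shot simulator, and a pipeline
    that reproduces dissociation-curve benchmarks for molecular nitrogen in
    a minimal basis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CSVQE-package.R'
    'utils.R'
    'pauli.R'
    'basis.R'
    'integrals.R'
    'scf.R'
    'fci.R'
    'mp2.R'
    'ccsd.R'
    'jordan-wigner.R'
    'tapering.R'
    'noncontextual.R'
    'stabilizers.R'
    'circuit.R'
    'graphs.R'
    'adapt.R'
    'casscf.R'
    'chem-io.R'
    'degeneracy.R'
    'noise.R'
    'measurement.R'
    'pauli-io.R'
    'zne.R'
    'pipeline.R'
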