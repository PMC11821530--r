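---
title: "Contextual-subspace VQE on a classical desk: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual-subspace VQE on a classical desk: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CSVQE simulates, end to end and without quantum hardware, the
contextual-subspace variational quantum eigensolver (CS-VQE) for small
molecules: a qubit Hamiltonian is built from first principles, exact
Z2 symmetries are tapered away, the remainder is split into a classically
solvable noncontextual component and a quantum correction confined to a
small "contextual subspace", and the subspace problem is attacked with an
adaptively grown ansatz on a noisy shot simulator with measurement-error
mitigation and zero-noise extrapolation.  This vignette records the models
the package implements, the tunable parameters and their defaults, the
numerical decisions taken where the methodology is genuinely open, and
what the shipped dinitrogen study does and does not demonstrate.

## The pipeline at a glance

For a geometry $R$ the chain is

1. restricted (open-shell) Hartree–Fock in the built-in STO-3G basis;
2. Jordan–Wigner mapping of the second-quantized Hamiltonian to a
   `PauliSum` on $2M$ qubits ($M$ spatial orbitals);
3. tapering of all independent Z2 symmetries (spin parities plus the
   point-group content exposed by symmetry-pure orbitals), $2M \to 2M-k$
   qubits with the spectrum in the reference sector preserved exactly;
4. a noncontextual/contextual split of the tapered Hamiltonian, whose
   noncontextual part is solved by a classical objective;
5. projection onto an $n_q$-qubit contextual subspace selected by an
   MP2- or CCSD-derived excitation guide; exact diagonalization of the
   reduced operator is the noise-free ceiling (CS-DD);
6. optionally, adaptive ansatz construction and (noisy) variational
   optimization in the subspace.

All reference energies (MP2, CISD, CCSD, CCSD(T), CASCI, CASSCF,
determinant FCI) come from the package's own electronic-structure engine;
the FCI code is validated against a brute-force second-quantized oracle
and against exact diagonalization of the Jordan–Wigner image, which are
independent code paths.

## Conventions

* Pauli strings render with **qubit 0 leftmost** (`"XZIY"`); internally
  masks are little-endian bit vectors.  The phase convention is
  $P = i^{|x \wedge z|} X^x Z^z$, making the $(1,1)$ mask exactly $Y$.
* Spin orbitals interleave as $\alpha_0, \beta_0, \alpha_1, \dots$, and
  the Jordan–Wigner chain runs over lower qubit indices.  Tapering
  generator identities depend on this ordering, which is why it is fixed
  and tested.
* Energies are Hartree; conversions use
  $1\,\mathrm{Ha} = 27.211386245988\,\mathrm{eV}$.
* Degenerate canonical orbitals are rotated onto symmetry-pure
  combinations (for homonuclear diatomics the converged Fock operator is
  re-diagonalized blockwise in a symmetry-adapted basis), and orbital
  signs are fixed deterministically.  Without this step, floating-point
  noise in the degenerate $\pi$ blocks hides the point-group Z2
  symmetries from the tapering kernel.

## The noncontextual component

A Pauli set is noncontextual when, after removing the terms that commute
with everything, commutation is transitive on the remainder: it splits
into cliques with intra-clique commutation and inter-clique
anticommutation.  Its spectrum is generated by a classical objective over
$q \in \{\pm 1\}^{|G|}$ (an assignment to an independent generating set
$G$ of the abelian symmetry group) and a unit vector $r$ over cliques:

$$E(q, r) \;=\; \sum_{j} h_j\,\nu_q(W_j)\;+\;\sum_i r_i \sum_{t \in C_i}
h_t\,\nu_q(W_t A_i),$$

minimized in closed form over $r$ (negative Euclidean norm of the clique
sums) and exhaustively over $q$ (capped at $2^{20}$ assignments, with a
seeded annealing fallback that the shipped systems never trigger).

Two split strategies are provided:

* **`"magnitude"`** — the greedy sweep in decreasing $|h|$, accepting a
  term whenever the running set stays noncontextual.  The admission test
  is incremental ($O(|S|)$ per candidate) and the resulting clique-bearing
  model feeds the full classical objective above, including
  unitary-partitioning rotations when a clique representative is enforced
  as a stabilizer.
* **`"diagonal"`** (default) — the diagonal ($Z/I$-only) sub-Hamiltonian.
  Its classical problem is an Ising minimization over computational
  configurations; the optimum is the best single configuration, found by
  exhaustive enumeration.  For the shipped molecules both strategies give
  the same noncontextual energy, the diagonal model is cheaper and its
  maximal abelian symmetry group (all single-qubit $Z$s) is exactly the
  parity group the stabilizer search needs.

The noncontextual dissociation curve equals the Hartree–Fock energy near
equilibrium and drops below it at stretch, where a different
configuration overtakes the reference — the classical component already
captures part of the static correlation.  The curve is non-smooth exactly
where the optimal configuration switches.  The package detects
discontinuities by locating those switches and bisecting them to 2 mÅ; a
neighbour-jump filter (ten times the median gap of the
Hartree–Fock-detrended curve) guards against switches between degenerate
configurations.  A detector thresholding raw neighbour gaps was rejected:
on a dissociation curve the smooth repulsive wall produces neighbour gaps
two orders of magnitude above the median, swamping any genuine
discontinuity.

## Stabilizer selection and projection

A contextual subspace on $n_q$ qubits is fixed by $k = n - n_q$
independent commuting stabilizers with chosen eigenvalues.  Projection is
mechanical: each stabilizer is rotated onto a distinct single-qubit $Z$
by at most two $\pi/2$ Clifford rotations (after clearing earlier target
qubits inside the current rotated frame), the $Z$ is replaced by its
eigenvalue, and the qubit is dropped; terms anticommuting with a
stabilizer are annihilated.  The same record replays on guides, pools and
statevectors.

Selection strategies:

* **`"significance"`** (default, diagonal model) — guide terms are
  grouped by X-mask and visited in decreasing weight; the retained
  X-space is grown greedily up to rank $n_q$, always protecting the
  heaviest excitations exactly; stabilizers are the Z-parities orthogonal
  to that space.  If the guide X-space has rank below $n_q$ (parity
  constraints), coordinate directions pad the basis.
* **`"weight"` / `"weight-refine"`** — nested greedy over the whole
  $2^{|G|}$ generator span maximizing the total retained guide
  $\ell_1$-norm, scored for all span elements at once with a
  Walsh–Hadamard transform; the refine variant adds coordinate-ascent
  (each chosen stabilizer re-optimized with the others fixed, enabled up
  to $|G| \le 16$).  Ties break on the smallest generator-combination
  index.  A truly exhaustive refinement over stabilizer choices is
  combinatorially infeasible (the candidates are subgroups of
  $GF(2)^{|G|}$), which is why coordinate ascent stands in for it.

Eigenvalues default to the **reference sector**: parities of the
Hartree–Fock determinant, so the reference state always survives the
projection and a VQE initialized there is well defined.  The noncontextual
assignment $q^\ast$ is available as the `"model"` sector; for the shipped
study both agree near equilibrium, and the reference sector gives the
lower-error subspaces at stretch.  When the requested reduction exceeds
$|G|$, one extra stabilizer comes from the anticommuting-clique degree of
freedom: exact (non-Clifford) Pauli rotations map $\sum_i r_i A_i$ onto a
single representative, which is then enforced with the sign of its
$r$-component.  This restores the endpoint identities
$E_{CS}(n_q = 0) = E_{nc}$ and $E_{CS}(n_q = n) = E_{\mathrm{exact}}$,
which the test suite asserts on random fixtures.

The MP2 guide uses doubles amplitudes only (canonical singles vanish by
Brillouin's theorem); the CCSD guide uses $t_1 + t_2$, configurable down
to $t_2$.

## Adaptive ansatz construction

The pool is the set of singles+doubles excitation generators with
antisymmetrized unit amplitudes, Jordan–Wigner mapped, pushed through the
tapering/projection records, and split into individual Pauli strings.
Scoring uses the gradient magnitude $|f(P)| =
|\langle\psi| i[H, P] |\psi\rangle|$ — the absolute value, standard ADAPT
practice where the sign only fixes the initial rotation direction —
optionally multiplied by a hardware bias: delete up to $D$ qubits from
the would-be circuit's coupling graph (subsets visited in ascending
removed weight $s(n)$, so the returned $s(n)$ is minimal and the score is
stable), stop at the first VF2 subgraph isomorphism into the target
topology, and weight by $(1 - s(n)/W)^b$; no embedding within depth $D$
scores zero.  Defaults $D = 2$, $b = 1$.  When every pool element scores
zero the selection falls back to the plain gradient.  Parameters are
re-optimized each cycle by BFGS with adjoint-mode analytic gradients
(the parameter-shift rule is implemented as the hardware path and agrees
to machine precision); the loop stops when the pool-gradient
$\ell_1$-norm falls below $10^{-3}$ Ha or after 50 cycles, with a single
seeded $10^{-3}$ parameter perturbation before a zero-gradient stop is
accepted.

Routing inserts SWAPs greedily along shortest paths (deterministic, each
SWAP three CNOTs) followed by a peephole pass cancelling adjacent inverse
pairs.  The initial logical-to-physical placement uses a VF2 embedding of
the circuit coupling graph when one exists — this is what lets
hardware-aware ansätze route without SWAP overhead, and the comparison
against hardware-agnostic construction at matched cycle count is asserted
as a strict routed-CNOT reduction in the suite.  Only this *relative*
claim is meaningful: absolute transpiled counts depend on the router.

## Measurement, mitigation, extrapolation

Expectation values are estimated by qubit-wise-commuting (QWC) groups:
greedy colouring of the incompatibility graph by descending degree, then
per-group basis rotations ($H$ for $X$, $R_x(\pi/2)$ for $Y$) and 5000
shots per clique by default.  The noise model is gate-located
depolarizing (rates $p_1$, $p_2$) plus terminal per-qubit readout
confusion $A^{(k)}$; there is deliberately **no idle-decoherence
channel**, so dynamical decoupling would act trivially and is excluded.
Measurement-error mitigation inverts the tensor-product confusion map on
the sampled distribution, clipping negative quasi-probabilities to zero
and renormalizing (a least-squares projection would also be defensible;
clipping is the documented default).

Zero-noise extrapolation replaces every CNOT by
$\mathrm{Had}_t [\mathrm{CPhase}(\pi/\lambda)]^\lambda \mathrm{Had}_t$
with each CPhase re-expressed natively as 2 CNOTs and 3 $R_z$, so one
CNOT costs $2\lambda$ CNOTs and $3\lambda + 2$ single-qubit gates while
the unitary is unchanged — asserted exactly for $\lambda \in \{1,2,3\}$.
Gains are calibrated as the expected error-event ratio
$G(\lambda) = (n_1(\lambda) p_1 + n_2(\lambda) p_2)/(n_1(1) p_1 +
n_2(1) p_2)$: a documented stand-in for hardware calibration, exact in
the limits the tests probe ($G = \lambda$ at $p_1 = 0$, sub-proportional
otherwise).  Extrapolation is inverse-variance weighted least squares,
linear by default and quadratic from four $\lambda$ points.  Circuit
tiling embeds disjoint replicas of the ansatz coupling graph across a
device (corner-first VF2 placement; the bundled heavy-hexagon maps of 16,
27 and 127 qubits tile 3, 5 and 25 five-qubit clusters respectively);
per-tile noise draws from a configurable relative spread (default 0.2)
emulate spatial inhomogeneity, and the reported value is the tile mean
with its standard error.

## Numerical choices

* Canonicalization drops Pauli coefficients below $10^{-12}$; the
  Jordan–Wigner builder keeps integral contributions above $10^{-14}$.
* SCF: DIIS over 8 Fock matrices, energy convergence $10^{-10}$ Ha;
  cold starts run 60 damped iterations (factor 0.7) first, which steers
  multiply bonded diatomics away from a symmetry-broken saddle; scans
  warm-start each geometry from the nearest converged neighbour so the
  curve stays on one branch.
* CCSD: amplitude DIIS, energy convergence $10^{-10}$ Ha.
* Exact ground states: dense diagonalization to 8 qubits, Lanczos with
  full reorthogonalization above (tolerance $10^{-11}$), with matvecs
  that group Pauli terms by X-mask.
* Study problem sizes (the package's choices for a single-CPU run): the
  equilibrium search scans 1.0–1.4 Å at 20 mÅ before golden-section and
  parabolic refinement to sub-mÅ; non-variationality onsets bracket on a
  50 mÅ grid and bisect to 0.5 mÅ; the discontinuity scan uses a 20 mÅ
  base grid (25 mÅ inside the test suite) with switch bisection to 2 mÅ;
  subspace sweeps run the ten-point study grid.
* Determinism: every stochastic component (shot sampling, tile noise
  draws, annealing fallback, plateau perturbation) takes an explicit
  seed; reruns are bit-identical.

## What the shipped study shows — and does not

The package's study conditions are the dinitrogen dissociation curve in
the minimal basis: ten evenly spaced separations on 0.8–2.0 Å for the
headline comparisons, with finer adaptive grids for the derived
quantities.  Within those conditions the suite verifies, among others:
20→15 tapering with the ground energy preserved to $10^{-8}$ Ha, the
endpoint identities of the projection, the CCSD-guided algorithmic
accuracy threshold, and the full mitigation algebra.

Known limitations, all documented where they bite:

* The noncontextual split and the stabilizer search are heuristics; the
  published positions of noncontextual discontinuities and the MP2-guided
  subspace error band are sensitive to their exact form, and this
  package's defaults produce a single configuration switch near 1.43 Å
  rather than several, with MP2-guided five-qubit errors of roughly
  0.7–1.2 eV across the scan.
* Bond-length-dependent features of the correlation methods (the FCI
  minimum, non-variationality onsets) carry the package's own integral
  and convergence stack; cross-validated against independent
  implementations, they are internally consistent to $10^{-8}$ Ha.
* The noisy simulator has no idle decoherence, no coherent errors and no
  correlated readout; conclusions about mitigation transfer to hardware
  only qualitatively.
* CASSCF uses direct orbital-rotation minimization with numerical
  gradients — robust at this scale, not performant beyond it.
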