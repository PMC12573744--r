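---
title: "Similarity-constrained CC2: model, solvers and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-constrained CC2: model, solvers and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **scc2**, the numerical
decisions behind the solvers, what the bundled test systems exercise, and
the known limitations.  Nothing here reports a number that the test suite
or `scripts/acceptance.R` does not itself compute.

## The models

### CC2 ground state

The coupled cluster wave function is `|CC> = exp(T)|HF>` over a canonical
closed-shell restricted Hartree-Fock reference.  With `T = T1 + T2`
(singlet excitations only) and the Hamiltonian split `H = F + U` into the
canonical Fock operator and the fluctuation potential, the CC2
approximation treats the singles equations exactly while truncating the
doubles equations to first order in `U`:

* singles: `Omega_mu1 = <mu1| H~ + [H~, T2] |HF> = 0`
* doubles: `Omega_mu2 = <mu2| H~ + [F, T2] |HF> = 0`

where `V~ = exp(-T1) V exp(T1)` denotes T1-transformed (dressed)
operators.  Because the doubles-doubles coupling reduces to the diagonal
orbital-energy differences, the doubles have the closed form
`t_abij = <ab||ij>~ / (e_i + e_j - e_a - e_b)` and can be *folded* into
the singles equations: only `t1` is iterated (DIIS, subspace 8, error
vector = the singles residual), the doubles being recomputed from the
dressed integrals at every step.  The energy is
`E0 = <HF| H~ + [H~, T2] |HF>`.

A convention note: the commutator `[F, T2]` in the doubles equation is
evaluated with the *bare canonical* Fock operator, so the doubles-doubles
Jacobian block is exactly diagonal in `e_a + e_b - e_i - e_j`.  This is
the convention consistent with a strictly diagonal doubles block, and it
is the one the determinant-space oracle reproduces symbolically.  A
dressed `F~` in that commutator would make the doubles implicit; the
diagonal convention is used throughout (amplitudes, Jacobian, folding).

### EOM-CC2 excited states

Excited states are right (and left) eigenvectors of the non-symmetric
CC2 Jacobian `A_mu,nu = <mu|[Hbar, tau_nu]|HF>` with the block structure

* `A11`: dressed one-particle + particle-hole terms plus the
  `[[U~, T2], tau]` double-commutator contributions,
* `A12 = dOmega1/dt2` (the same linear map as the singles residual's
  doubles part),
* `A21 = <mu2|[U~, tau_nu1]|HF>`,
* `A22 = diag(e_a + e_b - e_i - e_j)`.

Because `A22` is diagonal, the eigenproblem folds onto the singles space:
`[A11 + A12 (w - eps)^-1 A21] r1 = w r1`, a nonlinear eigenproblem in
`w` solved by a self-consistency loop (fixed-point with relaxation 0.5,
tolerance 1e-9, at most 50 cycles).  Two eigensolver paths exist:

* **dense**: the full `A` over all Sz = 0 singles and doubles labels is
  built explicitly and diagonalized; this is the only path that reports
  complex conjugate eigenvalue pairs, the diagnostic of a defective
  Jacobian near same-symmetry intersections;
* **Davidson**: a subspace iteration for the folded operator in the
  singlet singles space (the singlet block is invariant for a spin-free
  Hamiltonian over a closed-shell reference), seeded with eigenvectors of
  the omega-independent singles-singles block, with root homing by
  maximal overlap and eigenvalue self-consistency in the outer loop.

The ground-state contribution of a right state is `r0 = eta' r / w` with
`eta_nu = <HF|[Hbar, tau_nu]|HF>`; left states carry `l0 = 0` and are
scaled to biorthonormality `<L^k|R^l> = delta_kl`.

Right states are normalized to unit 2-norm over the excitation labels
(doubles weighted by 1/4 for the antisymmetric tensor storage) with the
phase fixed by making the largest-magnitude singles element positive,
ties broken toward the lowest composite index.  Eigenvalues are
independent of this convention; the constraint parameter `zeta` below is
not, and is reported as convention-dependent.

### SCC2

Standard CC2 is non-Hermitian: at a near-degeneracy of two same-symmetry
excited states the Jacobian can become defective.  The intersection seam
then acquires the wrong dimensionality (an `M - 1` dimensional "tube"
instead of an `M - 2` seam), the degeneracy is not lifted linearly, and
complex eigenvalue pairs appear inside the tube.  SCC2 restores the
correct topology by enforcing linear independence of the two target
states: the cluster operator is extended to `S = T1 + T2 + zeta X3` with
the triples-rank constraint operator

`X3 = sum (r^A_mu1 r^B_mu2 - r^B_mu1 r^A_mu2) tau_mu1 tau_mu2`

built bilinearly from the two states' own amplitudes, and the scalar
`zeta` is determined by the orthogonality condition `O(A, B) = 0` under
the natural projection `P = sum_{mu>=0} |mu><mu|`:

`O(A,B) = r0A r0B (1 + q'Sq) + r0A q'SQ rB + rA'Q'S q r0B + rA'Q'SQ rB`

with `q_mu = <mu|exp(S)|HF>`, `Q_munu = <mu|exp(S)|nu>` and `S_munu =
<mu|nu>`.  The working representation is the orthonormal spin-orbital
determinant basis, where `S` is the identity; the non-trivial Gram matrix
of spin-adapted configurations is implemented and tested separately
(`configuration_overlap_matrix`), and observables are
representation-independent because `P` projects onto the same
configuration space.  Under the CC2 perturbation ordering the *only*
modification to the equations is the extra term
`zeta <mu1|[H~, X3]|HF>` in the singles residual: the doubles equations
and the Jacobian used for the eigenpairs retain their CC2 form, evaluated
at the SCC2 ground amplitudes.  The correction itself is evaluated
through factorized contractions of the de-excitation integrals
`<kl||cd>~` with the state amplitudes (three double-commutator patterns
plus one fully-contracted scalar term); no triples tensor is ever formed,
preserving the O(N^5) cost structure of CC2.

## The coupled SCC2 solver

The coupled system is: singles amplitude equation (with the `zeta X3`
term), the two right eigenproblems, and `O(A,B) = 0`.  Two structural
facts shape the solver:

1. the eigenpairs depend on the amplitudes only (the constraint shifts
   them indirectly through `t1`), and at the desk scales this package
   targets they can be re-solved *exactly* at every iteration by a dense
   folded solve in the singlet singles space;
2. `O(A,B)` depends on `zeta` only through the converged `t1(zeta)`;
   along this one-parameter family the constraint is a scalar
   root-finding problem.

The solver therefore converges `t1` by DIIS at fixed `zeta` (with the
states, `r0`, `X3` and the correction refreshed every iteration and the
states tracked by maximal overlap with the previous iterate), and drives
`O(zeta)` to zero by safeguarded secant/bisection steps in the outer
loop.  This deviates deliberately from a single concatenated DIIS over
`(t1, zeta, r1A, r1B)`: with exact inner eigensolves the eigen-residuals
vanish identically, the two remaining residual classes decouple cleanly,
and the scalar outer problem can be safeguarded against the branch
structure described next.  At convergence all four residual classes are
below the requested threshold, which is verified.

**Branch structure.**  Inside a CC2 defect region the tracked pair is
complex at `zeta = 0`.  The pair coalesces at an exceptional point as
`|zeta|` grows and splits into two real states beyond it; `O(A,B)` is
only meaningful on the real branch (just past the splitting the two real
vectors nearly coincide and `O` is large, decaying and changing sign
further out).  The solver marches `zeta` outward in growing steps until
the pair is real, brackets the sign change of `O` on the real branch,
and refines by secant steps that fall back to bisection whenever a
proposal lands back inside the complex pocket or an inner solve fails.
During transient complex iterations the two tracked states are
"realified" onto the real invariant subspace of the conjugate pair
(orthonormalized real and imaginary parts, aligned with the tracking
references); the bilinear structure of `X3` makes the correction
invariant under rotations within that subspace, so the transient is
well-defined.  By the antisymmetry of `X3` the solutions come in mirror
pairs `(zeta, A, B) <-> (-zeta, B, A)`; the solver reports whichever
branch its march reaches first.

Thresholds default to 1e-8 on all residual classes (scan-quality); the
inner amplitude solve is converged two orders tighter so that the outer
scalar residual is evaluated above its noise floor.  Restarts from a
neighboring geometry (`guess`) carry `t1`, `zeta`, the two tracking
vectors and both eigenvalue estimates, which typically reduces a point to
a handful of inner iterations and one or two outer steps; state tracking
across geometries uses overlap of the singles vectors (MO sign alignment
is implicit in the deterministic phase convention of the SCF and the
overlap-based root homing).

## The determinant-space oracle

Every working equation is validated against brute-force linear algebra in
a complete Sz = 0 determinant basis (`det_basis`, capped at 20000
determinants): the Hamiltonian by Slater-Condon rules, cluster and
excited-state operators as explicit (nilpotent) matrices, similarity
transforms as terminating exponential series, residuals and `eta` as
projections, the Jacobian by explicit commutator columns, and the overlap
`O(A,B)` as `<R^A| P |R^B>` with `P` an explicit level projector.  The
oracle replicates the model's truncations symbolically — e.g. its doubles
residual uses the diagonal Fock commutator, and its Jacobian assembles the
CC2 block structure — so the comparisons validate the implemented
equations, not full CC.  Agreement is at the 1e-10 level on H2 (4
determinants), H4 (36) and H2O/minimal (441), at randomly drawn
amplitudes and states, which exercises every term including those that
vanish at the converged fixed point.

## Test systems and the defect-region fixture

All inputs are generated in code:

* **H2** (STO-3G, 0.74 A) — two orbitals, closed forms;
* **H4** (STO-3G trapezoids from `make_h4_geometry`) — the minimal
  strongly-correlated testbed with 36 determinants;
* **H2O** (STO-3G, a fixed bent geometry) — 441 determinants, the largest
  oracle system;
* **HOF** (STO-3G) — the intersection fixture.

For the intersection demonstrations the package scans hypofluorous acid
in the `(R_OH, R_OF)` plane at a fixed 90.5 degree angle.  In the minimal
basis the two lowest singlet states are both of A'' symmetry
(out-of-plane lone pair to in-plane sigma* character), and their seam
supports a genuine CC2 defect: a thin tube through approximately
`(R_OH, R_OF) = (1.441, 1.560)` A inside which the dense CC2 spectrum
shows conjugate complex pairs with imaginary parts up to roughly 1e-4
hartree, while SCC2 on the same grid yields purely real energies, a
point degeneracy and linear lifting.  The window and grid spacing
(0.001 A) were chosen once, by scanning for the seam of the A'' pair and
refining until the tube was resolved; the tube in this small basis is
narrow, so grids must be at least that fine to see interior points.  The
default scan windows in the tests and the acceptance script are centered
on this pocket.  This is a scaled-down analogue of the larger-basis HOF
intersection between the second and third singlet states of A' symmetry;
the physics demonstrated (tube vs point, complex vs real, sublinear vs
linear lifting) is the same, the specific states and window are those the
minimal basis affords.

Problem sizes throughout (minimal bases, a handful of states, grids of
order 5 x 5 to 7 x 7 for CC2 and 3 x 3 for SCC2, ray radii of
0.0008-0.0032 A) are chosen so the full validation runs comfortably on a
single CPU; they are statements of the package's desk-scale design
target, which trades basis quality for exhaustive oracle validation.

## Intersection location and its accuracy floor

`locate_intersection()` is a plain derivative-free pattern search over
the scan plane; because every gap evaluation is a full coupled SCC2
solve and a pattern search on a cone converges only linearly,
`refine_intersection()` supplements it by fitting the squared gap --
smooth and positive definite near a conical apex -- to a small stencil
and jumping to the fitted minimizer.  Ray fits for the linear-lifting
metric are taken at radii of 0.0008-0.0032 A around the located point;
each ray restarts the warm chain from a snapshot taken slightly off the
apex, and isolated evaluations that converge onto a different solution
branch (recognizable as gross upward breaks from the cone trend, since
the spurious branch pairs a different state) are retried from a fresh
chain and dropped if they persist.

A known limitation: within roughly 2e-5 hartree of the exact degeneracy
the coupled solve stops converging -- there the eigenvectors rotate
strongly under amplitude changes smaller than the residual threshold and
the X3-coupled singles iteration becomes stiff, which assignment
continuity, sign alignment and adaptive rotation damping mitigate but do
not remove.  The located-gap figure reported by the acceptance script is
therefore a measured minimum of order 1e-5 hartree, not an exact zero;
the signed diabatic gap descends linearly on both sides of the seam with
matching slopes, consistent with a true point degeneracy at the apex.

## What the synthetic systems do and do not show

The generator-driven fixtures demonstrate the *structural* claims:
exactness of the working equations against the oracle, size-extensivity
over noninteracting fragments (1e-8 hartree for CC2; about 1e-6 for SCC2,
whose natural projection is only approximately size-intensive), the
MP2 limit, folding/unfolding consistency, Davidson/dense agreement,
biorthonormality, the CC2 defect phenomenology and its SCC2 repair, and
the few-meV scale of the SCC2-CC2 difference away from intersections.
They do not demonstrate basis-set-converged excitation energies, the
behavior of diffuse or Rydberg states, frozen-core effects (all electrons
are correlated by default; a frozen-core window is not currently
exposed), or performance at production system sizes: the integral backend
carries s and p shells only (bundled STO-3G for H-Ne, 6-31G for H and O)
and all tensors are held dense in memory.

## Numerical choices and degenerate inputs

* SCF: symmetric orthogonalization, aufbau occupation at every
  iteration, DIIS on the orbital-gradient commutator, threshold 1e-9;
  final canonicalization rediagonalizes the converged Fock matrix.
* Doubles denominators below 1e-8 in magnitude abort with the offending
  index quadruple named, rather than being regularized silently; the
  folding denominator `w - eps` is guarded the same way.
* DIIS: subspace 8, restart on condition number above 1e12.
* Complex roots are computed on the dense path only; the Davidson path
  detects defect proximity through complex projected roots / stalled
  self-consistency and flags the state rather than fabricating a real
  eigenvalue.
* Tie-breaks: state tracking prefers maximal overlap, exact ties resolve
  toward the lower eigenvalue; phase fixing as described above.
* `zeta` secant steps are capped and bracket-safeguarded; an inner-solve
  failure during refinement triggers bisection instead of abandoning the
  bracket.

## Known limitations

* Left-state properties beyond biorthonormality checks (transition
  moments, oscillator strengths) are out of scope, as are analytic
  gradients and derivative couplings.
* Only two states can be constrained.
* The SCC equations are known (from the model family's literature) to
  admit convergence failures in some regions far from intersections; the
  solver reports these honestly with its residual history rather than
  attempting model switching, and the adaptive CC2/SCC2 hybrid idea is
  out of scope.
* The CC2 `zeta = 0` limit of the constrained solver reproduces plain
  CC2 to tight tolerance (tested); no attempt is made to follow `zeta`
  continuously through the mirror-symmetric pair of solution branches,
  so the sign of the reported `zeta` is an artifact of the march
  direction.
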