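---
title: "Spin-polarized tight binding with on-site Hubbard corrections: models, solvers and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-polarized tight binding with on-site Hubbard corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtbu)
```

## The model

`xtbu` implements a self-consistent, spin-polarized extended tight-binding
(GFN2-style) total energy for molecules,

$$E_\mathrm{tot} = E_\mathrm{rep} + E_\mathrm{EHT} + E_\mathrm{IES} + E_\mathrm{IXC}
 + E_\mathrm{AES} + E_\mathrm{AXC} + E_\mathrm{spin} + E_\mathrm{Fermi} + E_U ,$$

in an unrestricted two-channel formalism with a minimal valence basis of
Slater-type orbitals expanded in contracted Gaussians.  The terms are:

* **Repulsion** $E_\mathrm{rep}$: a pairwise sum
  $Z^\mathrm{eff}_A Z^\mathrm{eff}_B / R \cdot \exp(-\sqrt{a_A a_B}\,R^{k})$
  with $k = 1.5$ ($1.0$ for pairs of the lightest elements).
* **Extended Hückel** $E_\mathrm{EHT} = \sum_\sigma \mathrm{tr}(P^\sigma H^0)$.
  Off-diagonal $H^0_{\mu\nu}$ elements carry the usual shell-pair constants,
  an electronegativity-difference damping $(1 + k_\mathrm{EN}\,\Delta EN^2)$
  with $k_\mathrm{EN} < 0$, a square-root distance polynomial per shell, a
  Slater-exponent average factor, and coordination-number-shifted diagonal
  levels (double-logistic fractional coordination numbers).
* **Isotropic electrostatics + XC** $E_\mathrm{IES}, E_\mathrm{IXC}$:
  second-order shell-resolved Mulliken charge fluctuations with a damped
  Coulomb kernel $\gamma_{Al,Bl'} = (R^2 + \bar\eta^{-2})^{-1/2}$
  ($\bar\eta$ = harmonic mean of scaled shell hardnesses), plus the cubic
  third-order on-site term $\tfrac13\sum \Gamma_{Al}\, q_{Al}^3$.
* **Anisotropic electrostatics + XC** $E_\mathrm{AES}, E_\mathrm{AXC}$:
  interactions of cumulative atomic dipoles and traceless quadrupoles
  (charge–dipole, dipole–dipole, charge–quadrupole) with short-range damped
  $R^{-3}$/$R^{-5}$ kernels, and on-site dipole/quadrupole "XC" kernels.
* **Spin polarization**
  $E_\mathrm{spin} = \tfrac12 \sum_A \sum_{l,l' \in A} p_{Al}\,p_{Al'}\,W_{All'}$,
  where $p_{Al}$ is the difference of the $\alpha$ and $\beta$ Mulliken shell
  populations and $W_{All'}$ the symmetric atomic spin-constant matrix.
* **Fermi smearing** $E_\mathrm{Fermi} = -T S_\mathrm{el}$, the electronic
  entropy of Fermi–Dirac fractional occupations at electronic temperature
  $T$ (default 300 K, a flag selects 0 K).
* **Hubbard correction** $E_U$, described next.

All lengths are Bohr internally (Å at every interface), all energies Hartree;
spin-gap outputs use 627.5095 kcal·mol⁻¹ per Hartree.

### The on-site +U correction

The correction acts on shell-block occupation matrices obtained from the
symmetrized Mulliken projection
$n^\sigma = \tfrac12 (S P^\sigma + P^\sigma S)$ restricted to same-atom,
same-shell AO pairs — a rotationally invariant projector, as the tests verify
by applying random orthogonal rotations within a d-shell block.  Three
formulations are implemented (`uvariant` = `fll`, `psic`, `amf`), with
per-shell parameters $U_l \ge 0$ and a global scaling $\alpha$ (default 0.5):

$$E_U^\mathrm{FLL} = -\alpha \sum_{A,l} \frac{U_l}{2} \sum_\sigma
  \left[\mathrm{tr}\,(n^\sigma)^2 - \mathrm{tr}\,n^\sigma\right], \qquad
E_U^\mathrm{pSIC} = -\alpha \sum_{A,l} \frac{U_l}{2} \sum_\sigma
  \mathrm{tr}\,(n^\sigma)^2, \qquad
E_U^\mathrm{AMF} = -\alpha \sum_{A,l} \frac{U_l}{2} \sum_\sigma
  \mathrm{tr}\,(\delta n^\sigma)^2,$$

with $\delta n^\sigma = n^\sigma - \frac{\mathrm{tr}\, n^\sigma}{2l+1} I$.
FLL penalizes fractional occupations (zero at idempotent integer fillings),
pSIC removes a per-electron self-interaction proportional to
$\mathrm{tr}\,n^2$, and AMF penalizes deviations from the shell-averaged
mean field.

**A deliberate convention.** The occupation-space potentials are taken as the
exact derivatives of the energy expressions,
$V^\mathrm{FLL} = -\alpha U (n - \tfrac12 I)$,
$V^\mathrm{pSIC} = -\alpha U\, n$,
$V^\mathrm{AMF} = -\alpha U\, \delta n$, mapped to the AO Fock matrix through
the symmetric Mulliken chain rule $F = \tfrac12 (S \tilde V + \tilde V S)$.
Published presentations of the pSIC Fock operator sometimes carry an extra
factor $\tfrac12$; whether that factor belongs to the potential or is
absorbed by the projector symmetrization is ambiguous on paper.  We resolve
the ambiguity *variationally*: the package's finite-difference suite requires
$F_{\mu\nu} = \partial E / \partial P_{\mu\nu}$ to $10^{-7}$ for every term,
which forces the derivative convention above.  Without it, SCF energies would
not be stationary at convergence.  The same symmetric chain rule
($\tfrac12(SV + VS)$ pattern) is shared by the spin-polarization and
isotropic-charge potentials, so the whole Fock matrix is one consistent
Mulliken derivative.

The FLL linear term is applied through $\mathrm{tr}\,n$ (diagonal elements
only), which keeps energy and Fock mutually consistent and rotationally
invariant.  $\delta n$ uses the same-channel trace only.

## Parameters

Element parameters ship as a plain-text key-value file
(`inst/extdata/gfn2_elements.toml`), a transcription of the published GFN2
element tables for H, Li, C, N, O, F and Fe, extended with:

* `W` — atomic spin-constant matrices (Hartree), lower triangle in shell
  order.  Negative diagonal-dominant values of a few tens of milli-Hartree;
  only closed-shell-breaking states feel them.
* `U` — per-shell Hubbard parameters (Hartree), default 0 everywhere.
  Typical optimized magnitudes for a 3d metal are 0.05–0.4 Ha; the default
  search box used by the optimization layer is $W_{dd} \in [-0.05, 0]$ and
  $U_l \in [0, 0.5]$ Ha.
* `alpha` — the global +U scaling, default 0.5.

Missing `U` or `W` entries default to zero and a missing `alpha` to 0.5, so
a plain GFN2-style file runs unmodified.  `set_parameters()` overrides
individual entries (`Wdd`, `Ud`, ...) programmatically.

The STO-nG expansions of the Slater basis functions are not copied from any
published table: they are re-derived by deterministic maximum-overlap fits
(`data-raw/fit_sto_ng.R`) and frozen as source.  The (1s, 3G) fit reproduces
the classic STO-3G exponents to about six digits, which pins the procedure.

## SCF solvers

Three interchangeable drivers converge the same stationary condition
(|ΔE| and the error/gradient max-norm both below $10^{-6}$ by default, with
a 250-iteration cap; non-convergence is a *flagged result*, never an error):

* **DIIS** — Pulay extrapolation of the Fock matrix with commutator error
  vectors $X^\top(FPS - SPF)X$, history length 8, oldest-first pruning and
  automatic restart when the B-matrix becomes ill-conditioned.
* **GDM** — geometric direct minimization: the free energy is minimized
  directly over S-orthonormal orbitals via exponentials of antisymmetric
  generators among orbital pairs with differing occupations.  L-BFGS
  (memory 8) with a diagonal preconditioner from level differences, and a
  backtracking Armijo line search that *guarantees* a non-increasing energy
  for every accepted step — the property the tests assert on every fixture.
  Fermi occupations are re-resolved each macro-iteration and a refresh is
  accepted only if it does not raise the free energy; with *pinned*
  (constrained) occupations the occupation vector is fixed once and orbital
  rotations alone do the work, because re-running aufbau each iteration can
  swap degenerate frontier orbitals indefinitely.
* **`fixed`** — damped fixed-point iteration, kept as a slow, simple oracle.

On well-behaved systems DIIS and GDM agree to $10^{-6}$ Ha (asserted over
ten seeded closed-shell molecules).  On strongly stretched LiF the DIIS
iteration oscillates and fails while GDM descends monotonically to the
minimum — this qualitative solver contrast emerges from the physics (a
near-degenerate ionic/neutral crossing), not from any special-casing.

## Diagnostics

* `homo_lumo_gap()` identifies frontier orbitals per channel by an
  occupation threshold of ½ (meaningful at finite temperature).
* `spin_gap()` converges two multiplicities at identical geometry and
  reports $E_\mathrm{HS} - E_\mathrm{LS}$ in kcal·mol⁻¹, with sign
  bookkeeping against a reference gap (a zero reference counts as correct
  only for a numerically zero gap).
* `fractional_charge_scan()` adds a fractional electron $q \in [0,1]$ by
  pinning the occupation of the accepting frontier spin orbital (so $q$ is
  exact by construction, rather than approximated through Fermi filling) and
  reports $E_\mathrm{dev}(q) = E(q) - q\,\Delta E - E(0)$, which vanishes at
  both endpoints identically.  Convex $E_\mathrm{dev} < 0$ is the
  self-interaction-error signature; increasing $U_d$ flattens the profile
  and widens the HOMO–LUMO gap on the iron fixture, which the acceptance
  suite asserts as a monotone trend.  When frontier orbitals are degenerate
  within $10^{-6}$ Ha the lowest-index orbital accepts the fraction — a
  logged convention, not physics.
* `linear_response_u()` estimates $U$ from the curvature of $E(N)$ as
  $\varepsilon^\mathrm{HOMO}_{N+1} - \varepsilon^\mathrm{LUMO}_N$, optionally
  iterated self-consistently into the d-shell $U$ until $|\Delta U| <
  10^{-4}$ Ha.  On a model with exactly quadratic $E(N)$ the estimate equals
  the second difference $E(N{-}1) - 2E(N) + E(N{+}1)$ to $10^{-6}$.

## Parameter workflow

`objective_spec()` + `objective()` define the spin-gap RMSE over a task set
(kcal·mol⁻¹), with non-converged points contributing a fixed 100 kcal·mol⁻¹
penalty (reported separately) so the objective stays defined everywhere.
Engines are prebuilt per task and warm-started between evaluations, since
the free parameters ($W$, $U$) touch neither the integrals nor $H^0$.

`sobol_sensitivity()` implements Saltelli-style sampling with the standard
first-order estimator and the Jansen total-order estimator, bootstrap
confidence intervals, and seeded uniform Monte-Carlo base samples (a
quasi-random Sobol sequence generator is not available in the installed
stack; at the $2^{12}$ base samples used for validation the Monte-Carlo
error is well inside the reported confidence intervals, as the Ishigami
benchmark in the acceptance suite shows).

`two_stage_optimize()` runs a derivative-free Powell conjugate-direction
search (implemented in-package: bounded Brent line searches, direction
replacement with the standard extrapolation test) followed by bounded
L-BFGS-B refinement with numerical gradients.  The final objective never
exceeds the starting one.  An optional absolute floor `f_tol` stops
refinement once the objective is below it — appropriate when the exact
minimum is known to be zero, as in planted-parameter recovery.

## What the synthetic fixtures emulate — and what they do not

* `make_lif(d)` reproduces the printed LiF convergence-table protocol
  exactly (bond-length grid, 300 K, $10^{-6}$ thresholds, 250-iteration cap,
  no dispersion anywhere in the model).
* `make_hexammine()` builds an ideal octahedral [Fe(NH₃)₆]³⁺ with a fixed
  ammonia geometry (N–H 1.012 Å, H–N–H 106.7°) and a chosen Fe–N distance
  (default 2.2 Å), since no ligand geometry is published for this purpose.
  It supports *property* tests — monotone trends in $U_d$, gap widening,
  spin gaps — never value matching.
* `make_model_hamiltonian()` provides two-level, one-electron-dimer and
  linear-in-N models with closed-form energies, used as solver and
  diagnostics oracles.
* `make_random_molecule()` perturbs standard small closed-shell geometries
  deterministically for the variational-consistency and solver-equivalence
  suites.

A green property test therefore establishes internal correctness of the
implemented equations (variational consistency, invariances, solver
agreement, trend directions) — it does not establish quantitative agreement
with any external benchmark, which would require the published benchmark
structures that are out of scope here.

The planted-parameter recovery task set uses two atomic Fe⁺ spin-gap tasks
that share the sextet high-spin state but differ in the low-spin
multiplicity (quartet vs doublet).  This choice is deliberate and was made
after probing alternatives: with tasks that differ only in geometry (the
same multiplicity pair at two bond lengths), the sensitivity directions of
the gap with respect to $(W_{dd}, U_d)$ are nearly collinear and the
recovery problem is hopelessly ill-conditioned; differing multiplicities
give well-separated directions, making both parameters identifiable to the
$10^{-3}$ level the acceptance criterion demands.  Atomic tasks also avoid
the SCF branch hysteresis that molecular low-spin states show under warm
starts, so the recovery objective is evaluated cold (`warm_start = FALSE`)
and SCF thresholds are tightened to $10^{-8}$ so that convergence noise
(≈ $6\times10^{-4}$ kcal·mol⁻¹ per $10^{-6}$ Ha) stays below the
identification signal.

## Numerical choices

* Degeneracy tolerance for the 0 K symmetric frontier split: $10^{-9}$ Ha;
  chemical-potential bisection to $|{\sum f - N}| < 10^{-12}$.
* DIIS restart: B-matrix reciprocal condition below $10^{-14}$ drops the
  oldest entries.
* GDM: rotation pairs require an occupation difference above $10^{-8}$;
  line search halves the step at most 30 times; every 20 iterations the
  orbitals are re-orthonormalized against numerical drift; near
  stationarity a plain diagonalization move is attempted (accepted only if
  the free energy does not rise) so the rotation gradient can settle below
  threshold in the presence of occupation refresh.
* Overlap condition numbers above $10^{10}$ raise a diagnostic error;
  nuclei closer than 0.1 Bohr are a geometry error.
* All randomness (sensitivity sampling, fixture perturbations) flows through
  explicit seeds; identical seeds give bitwise-identical results.

## Known limitations

* The shipped element-parameter file is a transcription of the published
  GFN2 tables for seven elements; no dispersion correction is included by
  design (the reference protocol this package follows switches dispersion
  off), and f shells, effective core potentials and periodic systems are out
  of scope.
* Restricted open-shell references are not implemented (the formalism is
  unrestricted throughout).
* The +U projector is the Mulliken shell-block projector only; molecular-
  orbital projectors are not provided.
* Nuclear gradients are not implemented (single-point energies only).
* The eigenvalue-based linear-response U on the iron-hexammine fixture comes
  out near zero with the shipped parameter transcription: the within-orbital
  relaxation of the accepting d level nearly cancels the electrostatic shift
  at the transcribed Fe/N hardnesses.  The quadratic-model oracle (where the
  estimate provably equals the energy curvature) is the tested contract; the
  magnitude of the self-consistent estimate on real complexes is
  parameter-sensitive and should not be over-interpreted.
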