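# xtbu

Semi-empirical quantum chemistry underestimates the cost of putting electrons
into localized d orbitals, so spin-state orderings of open-shell
transition-metal complexes — which decide magnetism, spin crossover and
catalytic reactivity, and often differ by only a few kcal·mol⁻¹ — come out
wrong, and the small HOMO–LUMO gaps of such systems routinely break the
standard SCF accelerators.  `xtbu` is an R package for studying both
problems in a controlled setting.  It implements, self-contained and in pure
R:

* a spin-polarized **extended tight-binding (GFN2-style) Hamiltonian** with
  all of its terms — pairwise repulsion, extended-Hückel band energy,
  second/third-order isotropic charge fluctuations, anisotropic (multipole)
  electrostatics and exchange–correlation, the spin-polarization energy
  ½ Σ p<sub>Al</sub> p<sub>Al′</sub> W<sub>All′</sub>, and finite-temperature
  Fermi smearing;
* an **on-site Hubbard +U correction** in three formulations (fully
  localized limit, around-mean-field, pseudo self-interaction correction),
  acting on symmetrized Mulliken shell-block occupation matrices
  n<sup>σ</sup> = ½(SP<sup>σ</sup> + P<sup>σ</sup>S), with shell-resolved,
  element-wise U values entering the Fock matrix self-consistently;
* two interchangeable **SCF drivers** — Pulay DIIS extrapolation and a
  geometric direct minimization (GDM) that descends the free energy over
  orbital rotations with a guaranteed monotone line search — plus a damped
  fixed-point oracle;
* **diagnostics**: HOMO–LUMO gaps, high-spin/low-spin gaps in kcal·mol⁻¹,
  fractional-charge linearity scans E<sub>dev</sub>(q) (the direct probe of
  self-interaction error), and the linear-response estimate
  U = ε<sup>HOMO</sup><sub>N+1</sub> − ε<sup>LUMO</sup><sub>N</sub>;
* a **parameter workflow**: spin-gap RMSE objectives, Sobol variance-based
  sensitivity (Saltelli sampling), a two-stage Powell → L-BFGS-B optimizer,
  and exhaustive 2-D (W<sub>dd</sub>, U<sub>d</sub>) scans.

Element parameters (H, Li, C, N, O, F, Fe) ship as a plain-text transcription
of the published GFN2 tables extended with spin constants and U defaults; no
dispersion correction is included by design.  See the methods vignette
(`vignettes/methods.Rmd`) for the model, conventions and numerical choices.

## A worked example

Stretched lithium fluoride is the classic stress test for SCF convergence:
near 4 Å the neutral and ionic configurations are nearly degenerate, DIIS
oscillates, and direct minimization keeps descending.

```r
library(xtbu)

params <- load_parameters()          # shipped GFN2-style parameter file

r <- scf_solve(make_lif(1.25), params, scf_settings(solver = "diis"))
summary(r)
#> Self-consistent field summary (diis solver)
#>   converged : TRUE in 5 iterations
#>   energy breakdown (Hartree):
#>     E_rep          0.01905955
#>     E_EHT         -5.18892261
#>     E_IES          0.12231842
#>     E_IXC          0.01597590
#>     E_AES         -0.00283843
#>     E_AXC         -0.00005386
#>     E_spin         0.00000000
#>     E_U            0.00000000
#>     E_Fermi        0.00000000
#>     E_tot         -5.03446103
#>   HOMO-LUMO gap: 0.134405 Hartree (alpha 0.134405, beta 0.134405)

# at 4.00 A DIIS fails while GDM converges:
scf_solve(make_lif(4.0), params, scf_settings(solver = "diis"))$converged
#> [1] FALSE
r4 <- scf_solve(make_lif(4.0), params, scf_settings(solver = "gdm"))
r4
#> <tb_scf> gdm solver: converged after 15 iterations
#>   E(total) = -4.94446958 Hartree
```

The total energy is the sum of the printed terms (Hartree throughout); the
DIIS/GDM contrast at 4 Å reproduces the qualitative behaviour of the
reference implementation this model follows.

Adding a d-shell Hubbard U to an octahedral iron(III) hexammine widens the
HOMO–LUMO gap and flattens the fractional-charge profile — the
self-interaction-error mechanism the correction exists for:

```r
hex <- make_hexammine("Fe", charge = 3, multiplicity = 6, distance_ang = 2.2)
pU  <- set_parameters(params, "Fe", c(Ud = 0.2))
r0  <- scf_solve(hex, params, scf_settings(solver = "gdm"), uvariant = "psic")
rU  <- scf_solve(hex, pU,     scf_settings(solver = "gdm"), uvariant = "psic")
c(homo_lumo_gap(r0)$gap, homo_lumo_gap(rU)$gap)
#> [1] 0.04025587 0.08036032
```

A thin command-line wrapper over the same functions is installed at
`exec/xtbu` (subcommands `energy`, `scan`, `spin-gap`, `linearity`, `lr-u`,
`fixtures`; exit codes 0 = success, 2 = SCF non-convergence, 1 = input
error).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the converged LiF total energies of the reference convergence table
(bond lengths 1.25–3.00 Å with DIIS, 4.00 Å with GDM; 300 K smearing,
10⁻⁶ thresholds, dispersion-free Hamiltonian) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
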