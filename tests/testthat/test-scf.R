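# SCF drivers: Fermi occupations, DIIS mechanics, GDM contract, solver
# equivalence and the model-Hamiltonian oracles.

test_that("Fermi occupations: aufbau limit, degeneracy split, particle number", {
  # T = 0, non-degenerate: integer occupations, no entropy
  o <- fermi_occupations(c(-1, -0.5, 0.2, 1), 2, 0)
  expect_equal(o$f, c(1, 1, 0, 0))
  expect_equal(o$E_fermi, 0)
  # two degenerate levels, one electron: symmetric split at any temperature
  for (T in c(0, 300, 5000)) {
    o <- fermi_occupations(c(0.3, 0.3), 1, T)
    expect_equal(o$f, c(0.5, 0.5), tolerance = 1e-9)
  }
  # particle number conservation vs a brute-force chemical-potential grid
  set.seed(4)
  eps <- sort(rnorm(14))
  o <- fermi_occupations(eps, 6, 300)
  expect_equal(sum(o$f), 6, tolerance = 1e-10)
  kT <- tb_units[["kB_hartree_per_K"]] * 300
  grid <- seq(min(eps) - 0.1, max(eps) + 0.1, length.out = 400001)
  nf <- vapply(grid, function(mu) sum(1 / (1 + exp((eps - mu) / kT))), 0)
  mu_grid <- grid[which.min(abs(nf - 6))]
  # inside a gap the chemical potential is defined only up to a plateau, so
  # compare particle numbers and occupations, not the mu values themselves
  expect_lt(abs(sum(1 / (1 + exp((eps - o$mu) / kT))) - 6), 1e-9)
  expect_equal(o$f, 1 / (1 + exp((eps - mu_grid) / kT)), tolerance = 1e-4)
  # entropy contribution is non-positive and zero only for integer occupations
  expect_lte(o$E_fermi, 0)
  expect_error(fermi_occupations(c(-1, 0), 3, 300), "exceeds")
})

test_that("initial guess is deterministic and charge-consistent", {
  p <- tb_test_params()
  engH <- build_engine(atomic_structure("H", matrix(0, 1, 3), 0L, 2L), p)
  g <- initial_guess(engH, scf_settings())
  expect_equal(g$Pa, matrix(1, 1, 1), tolerance = 1e-12)
  expect_equal(g$Pb, matrix(0, 1, 1), tolerance = 1e-12)
  eng <- build_engine(make_lif(1.4), p)
  g1 <- initial_guess(eng, scf_settings())
  g2 <- initial_guess(eng, scf_settings())
  expect_identical(g1, g2)   # bitwise determinism
  expect_equal(sum(diag(g1$Pa %*% eng$S)), eng$n_alpha, tolerance = 1e-8)
})

test_that("DIIS step honours its fixed points and history pruning", {
  set.seed(8)
  Fa <- random_density(4, 81); Fb <- random_density(4, 82)
  # single entry: Fock returned unchanged
  out <- diis_step(list(list(Fa = Fa, Fb = Fb, err = rnorm(16))))
  expect_identical(out$Fa, Fa)
  # all-zero error vectors: coefficients are valid and leave a converged
  # (identical) Fock fixed
  hist <- list(list(Fa = Fa, Fb = Fb, err = rep(0, 16)),
               list(Fa = Fa, Fb = Fb, err = rep(0, 16)))
  out <- diis_step(hist)
  expect_equal(out$Fa, Fa, tolerance = 1e-9)
  expect_error(diis_step(list()), "at least one")
})

test_that("DIIS residual norm is non-increasing on a weakly nonlinear model", {
  eng <- make_model_hamiltonian("linear-in-N", n_alpha = 2, n_beta = 2,
                                levels = c(-1, -0.6, 0.1, 0.7), quadratic = 0.05)
  r <- scf_solve(eng, settings = scf_settings(solver = "diis", etemp = 0))
  expect_true(r$converged)
  errs <- r$trace$err
  expect_true(all(diff(errs[1:min(10, length(errs))]) <= 1e-12))
})

test_that("GDM restarted from a converged state stops immediately", {
  p <- tb_test_params()
  eng <- build_engine(make_lif(1.6), p)
  r1 <- scf_solve(eng, settings = scf_settings(solver = "gdm"))
  expect_true(r1$converged)
  # re-running from the solution: energy cannot drop below the minimum found
  r2 <- scf_solve(eng, settings = scf_settings(solver = "gdm"))
  expect_equal(r1$energy[["E_tot"]], r2$energy[["E_tot"]], tolerance = 1e-10)
})

test_that("GDM agrees with the damped fixed-point solver on H2", {
  p <- tb_test_params()
  h2 <- atomic_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  r_fp <- scf_solve(h2, p, scf_settings(solver = "fixed"))
  r_gdm <- scf_solve(h2, p, scf_settings(solver = "gdm"))
  expect_true(r_fp$converged && r_gdm$converged)
  expect_equal(r_gdm$energy[["E_tot"]], r_fp$energy[["E_tot"]], tolerance = 1e-8)
})

test_that("hubbard-dimer SCF reproduces exact 2x2 diagonalization", {
  t_hop <- -0.4
  eng <- make_model_hamiltonian("hubbard-dimer", n_alpha = 1, n_beta = 0,
                                levels = c(-0.3, 0.25), t = t_hop)
  r <- scf_solve(eng, settings = scf_settings(solver = "gdm", etemp = 0))
  H <- matrix(c(-0.3, t_hop, t_hop, 0.25), 2, 2)
  expect_equal(r$energy[["E_tot"]], min(eigen(H)$values), tolerance = 1e-9)
})

test_that("DIIS and GDM converge to the same energy on seeded fixtures", {
  p <- tb_test_params()
  for (i in 1:10) {
    mol <- make_random_molecule(i)
    r_d <- scf_solve(mol, p, scf_settings(solver = "diis"))
    r_g <- scf_solve(mol, p, scf_settings(solver = "gdm"))
    expect_true(r_d$converged, info = sprintf("diis fixture %d", i))
    expect_true(r_g$converged, info = sprintf("gdm fixture %d", i))
    expect_lt(abs(r_d$energy[["E_tot"]] - r_g$energy[["E_tot"]]), 1e-6)
    # GDM line-search contract: accepted energies never increase
    expect_true(all(diff(r_g$trace$E) <= 1e-11))
  }
})

test_that("at convergence the occupied-virtual Fock block is stationary", {
  p <- tb_test_params()
  r <- scf_solve(make_lif(2.0), p, scf_settings(solver = "gdm"))
  expect_true(r$converged)
  FM <- t(r$C$alpha) %*% fock_build(r$engine, r$Pa, r$Pb)$Fa %*% r$C$alpha
  occ <- r$occ$alpha > 0.5
  expect_lt(max(abs(FM[occ, !occ])), 1e-4)
})

test_that("Fermi smearing at 300 K changes gapped systems negligibly", {
  p <- tb_test_params()
  for (mol in list(make_random_molecule(1), make_random_molecule(4))) {
    r300 <- scf_solve(mol, p, scf_settings(solver = "diis", etemp = 300))
    r0 <- scf_solve(mol, p, scf_settings(solver = "diis", etemp = 0))
    expect_lt(abs(r300$energy[["E_tot"]] - r0$energy[["E_tot"]]), 1e-4)
  }
})

test_that("non-convergence is flagged data, not an exception", {
  p <- tb_test_params()
  r <- scf_solve(make_lif(4.0), p, scf_settings(solver = "diis", max_iter = 30))
  expect_false(r$converged)
  expect_s3_class(r, "tb_scf")
  expect_equal(nrow(r$trace), 30)
})
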