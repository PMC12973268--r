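# Hamiltonian terms: repulsion, Hueckel core, variational consistency of every
# self-consistent term, size consistency and rigid-motion invariance.

test_that("repulsion energy behaves as a pairwise decaying atomic sum", {
  p <- tb_test_params()
  e1 <- build_engine(atomic_structure("F", matrix(0, 1, 3), 0L, 2L), p)
  expect_equal(e1$E_rep, 0)
  e_close <- build_engine(make_lif(1.25), p)
  e_far <- build_engine(make_lif(2.50), p)
  expect_gt(e_close$E_rep, e_far$E_rep)
  expect_gt(e_far$E_rep, 0)
  expect_error(build_engine(atomic_structure(c("H", "H"),
    rbind(c(0, 0, 0), c(0, 0, 0.04)), 0L, 1L), p), "geometry error")
})

test_that("core Hamiltonian diagonal of an isolated atom equals its shell levels", {
  p <- tb_test_params()
  s <- atomic_structure("F", matrix(0, 1, 3), 0L, 2L)
  eng <- build_engine(s, p)
  lev <- xtbu:::ev2ha(p$elements$F$levels)   # CN = 0 for an isolated atom
  expect_equal(diag(eng$H0), lev[c(1, 2, 2, 2)], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(eng$H0, t(eng$H0))
})

test_that("every self-consistent term is variationally consistent (Fock = dE/dP)", {
  p <- tb_test_params()
  cases <- list(list(mol = make_random_molecule(1), terms = "scc2"),
                list(mol = make_random_molecule(2), terms = "scc3"),
                list(mol = make_random_molecule(4), terms = "aes"),
                list(mol = make_random_molecule(4), terms = "axc"),
                list(mol = make_random_molecule(1), terms = "spin"),
                list(mol = make_random_molecule(8),
                     terms = c("scc2", "scc3", "aes", "axc", "spin")))
  for (cs in cases) {
    eng <- build_engine(cs$mol, p, terms = cs$terms)
    Pa <- random_density(eng$nao, seed = 11, scale = 0.6)
    Pb <- random_density(eng$nao, seed = 12, scale = 0.5)
    for (ch in c("alpha", "beta")) {
      dev <- fd_fock_max_dev(eng, Pa, Pb, channel = ch, n_probe = 20)
      expect_lt(dev, 1e-6)
    }
  }
})

test_that("spin polarization term follows its closed forms", {
  p <- tb_test_params()
  # closed-shell density: zero spin populations, zero energy and Fock
  eng <- build_engine(make_random_molecule(1), p, terms = "spin")
  Pc <- random_density(eng$nao, seed = 3)
  fb <- fock_build(eng, Pc, Pc)
  expect_equal(fb$terms$E_spin, 0)
  expect_equal(fb$Fa, fb$Fb, tolerance = 1e-12)
  # one atom, one shell, p = 1: E = W/2
  sH <- atomic_structure("H", matrix(0, 1, 3), 0L, 2L)
  engH <- build_engine(sH, p, terms = "spin")
  fbH <- fock_build(engH, matrix(1, 1, 1), matrix(0, 1, 1))
  expect_equal(fbH$terms$E_spin, p$elements$H$W[1, 1] / 2, tolerance = 1e-12)
})

test_that("with all optional terms disabled the Fock matrix reduces to H0", {
  p <- tb_test_params()
  eng <- build_engine(make_lif(1.6), p, terms = character(0))
  Pa <- random_density(eng$nao, seed = 5)
  fb <- fock_build(eng, Pa, Pa)
  expect_equal(fb$Fa, eng$H0, tolerance = 1e-14)
  expect_equal(sum(unlist(fb$terms)), eng$E_rep + sum((2 * Pa) * eng$H0),
               tolerance = 1e-12)
})

test_that("total energy is size consistent for closed-shell fragments", {
  p <- tb_test_params()
  far <- 100 * tb_units[["angstrom_per_bohr"]]
  run <- function(s) scf_solve(s, p, scf_settings(solver = "diis", etemp = 0))
  h2 <- atomic_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  hf <- atomic_structure(c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 0.92)))
  pair <- atomic_structure(c("H", "H", "H", "F"),
                           rbind(c(0, 0, 0), c(0, 0, 0.74),
                                 c(far, 0, 0), c(far, 0, 0.92)))
  e_sum <- run(h2)$energy[["E_tot"]] + run(hf)$energy[["E_tot"]]
  e_pair <- run(pair)$energy[["E_tot"]]
  expect_equal(e_pair, e_sum, tolerance = 1e-8)
})

test_that("total energy is invariant under rigid translation and rotation", {
  p <- tb_test_params()
  for (mol in list(make_lif(1.6), make_random_molecule(1))) {
    r1 <- scf_solve(mol, p, scf_settings(solver = "diis"))
    r2 <- scf_solve(rotate_structure(mol), p, scf_settings(solver = "diis"))
    expect_lt(abs(r1$energy[["E_tot"]] - r2$energy[["E_tot"]]), 1e-9)
  }
})

test_that("energy breakdown sums to the total exactly", {
  p <- tb_test_params()
  r <- scf_solve(make_lif(1.4), p, scf_settings(solver = "diis"))
  en <- r$energy
  expect_equal(en[["E_tot"]], sum(en[names(en) != "E_tot"]), tolerance = 1e-13)
})
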