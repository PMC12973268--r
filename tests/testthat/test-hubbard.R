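# Hubbard +U: occupation matrices, the three energy formulations, their Fock
# contributions, and the structural properties that characterize them.

make_d_shell_basis <- function() {
  b <- data.frame(shell = 1L, atom = 1L, element = "Fe", shell_idx = 1L,
                  label = "3d", l = 2L, deg = 5L, ao_start = 1L, ao_end = 5L,
                  refocc = 6)
  attr(b, "nao") <- 5L
  class(b) <- c("tb_basis", class(b))
  b
}

test_that("occupation matrices reduce to density blocks in an orthonormal basis", {
  b <- make_d_shell_basis()
  P <- random_density(5, seed = 7)
  occ <- occupation_matrix(P, diag(5), b)
  expect_equal(occ$shells[[1]]$n[[1]], P, tolerance = 1e-14)
  expect_equal(sum(diag(occ$shells[[1]]$dn[[1]])), 0, tolerance = 1e-13)
})

test_that("occupation matrices match an explicit element-wise projection", {
  # independent oracle: loop-wise evaluation of the symmetrized Mulliken sum
  set.seed(21)
  nao <- 6
  b <- data.frame(shell = 1:2, atom = 1:2, element = "X", shell_idx = 1L,
                  label = c("2p", "2p"), l = 1L, deg = 3L,
                  ao_start = c(1L, 4L), ao_end = c(3L, 6L), refocc = 0)
  attr(b, "nao") <- nao
  class(b) <- c("tb_basis", class(b))
  P <- random_density(nao, seed = 22)
  A <- matrix(rnorm(nao * nao, sd = 0.2), nao)
  S <- diag(nao) + (A + t(A)) / 8    # valid symmetric positive definite overlap
  occ <- occupation_matrix(P, S, b)
  for (sh in 1:2) {
    ii <- b$ao_start[sh]:b$ao_end[sh]
    ref <- matrix(0, 3, 3)
    for (mi in seq_along(ii)) for (nu in seq_along(ii)) {
      acc <- 0
      for (tau in 1:nao)
        acc <- acc + S[ii[mi], tau] * P[tau, ii[nu]] + P[ii[mi], tau] * S[tau, ii[nu]]
      ref[mi, nu] <- acc / 2
    }
    expect_equal(occ$shells[[sh]]$n[[1]], ref, tolerance = 1e-13)
  }
  expect_error(occupation_matrix(P[1:4, 1:4], S, b), "dimension mismatch")
})

test_that("channel traces reproduce the Mulliken electron counts on converged LiF", {
  p <- tb_test_params()
  r <- scf_solve(make_lif(1.6), p, scf_settings(solver = "diis"))
  occ <- occupation_matrix(r$Pa, r$engine$S, r$engine$basis, Pb = r$Pb)
  tr_a <- sum(vapply(occ$shells, function(s) s$trace[1], 0))
  tr_b <- sum(vapply(occ$shells, function(s) s$trace[2], 0))
  expect_equal(tr_a, r$engine$n_alpha, tolerance = 1e-8)
  expect_equal(tr_b, r$engine$n_beta, tolerance = 1e-8)
})

test_that("Hubbard energies reproduce their closed forms", {
  b <- make_d_shell_basis()
  S <- diag(5)
  # FLL vanishes for integer idempotent diagonal occupations
  P_int <- diag(c(1, 1, 0, 1, 0))
  occ <- occupation_matrix(P_int, S, b)
  expect_equal(hubbard_energy(occ, "fll", U = 0.3, alpha = 0.5), 0, tolerance = 1e-14)
  # pSIC closed form: one electron, alpha = 0.5, U = 0.2 -> -0.05 Hartree
  occ1 <- occupation_matrix(diag(c(1, 0, 0, 0, 0)), S, b)
  expect_equal(hubbard_energy(occ1, "psic", U = 0.2, alpha = 0.5), -0.05,
               tolerance = 1e-14)
  # FLL at a half-filled d shell, both spins: +0.0625 Hartree
  occ2 <- occupation_matrix(diag(5) / 2, S, b, Pb = diag(5) / 2)
  expect_equal(hubbard_energy(occ2, "fll", U = 0.1, alpha = 0.5), 0.0625,
               tolerance = 1e-14)
  # AMF vanishes exactly at uniform occupations
  expect_equal(hubbard_energy(occ2, "amf", U = 0.1, alpha = 0.5), 0, tolerance = 1e-14)
  # zero U means zero energy, negative U is rejected
  expect_equal(hubbard_energy(occ2, "psic", U = 0, alpha = 0.5), 0)
  expect_error(hubbard_energy(occ2, "fll", U = -0.1, alpha = 0.5), ">= 0")
})

test_that("FLL and pSIC are related by the linear trace term exactly", {
  b <- make_d_shell_basis()
  P <- random_density(5, seed = 9, scale = 0.8)
  A <- matrix(rnorm(25, sd = 0.1), 5)
  S <- diag(5) + (A + t(A)) / 10
  occ <- occupation_matrix(P, S, b)
  U <- 0.23; al <- 0.5
  e_fll <- hubbard_energy(occ, "fll", U, al)
  e_psic <- hubbard_energy(occ, "psic", U, al)
  tr_n <- occ$shells[[1]]$trace[1]
  expect_equal(e_fll, e_psic + al * U / 2 * tr_n, tolerance = 1e-13)
})

test_that("E_U is invariant under within-shell orthogonal rotations", {
  b <- make_d_shell_basis()
  P <- random_density(5, seed = 13, scale = 0.7)
  occ <- occupation_matrix(P, diag(5), b)
  set.seed(14)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  occ_rot <- occupation_matrix(Q %*% P %*% t(Q), diag(5), b)
  for (v in c("fll", "amf", "psic")) {
    expect_lt(abs(hubbard_energy(occ, v, 0.15, 0.5) -
                  hubbard_energy(occ_rot, v, 0.15, 0.5)), 1e-10)
  }
})

test_that("Fock contributions are exact derivatives of the energies", {
  p0 <- tb_test_params()
  p <- set_parameters(p0, "Fe", c(Ud = 0.18, Us = 0.11, Up = 0.07))
  s <- atomic_structure(c("Fe", "N"), rbind(c(0, 0, 0), c(0, 0, 2.0)), 0L, 4L)
  for (v in c("fll", "amf", "psic")) {
    eng <- build_engine(s, p, uvariant = v, terms = character(0))
    Pa <- random_density(eng$nao, seed = 31, scale = 0.5)
    Pb <- random_density(eng$nao, seed = 32, scale = 0.4)
    dev <- fd_fock_max_dev(eng, Pa, Pb, channel = "alpha", n_probe = 20)
    expect_lt(dev, 1e-7)
  }
  # zero-U engines contribute nothing
  eng0 <- build_engine(s, p0, uvariant = "fll", terms = character(0))
  Pa <- random_density(eng0$nao, seed = 33)
  fb <- fock_build(eng0, Pa, Pa)
  expect_equal(fb$terms$E_U, 0)
  expect_equal(fb$Fa, eng0$H0, tolerance = 1e-14)
})

test_that("FLL occupation-space potential vanishes at half filling", {
  b <- make_d_shell_basis()
  occ <- occupation_matrix(diag(5) / 2, diag(5), b)
  Fk <- hubbard_fock(occ, "fll", U = 0.2, S = diag(5), basis = b, alpha = 0.5)
  expect_equal(Fk[[1]], matrix(0, 5, 5), tolerance = 1e-14)
})

test_that("AMF vanishes iff the occupation is a multiple of the identity", {
  b <- make_d_shell_basis()
  occ_u <- occupation_matrix(diag(5) * 0.37, diag(5), b)
  expect_equal(hubbard_energy(occ_u, "amf", 0.2, 0.5), 0, tolerance = 1e-14)
  P <- diag(c(0.5, 0.4, 0.35, 0.35, 0.25))
  occ_n <- occupation_matrix(P, diag(5), b)
  expect_lt(hubbard_energy(occ_n, "amf", 0.2, 0.5), -1e-6)
})

test_that("FLL penalizes fractional occupations: integer filling minimizes E", {
  # enumeration over a 0.01 grid on a 2-orbital shell at fixed trace 1
  b <- data.frame(shell = 1L, atom = 1L, element = "X", shell_idx = 1L,
                  label = "2p", l = 0L, deg = 2L, ao_start = 1L, ao_end = 2L,
                  refocc = 0)
  attr(b, "nao") <- 2L
  class(b) <- c("tb_basis", class(b))
  evals <- vapply(seq(0, 1, by = 0.01), function(x) {
    occ <- occupation_matrix(diag(c(x, 1 - x)), diag(2), b)
    hubbard_energy(occ, "fll", U = 0.2, alpha = 0.5)
  }, 0)
  e_int <- evals[c(1, length(evals))]
  expect_true(all(evals >= min(e_int) - 1e-14))
  expect_equal(min(evals), min(e_int), tolerance = 1e-14)
})
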