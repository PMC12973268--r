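# Shared helpers: cached parameter set, random-but-seeded density matrices,
# and the central finite-difference oracle for variational-consistency tests.

tb_test_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parameters()
    cache
  }
})

# deterministic symmetric "density-like" matrix with given trace scale
random_density <- function(nao, seed, scale = 1) {
  set.seed(seed)
  A <- matrix(rnorm(nao * nao, sd = 0.3), nao, nao)
  P <- crossprod(A) / nao * scale
  (P + t(P)) / 2
}

# central finite difference of the total term energy w.r.t. symmetric
# density-matrix perturbations, compared against the analytic Fock matrix
fd_fock_max_dev <- function(engine, Pa, Pb, h = 1e-6, channel = "alpha",
                            n_probe = 25, seed = 1) {
  fb <- fock_build(engine, Pa, Pb)
  Fmat <- if (channel == "alpha") fb$Fa else fb$Fb
  nao <- engine$nao
  set.seed(seed)
  idx <- cbind(sample.int(nao, n_probe, replace = TRUE),
               sample.int(nao, n_probe, replace = TRUE))
  idx <- unique(idx)
  dev <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    pert <- function(s) {
      P <- if (channel == "alpha") Pa else Pb
      P[i, j] <- P[i, j] + s
      if (i != j) P[j, i] <- P[j, i] + s
      P
    }
    ep <- if (channel == "alpha") sum(unlist(fock_build(engine, pert(h), Pb)$terms))
          else sum(unlist(fock_build(engine, Pa, pert(h))$terms))
    em <- if (channel == "alpha") sum(unlist(fock_build(engine, pert(-h), Pb)$terms))
          else sum(unlist(fock_build(engine, Pa, pert(-h))$terms))
    num <- (ep - em) / (2 * h)
    ana <- if (i == j) Fmat[i, j] else 2 * Fmat[i, j]
    dev <- max(dev, abs(num - ana))
  }
  dev
}

# rigid rotation of a structure (angle in radians about given axis)
rotate_structure <- function(s, angle = 0.73, axis = c(1, 2, 2), shift = c(0.3, -1.1, 0.7)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  s$coords_ang <- t(R %*% t(s$coords_ang)) + rep(shift, each = nrow(s$coords_ang))
  s
}
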