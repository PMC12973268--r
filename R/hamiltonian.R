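# Tight-binding engine: zeroth-order Hamiltonian (repulsion + extended-Hueckel
# term), self-consistent isotropic second/third-order charge terms, anisotropic
# (multipole) electrostatics and exchange-correlation, spin polarization, and
# the on-site Hubbard correction.  The engine object precomputes everything
# that does not depend on the density so SCF iterations and parameter sweeps
# (which only touch W and U) are cheap.

# GFN-type fractional coordination number (double-logistic counting function)
.coordination_numbers <- function(xyz, elements, params) {
  g <- params$global
  nat <- nrow(xyz)
  cn <- numeric(nat)
  rc <- vapply(elements, function(el) params$elements[[el]]$rcov, 0)
  for (a in seq_len(nat)) {
    s <- 0
    for (b in seq_len(nat)) {
      if (a == b) next
      R <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      r0 <- ang2bohr(rc[a] + rc[b]) * 4 / 3
      s <- s + 1 / (1 + exp(-g$cn_ka * (r0 / R - 1))) /
               (1 + exp(-g$cn_kb * ((r0 + g$cn_rshift) / R - 1)))
    }
    cn[a] <- s
  }
  cn
}

.pair_repulsion <- function(xyz, elements, params) {
  g <- params$global
  nat <- nrow(xyz)
  e_rep <- 0
  light <- c("H", "He")
  for (a in seq_len(nat)) for (b in seq_len(nat)) {
    if (b <= a) next
    R <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    if (R < 0.1) stop(sprintf("geometry error: atoms %d and %d are %.3f Bohr apart", a, b, R))
    pa <- params$elements[[elements[a]]]; pb <- params$elements[[elements[b]]]
    kf <- if (elements[a] %in% light && elements[b] %in% light) g$rep_kexp_light else g$rep_kexp
    e_rep <- e_rep + pa$zeff * pb$zeff / R * exp(-sqrt(pa$arep * pb$arep) * R^kf)
  }
  e_rep
}

# Extended-Hueckel core Hamiltonian with CN-shifted levels, EN and
# shell-polynomial distance scaling, and Slater-exponent scaling.
.build_h0 <- function(basis, ints, cn, params) {
  g <- params$global
  nao <- attr(basis, "nao")
  nsh <- nrow(basis)
  kl <- c(g$ks, g$kp, g$kd)
  # CN-shifted shell levels (Hartree)
  h <- numeric(nsh)
  zeta <- numeric(nsh); shp <- numeric(nsh); en <- numeric(nsh); rcov <- numeric(nsh)
  for (s in seq_len(nsh)) {
    e <- params$elements[[basis$element[s]]]
    k <- basis$shell_idx[s]
    h[s] <- ev2ha(e$levels[k] - e$kcn[k] * cn[basis$atom[s]])
    zeta[s] <- e$slater[k]; shp[s] <- e$shpoly[k]; en[s] <- e$en; rcov[s] <- e$rcov
  }
  H0 <- matrix(0, nao, nao)
  for (s1 in seq_len(nsh)) {
    i1 <- basis$ao_start[s1]:basis$ao_end[s1]
    H0[cbind(i1, i1)] <- h[s1]
    for (s2 in seq_len(nsh)) {
      if (s2 == s1) next
      a <- basis$atom[s1]; b <- basis$atom[s2]
      if (a == b) next   # on-site off-diagonal blocks are zero
      i2 <- basis$ao_start[s2]:basis$ao_end[s2]
      l1 <- basis$l[s1]; l2 <- basis$l[s2]
      K <- if (l1 == l2) kl[l1 + 1] else 0.5 * (kl[l1 + 1] + kl[l2 + 1])
      Ken <- 1 + g$ken * (en[s1] - en[s2])^2
      Y <- (2 * sqrt(zeta[s1] * zeta[s2]) / (zeta[s1] + zeta[s2]))^g$wexp
      R <- sqrt(sum((ints$coords_bohr[a, ] - ints$coords_bohr[b, ])^2))
      R0 <- ang2bohr(rcov[s1] + rcov[s2])
      Pi <- (1 + shp[s1] * sqrt(R / R0)) * (1 + shp[s2] * sqrt(R / R0))
      H0[i1, i2] <- 0.5 * K * Ken * Y * Pi * ints$S[i1, i2] * (h[s1] + h[s2])
    }
  }
  (H0 + t(H0)) / 2
}

# shell-resolved second-order Coulomb kernel (harmonic-mean hardness damping)
.build_gamma <- function(basis, ints, params) {
  nsh <- nrow(basis)
  g <- params$global
  eta <- numeric(nsh)
  for (s in seq_len(nsh)) {
    e <- params$elements[[basis$element[s]]]
    eta[s] <- e$gam * e$lgam[basis$shell_idx[s]]
  }
  G <- matrix(0, nsh, nsh)
  for (s1 in seq_len(nsh)) for (s2 in s1:nsh) {
    R <- sqrt(sum((ints$coords_bohr[basis$atom[s1], ] - ints$coords_bohr[basis$atom[s2], ])^2))
    hm <- 2 * eta[s1] * eta[s2] / (eta[s1] + eta[s2])
    G[s1, s2] <- G[s2, s1] <- (R^g$gexp + hm^(-g$gexp))^(-1 / g$gexp)
  }
  G
}

# CN-dependent multipole damping radii and pair damping factors
.build_aes_kernels <- function(basis, ints, cn, params) {
  g <- params$global
  atoms <- unique(basis$atom)
  nat <- length(atoms)
  elements <- vapply(atoms, function(a) basis$element[match(a, basis$atom)], "")
  mrad <- numeric(nat); dk <- numeric(nat); qk <- numeric(nat)
  for (a in seq_len(nat)) {
    e <- params$elements[[elements[a]]]
    t1 <- exp(-g$mp_kexp * (cn[a] - e$mpvcn - g$mp_shift))
    mrad[a] <- e$mprad + (g$mp_rmax - e$mprad) / (1 + t1)
    dk[a] <- e$dkernel; qk[a] <- e$qkernel
  }
  f3 <- matrix(0, nat, nat); f5 <- matrix(0, nat, nat)
  for (a in seq_len(nat)) for (b in seq_len(nat)) {
    if (a == b) next
    R <- sqrt(sum((ints$coords_bohr[a, ] - ints$coords_bohr[b, ])^2))
    rr <- 0.5 * (mrad[a] + mrad[b]) / R
    f3[a, b] <- 1 / (1 + 6 * rr^g$dmp3) / R^3
    f5[a, b] <- 1 / (1 + 6 * rr^g$dmp5) / R^5
  }
  list(f3 = f3, f5 = f5, dkernel = dk, qkernel = qk)
}

#' Build a tight-binding engine for a structure
#'
#' Precomputes integrals, the zeroth-order Hamiltonian, repulsion energy and
#' all density-independent interaction kernels, and returns closures that
#' evaluate the Fock matrices and the term-resolved energy breakdown for given
#' spin-channel density matrices.
#'
#' @param structure A `tb_structure`.
#' @param params A `tb_parameters` object.
#' @param uvariant Hubbard variant: `"none"`, `"fll"`, `"amf"` or `"psic"`.
#' @param terms Character vector of self-consistent terms to enable; default
#'   all of `c("scc2", "scc3", "aes", "axc", "spin")`.  The reduced Hamiltonian
#'   used by some tests switches off the anisotropic pieces.
#' @return An object of class `tb_engine`.
#' @export
build_engine <- function(structure, params = load_parameters(),
                         uvariant = c("none", "fll", "amf", "psic"),
                         terms = c("scc2", "scc3", "aes", "axc", "spin")) {
  uvariant <- match.arg(uvariant)
  basis <- build_basis(structure, params)
  ints <- compute_integrals(structure, params, basis)
  cn <- .coordination_numbers(ints$coords_bohr, structure$elements, params)
  H0 <- .build_h0(basis, ints, cn, params)
  E_rep <- if (length(structure$elements) > 1)
    .pair_repulsion(ints$coords_bohr, structure$elements, params) else 0
  G <- .build_gamma(basis, ints, params)
  aes <- .build_aes_kernels(basis, ints, cn, params)
  cnt <- electron_counts(structure, params)

  nsh <- nrow(basis)
  gam3 <- numeric(nsh); Ush <- numeric(nsh)
  for (s in seq_len(nsh)) {
    e <- params$elements[[basis$element[s]]]
    gam3[s] <- e$gam3 * params$global$gam3_shell[basis$l[s] + 1]
    Ush[s] <- e$U[basis$shell_idx[s]]
  }
  nat <- length(structure$elements)
  Wat <- vector("list", nat)
  for (a in seq_len(nat)) {
    sh <- which(basis$atom == a)
    e <- params$elements[[structure$elements[a]]]
    Wat[[a]] <- e$W[basis$shell_idx[sh], basis$shell_idx[sh], drop = FALSE]
  }
  ao_shell <- rep(basis$shell, basis$deg)
  ao_atom <- rep(basis$atom, basis$deg)

  eng <- list(
    structure = structure, params = params, basis = basis, nao = attr(basis, "nao"),
    S = ints$S, D = ints$D, Q = ints$Q, coords_bohr = ints$coords_bohr,
    H0 = H0, E_rep = E_rep, gamma = G, gam3 = gam3, aes = aes, cn = cn,
    n0 = basis$refocc, ao_shell = ao_shell, ao_atom = ao_atom,
    W = Wat, U = Ush, uvariant = uvariant, alpha = params$global$alpha,
    terms = terms, n_alpha = cnt$n_alpha, n_beta = cnt$n_beta, nelec = cnt$nelec,
    kind = "molecule")
  class(eng) <- "tb_engine"
  eng
}

# Mulliken shell populations from a (total or spin) density matrix
.shell_pops <- function(engine, P) {
  d <- rowSums(P * engine$S)   # diag(P S)
  as.numeric(rowsum(d, engine$ao_shell))
}

#' Fock matrices and energy terms for given channel densities
#'
#' Evaluates every density-dependent term of the Hamiltonian on the supplied
#' spin-channel density matrices and returns the per-channel Fock matrices
#' together with the term-resolved energy breakdown (excluding the Fermi
#' entropy term, which is owned by the SCF driver).
#'
#' @param engine A `tb_engine` (molecular or model).
#' @param Pa,Pb Spin-channel density matrices.
#' @return List with `Fa`, `Fb` and `terms` (named energies, Hartree).
#' @export
fock_build <- function(engine, Pa, Pb) UseMethod("fock_build")

#' @export
fock_build.tb_engine <- function(engine, Pa, Pb) {
  S <- engine$S
  P <- Pa + Pb
  nao <- engine$nao
  terms <- engine$terms
  E <- list(E_rep = engine$E_rep, E_EHT = sum(P * engine$H0), E_IES = 0,
            E_IXC = 0, E_AES = 0, E_AXC = 0, E_spin = 0, E_U = 0)
  Fa <- engine$H0
  Fb <- engine$H0

  pop <- .shell_pops(engine, P)
  q <- engine$n0 - pop
  vsh <- numeric(length(q))
  if ("scc2" %in% terms) {
    E$E_IES <- 0.5 * sum(q * (engine$gamma %*% q))
    vsh <- vsh + as.numeric(engine$gamma %*% q)
  }
  if ("scc3" %in% terms) {
    E$E_IXC <- sum(engine$gam3 * q^3) / 3
    vsh <- vsh + engine$gam3 * q^2
  }
  if (any(vsh != 0)) {
    vao <- vsh[engine$ao_shell]
    Fq <- -0.5 * S * outer(vao, vao, "+")
    Fa <- Fa + Fq; Fb <- Fb + Fq
  }

  if (any(c("aes", "axc") %in% terms)) {
    up <- .aes_axc(engine, P, q)
    E$E_AES <- up$E_AES; E$E_AXC <- up$E_AXC
    Fa <- Fa + up$F; Fb <- Fb + up$F
  }

  if ("spin" %in% terms) {
    pa <- .shell_pops(engine, Pa); pb <- .shell_pops(engine, Pb)
    p <- pa - pb
    Vsh <- numeric(length(p))
    for (a in seq_along(engine$W)) {
      sh <- which(engine$basis$atom == a)
      E$E_spin <- E$E_spin + 0.5 * sum(p[sh] * (engine$W[[a]] %*% p[sh]))
      Vsh[sh] <- engine$W[[a]] %*% p[sh]
    }
    vao <- Vsh[engine$ao_shell]
    Fs <- 0.5 * S * outer(vao, vao, "+")
    Fa <- Fa + Fs; Fb <- Fb - Fs
  }

  if (engine$uvariant != "none" && any(engine$U > 0)) {
    hu <- .hubbard_contribution(engine, Pa, Pb)
    E$E_U <- hu$energy
    Fa <- Fa + hu$Fa; Fb <- Fb + hu$Fb
  }
  list(Fa = (Fa + t(Fa)) / 2, Fb = (Fb + t(Fb)) / 2, terms = E)
}

# anisotropic electrostatics (cumulative atomic multipoles) + on-site
# multipole exchange-correlation kernels
.aes_axc <- function(engine, P, qsh) {
  nat <- nrow(engine$coords_bohr)
  nao <- engine$nao
  aidx <- lapply(seq_len(nat), function(a) which(engine$ao_atom == a))
  qat <- as.numeric(rowsum(qsh, engine$basis$atom))
  # charge-signed cumulative atomic dipoles and traceless quadrupoles
  m <- matrix(0, nat, 3)
  Mfull <- array(0, c(nat, 3, 3))
  qmap <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (a in seq_len(nat)) {
    ii <- aidx[[a]]
    for (d in 1:3) m[a, d] <- -sum(P[ii, , drop = FALSE] * engine$D[ii, , d])
    for (k in 1:6) {
      v <- -sum(P[ii, , drop = FALSE] * engine$Q[ii, , k])
      Mfull[a, qmap[k, 1], qmap[k, 2]] <- Mfull[a, qmap[k, 1], qmap[k, 2]] + v
      if (qmap[k, 1] != qmap[k, 2])
        Mfull[a, qmap[k, 2], qmap[k, 1]] <- Mfull[a, qmap[k, 2], qmap[k, 1]] + v
    }
  }
  th <- array(0, c(nat, 3, 3))
  for (a in seq_len(nat)) {
    tr <- sum(diag(Mfull[a, , ]))
    th[a, , ] <- 1.5 * Mfull[a, , ] - 0.5 * tr * diag(3)
  }

  E_AES <- 0; E_AXC <- 0
  vq <- numeric(nat); vm <- matrix(0, nat, 3); vth <- array(0, c(nat, 3, 3))
  do_aes <- "aes" %in% engine$terms
  do_axc <- "axc" %in% engine$terms
  if (do_aes) {
    f3 <- engine$aes$f3; f5 <- engine$aes$f5
    for (a in seq_len(nat)) for (b in seq_len(nat)) {
      if (a == b) next
      Rv <- engine$coords_bohr[a, ] - engine$coords_bohr[b, ]
      R2 <- sum(Rv^2)
      # charge(a)-dipole(b)
      E_AES <- E_AES + qat[a] * sum(m[b, ] * Rv) * f3[a, b]
      vq[a] <- vq[a] + sum(m[b, ] * Rv) * f3[a, b]
      vm[b, ] <- vm[b, ] + qat[a] * Rv * f3[a, b]
      # charge(a)-quadrupole(b)
      qq <- as.numeric(Rv %*% th[b, , ] %*% Rv)
      E_AES <- E_AES + qat[a] * qq * f5[a, b]
      vq[a] <- vq[a] + qq * f5[a, b]
      vth[b, , ] <- vth[b, , ] + qat[a] * f5[a, b] * outer(Rv, Rv)
      # dipole-dipole (half of ordered double count)
      dd <- (sum(m[a, ] * m[b, ]) * R2 - 3 * sum(m[a, ] * Rv) * sum(m[b, ] * Rv)) * f5[a, b]
      E_AES <- E_AES + 0.5 * dd
      vm[a, ] <- vm[a, ] + (m[b, ] * R2 - 3 * Rv * sum(m[b, ] * Rv)) * f5[a, b]
    }
  }
  if (do_axc) {
    for (a in seq_len(nat)) {
      E_AXC <- E_AXC + engine$aes$dkernel[a] * sum(m[a, ]^2) +
               engine$aes$qkernel[a] * sum(th[a, , ]^2)
      vm[a, ] <- vm[a, ] + 2 * engine$aes$dkernel[a] * m[a, ]
      vth[a, , ] <- vth[a, , ] + 2 * engine$aes$qkernel[a] * th[a, , ]
    }
  }

  # fold potentials back through the density dependence of q, m, theta
  Fm <- matrix(0, nao, nao)
  vq_ao <- vq[engine$ao_atom]
  Fm <- Fm - 0.5 * engine$S * outer(vq_ao, vq_ao, "+")
  for (a in seq_len(nat)) {
    ii <- aidx[[a]]
    acc <- matrix(0, length(ii), nao)
    for (d in 1:3) acc <- acc - vm[a, d] * engine$D[ii, , d]
    Wt <- 1.5 * vth[a, , ] - 0.5 * sum(diag(vth[a, , ])) * diag(3)
    for (k in 1:6) {
      w <- Wt[qmap[k, 1], qmap[k, 2]]
      if (qmap[k, 1] != qmap[k, 2]) w <- 2 * w
      acc <- acc - w * engine$Q[ii, , k]
    }
    Fm[ii, ] <- Fm[ii, ] + acc
  }
  Fm <- (Fm + t(Fm)) / 2
  list(E_AES = E_AES, E_AXC = E_AXC, F = Fm)
}
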