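# Geometric direct minimization: minimize the electronic (free) energy
# directly on the manifold of S-orthonormal orbitals via exponentials of
# antisymmetric rotation generators among orbital pairs with differing
# occupations.  Quasi-Newton (L-BFGS) accumulation with a diagonal
# preconditioner built from orbital-energy differences, and a backtracking
# line search that guarantees a non-increasing energy for every accepted step.
# Occupations are re-resolved from Fermi smearing at every macro-iteration;
# a refresh is only accepted if it does not raise the free energy (otherwise
# a damped refresh is tried), so the recorded energy sequence is monotone.

.skew_from_pairs <- function(kappa, pairs, n) {
  K <- matrix(0, n, n)
  K[pairs] <- kappa
  K - t(K)
}

.expm_skew <- function(K) {
  # exp of a real antisymmetric matrix via the Hermitian eigenproblem of iK
  e <- eigen(1i * K, symmetric = TRUE)
  Re(e$vectors %*% (exp(-1i * e$values) * t(Conj(e$vectors))))
}

.gdm_channel_pairs <- function(f, tol = 1e-8) {
  df <- outer(f, f, "-")
  which(upper.tri(df) & abs(df) > tol, arr.ind = TRUE)
}

.scf_gdm <- function(engine, settings) {
  S <- engine$S
  X <- .sqrt_inv(S)$X
  g <- initial_guess(engine, settings)
  Na <- settings$n_alpha %||% engine$n_alpha
  Nb <- settings$n_beta %||% engine$n_beta
  Ca <- g$Ca; Cb <- g$Cb
  occ0 <- .resolve_occupations(settings, g$eps_a, g$eps_b, Na, Nb)
  fa <- occ0$fa; fbocc <- occ0$fb
  E_fermi <- occ0$E_fermi; mu <- occ0$mu

  energy_at <- function(Ca, Cb, fa, fb) {
    fb_ <- fock_build(engine, .density(Ca, fa), .density(Cb, fb))
    list(E = sum(unlist(fb_$terms)), fb = fb_)
  }
  grad_of <- function(st, Ca, Cb, fa, fb, pa, pb) {
    FMa <- t(Ca) %*% st$fb$Fa %*% Ca
    FMb <- t(Cb) %*% st$fb$Fb %*% Cb
    list(FMa = FMa, FMb = FMb,
         g = c(if (nrow(pa)) 2 * FMa[pa] * (fa[pa[, 2]] - fa[pa[, 1]]) else numeric(0),
               if (nrow(pb)) 2 * FMb[pb] * (fb[pb[, 2]] - fb[pb[, 1]]) else numeric(0)))
  }

  st <- energy_at(Ca, Cb, fa, fbocc)
  E <- st$E + E_fermi
  trace <- data.frame()
  mem <- list()
  pairs_a <- .gdm_channel_pairs(fa); pairs_b <- .gdm_channel_pairs(fbocc)
  converged <- FALSE
  it <- 0
  while (it < settings$max_iter) {
    it <- it + 1
    gr <- grad_of(st, Ca, Cb, fa, fbocc, pairs_a, pairs_b)
    eps_a <- diag(gr$FMa); eps_b <- diag(gr$FMb)

    # Occupation refresh, accepted only if the free energy does not rise.
    # With pinned (constrained) occupations the occupation vector is fixed
    # once and orbital rotations alone do the work: re-running aufbau each
    # iteration would swap degenerate frontier orbitals back and forth.
    occn <- if (is.null(settings$occupations))
      .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
    else list(fa = fa, fb = fbocc, mu = mu, E_fermi = 0)
    dfmax <- max(abs(occn$fa - fa), abs(occn$fb - fbocc))
    if (dfmax > 1e-12) {
      for (w in c(1, 0.3, 0.1)) {
        fa_t <- fa + w * (occn$fa - fa)
        fb_t <- fbocc + w * (occn$fb - fbocc)
        # entropy of mixed occupations (exact at w = 1)
        kT <- tb_units[["kB_hartree_per_K"]] * settings$etemp
        sfun <- function(x) ifelse(x > 1e-15 & x < 1 - 1e-15,
                                   x * log(x) + (1 - x) * log(1 - x), 0)
        EF_t <- if (is.null(settings$occupations)) kT * (sum(sfun(fa_t)) + sum(sfun(fb_t))) else 0
        st_t <- energy_at(Ca, Cb, fa_t, fb_t)
        if (st_t$E + EF_t <= E + 1e-12) {
          fa <- fa_t; fbocc <- fb_t; E_fermi <- EF_t; mu <- occn$mu
          st <- st_t; E <- st$E + E_fermi
          pa_new <- .gdm_channel_pairs(fa); pb_new <- .gdm_channel_pairs(fbocc)
          if (dfmax > 1e-6 || !identical(unname(pa_new), unname(pairs_a)) ||
              !identical(unname(pb_new), unname(pairs_b))) mem <- list()
          pairs_a <- pa_new; pairs_b <- pb_new
          gr <- grad_of(st, Ca, Cb, fa, fbocc, pairs_a, pairs_b)
          eps_a <- diag(gr$FMa); eps_b <- diag(gr$FMb)
          break
        }
      }
    }

    grad <- gr$g
    gnorm <- if (length(grad)) max(abs(grad)) else 0
    dE_last <- if (nrow(trace)) E - trace$E[nrow(trace)] else NA
    trace <- rbind(trace, data.frame(iter = it, E = E, dE = dE_last, err = gnorm))
    if (settings$verbose)
      message(sprintf("gdm %3d  E = %.10f  |g| = %9.3e", it, E, gnorm))
    if ((!is.na(dE_last) && abs(dE_last) < settings$conv_e && gnorm < settings$conv_err) ||
        (is.na(dE_last) && gnorm < settings$conv_err)) {
      converged <- TRUE; break
    }
    if (!length(grad)) { converged <- TRUE; break }

    dgap <- c(if (nrow(pairs_a)) abs((eps_a[pairs_a[, 2]] - eps_a[pairs_a[, 1]]) *
                                     (fa[pairs_a[, 1]] - fa[pairs_a[, 2]])) else numeric(0),
              if (nrow(pairs_b)) abs((eps_b[pairs_b[, 2]] - eps_b[pairs_b[, 1]]) *
                                     (fbocc[pairs_b[, 1]] - fbocc[pairs_b[, 2]])) else numeric(0))
    prec <- 1 / pmax(4 * dgap, 0.1)

    d <- -grad * prec
    if (length(mem)) {
      qv <- grad
      al <- numeric(length(mem))
      for (i in rev(seq_along(mem))) {
        al[i] <- mem[[i]]$rho * sum(mem[[i]]$s * qv)
        qv <- qv - al[i] * mem[[i]]$y
      }
      r <- qv * prec
      for (i in seq_along(mem)) {
        be <- mem[[i]]$rho * sum(mem[[i]]$y * r)
        r <- r + mem[[i]]$s * (al[i] - be)
      }
      d <- -r
      if (sum(d * grad) >= 0) { d <- -grad * prec; mem <- list() }
    }

    # near stationarity the occupation refresh can keep the rotation gradient
    # hovering; a plain diagonalization move (accepted only if it does not raise
    # the free energy) canonicalizes the orbitals and lets the gradient settle
    if (is.null(settings$occupations) &&
        !is.na(dE_last) && abs(dE_last) < 10 * settings$conv_e && it %% 3 == 0) {
      ea_c <- eigen(t(X) %*% st$fb$Fa %*% X, symmetric = TRUE)
      eb_c <- eigen(t(X) %*% st$fb$Fb %*% X, symmetric = TRUE)
      occ_c <- .resolve_occupations(settings, ea_c$values, eb_c$values, Na, Nb)
      st_c <- energy_at(X %*% ea_c$vectors, X %*% eb_c$vectors, occ_c$fa, occ_c$fb)
      if (st_c$E + occ_c$E_fermi <= E + 1e-12) {
        Ca <- X %*% ea_c$vectors; Cb <- X %*% eb_c$vectors
        fa <- occ_c$fa; fbocc <- occ_c$fb
        E_fermi <- occ_c$E_fermi; mu <- occ_c$mu
        st <- st_c; E <- st$E + E_fermi
        pairs_a <- .gdm_channel_pairs(fa); pairs_b <- .gdm_channel_pairs(fbocc)
        mem <- list()
        gr <- grad_of(st, Ca, Cb, fa, fbocc, pairs_a, pairs_b)
        eps_a <- diag(gr$FMa); eps_b <- diag(gr$FMb)
        grad <- gr$g
        gnorm <- if (length(grad)) max(abs(grad)) else 0
        if (gnorm < settings$conv_err) { converged <- TRUE; break }
        if (!length(grad)) { converged <- TRUE; break }
        d <- -grad / pmax(4 * abs(grad), 0.1)
      }
    }

    slope <- sum(d * grad)
    t_step <- 1
    accepted <- FALSE
    for (ls in 1:30) {
      ka <- if (nrow(pairs_a)) t_step * d[seq_len(nrow(pairs_a))] else numeric(0)
      kb <- if (nrow(pairs_b)) t_step * d[nrow(pairs_a) + seq_len(nrow(pairs_b))] else numeric(0)
      Ca_t <- if (length(ka)) Ca %*% .expm_skew(.skew_from_pairs(ka, pairs_a, ncol(Ca))) else Ca
      Cb_t <- if (length(kb)) Cb %*% .expm_skew(.skew_from_pairs(kb, pairs_b, ncol(Cb))) else Cb
      st_t <- energy_at(Ca_t, Cb_t, fa, fbocc)
      E_t <- st_t$E + E_fermi
      if (E_t <= E + 1e-4 * t_step * slope + 1e-14) {
        gr2 <- grad_of(st_t, Ca_t, Cb_t, fa, fbocc, pairs_a, pairs_b)
        yv <- gr2$g - grad
        s_vec <- t_step * d
        sy <- sum(s_vec * yv)
        if (is.finite(sy) && sy > 1e-12) {
          mem[[length(mem) + 1]] <- list(s = s_vec, y = yv, rho = 1 / sy)
          if (length(mem) > 8) mem <- mem[-1]
        }
        Ca <- Ca_t; Cb <- Cb_t; st <- st_t; E <- E_t
        accepted <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!accepted) {
      mem <- list()
      if (gnorm < 10 * settings$conv_err) { converged <- gnorm < settings$conv_err; break }
    }
    if (it %% 20 == 0) {  # guard against orthonormality drift
      Ca <- Ca %*% .sqrt_inv(t(Ca) %*% S %*% Ca)$X
      Cb <- Cb %*% .sqrt_inv(t(Cb) %*% S %*% Cb)$X
    }
  }

  # canonicalize for reporting: diagonalize the converged Fock once, keep the
  # canonical state only if it does not raise the energy beyond threshold
  ea <- eigen(t(X) %*% st$fb$Fa %*% X, symmetric = TRUE)
  eb <- eigen(t(X) %*% st$fb$Fb %*% X, symmetric = TRUE)
  occf <- .resolve_occupations(settings, ea$values, eb$values, Na, Nb)
  st_f <- energy_at(X %*% ea$vectors, X %*% eb$vectors, occf$fa, occf$fb)
  if (st_f$E + occf$E_fermi <= E + settings$conv_e) {
    Ca <- X %*% ea$vectors; Cb <- X %*% eb$vectors
    fa <- occf$fa; fbocc <- occf$fb
    eps_a <- ea$values; eps_b <- eb$values
    st <- st_f; E_fermi <- occf$E_fermi; mu <- occf$mu
  } else {
    # keep the minimizing non-canonical orbitals; order them by level
    FMa <- t(Ca) %*% st$fb$Fa %*% Ca
    FMb <- t(Cb) %*% st$fb$Fb %*% Cb
    oa <- order(diag(FMa)); ob <- order(diag(FMb))
    Ca <- Ca[, oa]; Cb <- Cb[, ob]
    fa <- fa[oa]; fbocc <- fbocc[ob]
    eps_a <- diag(FMa)[oa]; eps_b <- diag(FMb)[ob]
  }
  .finish_state(engine, settings, converged, it, st$fb, E_fermi,
                Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, "gdm")
}

#' Geometric direct minimization
#'
#' Runs the GDM driver on an engine or structure; thin wrapper over
#' [scf_solve()] with `solver = "gdm"`.
#'
#' @inheritParams scf_solve
#' @return A `tb_scf` object (flagged, never an exception, on non-convergence).
#' @export
gdm_minimize <- function(x, params = load_parameters(), settings = scf_settings(solver = "gdm"),
                         uvariant = "none", terms = c("scc2", "scc3", "aes", "axc", "spin")) {
  settings$solver <- "gdm"
  scf_solve(x, params, settings, uvariant = uvariant, terms = terms)
}
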