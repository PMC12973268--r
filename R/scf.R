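# Self-consistent field drivers: Pulay DIIS extrapolation, geometric direct
# minimization (GDM) over orbital rotations, and a damped fixed-point fallback,
# all under finite-temperature Fermi smearing in an unrestricted two-channel
# formalism.  Non-convergence is data (a flagged result), never an exception.

#' SCF settings
#'
#' @param solver `"diis"`, `"gdm"` or `"fixed"` (damped fixed-point).
#' @param etemp Electronic temperature in Kelvin (default 300; 0 selects
#'   aufbau occupations with symmetric splitting over exact degeneracies).
#' @param conv_e Energy convergence threshold (Hartree).
#' @param conv_err Convergence threshold on the DIIS error / GDM gradient
#'   max-norm.
#' @param max_iter Maximum iterations (default 250).
#' @param diis_n DIIS history length.
#' @param damping Mixing factor of the fixed-point solver.
#' @param occupations `NULL` for Fermi occupations, or a list
#'   `list(mode = "pinned", channel = "alpha"|"beta", fraction = q)` pinning a
#'   fractional occupation on the frontier orbital of one channel.
#' @param n_alpha,n_beta Optional (possibly fractional) channel electron-count
#'   overrides; defaults come from the structure.
#' @param guess Optional warm start: a previous `tb_scf` result (or list with
#'   `Ca`, `Cb`) whose orbitals seed the new solve; used heavily by the
#'   parameter-optimization layer where successive evaluations differ only in
#'   `W`/`U` values.
#' @param verbose Print per-iteration lines.
#' @return A list of class `tb_scf_settings`.
#' @export
scf_settings <- function(solver = c("diis", "gdm", "fixed"), etemp = 300,
                         conv_e = 1e-6, conv_err = 1e-6, max_iter = 250,
                         diis_n = 8, damping = 0.4, occupations = NULL,
                         n_alpha = NULL, n_beta = NULL, guess = NULL,
                         verbose = FALSE) {
  solver <- match.arg(solver)
  stopifnot(conv_e > 0, conv_err > 0, etemp >= 0)
  structure(list(solver = solver, etemp = etemp, conv_e = conv_e,
                 conv_err = conv_err, max_iter = max_iter, diis_n = diis_n,
                 damping = damping, occupations = occupations,
                 n_alpha = n_alpha, n_beta = n_beta, guess = guess,
                 verbose = verbose),
            class = "tb_scf_settings")
}

#' Fermi occupations with entropy term
#'
#' Fermi-Dirac occupations `f_i = 1/(1 + exp((e_i - mu)/kT))` with the
#' chemical potential determined by bisection so that `sum(f) = N` to 1e-10,
#' and the electronic free-energy contribution `-T * S_el`.  At `T = 0`
#' aufbau filling is used, with a symmetric fractional split over frontier
#' levels that are degenerate within `degen_tol`.
#'
#' @param eps Orbital energies of one spin channel (Hartree).
#' @param N Electron count of the channel (may be fractional at `T > 0`).
#' @param T Electronic temperature (K).
#' @param degen_tol Degeneracy tolerance for the `T = 0` frontier split.
#' @return List with `f`, `mu` and `E_fermi` (the `-T S_el` contribution).
#' @export
fermi_occupations <- function(eps, N, T, degen_tol = 1e-9) {
  norb <- length(eps)
  if (N > norb + 1e-12) stop("channel electron count exceeds orbital count")
  if (N < 0) stop("negative electron count")
  kT <- tb_units[["kB_hartree_per_K"]] * T
  if (N == 0) return(list(f = numeric(norb), mu = -Inf, E_fermi = 0))
  if (kT <= 0) {
    ord <- order(eps)
    f <- numeric(norb)
    nfull <- floor(N + 1e-12)
    if (nfull > 0) f[ord[seq_len(nfull)]] <- 1
    rest <- N - nfull
    if (rest > 1e-12) {
      # symmetric split over levels degenerate with the frontier
      lvl <- eps[ord[nfull + 1]]
      idx <- ord[which(abs(eps[ord] - lvl) < degen_tol & seq_len(norb) > nfull)]
      f[idx] <- rest / length(idx)
    } else if (nfull > 0) {
      # degenerate HOMO group shares its electrons symmetrically
      lvl <- eps[ord[nfull]]
      grp <- which(abs(eps - lvl) < degen_tol)
      if (length(grp) > 1) {
        nin <- sum(f[grp])
        f[grp] <- nin / length(grp)
      }
    }
    return(list(f = f, mu = if (nfull > 0) eps[ord[nfull]] else min(eps), E_fermi = 0))
  }
  nf <- function(mu) sum(1 / (1 + exp(pmin(pmax((eps - mu) / kT, -500), 500))))
  lo <- min(eps) - 100 * kT - 10
  hi <- max(eps) + 100 * kT + 10
  for (i in 1:120) {
    mid <- (lo + hi) / 2
    dn <- nf(mid) - N
    if (abs(dn) < 1e-12) { lo <- hi <- mid; break }
    if (dn < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, abs(mid))) break
  }
  mu <- (lo + hi) / 2
  f <- 1 / (1 + exp(pmin(pmax((eps - mu) / kT, -500), 500)))
  # entropy; guard the 0 log 0 limits
  s <- function(x) ifelse(x > 1e-15 & x < 1 - 1e-15, x * log(x) + (1 - x) * log(1 - x), 0)
  list(f = f, mu = mu, E_fermi = kT * sum(s(f)))
}

# occupation resolver shared by all drivers
.resolve_occupations <- function(settings, eps_a, eps_b, Na, Nb) {
  occ <- settings$occupations
  if (is.null(occ)) {
    oa <- fermi_occupations(eps_a, Na, settings$etemp)
    ob <- fermi_occupations(eps_b, Nb, settings$etemp)
    return(list(fa = oa$f, fb = ob$f, mu = c(oa$mu, ob$mu),
                E_fermi = oa$E_fermi + ob$E_fermi))
  }
  if (occ$mode != "pinned") stop("unknown occupation mode: ", occ$mode)
  # aufbau filling with any fractional remainder pinned on the frontier
  # orbital (ties resolved toward the lowest orbital index, which is logged
  # as a convention, not physics)
  pin <- function(eps, N) {
    f <- numeric(length(eps))
    ord <- order(eps)
    nfull <- floor(N + 1e-9)
    if (nfull > 0) f[ord[seq_len(nfull)]] <- 1
    rest <- N - nfull
    if (rest > 1e-12) f[ord[nfull + 1]] <- rest
    f
  }
  list(fa = pin(eps_a, Na), fb = pin(eps_b, Nb), mu = c(NA, NA), E_fermi = 0)
}

.sqrt_inv <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  X <- e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  Xh <- e$vectors %*% diag(sqrt(e$values), length(e$values)) %*% t(e$vectors)
  list(X = X, Xh = Xh)
}

#' Initial guess from the zeroth-order Hamiltonian
#'
#' Diagonalizes the core Hamiltonian and fills orbitals with Fermi (or aufbau)
#' occupations; deterministic for identical inputs.
#'
#' @param engine A `tb_engine`.
#' @param settings A `tb_scf_settings`.
#' @return List with orbital coefficients, occupations and density matrices.
#' @export
initial_guess <- function(engine, settings = scf_settings()) {
  Na <- settings$n_alpha %||% engine$n_alpha
  Nb <- settings$n_beta %||% engine$n_beta
  gs <- settings$guess
  if (!is.null(gs)) {
    Ca <- if (!is.null(gs$C)) gs$C$alpha else gs$Ca
    Cb <- if (!is.null(gs$C)) gs$C$beta else gs$Cb
    if (!is.null(Ca) && nrow(Ca) == engine$nao) {
      eps_a <- if (!is.null(gs$eps)) gs$eps$alpha else seq_len(ncol(Ca))
      eps_b <- if (!is.null(gs$eps)) gs$eps$beta else seq_len(ncol(Cb))
      occ <- .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
      return(list(Ca = Ca, Cb = Cb, eps_a = eps_a, eps_b = eps_b,
                  fa = occ$fa, fb = occ$fb,
                  Pa = Ca %*% (occ$fa * t(Ca)), Pb = Cb %*% (occ$fb * t(Cb))))
    }
  }
  X <- .sqrt_inv(engine$S)$X
  e <- eigen(t(X) %*% engine$H0 %*% X, symmetric = TRUE)
  C <- X %*% e$vectors
  occ <- .resolve_occupations(settings, e$values, e$values, Na, Nb)
  list(Ca = C, Cb = C, eps_a = e$values, eps_b = e$values,
       fa = occ$fa, fb = occ$fb,
       Pa = C %*% (occ$fa * t(C)), Pb = C %*% (occ$fb * t(C)))
}

.density <- function(C, f) C %*% (f * t(C))

# ---------------------------------------------------------------------------
# DIIS

.diis_solve <- function(hist) {
  # returns extrapolated Fock matrices; prunes ill-conditioned systems
  while (TRUE) {
    m <- length(hist)
    if (m == 1) return(list(Fa = hist[[1]]$Fa, Fb = hist[[1]]$Fb, hist = hist))
    B <- matrix(0, m + 1, m + 1)
    for (i in seq_len(m)) for (j in i:m) {
      B[i, j] <- B[j, i] <- sum(hist[[i]]$err * hist[[j]]$err)
    }
    B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- 1
    rhs <- c(numeric(m), 1)
    sol <- tryCatch({
      if (rcond(B) < 1e-14) stop("ill-conditioned")
      solve(B, rhs)
    }, error = function(e) NULL)
    if (is.null(sol)) { hist <- hist[-1]; next }
    cf <- sol[seq_len(m)]
    Fa <- Reduce(`+`, Map(function(h, c) c * h$Fa, hist, cf))
    Fb <- Reduce(`+`, Map(function(h, c) c * h$Fb, hist, cf))
    return(list(Fa = Fa, Fb = Fb, hist = hist))
  }
}

#' One DIIS extrapolation step
#'
#' Solves the standard DIIS least-squares system with the constraint that the
#' coefficients sum to one, pruning the oldest entries when the system becomes
#' ill-conditioned.  Exposed for testing; [scf_solve()] drives it internally.
#'
#' @param history List of entries `list(Fa, Fb, err)` (error = orthonormalized
#'   `FPS - SPF`).
#' @return List with extrapolated `Fa`, `Fb` and the (possibly pruned)
#'   history.
#' @export
diis_step <- function(history) {
  if (length(history) < 1) stop("DIIS needs at least one history entry")
  .diis_solve(history)
}

# ---------------------------------------------------------------------------
# main driver

#' Solve the self-consistent field
#'
#' Converges the spin-polarized tight-binding equations for a structure (or a
#' prebuilt engine) with the selected driver and returns a classed result with
#' the term-resolved energy breakdown.
#'
#' @param x A `tb_structure` or a `tb_engine`.
#' @param params A `tb_parameters` object (ignored when `x` is an engine).
#' @param settings A `tb_scf_settings`.
#' @param uvariant,terms Passed to [build_engine()] when `x` is a structure.
#' @return An object of class `tb_scf` with components `converged`, `niter`,
#'   `energy` (named breakdown including `E_Fermi` and the total), `eps`,
#'   `occ`, `C`, `Pa`, `Pb`, `mu`, `trace` and the engine used.
#' @export
scf_solve <- function(x, params = load_parameters(), settings = scf_settings(),
                      uvariant = "none", terms = c("scc2", "scc3", "aes", "axc", "spin")) {
  engine <- if (inherits(x, "tb_engine")) x
            else build_engine(x, params, uvariant = uvariant, terms = terms)
  res <- switch(settings$solver,
                diis  = .scf_diis(engine, settings, use_diis = TRUE),
                fixed = .scf_fixed(engine, settings),
                gdm   = .scf_gdm(engine, settings))
  res$engine <- engine
  res$settings <- settings
  class(res) <- "tb_scf"
  res
}

.finish_state <- function(engine, settings, converged, niter, fb, E_fermi,
                          Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, solver) {
  en <- unlist(fb$terms)
  en["E_Fermi"] <- E_fermi
  en["E_tot"] <- sum(en[names(en) != "E_tot"])
  list(converged = converged, niter = niter, energy = en,
       eps = list(alpha = eps_a, beta = eps_b),
       occ = list(alpha = fa, beta = fbocc),
       C = list(alpha = Ca, beta = Cb),
       Pa = .density(Ca, fa), Pb = .density(Cb, fbocc),
       mu = mu, trace = trace, solver = solver)
}

.scf_diis <- function(engine, settings, use_diis = TRUE) {
  X <- .sqrt_inv(engine$S)$X
  S <- engine$S
  g <- initial_guess(engine, settings)
  Na <- settings$n_alpha %||% engine$n_alpha
  Nb <- settings$n_beta %||% engine$n_beta
  Pa <- g$Pa; Pb <- g$Pb
  Ca <- g$Ca; Cb <- g$Cb; fa <- g$fa; fbocc <- g$fb
  eps_a <- g$eps_a; eps_b <- g$eps_b
  occ <- .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
  E_prev <- NA; hist <- list()
  tr_E <- tr_dE <- tr_err <- numeric(0)
  E_fermi <- 0; mu <- c(NA, NA)
  for (it in seq_len(settings$max_iter)) {
    fb <- fock_build(engine, Pa, Pb)
    E_fermi <- occ$E_fermi
    E <- sum(unlist(fb$terms)) + E_fermi
    erra <- t(X) %*% (fb$Fa %*% Pa %*% S - S %*% Pa %*% fb$Fa) %*% X
    errb <- t(X) %*% (fb$Fb %*% Pb %*% S - S %*% Pb %*% fb$Fb) %*% X
    err <- max(abs(c(erra, errb)))
    dE <- if (is.na(E_prev)) NA else E - E_prev
    tr_E <- c(tr_E, E); tr_dE <- c(tr_dE, dE); tr_err <- c(tr_err, err)
    if (settings$verbose)
      message(sprintf("iter %3d  E = %.10f  dE = %10.3e  err = %10.3e", it, E, dE, err))
    if (!is.na(dE) && abs(dE) < settings$conv_e && err < settings$conv_err) {
      trace <- data.frame(iter = seq_along(tr_E), E = tr_E, dE = tr_dE, err = tr_err)
      return(.finish_state(engine, settings, TRUE, it, fb, E_fermi,
                           Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, "diis"))
    }
    E_prev <- E
    Fa_use <- fb$Fa; Fb_use <- fb$Fb
    if (use_diis) {
      hist[[length(hist) + 1]] <- list(Fa = fb$Fa, Fb = fb$Fb, err = c(erra, errb))
      if (length(hist) > settings$diis_n) hist <- hist[-1]
      ex <- .diis_solve(hist)
      hist <- ex$hist
      Fa_use <- ex$Fa; Fb_use <- ex$Fb
    }
    ea <- eigen(t(X) %*% Fa_use %*% X, symmetric = TRUE)
    eb <- eigen(t(X) %*% Fb_use %*% X, symmetric = TRUE)
    Ca <- X %*% ea$vectors; Cb <- X %*% eb$vectors
    eps_a <- ea$values; eps_b <- eb$values
    occ <- .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
    fa <- occ$fa; fbocc <- occ$fb; mu <- occ$mu
    Pa <- .density(Ca, fa); Pb <- .density(Cb, fbocc)
  }
  fbk <- fock_build(engine, Pa, Pb)
  trace <- data.frame(iter = seq_along(tr_E), E = tr_E, dE = tr_dE, err = tr_err)
  .finish_state(engine, settings, FALSE, settings$max_iter, fbk, E_fermi,
                Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, "diis")
}

.scf_fixed <- function(engine, settings) {
  X <- .sqrt_inv(engine$S)$X
  g <- initial_guess(engine, settings)
  Na <- settings$n_alpha %||% engine$n_alpha
  Nb <- settings$n_beta %||% engine$n_beta
  Pa <- g$Pa; Pb <- g$Pb
  Ca <- g$Ca; Cb <- g$Cb; fa <- g$fa; fbocc <- g$fb
  eps_a <- g$eps_a; eps_b <- g$eps_b
  E_prev <- NA; trace <- data.frame(); E_fermi <- 0; mu <- c(NA, NA)
  lam <- settings$damping
  for (it in seq_len(settings$max_iter)) {
    fb <- fock_build(engine, Pa, Pb)
    occf <- .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
    E_fermi <- occf$E_fermi
    E <- sum(unlist(fb$terms)) + E_fermi
    erra <- fb$Fa %*% Pa %*% engine$S - engine$S %*% Pa %*% fb$Fa
    err <- max(abs(erra))
    dE <- if (is.na(E_prev)) NA else E - E_prev
    trace <- rbind(trace, data.frame(iter = it, E = E, dE = dE, err = err))
    if (!is.na(dE) && abs(dE) < settings$conv_e && err < settings$conv_err)
      return(.finish_state(engine, settings, TRUE, it, fb, E_fermi,
                           Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, "fixed"))
    E_prev <- E
    ea <- eigen(t(X) %*% fb$Fa %*% X, symmetric = TRUE)
    eb <- eigen(t(X) %*% fb$Fb %*% X, symmetric = TRUE)
    Ca <- X %*% ea$vectors; Cb <- X %*% eb$vectors
    eps_a <- ea$values; eps_b <- eb$values
    occ <- .resolve_occupations(settings, eps_a, eps_b, Na, Nb)
    fa <- occ$fa; fbocc <- occ$fb; mu <- occ$mu
    Pa <- (1 - lam) * Pa + lam * .density(Ca, fa)
    Pb <- (1 - lam) * Pb + lam * .density(Cb, fbocc)
  }
  fbk <- fock_build(engine, Pa, Pb)
  .finish_state(engine, settings, FALSE, settings$max_iter, fbk, E_fermi,
                Ca, Cb, eps_a, eps_b, fa, fbocc, mu, trace, "fixed")
}
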