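# Pluggable toy model Hamiltonians implementing the engine interface, used as
# oracle substrates for the SCF and analysis layers: closed-form reference
# energies are available for each of them.

#' Construct a model Hamiltonian engine
#'
#' Three kinds are available:
#' * `"two-level"`: two orbitals with fixed level energies (default -1, +1),
#'   no interactions; the ground state energy is the occupation-weighted level
#'   sum, in closed form.
#' * `"hubbard-dimer"`: two sites with hopping `t` and on-site levels `e1`,
#'   `e2`; one electron, so the self-consistent solution coincides with exact
#'   diagonalization of the 2x2 one-particle Hamiltonian.  A shell-resolved
#'   Hubbard `U` can be switched on to exercise the +U machinery.
#' * `"linear-in-N"`: `norb` fixed levels with no interaction, so the total
#'   energy is exactly linear in the (possibly fractional) electron count and
#'   fractional-charge scans have zero deviation from linearity by
#'   construction.
#'
#' @param kind Model kind.
#' @param n_alpha,n_beta Channel electron counts.
#' @param levels Orbital energies (model-dependent defaults).
#' @param t Hopping matrix element (hubbard-dimer).
#' @param U Hubbard U applied per site/shell (hubbard-dimer; default 0).
#' @param uvariant Hubbard variant for the model.
#' @param quadratic Optional quadratic coefficient `a`: adds `a * (N - N0)^2`
#'   style charge curvature through a diagonal second-order kernel, used by
#'   the linear-response oracle tests.
#' @return A `tb_engine`-compatible object of class `tb_model_engine`.
#' @export
make_model_hamiltonian <- function(kind = c("two-level", "hubbard-dimer", "linear-in-N"),
                                   n_alpha = 1, n_beta = 0, levels = NULL,
                                   t = -0.5, U = 0, uvariant = "none",
                                   quadratic = 0) {
  kind <- match.arg(kind)
  if (kind == "two-level") {
    lev <- levels %||% c(-1, 1)
    H0 <- diag(lev)
  } else if (kind == "hubbard-dimer") {
    lev <- levels %||% c(-0.2, 0.2)
    H0 <- matrix(c(lev[1], t, t, lev[2]), 2, 2)
  } else {
    lev <- levels %||% c(-1.0, -0.5, 0.0, 0.5)
    H0 <- diag(lev)
  }
  nao <- nrow(H0)
  basis <- data.frame(shell = seq_len(nao), atom = seq_len(nao),
                      element = "X", shell_idx = 1L, label = "1s",
                      l = 0L, n = 1L, deg = 1L,
                      ao_start = seq_len(nao), ao_end = seq_len(nao),
                      refocc = 0)
  attr(basis, "nao") <- nao
  class(basis) <- c("tb_basis", class(basis))
  eng <- list(kind = paste0("model:", kind), nao = nao, S = diag(nao), H0 = H0,
              E_rep = 0, basis = basis, ao_shell = seq_len(nao),
              ao_atom = seq_len(nao), n0 = rep(0, nao),
              U = rep(U, nao), alpha = 0.5, uvariant = uvariant,
              quadratic = quadratic,
              n_alpha = n_alpha, n_beta = n_beta, nelec = n_alpha + n_beta)
  class(eng) <- c("tb_model_engine", "tb_engine")
  eng
}

#' @export
fock_build.tb_model_engine <- function(engine, Pa, Pb) {
  E <- list(E_rep = 0, E_EHT = sum((Pa + Pb) * engine$H0), E_IES = 0,
            E_IXC = 0, E_AES = 0, E_AXC = 0, E_spin = 0, E_U = 0)
  Fa <- engine$H0; Fb <- engine$H0
  if (engine$quadratic != 0) {
    # diagonal charge-curvature kernel: E = a * sum_i n_i^2
    na <- diag(Pa); nb <- diag(Pb)
    n <- na + nb
    E$E_IES <- engine$quadratic * sum(n^2)
    Fq <- diag(2 * engine$quadratic * n, engine$nao)
    Fa <- Fa + Fq; Fb <- Fb + Fq
  }
  if (engine$uvariant != "none" && any(engine$U > 0)) {
    hu <- .hubbard_contribution(engine, Pa, Pb)
    E$E_U <- hu$energy
    Fa <- Fa + hu$Fa; Fb <- Fb + hu$Fb
  }
  list(Fa = Fa, Fb = Fb, terms = E)
}
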