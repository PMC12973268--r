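# S3 methods for the classed result objects.

#' @export
print.tb_scf <- function(x, ...) {
  cat(sprintf("<tb_scf> %s solver: %s after %d iterations\n",
              x$solver, if (x$converged) "converged" else "NOT converged", x$niter))
  cat(sprintf("  E(total) = %.8f Hartree\n", x$energy[["E_tot"]]))
  invisible(x)
}

#' @export
summary.tb_scf <- function(object, ...) {
  cat(sprintf("Self-consistent field summary (%s solver)\n", object$solver))
  cat(sprintf("  converged : %s in %d iterations\n", object$converged, object$niter))
  cat("  energy breakdown (Hartree):\n")
  for (nm in names(object$energy))
    cat(sprintf("    %-8s %16.8f\n", nm, object$energy[[nm]]))
  gp <- tryCatch(homo_lumo_gap(object), error = function(e) NULL)
  if (!is.null(gp))
    cat(sprintf("  HOMO-LUMO gap: %.6f Hartree (alpha %.6f, beta %.6f)\n",
                gp$gap, gp$alpha, gp$beta))
  invisible(object)
}

#' @export
coef.tb_scf <- function(object, ...) object$C

#' Energy breakdown accessor
#'
#' @param object A `tb_scf` result.
#' @param ... Unused.
#' @return Named numeric vector of the term-resolved energies (Hartree).
#' @export
energy_breakdown <- function(object, ...) {
  stopifnot(inherits(object, "tb_scf"))
  object$energy
}

#' @export
print.tb_engine <- function(x, ...) {
  cat(sprintf("<tb_engine> %s: %d AOs, %g alpha / %g beta electrons, +U variant '%s'\n",
              x$kind, x$nao, x$n_alpha, x$n_beta, x$uvariant))
  invisible(x)
}

#' @export
print.tb_parameters <- function(x, ...) {
  cat(sprintf("<tb_parameters> %d elements: %s (alpha = %g)\n",
              length(x$elements), paste(names(x$elements), collapse = ", "),
              x$global$alpha))
  invisible(x)
}
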