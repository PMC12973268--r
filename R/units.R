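# Physical constants and unit conversions.  Lengths are Bohr internally and
# Angstrom at all user-facing interfaces; energies are Hartree throughout.

#' Unit conversion constants
#'
#' Named constants used throughout the package: `bohr_per_angstrom`,
#' `ev_per_hartree`, `kcalmol_per_hartree` and the Boltzmann constant
#' `kB_hartree_per_K`.
#'
#' @format A named numeric vector.
#' @export
tb_units <- c(
  bohr_per_angstrom   = 1 / 0.529177210903,
  angstrom_per_bohr   = 0.529177210903,
  ev_per_hartree      = 27.211386245988,
  kcalmol_per_hartree = 627.5095,
  kB_hartree_per_K    = 3.166811563e-6
)

ang2bohr <- function(x) x * tb_units[["bohr_per_angstrom"]]
bohr2ang <- function(x) x * tb_units[["angstrom_per_bohr"]]
ev2ha <- function(x) x / tb_units[["ev_per_hartree"]]
ha2kcal <- function(x) x * tb_units[["kcalmol_per_hartree"]]
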