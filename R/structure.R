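# Molecular structures: element symbols + Cartesian coordinates (Angstrom at
# the interface, Bohr internally), total charge and spin-channel electron
# counts.  Multiplicity maps to channels via n_alpha - n_beta = mult - 1.

.element_symbols <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                      "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
                      "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn")

.normalize_symbol <- function(x) {
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  if (!all(x %in% .element_symbols))
    stop("unknown element symbol(s): ", paste(setdiff(x, .element_symbols), collapse = ", "))
  x
}

#' Construct a molecular structure
#'
#' @param elements Character vector of element symbols.
#' @param coords_ang N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param charge Integer total charge.
#' @param multiplicity Spin multiplicity 2S+1; it must be consistent with the
#'   parity of the electron count.  Valence electron counts are resolved when
#'   the structure is combined with a parameter set; here only the bookkeeping
#'   fields are stored.
#' @return An object of class `tb_structure`.
#' @export
atomic_structure <- function(elements, coords_ang, charge = 0L, multiplicity = 1L) {
  coords_ang <- matrix(as.numeric(coords_ang), ncol = 3)
  if (length(elements) < 1) stop("structure needs at least one atom")
  if (nrow(coords_ang) != length(elements))
    stop("coordinate rows (", nrow(coords_ang), ") do not match atom count (", length(elements), ")")
  if (!all(is.finite(coords_ang))) stop("coordinates must be finite")
  structure(list(elements = .normalize_symbol(elements),
                 coords_ang = coords_ang,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "tb_structure")
}

#' @export
print.tb_structure <- function(x, ...) {
  cat(sprintf("<tb_structure> %d atoms, charge %+d, multiplicity %d\n",
              length(x$elements), x$charge, x$multiplicity))
  invisible(x)
}

# Resolve per-channel electron counts from valence electrons, charge and
# multiplicity.  Kept separate from atomic_structure() because the valence
# electron count is a property of the parameter set.
electron_counts <- function(structure, params) {
  nval <- sum(vapply(structure$elements, function(el) {
    e <- params$elements[[el]]
    if (is.null(e)) stop("unsupported element: ", el, " (not in parameter set)")
    sum(e$refocc)
  }, 0))
  nelec <- nval - structure$charge
  if (nelec < 0) stop("negative electron count")
  d <- structure$multiplicity - 1L
  if ((nelec - d) %% 2 != 0 || d > nelec)
    stop(sprintf("multiplicity %d inconsistent with %d electrons",
                 structure$multiplicity, nelec))
  n_beta <- (nelec - d) / 2
  list(n_alpha = n_beta + d, n_beta = n_beta, nelec = nelec)
}

#' Read a molecular structure from an XYZ file
#'
#' Standard XYZ: first line atom count, second line a comment which may carry
#' `charge=<int>` and `multiplicity=<int>` tokens, then one `El x y z` line per
#' atom (Angstrom).
#'
#' @param path Path to the XYZ file.
#' @param charge,multiplicity Optional overrides of the comment-line tokens.
#' @return A `tb_structure`.
#' @export
read_xyz <- function(path, charge = NULL, multiplicity = NULL) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("parse error at line 1: truncated XYZ file")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("parse error at line 1: expected an atom count, got '", lines[1], "'")
  if (length(lines) < 2 + nat)
    stop("parse error at line 1: header declares ", nat, " atoms but file has ",
         max(0, length(lines) - 2), " atom lines")
  comment <- lines[2]
  tok <- function(key) {
    m <- regmatches(comment, regexec(paste0(key, "\\s*=\\s*(-?[0-9]+)"), comment))[[1]]
    if (length(m) == 2) as.integer(m[2]) else NULL
  }
  charge <- charge %||% tok("charge") %||% 0L
  multiplicity <- multiplicity %||% tok("multiplicity") %||% NULL
  el <- character(nat); xyz <- matrix(0, nat, 3)
  for (i in seq_len(nat)) {
    parts <- strsplit(trimws(lines[2 + i]), "\\s+")[[1]]
    if (length(parts) < 4)
      stop("parse error at line ", 2 + i, ": expected 'El x y z'")
    el[i] <- parts[1]
    xyz[i, ] <- as.numeric(parts[2:4])
  }
  if (is.null(multiplicity)) multiplicity <- 1L  # resolved against parity at solve time
  atomic_structure(el, xyz, charge, multiplicity)
}

#' Write a molecular structure to an XYZ file
#'
#' @param structure A `tb_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  out <- c(sprintf("%d", length(structure$elements)),
           sprintf("charge=%d multiplicity=%d", structure$charge, structure$multiplicity),
           sprintf("%-2s %18.12f %18.12f %18.12f", structure$elements,
                   structure$coords_ang[, 1], structure$coords_ang[, 2],
                   structure$coords_ang[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' Build the shell-resolved minimal basis for a structure
#'
#' Shell ordering is fixed: atoms in input order, shells per atom in the order
#' of the parameter file (which lists them by increasing principal quantum
#' number/valence convention), atomic orbitals within a shell in m = -l..+l
#' order.  The AO count is the sum of shell degeneracies 2l+1.
#'
#' @param structure A `tb_structure`.
#' @param params A `tb_parameters` object covering every element present.
#' @return An object of class `tb_basis`: a data frame of shells with AO index
#'   ranges plus attributes `nao` and per-shell metadata.
#' @export
build_basis <- function(structure, params) {
  rows <- list(); ao <- 0L; ish <- 0L
  for (a in seq_along(structure$elements)) {
    el <- structure$elements[a]
    e <- params$elements[[el]]
    if (is.null(e)) stop("unsupported element: ", el, " (not in parameter set)")
    ord <- order(e$l)  # increasing angular momentum within the atom
    for (s in ord) {
      ish <- ish + 1L
      deg <- 2L * e$l[s] + 1L
      rows[[ish]] <- data.frame(shell = ish, atom = a, element = el,
                                shell_idx = s, label = e$shells[s],
                                l = e$l[s], n = e$n[s], deg = deg,
                                ao_start = ao + 1L, ao_end = ao + deg,
                                refocc = e$refocc[s],
                                stringsAsFactors = FALSE)
      ao <- ao + deg
    }
  }
  basis <- do.call(rbind, rows)
  attr(basis, "nao") <- ao
  class(basis) <- c("tb_basis", class(basis))
  basis
}
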