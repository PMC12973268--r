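# Deterministic structure generators: every test system is built in code so
# the package is fully self-contained (no downloads, no external geometries).

#' Lithium fluoride diatomic
#'
#' Li at the origin, F on +z at the requested bond length; neutral singlet.
#'
#' @param bond_length_ang Bond length in Angstrom.
#' @return A `tb_structure`.
#' @export
make_lif <- function(bond_length_ang) {
  stopifnot(bond_length_ang > 0)
  atomic_structure(c("Li", "F"),
                   rbind(c(0, 0, 0), c(0, 0, bond_length_ang)),
                   charge = 0L, multiplicity = 1L)
}

#' Octahedral hexammine complex
#'
#' Ideal octahedron of NH3 ligands around a metal centre, nitrogen lone pairs
#' pointing at the metal.  The internal ammonia geometry is fixed (N-H
#' 1.012 Angstrom, H-N-H 106.7 degrees) and documented; it supports property
#' tests (monotone trends in U, spin gaps), never value matching.
#'
#' @param metal Element symbol of the centre (default `"Fe"`).
#' @param charge Total charge of the complex.
#' @param multiplicity Spin multiplicity.
#' @param distance_ang Metal-nitrogen distance in Angstrom.
#' @return A `tb_structure` with 25 atoms.
#' @export
make_hexammine <- function(metal = "Fe", charge = 3L, multiplicity = 6L,
                           distance_ang = 2.2) {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nh <- 1.012
  hnh <- 106.7 * pi / 180
  # local ammonia frame: N at origin, lone pair along -z (toward the metal at
  # -z), three H above forming the umbrella
  cosb <- cos(hnh)
  # angle theta of N-H bonds from +z axis: cos(hnh) = cos^2(t)+sin^2(t)*cos(120)
  cost2 <- (2 * cosb + 1) / 3
  theta <- acos(sqrt(max(cost2, 0)))
  hloc <- t(vapply(0:2, function(k) {
    phi <- 2 * pi * k / 3
    nh * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }, numeric(3)))
  elements <- metal
  coords <- matrix(0, 1, 3)
  for (i in 1:6) {
    z <- axes[i, ]                       # metal -> N direction
    # orthonormal frame (u, v, z)
    u <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * z) * z; u <- u / sqrt(sum(u^2))
    v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
    Np <- distance_ang * z
    elements <- c(elements, "N")
    coords <- rbind(coords, Np)
    for (k in 1:3) {
      # local +z maps to the outward direction z
      hl <- hloc[k, ]
      hp <- Np + hl[1] * u + hl[2] * v + hl[3] * z
      elements <- c(elements, "H")
      coords <- rbind(coords, hp)
    }
  }
  atomic_structure(elements, coords, charge = charge, multiplicity = multiplicity)
}

#' Randomized small closed-shell molecules
#'
#' Deterministic (seeded) generator of small closed-shell main-group molecules
#' with mildly perturbed standard geometries; used by the solver-equivalence
#' and variational-consistency property tests.
#'
#' @param i Index of the base molecule (recycled).
#' @param seed Seed controlling the geometric perturbation.
#' @param scale Perturbation amplitude in Angstrom.
#' @return A `tb_structure`.
#' @export
make_random_molecule <- function(i, seed = 42, scale = 0.04) {
  base <- list(
    list(el = c("O", "H", "H"),
         xyz = rbind(c(0, 0, 0.117), c(0, 0.757, -0.469), c(0, -0.757, -0.469))),
    list(el = c("N", "H", "H", "H"),
         xyz = rbind(c(0, 0, 0.065), c(0, 0.94, -0.3), c(0.82, -0.47, -0.3),
                     c(-0.82, -0.47, -0.3))),
    list(el = c("C", "H", "H", "H", "H"),
         xyz = rbind(c(0, 0, 0), c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
                     c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63))),
    list(el = c("H", "F"), xyz = rbind(c(0, 0, 0), c(0, 0, 0.92))),
    list(el = c("Li", "H"), xyz = rbind(c(0, 0, 0), c(0, 0, 1.6))),
    list(el = c("C", "O"), xyz = rbind(c(0, 0, 0), c(0, 0, 1.13))),
    list(el = c("H", "H"), xyz = rbind(c(0, 0, 0), c(0, 0, 0.74))),
    list(el = c("Li", "F"), xyz = rbind(c(0, 0, 0), c(0, 0, 1.58))),
    list(el = c("F", "H", "F"), xyz = rbind(c(0, 0, -1.15), c(0, 0, 0), c(0, 0, 1.15))),
    list(el = c("O", "C", "O"), xyz = rbind(c(0, 0, -1.16), c(0, 0, 0), c(0, 0, 1.16))))
  b <- base[[(i - 1) %% length(base) + 1]]
  set.seed(seed + i)
  pert <- matrix(stats::rnorm(length(b$el) * 3, sd = scale), ncol = 3)
  chg <- if ((i - 1) %% length(base) + 1 == 9) -1L else 0L  # bifluoride anion
  atomic_structure(b$el, b$xyz + pert, charge = chg, multiplicity = 1L)
}

#' Write fixture structures as XYZ files
#'
#' @param name One of `"lif"`, `"hexammine"`.
#' @param out_dir Output directory.
#' @param ... Passed to the generator.
#' @return The written path(s), invisibly.
#' @export
write_fixture <- function(name = c("lif", "hexammine"), out_dir = ".", ...) {
  name <- match.arg(name)
  s <- switch(name, lif = make_lif(...), hexammine = make_hexammine(...))
  path <- file.path(out_dir, paste0(name, ".xyz"))
  write_xyz(s, path)
  invisible(path)
}
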