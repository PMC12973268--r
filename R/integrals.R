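# One-electron integrals over contracted-Gaussian expansions of Slater-type
# orbitals: overlap, dipole and second-moment (quadrupole) integrals.
# Internally everything is Bohr.  AO ordering within a shell is m = -l..+l,
# i.e. p: (y, z, x) and d: (xy, yz, z2, xz, x2-y2); cartesian intermediates
# use the order x,y,z and xx,yy,zz,xy,xz,yz.

.cart_monomials <- list(
  matrix(c(0L, 0L, 0L), 1, 3),
  rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
  rbind(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
        c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L)))

# cartesian -> real spherical transforms (rows: m = -l..+l)
.sph_transform <- list(
  matrix(1, 1, 1),
  rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
  rbind(c(0, 0, 0, 1, 0, 0),
        c(0, 0, 0, 0, 0, 1),
        c(-0.5 / sqrt(3), -0.5 / sqrt(3), 1 / sqrt(3), 0, 0, 0),
        c(0, 0, 0, 0, 1, 0),
        c(0.5, -0.5, 0, 0, 0, 0)))

# normalization of the reference cartesian primitive per l (s; x; xy-type)
.cart_norm <- function(l, alpha) {
  switch(l + 1L,
         (2 * alpha / pi)^0.75,
         (2 * alpha / pi)^0.75 * 2 * sqrt(alpha),
         (2 * alpha / pi)^0.75 * 4 * alpha)
}

.sto_expansion <- function(n, l, ngauss, zeta) {
  key <- sprintf("n%dl%dg%d", n, l, ngauss)
  tab <- .sto_ng_table[[key]]
  if (is.null(tab)) stop("no STO-nG table for ", key)
  list(alpha = tab$alpha * zeta^2, coef = tab$coef)
}

# 1D Hermite/OS overlap table S[i+1, j+1] for i <= imax, j <= jmax
.os_1d <- function(a, b, A, B, imax, jmax) {
  p <- a + b
  P <- (a * A + b * B) / p
  S <- matrix(0, imax + 1, jmax + 1)
  S[1, 1] <- sqrt(pi / p) * exp(-a * b / p * (A - B)^2)
  for (i in 0:imax) for (j in 0:jmax) {
    if (i == 0 && j == 0) next
    if (i > 0) {
      v <- (P - A) * S[i, j + 1]
      if (i > 1) v <- v + (i - 1) / (2 * p) * S[i - 1, j + 1]
      if (j > 0) v <- v + j / (2 * p) * S[i, j]
      S[i + 1, j + 1] <- v
    } else {
      v <- (P - B) * S[1, j]
      if (j > 1) v <- v + (j - 1) / (2 * p) * S[1, j - 1]
      S[1, j + 1] <- v
    }
  }
  S
}

# Overlap, dipole and second-moment blocks between two contracted shells.
# Moments are taken relative to the center of the first (bra) shell.
.shell_pair_ints <- function(l1, l2, exp1, exp2, R1, R2) {
  c1 <- .cart_monomials[[l1 + 1]]; c2 <- .cart_monomials[[l2 + 1]]
  n1 <- nrow(c1); n2 <- nrow(c2)
  Sc <- matrix(0, n1, n2)
  Dc <- array(0, c(n1, n2, 3))
  Qc <- array(0, c(n1, n2, 6))
  qpairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (ip in seq_along(exp1$alpha)) for (jp in seq_along(exp2$alpha)) {
    a <- exp1$alpha[ip]; b <- exp2$alpha[jp]
    mu <- a * b / (a + b)
    r2 <- sum((R1 - R2)^2)
    if (mu * r2 > 46) next
    cc <- exp1$coef[ip] * exp2$coef[jp] * .cart_norm(l1, a) * .cart_norm(l2, b)
    sx <- lapply(1:3, function(d) .os_1d(a, b, R1[d], R2[d], l1 + 2, l2))
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      e1 <- c1[i, ]; e2 <- c2[j, ]
      s3 <- c(sx[[1]][e1[1] + 1, e2[1] + 1],
              sx[[2]][e1[2] + 1, e2[2] + 1],
              sx[[3]][e1[3] + 1, e2[3] + 1])
      Sc[i, j] <- Sc[i, j] + cc * prod(s3)
      for (d in 1:3) {
        m1 <- sx[[d]][e1[d] + 2, e2[d] + 1]   # one power of (x - A) extra
        Dc[i, j, d] <- Dc[i, j, d] + cc * m1 * prod(s3[-d])
      }
      for (k in 1:6) {
        d1 <- qpairs[k, 1]; d2 <- qpairs[k, 2]
        if (d1 == d2) {
          m2 <- sx[[d1]][e1[d1] + 3, e2[d1] + 1]
          Qc[i, j, k] <- Qc[i, j, k] + cc * m2 * prod(s3[-d1])
        } else {
          m1a <- sx[[d1]][e1[d1] + 2, e2[d1] + 1]
          m1b <- sx[[d2]][e1[d2] + 2, e2[d2] + 1]
          d3 <- setdiff(1:3, c(d1, d2))
          Qc[i, j, k] <- Qc[i, j, k] + cc * m1a * m1b * s3[d3]
        }
      }
    }
  }
  T1 <- .sph_transform[[l1 + 1]]; T2 <- .sph_transform[[l2 + 1]]
  out_S <- T1 %*% Sc %*% t(T2)
  out_D <- array(0, c(nrow(T1), nrow(T2), 3))
  out_Q <- array(0, c(nrow(T1), nrow(T2), 6))
  for (d in 1:3) out_D[, , d] <- T1 %*% Dc[, , d] %*% t(T2)
  for (k in 1:6) out_Q[, , k] <- T1 %*% Qc[, , k] %*% t(T2)
  list(S = out_S, D = out_D, Q = out_Q)
}

#' Compute overlap and multipole-moment integrals
#'
#' Builds the AO overlap matrix plus dipole and second-moment integral tensors
#' for a structure/basis pair.  Moment integrals for row index mu are taken
#' relative to the nucleus that hosts mu, which is the convention the
#' cumulative atomic multipole moments of the anisotropic electrostics expect.
#'
#' @param structure A `tb_structure`.
#' @param params A `tb_parameters` object.
#' @param basis The `tb_basis` from [build_basis()].
#' @param cond_threshold Condition-number threshold above which a diagnostic
#'   error is raised for a near-singular overlap.
#' @return List with `S` (nao x nao), `D` (nao x nao x 3), `Q` (nao x nao x 6,
#'   second moments in the order xx,yy,zz,xy,xz,yz) and `coords_bohr`.
#' @export
compute_integrals <- function(structure, params, basis, cond_threshold = 1e10) {
  nao <- attr(basis, "nao")
  xyz <- ang2bohr(structure$coords_ang)
  nsh <- nrow(basis)
  expn <- vector("list", nsh)
  for (s in seq_len(nsh)) {
    e <- params$elements[[basis$element[s]]]
    k <- basis$shell_idx[s]
    expn[[s]] <- .sto_expansion(e$n[k], e$l[k], e$ngauss[k], e$slater[k])
  }
  S <- matrix(0, nao, nao)
  D <- array(0, c(nao, nao, 3))
  Q <- array(0, c(nao, nao, 6))
  for (s1 in seq_len(nsh)) for (s2 in seq_len(nsh)) {
    i1 <- basis$ao_start[s1]:basis$ao_end[s1]
    i2 <- basis$ao_start[s2]:basis$ao_end[s2]
    pr <- .shell_pair_ints(basis$l[s1], basis$l[s2], expn[[s1]], expn[[s2]],
                           xyz[basis$atom[s1], ], xyz[basis$atom[s2], ])
    S[i1, i2] <- pr$S
    D[i1, i2, ] <- pr$D
    Q[i1, i2, ] <- pr$Q
  }
  # exact AO normalization (removes residual contraction-normalization error)
  z <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(z)
  for (d in 1:3) D[, , d] <- D[, , d] * tcrossprod(z)
  for (k in 1:6) Q[, , k] <- Q[, , k] * tcrossprod(z)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_threshold)
    stop(sprintf("near-singular overlap matrix (condition number %.3g)",
                 max(ev) / max(min(ev), .Machine$double.eps)))
  list(S = S, D = D, Q = Q, coords_bohr = xyz)
}
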