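# Derive STO-nG expansions: least-squares/maximum-overlap fits of a normalized
# Slater radial function r^(n-1) exp(-r) (zeta = 1) by n primitive Gaussians of
# angular momentum l.  Exponents are scaled by zeta^2 at use time.  The fits are
# deterministic; results are frozen into R/sto-ng-tables.R as plain source.
# Run from the package root: Rscript data-raw/fit_sto_ng.R

## radial quadrature grid (Gauss-Legendre on [0, rmax] via statmod-free recursion)
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

sto_radial <- function(r, n) {
  nrm <- 2^(n + 0.5) / sqrt(factorial(2 * n))
  nrm * r^(n - 1) * exp(-r)
}

gto_radial <- function(r, l, alpha) {
  nrm <- sqrt(2 * (2 * alpha)^(l + 1.5) / gamma(l + 1.5))
  nrm * r^l * exp(-alpha * r^2)
}

fit_sto_ng <- function(n, l, ng) {
  q <- gauss_legendre(600, 0, 45)
  r <- q$x; w <- q$w * r^2
  sto <- sto_radial(r, n)
  obj <- function(t) {
    a <- exp(t)
    G <- sapply(a, function(al) gto_radial(r, l, al))
    s <- as.numeric(crossprod(G, w * sto))          # <G_i|STO>
    S <- crossprod(G, w * G)                        # <G_i|G_j>
    ov <- tryCatch(sqrt(drop(t(s) %*% solve(S, s))), error = function(e) 0)
    -ov
  }
  # geometric starts spanning the STO decay scales; multi-start to avoid local optima
  spans <- list(c(0.03, 3), c(0.05, 8), c(0.06, 20), c(0.02, 60), c(0.1, 40), c(0.01, 10))
  best <- NULL
  for (sp in spans) {
    t0 <- seq(log(sp[1]), log(sp[2]), length.out = ng)
    r1 <- optim(t0, obj, method = "Nelder-Mead",
                control = list(maxit = 30000, reltol = 1e-15))
    r1 <- optim(r1$par, obj, method = "BFGS",
                control = list(maxit = 3000, reltol = 1e-14))
    if (is.null(best) || r1$value < best$value) best <- r1
  }
  a <- exp(best$par)
  G <- sapply(a, function(al) gto_radial(r, l, al))
  s <- as.numeric(crossprod(G, w * sto))
  S <- crossprod(G, w * G)
  c0 <- solve(S, s)
  c0 <- c0 / sqrt(drop(t(c0) %*% S %*% c0))        # normalized contraction
  o <- order(a, decreasing = TRUE)
  list(alpha = a[o], coef = c0[o], overlap = -best$value)
}

cases <- list(c(1, 0), c(2, 0), c(2, 1), c(3, 0), c(3, 1), c(3, 2), c(4, 0), c(4, 1))
ngs <- c(3, 4, 6)

out <- list()
for (cs in cases) for (ng in ngs) {
  f <- fit_sto_ng(cs[1], cs[2], ng)
  key <- sprintf("n%dl%dg%d", cs[1], cs[2], ng)
  out[[key]] <- f
  cat(sprintf("%s  overlap=%.8f\n", key, f$overlap))
}

con <- file("R/sto-ng-tables.R", "w")
writeLines(c(
  "# STO-nG expansion tables (zeta = 1), generated by data-raw/fit_sto_ng.R via",
  "# deterministic maximum-overlap fits.  Do not edit by hand.",
  ".sto_ng_table <- list("), con)
keys <- names(out)
for (i in seq_along(keys)) {
  f <- out[[keys[i]]]
  writeLines(sprintf("  %s = list(alpha = c(%s),\n    coef = c(%s))%s",
    keys[i],
    paste(sprintf("%.12e", f$alpha), collapse = ", "),
    paste(sprintf("%.12e", f$coef), collapse = ", "),
    if (i < length(keys)) "," else ""), con)
}
writeLines(")", con)
close(con)
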