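# Parameter workflow: spin-gap objective over a task set, Sobol
# variance-based sensitivity (Saltelli sampling, Jansen-style estimators),
# a two-stage derivative-free (Powell) + bounded quasi-Newton (L-BFGS-B)
# optimizer, and exhaustive 2-D parameter scans.

#' Define a spin-gap objective
#'
#' Bundles a set of spin-gap tasks (structure + high/low-spin multiplicities +
#' reference gap) with the free-parameter names and bounds.  Engines are
#' prebuilt once per task and reused across objective evaluations, since the
#' free parameters (spin constants `W`, Hubbard `U`) do not touch the
#' integrals or the zeroth-order Hamiltonian.
#'
#' @param tasks List of tasks `list(structure=, hs=, ls=, reference=)`.
#' @param free Character vector of free-parameter names (`"Wdd"`, `"Ud"`, ...).
#' @param bounds 2 x p matrix (rows: lower, upper) or list of c(lo, hi).
#' @param element Element whose parameters are free (default `"Fe"`).
#' @param params Base parameter set.
#' @param settings SCF settings used for every task.
#' @param uvariant Hubbard variant applied when any `U` parameter is free/set.
#' @param penalty RMSE penalty (kcal/mol) for a non-converged SCF point.
#' @param warm_start Reuse converged orbitals of the previous evaluation as
#'   the SCF guess of the next one (fast, but makes the objective depend
#'   weakly on evaluation order near state crossings; switch off when strict
#'   determinism matters more than speed).
#' @return An object of class `tb_objective_spec`.
#' @export
objective_spec <- function(tasks, free, bounds, element = "Fe",
                           params = load_parameters(),
                           settings = scf_settings(), uvariant = "psic",
                           penalty = 100, warm_start = TRUE) {
  stopifnot(length(tasks) >= 1)
  if (is.list(bounds)) bounds <- vapply(bounds, identity, numeric(2))
  bounds <- matrix(as.numeric(bounds), nrow = 2)
  stopifnot(ncol(bounds) == length(free), all(is.finite(bounds)))
  engines <- lapply(tasks, function(tk) {
    mk <- function(mult) {
      s <- tk$structure; s$multiplicity <- as.integer(mult)
      build_engine(s, params, uvariant = uvariant)
    }
    list(hs = mk(tk$hs), ls = mk(tk$ls), reference = tk$reference)
  })
  structure(list(tasks = tasks, engines = engines, free = free,
                 bounds = bounds, element = element, params = params,
                 settings = settings, uvariant = uvariant, penalty = penalty,
                 cache = if (warm_start) new.env(parent = emptyenv())),
            class = "tb_objective_spec")
}

# apply free-parameter values to a prebuilt engine (W and U only)
.apply_free <- function(engine, element, free, x) {
  lmap <- c(s = 0L, p = 1L, d = 2L)
  basis <- engine$basis
  for (k in seq_along(free)) {
    nm <- free[k]
    for (a in which(engine$structure$elements == element)) {
      sh <- which(basis$atom == a)
      ls <- basis$l[sh]
      if (grepl("^W[spd][spd]$", nm)) {
        i <- match(lmap[[substr(nm, 2, 2)]], ls)
        j <- match(lmap[[substr(nm, 3, 3)]], ls)
        if (is.na(i) || is.na(j)) stop("no shell pair for ", nm)
        engine$W[[a]][i, j] <- engine$W[[a]][j, i] <- x[k]
      } else if (grepl("^U[spd]$", nm)) {
        i <- match(lmap[[substr(nm, 2, 2)]], ls)
        if (is.na(i)) stop("no shell for ", nm)
        engine$U[sh[i]] <- x[k]
      } else stop("unknown free parameter: ", nm)
    }
  }
  engine
}

#' Evaluate the spin-gap objective
#'
#' Root-mean-square error of predicted versus reference spin gaps (kcal/mol)
#' over the task set, with non-converged points contributing the fixed
#' penalty, plus the count of correctly predicted gap signs.
#'
#' @param x Numeric vector of free-parameter values (length = number of free
#'   parameters in `spec`).
#' @param spec A `tb_objective_spec`.
#' @return List with `rmse`, `sign_correct`, `n`, `n_failed` and the per-task
#'   gaps.
#' @export
objective <- function(x, spec) {
  stopifnot(inherits(spec, "tb_objective_spec"), length(x) == length(spec$free))
  errs <- numeric(0); signs <- 0; nfail <- 0; gaps <- numeric(0)
  for (ti in seq_along(spec$engines)) {
    tk <- spec$engines[[ti]]
    e_hs <- .apply_free(tk$hs, spec$element, spec$free, x)
    e_ls <- .apply_free(tk$ls, spec$element, spec$free, x)
    st_hs <- spec$settings; st_ls <- spec$settings
    if (!is.null(spec$cache)) {   # warm starts from the previous evaluation
      st_hs$guess <- spec$cache[[paste0("hs", ti)]]
      st_ls$guess <- spec$cache[[paste0("ls", ti)]]
    }
    r_hs <- scf_solve(e_hs, settings = st_hs)
    r_ls <- scf_solve(e_ls, settings = st_ls)
    if (!is.null(spec$cache)) {
      if (r_hs$converged) spec$cache[[paste0("hs", ti)]] <- r_hs[c("C", "eps")]
      if (r_ls$converged) spec$cache[[paste0("ls", ti)]] <- r_ls[c("C", "eps")]
    }
    if (!r_hs$converged || !r_ls$converged) {
      nfail <- nfail + 1
      errs <- c(errs, spec$penalty)
      gaps <- c(gaps, NA)
      next
    }
    gap <- ha2kcal(r_hs$energy[["E_tot"]] - r_ls$energy[["E_tot"]])
    gaps <- c(gaps, gap)
    errs <- c(errs, gap - tk$reference)
    if (tk$reference != 0 && sign(gap) == sign(tk$reference)) signs <- signs + 1
  }
  if (nfail == length(spec$engines)) stop("objective error: all tasks failed to converge")
  list(rmse = sqrt(mean(errs^2)), sign_correct = signs,
       n = length(spec$engines), n_failed = nfail, gaps = gaps)
}

# ---------------------------------------------------------------------------
# Sobol sensitivity (Saltelli sampling; first-order and total indices)

#' Sobol variance-based sensitivity analysis
#'
#' Saltelli-style sampling of a scalar function over a box, with the standard
#' first-order estimator `S1_i = mean(fB * (fAB_i - fA)) / V` and the
#' Jansen total-order estimator `ST_i = mean((fA - fAB_i)^2) / (2 V)`.
#' Confidence intervals are bootstrap estimates.  Deterministic for a fixed
#' seed; base samples are seeded uniform Monte-Carlo draws.
#'
#' @param f Scalar function of a parameter vector, or a `tb_objective_spec`
#'   (in which case the RMSE is the analyzed output).
#' @param bounds 2 x p matrix (rows: lower, upper).
#' @param n_base Base sample count (a power of 2).
#' @param seed RNG seed.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @return A `tb_sensitivity`: data frame with `S1`, `S1_ci`, `ST`, `ST_ci`
#'   per parameter, plus the sample count.
#' @export
sobol_sensitivity <- function(f, bounds, n_base = 1024, seed = 42, n_boot = 200) {
  if (inherits(f, "tb_objective_spec")) {
    spec <- f
    f <- function(x) objective(x, spec)$rmse
  }
  if (is.list(bounds)) bounds <- vapply(bounds, identity, numeric(2))
  bounds <- matrix(as.numeric(bounds), nrow = 2)
  p <- ncol(bounds)
  if (abs(log2(n_base) - round(log2(n_base))) > 1e-12)
    stop("n_base must be a power of 2")
  set.seed(seed)
  scale <- function(M) sweep(sweep(M, 2, bounds[2, ] - bounds[1, ], "*"), 2, bounds[1, ], "+")
  A <- scale(matrix(stats::runif(n_base * p), n_base, p))
  B <- scale(matrix(stats::runif(n_base * p), n_base, p))
  fA <- apply(A, 1, f); fB <- apply(B, 1, f)
  fAB <- matrix(0, n_base, p)
  for (i in seq_len(p)) {
    ABi <- A; ABi[, i] <- B[, i]
    fAB[, i] <- apply(ABi, 1, f)
  }
  V <- stats::var(c(fA, fB))
  if (V < 1e-300) {
    warning("degenerate (constant) objective: all Sobol indices set to 0")
    res <- data.frame(parameter = paste0("x", seq_len(p)), S1 = 0, S1_ci = 0,
                      ST = 0, ST_ci = 0)
    return(structure(list(indices = res, n_base = n_base), class = "tb_sensitivity"))
  }
  est <- function(idx) {
    Vl <- stats::var(c(fA[idx], fB[idx]))
    s1 <- vapply(seq_len(p), function(i) mean(fB[idx] * (fAB[idx, i] - fA[idx])) / Vl, 0)
    st <- vapply(seq_len(p), function(i) mean((fA[idx] - fAB[idx, i])^2) / (2 * Vl), 0)
    c(s1, st)
  }
  full <- est(seq_len(n_base))
  boot <- replicate(n_boot, est(sample.int(n_base, replace = TRUE)))
  ci <- 1.96 * apply(boot, 1, stats::sd)
  res <- data.frame(parameter = paste0("x", seq_len(p)),
                    S1 = full[seq_len(p)], S1_ci = ci[seq_len(p)],
                    ST = full[p + seq_len(p)], ST_ci = ci[p + seq_len(p)])
  structure(list(indices = res, n_base = n_base), class = "tb_sensitivity")
}

#' @export
print.tb_sensitivity <- function(x, ...) {
  cat(sprintf("<tb_sensitivity> n_base = %d\n", x$n_base))
  print(x$indices, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# optimizers

# Powell's conjugate-direction method with a bounded Brent line search.
.powell <- function(fn, x0, lower, upper, tol = 1e-8, maxit = 60,
                    f_tol = 0, ls_tol = 1e-10) {
  p <- length(x0)
  dirs <- diag(p)
  x <- pmin(pmax(x0, lower), upper)
  fx <- fn(x)
  evals <- 1
  line_min <- function(x, d, fx) {
    # feasible step interval along d
    tmax <- Inf; tmin <- -Inf
    for (k in seq_len(p)) {
      if (d[k] > 1e-300) {
        tmax <- min(tmax, (upper[k] - x[k]) / d[k])
        tmin <- max(tmin, (lower[k] - x[k]) / d[k])
      } else if (d[k] < -1e-300) {
        tmax <- min(tmax, (lower[k] - x[k]) / d[k])
        tmin <- max(tmin, (upper[k] - x[k]) / d[k])
      }
    }
    if (!is.finite(tmax)) tmax <- 1
    if (!is.finite(tmin)) tmin <- -1
    if (tmax - tmin < 1e-14) return(list(x = x, f = fx, t = 0))
    o <- stats::optimize(function(t) fn(x + t * d), lower = tmin, upper = tmax,
                         tol = ls_tol)
    if (o$objective < fx) list(x = x + o$minimum * d, f = o$objective, t = o$minimum)
    else list(x = x, f = fx, t = 0)
  }
  for (it in seq_len(maxit)) {
    if (fx <= f_tol) break
    f0 <- fx; x_start <- x
    biggest <- 0; ibig <- 1
    for (i in seq_len(p)) {
      r <- line_min(x, dirs[, i], fx)
      if (fx - r$f > biggest) { biggest <- fx - r$f; ibig <- i }
      x <- r$x; fx <- r$f
    }
    if (fx <= f_tol) break
    if (2 * (f0 - fx) <= tol * (abs(f0) + abs(fx)) + 1e-14) break
    # Powell's direction replacement with extrapolation test
    d_new <- x - x_start
    if (sqrt(sum(d_new^2)) > 1e-14) {
      xe <- pmin(pmax(2 * x - x_start, lower), upper)
      fe <- fn(xe)
      if (fe < f0) {
        t1 <- 2 * (f0 - 2 * fx + fe) * (f0 - fx - biggest)^2 - biggest * (f0 - fe)^2
        if (t1 < 0) {
          r <- line_min(x, d_new, fx)
          x <- r$x; fx <- r$f
          dirs[, ibig] <- dirs[, p]
          dirs[, p] <- d_new / sqrt(sum(d_new^2))
        }
      }
    }
  }
  list(par = x, value = fx)
}

#' Two-stage parameter optimization
#'
#' Stage 1 is a derivative-free Powell conjugate-direction search from the
#' start point; stage 2 refines the stage-1 result with bounded L-BFGS-B
#' (numerical gradients).  The final objective never exceeds the starting
#' objective; optimizer failures return the best-seen parameters with a flag.
#'
#' @param f Scalar objective function of the parameter vector, or a
#'   `tb_objective_spec` (RMSE objective).
#' @param start Start vector (must lie within bounds).
#' @param bounds 2 x p matrix (rows: lower, upper).
#' @param seed RNG seed (recorded; both stages are deterministic).
#' @param f_tol Absolute objective floor: once the objective drops below it,
#'   further refinement is skipped (useful when the objective has a known
#'   exact minimum of zero, as in planted-parameter recovery).
#' @param ls_tol Line-search tolerance of the Powell stage.
#' @return List with `par`, `value`, `start_value`, `stage1`, `trace` and
#'   `flag`.
#' @export
two_stage_optimize <- function(f, start, bounds, seed = 42, f_tol = 0,
                               ls_tol = 1e-10) {
  if (inherits(f, "tb_objective_spec")) {
    spec <- f
    f <- function(x) objective(x, spec)$rmse
  }
  if (is.list(bounds)) bounds <- vapply(bounds, identity, numeric(2))
  bounds <- matrix(as.numeric(bounds), nrow = 2)
  lower <- bounds[1, ]; upper <- bounds[2, ]
  stopifnot(all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  set.seed(seed)
  trace <- list()
  fwrap <- function(x) {
    v <- f(x)
    trace[[length(trace) + 1]] <<- c(x, v)
    v
  }
  f0 <- fwrap(start)
  s1 <- tryCatch(.powell(fwrap, start, lower, upper, f_tol = f_tol, ls_tol = ls_tol),
                 error = function(e) list(par = start, value = f0, failed = TRUE))
  s2_maxit <- if (s1$value <= f_tol) 1 else 200
  s2 <- tryCatch(
    stats::optim(s1$par, fwrap, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = s2_maxit)),
    error = function(e) list(par = s1$par, value = s1$value, failed = TRUE))
  cand <- list(list(par = start, value = f0), s1, s2)
  best <- cand[[which.min(vapply(cand, function(c) c$value, 0))]]
  tr <- do.call(rbind, trace)
  colnames(tr) <- c(paste0("x", seq_along(start)), "f")
  list(par = best$par, value = best$value, start_value = f0,
       stage1 = list(par = s1$par, value = s1$value),
       trace = as.data.frame(tr),
       flag = isTRUE(s1$failed) || isTRUE(s2$failed))
}

#' Exhaustive 2-D parameter scan
#'
#' Evaluates the objective on the full cross product of two parameter grids.
#'
#' @param spec A `tb_objective_spec` with exactly two free parameters, or a
#'   scalar function of a length-2 vector.
#' @param grid_x,grid_y Grid values for the first/second free parameter.
#' @return A `tb_grid_scan`: list with matrices `rmse` and `sign_correct`
#'   (rows: grid_x), the grids, and the argmin/argmax cells (ties broken
#'   toward the cell closest to the grid centre, i.e. default-most values).
#' @export
grid_scan_2d <- function(spec, grid_x, grid_y) {
  stopifnot(length(grid_x) >= 1, length(grid_y) >= 1)
  fn <- if (inherits(spec, "tb_objective_spec")) {
    stopifnot(length(spec$free) == 2)
    function(x) { o <- objective(x, spec); c(o$rmse, o$sign_correct) }
  } else function(x) { v <- spec(x); c(v[1], if (length(v) > 1) v[2] else NA) }
  rmse <- matrix(NA_real_, length(grid_x), length(grid_y))
  signs <- matrix(NA_real_, length(grid_x), length(grid_y))
  for (i in seq_along(grid_x)) for (j in seq_along(grid_y)) {
    v <- fn(c(grid_x[i], grid_y[j]))
    rmse[i, j] <- v[1]; signs[i, j] <- v[2]
  }
  # tie-break toward the centre of the scanned box (default-most cell)
  centre <- c(mean(range(grid_x)), mean(range(grid_y)))
  pick <- function(M, what) {
    tgt <- if (what == "min") min(M) else max(M)
    cand <- which(abs(M - tgt) < 1e-12, arr.ind = TRUE)
    d <- (grid_x[cand[, 1]] - centre[1])^2 + (grid_y[cand[, 2]] - centre[2])^2
    cand[which.min(d), ]
  }
  structure(list(rmse = rmse, sign_correct = signs,
                 grid_x = grid_x, grid_y = grid_y,
                 argmin_rmse = pick(rmse, "min"),
                 argmax_signs = if (!anyNA(signs)) pick(signs, "max") else NULL),
            class = "tb_grid_scan")
}

#' Export a 2-D scan as CSV
#'
#' @param scan A `tb_grid_scan`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_scan <- function(scan, path) {
  df <- expand.grid(x = scan$grid_x, y = scan$grid_y)
  df$rmse <- as.vector(scan$rmse)
  df$sign_correct <- as.vector(scan$sign_correct)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
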