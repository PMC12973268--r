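# Parameter workflow: objective bookkeeping, Sobol sensitivity, the two-stage
# optimizer and grid scans (cheap function-level oracles; the engine-level
# recovery test lives in the acceptance suite).

test_that("objective RMSE and sign counting match a brute-force recomputation", {
  p <- tb_test_params()
  s1 <- atomic_structure(c("Fe", "N"), rbind(c(0, 0, 0), c(0, 0, 2.0)), 1L, 5L)
  s2 <- atomic_structure(c("Fe", "N"), rbind(c(0, 0, 0), c(0, 0, 2.2)), 1L, 5L)
  st <- scf_settings(solver = "gdm", max_iter = 400)
  tasks <- list(list(structure = s1, hs = 5, ls = 1, reference = 0),
                list(structure = s2, hs = 5, ls = 1, reference = 0))
  spec <- objective_spec(tasks, free = c("Wdd", "Ud"),
                         bounds = list(c(-0.05, 0), c(0, 0.5)),
                         params = p, settings = st, uvariant = "psic")
  o <- objective(c(-0.02, 0.1), spec)
  expect_equal(o$n, 2)
  # brute-force oracle: recompute the RMSE from the reported gaps
  refs <- c(0, 0)
  expect_equal(o$rmse, sqrt(mean((o$gaps - refs)^2)), tolerance = 1e-12)
  # shifted references give the closed-form error vector (0, 2) -> sqrt(2)
  tasks2 <- list(list(structure = s1, hs = 5, ls = 1, reference = o$gaps[1]),
                 list(structure = s2, hs = 5, ls = 1, reference = o$gaps[2] - 2))
  spec2 <- objective_spec(tasks2, free = c("Wdd", "Ud"),
                          bounds = list(c(-0.05, 0), c(0, 0.5)),
                          params = p, settings = st, uvariant = "psic")
  o2 <- objective(c(-0.02, 0.1), spec2)
  expect_equal(o2$rmse, sqrt(2), tolerance = 1e-8)
  # predicted == reference: zero RMSE, every sign correct
  tasks3 <- list(list(structure = s1, hs = 5, ls = 1, reference = o$gaps[1]),
                 list(structure = s2, hs = 5, ls = 1, reference = o$gaps[2]))
  spec3 <- objective_spec(tasks3, free = c("Wdd", "Ud"),
                          bounds = list(c(-0.05, 0), c(0, 0.5)),
                          params = p, settings = st, uvariant = "psic")
  o3 <- objective(c(-0.02, 0.1), spec3)
  expect_equal(o3$rmse, 0, tolerance = 1e-7)
  expect_equal(o3$sign_correct, 2)
})

test_that("Sobol indices: degenerate and additive analytic cases", {
  bounds <- rbind(c(0, 0), c(1, 1))
  expect_warning(s0 <- sobol_sensitivity(function(x) 1.0, bounds, n_base = 64),
                 "degenerate")
  expect_true(all(s0$indices$S1 == 0) && all(s0$indices$ST == 0))
  # f depends on x1 only: S1(x1) ~ 1, S1(x2) ~ 0
  s1 <- sobol_sensitivity(function(x) 3 * x[1] - 1, bounds, n_base = 512, seed = 7)
  expect_gt(s1$indices$S1[1], 1 - 3 * s1$indices$S1_ci[1] - 0.05)
  expect_lt(abs(s1$indices$S1[2]), s1$indices$S1_ci[2] + 0.05)
  expect_lt(s1$indices$ST[2], 0.05)
  # total >= first order (within confidence)
  expect_gt(s1$indices$ST[1], s1$indices$S1[1] - s1$indices$S1_ci[1] - 0.05)
  # deterministic for a fixed seed
  s1b <- sobol_sensitivity(function(x) 3 * x[1] - 1, bounds, n_base = 512, seed = 7)
  expect_identical(s1$indices, s1b$indices)
  expect_error(sobol_sensitivity(function(x) x[1], bounds, n_base = 100), "power of 2")
})

test_that("two-stage optimizer: quadratic bowls and the descent contract", {
  bowl <- function(x) (x[1] - 0.3)^2 + 2 * (x[2] + 0.1)^2 + 0.05
  bounds <- rbind(c(-1, -1), c(1, 1))
  r <- two_stage_optimize(bowl, start = c(-0.8, 0.9), bounds = bounds, seed = 1)
  expect_equal(r$par, c(0.3, -0.1), tolerance = 1e-6)
  expect_equal(r$value, 0.05, tolerance = 1e-10)
  expect_lte(r$value, r$start_value)
  # starting at the optimum returns the start
  r2 <- two_stage_optimize(bowl, start = c(0.3, -0.1), bounds = bounds, seed = 1)
  expect_equal(r2$par, c(0.3, -0.1), tolerance = 1e-8)
  # a nastier multimodal function still never ends above its start
  rast <- function(x) sum(x^2) + 0.3 * sum(1 - cos(7 * x))
  r3 <- two_stage_optimize(rast, start = c(0.9, -0.7), bounds = bounds, seed = 1)
  expect_lte(r3$value, r3$start_value)
  # determinism of the trace
  r4 <- two_stage_optimize(rast, start = c(0.9, -0.7), bounds = bounds, seed = 1)
  expect_identical(r3$trace, r4$trace)
})

test_that("grid scans match pointwise objective evaluation", {
  f <- function(x) c((x[1] - 1)^2 + (x[2] - 2)^2, NA)
  gx <- seq(0, 2, by = 0.5); gy <- seq(1, 3, by = 0.5)
  sc <- grid_scan_2d(function(x) f(x)[1], gx, gy)
  for (i in seq_along(gx)) for (j in seq_along(gy))
    expect_equal(sc$rmse[i, j], f(c(gx[i], gy[j]))[1], tolerance = 1e-14)
  # separable quadratic: minimum at the analytic vertex cell
  expect_equal(unname(sc$argmin_rmse), c(match(1, gx), match(2, gy)),
               ignore_attr = TRUE)
  # 1x1 grid is a single evaluation
  sc1 <- grid_scan_2d(function(x) f(x)[1], 0.5, 1.5)
  expect_equal(sc1$rmse[1, 1], f(c(0.5, 1.5))[1])
})
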