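# Parameter model, structures and shell basis.

test_that("parameter loading applies documented defaults and validates", {
  p <- tb_test_params()
  expect_s3_class(p, "tb_parameters")
  # U defaults to zero for every shell when omitted
  for (el in c("H", "Li", "C", "N", "O", "F"))
    expect_true(all(p$elements[[el]]$U == 0))
  expect_equal(p$global$alpha, 0.5)
  # W is symmetric by construction
  for (el in names(p$elements))
    expect_identical(p$elements[[el]]$W, t(p$elements[[el]]$W))

  # alpha default when the key is absent entirely
  tmp <- tempfile(fileext = ".toml")
  writeLines(c("[element.H]", "shells = 1s", "ngauss = 3", "levels = -10.7",
               "slater = 1.23", "refocc = 1", "kcn = 0", "shpoly = 0",
               "gam = 0.4", "lgam = 1", "gam3 = 0.08", "arep = 2.2",
               "zeff = 1.1", "en = 2.2", "rcov = 0.32"), tmp)
  p2 <- load_parameters(tmp)
  expect_equal(p2$global$alpha, 0.5)
  expect_equal(p2$elements$H$U, 0)
  expect_true(all(p2$elements$H$W == 0))
})

test_that("malformed and incomplete parameter files raise named errors", {
  tmp <- tempfile(fileext = ".toml")
  writeLines(c("[element.H]", "shells = 1s", "gam = 0.4"), tmp)
  expect_error(load_parameters(tmp), "missing key 'ngauss'")
  writeLines(c("[global]", "just a broken line"), tmp)
  expect_error(load_parameters(tmp), "key = value")
  writeLines(c("[element.Fe]", "shells = 3d, 4s, 4p", "ngauss = 6,6,6",
               "levels = -7,-8,-3", "slater = 2,1.3,1.1", "refocc = 6,2,0",
               "kcn = 0,0,0", "shpoly = 0,0,0", "gam = .4", "lgam = 1,1,1",
               "gam3 = .05", "arep = 2", "zeff = 12", "en = 1.8", "rcov = 1.2",
               "U = -0.1, 0, 0"), tmp)
  expect_error(load_parameters(tmp), "U values must be >= 0")
})

test_that("write_parameters / load_parameters round trip is exact", {
  p <- tb_test_params()
  tmp <- tempfile(fileext = ".toml")
  write_parameters(p, tmp)
  p2 <- load_parameters(tmp)
  for (el in names(p$elements)) {
    expect_equal(p2$elements[[el]], p$elements[[el]], tolerance = 1e-12)
  }
  expect_equal(p2$global[order(names(p2$global))],
               p$global[order(names(p$global))], tolerance = 1e-12)
})

test_that("shell basis has documented ordering and AO counts", {
  p <- tb_test_params()
  b_lif <- build_basis(make_lif(1.25), p)
  expect_equal(attr(b_lif, "nao"), 8L)     # Li s,p + F s,p
  b_h <- build_basis(atomic_structure("H", matrix(0, 1, 3)), p)
  expect_equal(attr(b_h, "nao"), 1L)
  b_fe <- build_basis(atomic_structure("Fe", matrix(0, 1, 3), 0L, 5L), p)
  expect_equal(attr(b_fe, "nao"), 9L)      # s + p + d
  expect_equal(b_fe$l, c(0L, 1L, 2L))      # increasing angular momentum
  expect_equal(b_fe$deg, c(1L, 3L, 5L))
  expect_equal(b_fe$ao_end - b_fe$ao_start + 1L, b_fe$deg)
  # index ranges contiguous and disjoint
  expect_equal(b_fe$ao_start, c(1L, 2L, 5L))
  # pure function: repeated calls agree exactly
  expect_identical(build_basis(make_lif(1.25), p), b_lif)
  expect_error(build_basis(atomic_structure("He", matrix(0, 1, 3)), p),
               "unknown element|unsupported element")
})

test_that("electron bookkeeping follows charge and multiplicity", {
  p <- tb_test_params()
  cnt <- xtbu:::electron_counts(make_lif(1.25), p)
  expect_equal(cnt$nelec, 8)
  expect_equal(cnt$n_alpha, 4); expect_equal(cnt$n_beta, 4)
  hex <- make_hexammine("Fe", 3L, 6L, 2.2)
  cnt <- xtbu:::electron_counts(hex, p)
  expect_equal(cnt$nelec, 8 + 6 * 8 - 3)
  expect_equal(cnt$n_alpha - cnt$n_beta, 5)
  expect_true(cnt$n_alpha >= cnt$n_beta)
  expect_error(xtbu:::electron_counts(
    atomic_structure("H", matrix(0, 1, 3), 0L, 3L), p), "inconsistent")
})

test_that("XYZ files round trip and report parse errors with line numbers", {
  s <- make_hexammine("Fe", 3L, 6L, 2.15)
  tmp <- tempfile(fileext = ".xyz")
  write_xyz(s, tmp)
  s2 <- read_xyz(tmp)
  expect_equal(s2$elements, s$elements)
  expect_equal(s2$coords_ang, s$coords_ang, tolerance = 1e-12)
  expect_equal(s2$charge, 3L)
  expect_equal(s2$multiplicity, 6L)
  writeLines(c("3", "comment", "H 0 0 0", "H 0 0 1"), tmp)
  expect_error(read_xyz(tmp), "line 1")
  writeLines(c("not-a-count", "comment", "H 0 0 0"), tmp)
  expect_error(read_xyz(tmp), "line 1")
})
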