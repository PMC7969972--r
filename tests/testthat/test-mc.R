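test_that("simulator input contracts hold", {
  expect_error(simulate_reflectance(-1, 10), ">= 0")
  expect_error(mc_config(n_photons = 0), "n_photons")
  expect_error(mc_config(g = 1), "g must")
  expect_error(mc_config(weight_threshold = 0), "weight_threshold")
})

test_that("no scattering means nothing reaches a separated detector", {
  r <- simulate_reflectance(3, 0)
  expect_identical(r$value, 0)
  expect_identical(r$se, 0)
})

test_that("extreme absorption kills the signal", {
  r <- simulate_reflectance(1e4, 10, cfg = mc_config(n_photons = 5000,
                                                     seed = 2))
  expect_lt(r$value, 1e-6)
})

test_that("the estimate is seed-deterministic and seed-consistent", {
  cfg <- mc_config(n_photons = 20000, seed = 31)
  a <- simulate_reflectance(2, 30, cfg = cfg)
  b <- simulate_reflectance(2, 30, cfg = cfg)
  expect_identical(a$value, b$value)
  # two independent seeds agree within 3 combined standard errors
  c2 <- simulate_reflectance(2, 30,
                             cfg = mc_config(n_photons = 100000, seed = 31))
  c3 <- simulate_reflectance(2, 30,
                             cfg = mc_config(n_photons = 100000, seed = 77))
  expect_lt(abs(c2$value - c3$value), 3 * sqrt(c2$se^2 + c3$se^2))
})

test_that("lookup-table build has the right shape, order and metadata", {
  lut <- small_mc_lut()
  expect_s3_class(lut, "drs_lut")
  expect_identical(dim(lut$reflectance), c(8L, 8L))
  expect_true(all(lut$reflectance >= 0 & lut$reflectance <= 1))
  # musp = 0 column is exactly zero by construction
  expect_true(all(lut$reflectance[, 1] == 0))
  # the mua = 0 row dominates every other row within 3 SE
  tol <- 3 * sqrt(sweep(lut$se^2, 2, lut$se[1, ]^2, `+`))
  expect_true(all(lut$reflectance <=
                    rep(lut$reflectance[1, ], each = 8) + tol))
  expect_equal(lut$meta$config$n_photons, 4000)
})

test_that("rebuilding with the same seed is bit-identical", {
  lut <- small_mc_lut()
  again <- build_lut(lut$mua_axis, lut$musp_axis,
                     cfg = mc_config(n_photons = 4000, seed = 42))
  expect_identical(again$reflectance, lut$reflectance)
  expect_identical(again$se, lut$se)
})

test_that("bilinear interpolation is exact at nodes and averages cell centers", {
  lut <- analytic_lut(10)
  for (i in c(1, 4, 10)) for (j in c(1, 5, 10))
    expect_identical(lut_reflectance(lut, lut$mua_axis[i], lut$musp_axis[j]),
                     lut$reflectance[i, j])
  cx <- (lut$mua_axis[3] + lut$mua_axis[4]) / 2
  cy <- (lut$musp_axis[6] + lut$musp_axis[7]) / 2
  expect_equal(lut_reflectance(lut, cx, cy),
               mean(lut$reflectance[3:4, 6:7]), tolerance = 1e-12)
  expect_error(lut_reflectance(lut, 51, 10), "outside the grid")
  expect_error(lut_reflectance(lut, 10, -1), "outside the grid")
})

test_that("interpolation is continuous across cell boundaries", {
  lut <- analytic_lut(10)
  edge <- lut$mua_axis[5]
  eps <- 1e-9
  expect_equal(lut_reflectance(lut, edge - eps, 33),
               lut_reflectance(lut, edge + eps, 33), tolerance = 1e-6)
})

test_that("lookup-table persistence round-trips", {
  lut <- small_mc_lut()
  path <- withr::local_tempfile(fileext = ".json")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_equal(back$reflectance, lut$reflectance, tolerance = 1e-14)
  expect_equal(back$mua_axis, lut$mua_axis)
  expect_equal(back$meta$config$seed, 42)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_lut_table(lut, tsv)
  long <- read.delim(tsv)
  expect_identical(nrow(long), 64L)
  expect_equal(long$R[long$mua == lut$mua_axis[2] &
                        long$musp == lut$musp_axis[3]],
               lut$reflectance[2, 3], tolerance = 1e-12)
})
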