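test_that("responsivity rows are normalized Gaussians peaking at their centers", {
  resp <- default_resp()
  expect_identical(dim(resp$weights), c(6L, 100L))
  expect_equal(rowSums(resp$weights), rep(1, 6), tolerance = 1e-12)
  expect_true(all(resp$weights >= 0))
  grid <- resp$grid
  for (i in seq_along(resp$centers)) {
    peak <- grid[which.max(resp$weights[i, ])]
    nearest <- grid[which.min(abs(grid - resp$centers[i]))]
    expect_identical(peak, nearest)
  }
  # neighbouring 550 and 570 nm channels overlap through the Gaussian tails
  both <- resp$weights[4, ] > 1e-6 & resp$weights[3, ] > 1e-6
  expect_true(any(both))
  expect_error(make_responsivity(fwhm = 0), "fwhm")
  expect_error(make_responsivity(centers = c(450, 700)), "span")
})

test_that("downsampling is a convex average with the expected identities", {
  resp <- default_resp()
  flat <- drsml:::new_spectrum(resp$grid, rep(0.37, 100))
  ds <- downsample(flat, resp)
  expect_length(ds$values, 6)
  expect_equal(ds$values, rep(0.37, 6), tolerance = 1e-12)
  expect_identical(ds$wavelengths, channel_centers())
  # commutes with scaling
  spec <- drsml:::new_spectrum(resp$grid, runif(100))
  scaled <- drsml:::new_spectrum(resp$grid, 2.5 * spec$values)
  expect_equal(downsample(scaled, resp)$values,
               2.5 * downsample(spec, resp)$values, tolerance = 1e-12)
  # a linear spectrum maps interior channels to the value near the center
  lin <- drsml:::new_spectrum(resp$grid, 0.001 * resp$grid)
  dl <- downsample(lin, resp)
  step <- diff(resp$grid)[1]
  for (k in 2:5) {
    eff <- dl$values[k] / 0.001
    expect_lt(abs(eff - resp$centers[k]), step)
  }
  bad <- drsml:::new_spectrum(seq(400, 660, length.out = 90), runif(90))
  expect_error(downsample(bad, resp), "grid")
})

test_that("noise is multiplicative, seeded, floored at zero, and unbiased", {
  resp <- default_resp()
  spec <- drsml:::new_spectrum(resp$grid, seq(0.001, 0.005, length.out = 100))
  expect_identical(add_noise(spec, 0)$values, spec$values)
  a <- add_noise(spec, 0.05, seed = 4)
  b <- add_noise(spec, 0.05, seed = 4)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_error(add_noise(spec, -0.1), "sigma_rel")
  # law of large numbers: replicate means recover the clean spectrum
  reps <- vapply(seq_len(10000),
                 function(k) add_noise(spec, 0.05, seed = k)$values[c(1, 50, 100)],
                 numeric(3))
  se <- 0.05 * spec$values[c(1, 50, 100)] / sqrt(10000)
  expect_true(all(abs(rowMeans(reps) - spec$values[c(1, 50, 100)]) < 4 * se))
})

test_that("forward model produces valid spectra that darken with more blood", {
  lut <- analytic_lut()
  tab <- chrom_table()
  grid <- spectral_grid()
  p <- tissue_params(0.02, 15, 1.8, 0.4, 0.85)
  spec <- forward_spectrum(p, lut, tab, grid)
  expect_length(spec$values, 100)
  expect_true(all(spec$values >= 0 & spec$values <= 1))
  at550 <- function(bvf) {
    pp <- tissue_params(bvf, 15, 1.8, 0.4, 0.85)
    forward_spectrum(pp, lut, tab, grid)$values[which.min(abs(grid - 550))]
  }
  vals <- vapply(seq(0.01, 0.05, length.out = 5), at550, 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("factorial dataset has exact design structure and reproducibility", {
  ds <- small_dataset()
  expect_identical(nrow(ds$params), 3125L)  # 5^5
  rng <- param_ranges()
  for (pn in param_names()) {
    lev <- sort(unique(ds$params[[pn]]))
    expect_length(lev, 5)
    expect_identical(lev, seq(rng[[pn]][1], rng[[pn]][2], length.out = 5))
  }
  expect_identical(sum(ds$split == "test"), 938L)
  expect_identical(sum(ds$split == "train"), 312L)
  expect_identical(sum(ds$split == "train" & ds$split == "test"), 0L)
  expect_identical(dim(ds$spectra6), c(3125L, 6L))
  # bit-reproducible end to end
  again <- generate_dataset(analytic_lut(), chrom_table(), default_resp(),
                            sigma_rel = 0.01, seed = 9, levels = 5)
  expect_identical(again$spectra6, ds$spectra6)
  expect_identical(again$split, ds$split)
})

test_that("dataset generation rejects designs the lookup table cannot cover", {
  narrow <- analytic_lut()
  narrow$musp_axis <- seq(0, 50, length.out = 60)  # too small for the blue end
  expect_error(generate_dataset(narrow, chrom_table(), default_resp(),
                                seed = 1, levels = 3),
               "not representable")
})

test_that("dataset persistence round-trips the six-channel data", {
  ds <- small_dataset()
  prefix <- file.path(withr::local_tempdir(), "ds")
  write_dataset(ds, prefix)
  back <- read_dataset(prefix)
  expect_equal(back$spectra6, ds$spectra6, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$split, ds$split)
  expect_equal(back$params$bvf, ds$params$bvf, tolerance = 1e-12)
  expect_identical(back$meta$levels, 5L)
})
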