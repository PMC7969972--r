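# Inverse-model tests run against the smooth analytic lookup table so that
# self-consistency statements are exact, not Monte Carlo noise-limited.

point_sample_spectrum <- function(p, lut, tab) {
  centers <- channel_centers()
  drsml:::lut_reflectance(lut, mua_at(p, centers, tab), musp_at(p, centers))
}

test_that("noiseless point-sample spectra refit to numerically zero residual", {
  lut <- analytic_lut()
  tab <- chrom_table()
  truths <- list(
    tissue_params(0.02, 14, 1.6, 0.5, 0.80),
    tissue_params(0.04, 25, 2.2, 1.5, 0.95),
    tissue_params(0.013, 11, 1.4, 0.1, 0.65))
  for (p in truths) {
    meas <- point_sample_spectrum(p, lut, tab)
    fit <- fit_spectrum(meas, lut, tab, seed = 7)
    expect_lt(fit$residual, 1e-10)
    model <- point_sample_spectrum(fit$params, lut, tab)
    expect_equal(model, meas, tolerance = 1e-5)
    # bounds contract
    rng <- param_ranges()
    for (pn in param_names()) {
      expect_gte(fit$params[[pn]], rng[[pn]][1])
      expect_lte(fit$params[[pn]], rng[[pn]][2])
    }
  }
})

test_that("starting at the optimum is a no-op and never worsens the residual", {
  lut <- analytic_lut()
  tab <- chrom_table()
  p <- tissue_params(0.03, 18, 1.9, 0.8, 0.7)
  meas <- point_sample_spectrum(p, lut, tab)
  fit <- fit_spectrum(meas, lut, tab, init = p, n_starts = 1)
  expect_lt(fit$residual, 1e-20)
  expect_true(fit$converged)
  # residual at the returned params never exceeds the residual at init,
  # even for an arbitrary noisy target
  noisy <- meas * c(1.1, 0.9, 1.2, 0.95, 1.05, 0.8)
  init <- tissue_params(0.05, 30, 2.5, 2, 1)
  f0 <- sum((point_sample_spectrum(init, lut, tab) - noisy)^2)
  fit2 <- fit_spectrum(noisy, lut, tab, init = init, seed = 3)
  expect_lte(fit2$residual, f0)
})

test_that("more starts never worsen the best residual", {
  lut <- analytic_lut()
  tab <- chrom_table()
  meas <- point_sample_spectrum(tissue_params(0.045, 28, 2.4, 1.8, 0.98),
                                lut, tab) * 1.07
  f1 <- fit_spectrum(meas, lut, tab, n_starts = 1, seed = 5)$residual
  f5 <- fit_spectrum(meas, lut, tab, n_starts = 5, seed = 5)$residual
  expect_lte(f5, f1 + 1e-15)
})

test_that("weighted mode is consistent with the weighted forward model", {
  lut <- analytic_lut()
  tab <- chrom_table()
  resp <- default_resp()
  p <- tissue_params(0.025, 16, 1.7, 0.6, 0.9)
  clean <- forward_spectrum(p, lut, tab)
  meas <- downsample(clean, resp)$values
  fit <- fit_spectrum(meas, lut, tab, mode = "weighted", resp = resp,
                      init = p, n_starts = 1)
  expect_lt(fit$residual, 1e-12)
})

test_that("invalid measurements are data errors, batches isolate failures", {
  lut <- analytic_lut()
  tab <- chrom_table()
  expect_error(fit_spectrum(c(1, 2, 3), lut, tab), "six")
  expect_error(fit_spectrum(c(1, 2, 3, NA, 5, 6), lut, tab), "finite")

  meas <- point_sample_spectrum(tissue_params(0.02, 15, 1.5, 0.3, 0.8),
                                lut, tab)
  batch <- rbind(meas, rep(NA_real_, 6), meas * 1.02)
  res <- fit_batch(batch, lut, tab, seed = 2)
  expect_identical(res$fits$failed, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(res$fits$residual[2])))
  expect_lt(res$fits$residual[1], 1e-10)
  # batch of one equals the single fit with the same derived seed
  single <- fit_spectrum(meas, lut, tab, seed = drsml::derive_seed(2, 1))
  one <- fit_batch(matrix(meas, nrow = 1), lut, tab, seed = 2)
  expect_equal(one$fits$residual[1], single$residual, tolerance = 1e-12)
  expect_equal(unlist(one$fits[1, param_names()]),
               unlist(single$params), tolerance = 1e-8,
               ignore_attr = TRUE)
})
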