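test_that("mean absolute error matches hand arithmetic and a brute force", {
  expect_identical(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(4, 5), c(2, 3)), 2)
  expect_equal(mae(c(1, 3), c(2, 5)), 1.5)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  expect_error(mae(c(1, NA), c(1, 2)), "finite")
  set.seed(101)
  for (k in 1:20) {
    p <- rnorm(50); t <- rnorm(50)
    expect_equal(mae(p, t), sum(abs(p - t)) / 50, tolerance = 1e-14)
  }
})

test_that("percent error averages ratios and excludes zero-truth rows", {
  expect_identical(as.numeric(mape(c(1, 2), c(1, 2))), 0)
  expect_equal(as.numeric(mape(1.1 * c(2, 5, 9), c(2, 5, 9))), 10,
               tolerance = 1e-12)
  m <- mape(c(1, 2.2), c(0, 2))
  expect_equal(as.numeric(m), 10, tolerance = 1e-12)
  expect_identical(attr(m, "n_excluded"), 1L)
  expect_error(mape(c(1, 2), c(0, 0)), "undefined")
  set.seed(102)
  p <- runif(40); t <- runif(40) + 0.5
  expect_equal(as.numeric(mape(p, t)), mean(abs(p - t) / t) * 100,
               tolerance = 1e-12)
})

test_that("crosstalk matrix is Pearson truth-vs-predicted", {
  ds <- small_dataset()
  truth <- as.matrix(ds$params[ds$split == "test", ])
  ct <- crosstalk(truth, truth)
  expect_equal(unname(diag(ct)), rep(1, 5), tolerance = 1e-12)
  # balanced factorial columns are orthogonal: perfect extraction of one
  # parameter cannot correlate with any other truth column
  full <- as.matrix(ds$params)
  ct_full <- crosstalk(full, full)
  off <- ct_full - diag(diag(ct_full))
  expect_lt(max(abs(off)), 1e-10)
  # zero-variance prediction gives NA, not an error
  degen <- truth
  degen[, 2] <- 7
  expect_true(all(is.na(crosstalk(truth, degen)[, 2])))
  expect_error(crosstalk(truth[1:2, ], truth[1:2, ]), ">= 3")
})

test_that("win rates honour the strict-improvement tie rule", {
  lev <- rep(c(1, 2), each = 50)
  ea <- runif(100, 1, 2)
  wr <- winrate_by_level(ea, ea / 2, lev)
  expect_equal(wr$win_rate, c(1, 1))
  expect_equal(winrate_by_level(ea, ea, lev)$win_rate, c(0, 0))
  # antisymmetric differences hover near one half
  set.seed(5)
  eb <- ea + sample(c(-0.3, 0.3), 100, replace = TRUE)
  wr2 <- winrate_by_level(ea, eb, lev)
  expect_true(all(abs(wr2$win_rate - 0.5) < 0.25))
  expect_identical(wr2$n, c(50L, 50L))
})

test_that("paired bootstrap comparison has the stated degenerate behaviour", {
  set.seed(6)
  e <- matrix(abs(rnorm(200)), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  out <- compare_models(list(m1 = e, m2 = e), n_boot = 1000, seed = 3)
  self <- out[out$model_a == "m1" & out$model_b == "m2", ]
  expect_equal(self$mean_diff, c(0, 0))
  expect_true(all(self$ci_lo <= 0 & self$ci_hi >= 0))
  shifted <- compare_models(list(m1 = e, m2 = e - 1), n_boot = 1000,
                            seed = 3)
  row <- shifted[shifted$model_a == "m1" & shifted$model_b == "m2", ]
  expect_equal(row$mean_diff, c(-1, -1), tolerance = 1e-12)
  expect_equal(row$ci_lo, c(-1, -1), tolerance = 1e-12)
  expect_equal(row$ci_hi, c(-1, -1), tolerance = 1e-12)
  expect_error(compare_models(list(a = e, b = e[1:50, ]), n_boot = 1000),
               "dimensions")
  expect_error(compare_models(list(a = e, b = e), n_boot = 10), "1000")
})

test_that("runtime benchmark reports one row per batch size", {
  ds <- small_dataset()
  ex <- train_extractors("glm", ds)
  X <- ds$spectra6[ds$split == "test", ]
  bench <- runtime_bench(function(m) predict_params(ex, m), X,
                         batch_sizes = c(1, 10, 50), trials = 3, seed = 2)
  expect_identical(nrow(bench), 3L)
  expect_true(all(bench$mean_seconds >= 0))
  expect_error(runtime_bench(function(m) m, X, batch_sizes = 1e6),
               "exceeds")
})

test_that("evaluation report aggregates, serializes and round-trips", {
  ds <- small_dataset()
  te <- ds$split == "test"
  truth <- as.matrix(ds$params[te, ])
  set.seed(8)
  predictions <- list(
    good = truth * matrix(1 + rnorm(length(truth), 0, 0.02), nrow(truth)),
    bad = truth * matrix(1 + rnorm(length(truth), 0, 0.2), nrow(truth)))
  rep <- evaluate_predictions(predictions, ds, reference = "bad",
                              n_boot = 1000, seed = 1)
  expect_identical(nrow(rep$errors), 10L)
  expect_true(all(rep$errors$mae >= 0))
  expect_true(all(rep$errors$mape >= 0))
  good_tab <- rep$errors[rep$errors$model == "good", ]
  bad_tab <- rep$errors[rep$errors$model == "bad", ]
  expect_true(all(good_tab$mae < bad_tab$mae))
  expect_true(all(abs(rep$crosstalk$good) <= 1))
  wr <- rep$winrates$good$bvf
  expect_identical(nrow(wr), 5L)
  expect_true(all(wr$win_rate >= 0 & wr$win_rate <= 1, na.rm = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$errors$mae, rep$errors$mae, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", "_errors.tsv", path)))
})
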