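#' Run the full simulation study end-to-end
#'
#' Builds (or reuses) the lookup table, generates the factorial dataset,
#' trains the requested regression families on the training split, applies
#' them to the test split, optionally fits the lookup-table inverse model on
#' a seeded subsample of the test split, and evaluates everything.
#'
#' @param seed Master seed; every stage draws from a derived stream.
#' @param photons_per_node Monte Carlo photons per lookup-table node.
#' @param levels Factorial levels per parameter (10 for the study design).
#' @param sigma_rel Relative Gaussian noise on the 100-wavelength spectra.
#' @param fwhm Channel bandpass FWHM, nm.
#' @param families Regression families to train.
#' @param mclut_n Number of test spectra to run through the lookup-table
#'   inverse model: `Inf` fits every test row, `0` skips the inverse model.
#'   The inverse fit costs a nonlinear optimization per spectrum, so large
#'   test splits are typically subsampled.
#' @param lut Optional pre-built lookup table (skips the build).
#' @param n_boot Bootstrap replicates for the model comparison (0 skips).
#' @param verbose Print stage progress.
#' @return List with `lut`, `dataset`, `extractors`, `predictions`,
#'   `mclut_rows` (indices into the test split the inverse model was run
#'   on, or `NULL`), and `report` (an `eval_report` over the fitted
#'   models; for a subsampled inverse model a second report
#'   `report_mclut` compares all models on the subsampled rows).
#' @export
run_study <- function(seed = 1, photons_per_node = 20000, levels = 10,
                      sigma_rel = 0.01, fwhm = 40,
                      families = c("dl", "rf", "gbm", "glm"),
                      mclut_n = 1000, lut = NULL, n_boot = 2000,
                      verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  table <- load_chromophores()
  if (is.null(lut)) {
    say("building %d x %d lookup table at %d photons/node ...", 40, 40,
        photons_per_node)
    lut <- build_lut(cfg = mc_config(n_photons = photons_per_node,
                                     seed = derive_seed(seed, 11)),
                     verbose = verbose)
    say("lookup table done (%.0f s)", proc.time()[["elapsed"]] - t0)
  }
  resp <- make_responsivity(fwhm = fwhm)
  say("generating %d-level factorial dataset ...", levels)
  dataset <- generate_dataset(lut, table, resp, sigma_rel = sigma_rel,
                              seed = derive_seed(seed, 22), levels = levels,
                              keep_full = FALSE)
  test <- dataset$split == "test"
  X_test <- dataset$spectra6[test, , drop = FALSE]

  extractors <- list()
  predictions <- list()
  for (fam in families) {
    say("training %s ...", toupper(fam))
    extractors[[fam]] <- train_extractors(fam, dataset,
                                          seed = derive_seed(seed, 33))
    predictions[[fam]] <- predict_params(extractors[[fam]], X_test)
  }

  mclut_rows <- NULL
  report_mclut <- NULL
  if (mclut_n > 0) {
    n_test <- nrow(X_test)
    mclut_rows <- if (is.finite(mclut_n) && mclut_n < n_test)
      sort(with_seed(derive_seed(seed, 44),
                     sample.int(n_test, mclut_n))) else seq_len(n_test)
    say("lookup-table inverse fit on %d test spectra ...",
        length(mclut_rows))
    fb <- fit_batch(X_test[mclut_rows, , drop = FALSE], lut, table,
                    mode = "point_sample", seed = derive_seed(seed, 55))
    predictions$mclut <- as.matrix(fb$fits[param_names()])
    if (length(mclut_rows) < n_test) {
      sub_ds <- dataset
      keep <- which(test)[mclut_rows]
      sub_ds$params <- dataset$params[keep, , drop = FALSE]
      sub_ds$spectra6 <- dataset$spectra6[keep, , drop = FALSE]
      sub_ds$split <- factor(rep("test", length(keep)),
                             levels = c("train", "test", "unused"))
      sub_pred <- lapply(predictions[names(predictions) != "mclut"],
                         function(p) p[mclut_rows, , drop = FALSE])
      sub_pred$mclut <- predictions$mclut
      report_mclut <- evaluate_predictions(sub_pred, sub_ds,
                                           reference = "mclut",
                                           n_boot = n_boot,
                                           seed = derive_seed(seed, 66))
    }
  }
  ml_pred <- predictions[names(predictions) %in% families]
  report <- evaluate_predictions(
    if (is.null(report_mclut) && !is.null(predictions$mclut))
      predictions else ml_pred,
    dataset, n_boot = n_boot, seed = derive_seed(seed, 77))
  say("study complete (%.0f s)", proc.time()[["elapsed"]] - t0)
  list(lut = lut, dataset = dataset, extractors = extractors,
       predictions = predictions, mclut_rows = mclut_rows,
       report = report, report_mclut = report_mclut)
}
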