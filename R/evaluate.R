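#' Mean absolute error
#'
#' `mean(|pred - truth|)`, in the units of the parameter.
#'
#' @param pred,truth Equal-length finite numeric vectors.
#' @return Single non-negative number.
#' @export
mae <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop_domain("pred and truth must be non-empty and equal length")
  if (!all(is.finite(pred)) || !all(is.finite(truth)))
    stop_domain("mae requires finite inputs")
  mean(abs(pred - truth))
}

#' Mean absolute percent error
#'
#' `mean(100 * |pred - truth| / truth)` over rows with non-zero truth. Rows
#' with `truth == 0` (possible only for melanin, whose design grid includes
#' zero) are excluded — the ratio is undefined there — and the exclusion
#' count is attached as attribute `n_excluded`.
#'
#' @param pred,truth Equal-length finite numeric vectors.
#' @return Percent error (single number) with attribute `n_excluded`.
#' @export
mape <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop_domain("pred and truth must be non-empty and equal length")
  keep <- truth != 0
  if (!any(keep))
    stop_domain("all rows have zero truth; percent error undefined")
  out <- mean(100 * abs(pred[keep] - truth[keep]) / truth[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Truth-versus-prediction crosstalk matrix
#'
#' Entry `(i, j)` is the Pearson correlation between true parameter `i` and
#' predicted parameter `j`. On a balanced factorial design a perfect
#' extractor yields (near-)zero off-diagonal entries; non-zero off-diagonal
#' values indicate crosstalk between parameters. Zero-variance columns give
#' `NA` entries rather than an error.
#'
#' @param truth,pred `n x 5` matrices (n >= 3), columns in parameter order.
#' @return `5 x 5` matrix of correlations, rows = truth, cols = predicted.
#' @export
crosstalk <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (nrow(truth) < 3 || !identical(dim(truth), dim(pred)))
    stop_domain("need matching truth/pred matrices with >= 3 rows")
  r <- suppressWarnings(cor(truth, pred))
  dimnames(r) <- list(truth = param_names(), predicted = param_names())
  r
}

#' Per-level win rate of one extractor over another
#'
#' For each truth level, the fraction of rows where `err_b < err_a`
#' (strictly; ties count as not better). Used to compare the deep-learning
#' extractor against the lookup-table inverse per parameter value.
#'
#' @param err_a,err_b Aligned absolute-error vectors (model A = reference,
#'   model B = challenger).
#' @param truth_level Truth values defining the level groups.
#' @return Data frame with `level`, `n`, `win_rate` (fraction where B beats
#'   A; `NA` for empty levels).
#' @export
winrate_by_level <- function(err_a, err_b, truth_level) {
  if (length(err_a) != length(err_b) || length(err_a) != length(truth_level))
    stop_domain("err_a, err_b and truth_level must be aligned")
  lev <- sort(unique(truth_level))
  wins <- vapply(lev, function(l) {
    sel <- truth_level == l
    if (!any(sel)) return(NA_real_)
    mean(err_a[sel] - err_b[sel] > 0)
  }, 0)
  data.frame(level = lev,
             n = as.vector(table(factor(truth_level, levels = lev))),
             win_rate = wins)
}

#' Paired bootstrap comparison of model errors
#'
#' For every pair of models and every parameter: the mean difference in
#' absolute error, a 95% percentile confidence interval from paired row
#' resampling, and the two-sided exceedance fraction (bootstrap analogue of
#' a p-value). Replaces a parametric mixed-model analysis with a
#' distribution-free test of the same substantive question — which model's
#' errors are lower.
#'
#' @param abs_errors Named list of `n x p` absolute-error matrices (or
#'   vectors for a single parameter), rows aligned across models.
#' @param n_boot Bootstrap replicates (>= 1000).
#' @param seed Seed for resampling.
#' @param conf Confidence level.
#' @return Data frame: `parameter`, `model_a`, `model_b`, `mean_diff`
#'   (B - A), `ci_lo`, `ci_hi`, `p_exceed`.
#' @export
compare_models <- function(abs_errors, n_boot = 2000, seed = 1,
                           conf = 0.95) {
  if (n_boot < 1000) stop_domain("n_boot must be >= 1000")
  abs_errors <- lapply(abs_errors, function(e) {
    if (is.null(dim(e))) e <- matrix(e, ncol = 1,
                                     dimnames = list(NULL, "value"))
    as.matrix(e)
  })
  dims <- vapply(abs_errors, dim, c(1L, 1L))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop_domain("error matrices must share dimensions across models")
  n <- dims[1, 1]
  pnames <- colnames(abs_errors[[1]])
  if (is.null(pnames)) pnames <- paste0("p", seq_len(dims[2, 1]))
  models <- names(abs_errors)
  idx <- with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                n, n_boot))
  alpha <- (1 - conf) / 2
  rows <- list()
  for (a in seq_along(models)) for (b in seq_along(models)) {
    if (a == b) next
    for (p in seq_along(pnames)) {
      d <- abs_errors[[b]][, p] - abs_errors[[a]][, p]
      boots <- colMeans(matrix(d[idx], n, n_boot))
      ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pnames[p], model_a = models[a], model_b = models[b],
        mean_diff = mean(d), ci_lo = ci[1], ci_hi = ci[2],
        p_exceed = 2 * min(mean(boots > 0), mean(boots < 0)))
    }
  }
  do.call(rbind, rows)
}

#' Runtime benchmark of a trained extractor
#'
#' Mean wall-clock time to extract parameters from batches of 1, 10, 50 and
#' 100 spectra, over seeded random batch draws from the dataset. Timings are
#' hardware-dependent and are reported, never asserted.
#'
#' @param extract_fun Function taking an `n x 6` matrix and returning
#'   predictions.
#' @param spectra6 Matrix of available spectra.
#' @param batch_sizes Batch sizes to time.
#' @param trials Random draws per batch size.
#' @param seed Seed for batch selection.
#' @return Data frame: `batch_size`, `mean_seconds`, `sd_seconds`.
#' @export
runtime_bench <- function(extract_fun, spectra6,
                          batch_sizes = c(1, 10, 50, 100), trials = 50,
                          seed = 1) {
  n <- nrow(spectra6)
  if (any(batch_sizes > n))
    stop_domain("batch size exceeds the number of available spectra")
  res <- lapply(seq_along(batch_sizes), function(bi) {
    bs <- batch_sizes[bi]
    times <- vapply(seq_len(trials), function(tr) {
      idx <- with_seed(derive_seed(seed, bi * 1000 + tr),
                       sample.int(n, bs, replace = FALSE))
      t0 <- proc.time()[["elapsed"]]
      extract_fun(spectra6[idx, , drop = FALSE])
      proc.time()[["elapsed"]] - t0
    }, 0)
    data.frame(batch_size = bs, mean_seconds = mean(times),
               sd_seconds = sd(times))
  })
  do.call(rbind, res)
}

#' Evaluate extractors against the test split
#'
#' Computes the full evaluation report for a set of per-model predictions on
#' the test split: per model and parameter mean absolute error, error
#' standard deviation and mean absolute percent error (zero-truth rows
#' excluded and counted); the 5 x 5 truth-versus-prediction crosstalk matrix
#' per model; per-level win rates of each model against a reference model;
#' and paired bootstrap comparisons across models.
#'
#' @param predictions Named list of `n_test x 5` prediction matrices.
#' @param dataset The `drs_dataset` the predictions refer to.
#' @param reference Name of the reference model for win rates (default
#'   `"mclut"` if present).
#' @param n_boot Bootstrap replicates for [compare_models()] (0 skips it).
#' @param seed Seed for the bootstrap.
#' @return An `eval_report`: list with `errors` (data frame), `crosstalk`
#'   (list of matrices), `winrates` (list of data frames), `comparison`.
#' @export
evaluate_predictions <- function(predictions, dataset, reference = NULL,
                                 n_boot = 2000, seed = 1) {
  truth <- as.matrix(dataset$params[dataset$split == "test", ])
  stopifnot(all(vapply(predictions, nrow, 1L) == nrow(truth)))
  err_tabs <- list()
  abs_err <- list()
  xtalk <- list()
  for (m in names(predictions)) {
    pred <- as.matrix(predictions[[m]])
    ae <- abs(pred - truth)
    colnames(ae) <- param_names()
    abs_err[[m]] <- ae
    per <- lapply(param_names(), function(pn) {
      mp <- mape(pred[, pn], truth[, pn])
      data.frame(model = m, parameter = pn,
                 mae = mae(pred[, pn], truth[, pn]),
                 sd_abs_err = sd(ae[, pn]),
                 mape = as.numeric(mp),
                 mape_n_excluded = attr(mp, "n_excluded"))
    })
    err_tabs[[m]] <- do.call(rbind, per)
    xtalk[[m]] <- crosstalk(truth, pred)
  }
  winrates <- NULL
  if (is.null(reference) && "mclut" %in% names(predictions))
    reference <- "mclut"
  if (!is.null(reference) && reference %in% names(predictions)) {
    winrates <- list()
    for (m in setdiff(names(predictions), reference)) {
      winrates[[m]] <- lapply(param_names(), function(pn)
        winrate_by_level(abs_err[[reference]][, pn], abs_err[[m]][, pn],
                         truth[, pn]))
      names(winrates[[m]]) <- param_names()
    }
  }
  comparison <- if (n_boot >= 1000 && length(predictions) > 1)
    compare_models(abs_err, n_boot = n_boot, seed = seed) else NULL
  structure(list(errors = do.call(rbind, err_tabs), crosstalk = xtalk,
                 winrates = winrates, comparison = comparison),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("evaluation report (test split)\n")
  print(x$errors, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report to JSON (tables also as TSV)
#'
#' @param report An `eval_report`.
#' @param path JSON output path; the error table is additionally written
#'   next to it with suffix `_errors.tsv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  write.table(report$errors, sub("\\.json$", "_errors.tsv", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
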