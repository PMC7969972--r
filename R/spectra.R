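#' The 100-point simulation wavelength grid
#'
#' @param n Number of wavelengths.
#' @param range Band limits in nm.
#' @return Numeric vector of evenly spaced wavelengths.
#' @export
spectral_grid <- function(n = 100, range = c(410, 650)) {
  seq(range[1], range[2], length.out = n)
}

#' The six sensor channel centers
#'
#' Channel center wavelengths of the six-channel visible multispectral
#' sensor emulated by the down-sampling step.
#' @return `c(450, 500, 550, 570, 600, 650)` nm.
#' @export
channel_centers <- function() c(450, 500, 550, 570, 600, 650)

new_spectrum <- function(wavelengths, values) {
  structure(list(wavelengths = wavelengths, values = values),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("reflectance spectrum: %d wavelengths, %.0f-%.0f nm, R in [%.4g, %.4g]\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Forward-model a reflectance spectrum from tissue parameters
#'
#' Maps physiological parameters to `(mua, musp)` at every grid wavelength
#' and queries the lookup table:
#' `R(lambda) = lut_reflectance(mua(lambda), musp(lambda))`.
#'
#' @param params A [tissue_params()] object.
#' @param lut A [build_lut()] lookup table.
#' @param table A [load_chromophores()] table.
#' @param grid Wavelength grid, nm.
#' @return A `drs_spectrum` on `grid`.
#' @export
forward_spectrum <- function(params, lut, table, grid = spectral_grid()) {
  mua <- mua_at(params, grid, table)
  musp <- musp_at(params, grid)
  new_spectrum(grid, lut_reflectance(lut, mua, musp))
}

# matrix version: params_df (n x 5) -> n x length(grid) reflectance matrix
forward_matrix <- function(params_df, lut, table, grid = spectral_grid()) {
  mua <- mua_matrix(params_df, grid, table)
  musp <- musp_matrix(params_df, grid)
  out <- lut_reflectance(lut, as.vector(mua), as.vector(musp))
  matrix(out, nrow(params_df), length(grid))
}

#' Add multiplicative Gaussian noise to a spectrum
#'
#' Each value is perturbed by independent zero-mean Gaussian noise with
#' standard deviation `sigma_rel * value`; negative results are floored at
#' zero (reflectance is physical).
#'
#' @param spec A `drs_spectrum`, or a numeric matrix of spectra (rows =
#'   spectra).
#' @param sigma_rel Relative noise level (>= 0).
#' @param seed Integer seed.
#' @return Same shape as the input.
#' @export
add_noise <- function(spec, sigma_rel, seed = 1) {
  if (sigma_rel < 0) stop_domain("sigma_rel must be >= 0")
  noisy <- function(v) {
    if (sigma_rel == 0) return(v)
    pmax(0, v * (1 + with_seed(seed, rnorm(length(v), 0, sigma_rel))))
  }
  if (inherits(spec, "drs_spectrum"))
    return(new_spectrum(spec$wavelengths, noisy(spec$values)))
  m <- noisy(as.vector(spec))
  matrix(m, nrow(spec), ncol(spec))
}

#' Gaussian channel responsivity matrix
#'
#' One Gaussian bandpass per sensor channel, centered at the channel center
#' with the configured full width at half maximum (`sigma = FWHM / 2.3548`),
#' evaluated on the simulation grid, truncated to the grid, and renormalized
#' so each row sums to one. Down-sampling is then a convex weighted average
#' per channel.
#'
#' @param centers Channel centers, nm.
#' @param fwhm Channel full width at half maximum, nm (default 40, the
#'   nominal bandwidth of the emulated six-channel sensor).
#' @param grid Wavelength grid, nm.
#' @return A `channel_responsivity`: list with `centers`, `fwhm`, `grid` and
#'   a `length(centers) x length(grid)` `weights` matrix.
#' @export
make_responsivity <- function(centers = channel_centers(), fwhm = 40,
                              grid = spectral_grid()) {
  if (fwhm <= 0) stop_domain("fwhm must be > 0")
  if (any(centers < min(grid)) || any(centers > max(grid)))
    stop_domain("channel centers must lie inside the grid span")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- outer(centers, grid, function(c, l) exp(-0.5 * ((l - c) / sigma)^2))
  w <- w / rowSums(w)
  structure(list(centers = centers, fwhm = fwhm, grid = grid, weights = w),
            class = "channel_responsivity")
}

#' Down-sample a spectrum to the sensor channels
#'
#' Each channel value is the responsivity-weighted average of the
#' 100-wavelength spectrum.
#'
#' @param spec A `drs_spectrum` on the responsivity grid, or an
#'   `n x length(grid)` matrix of spectra.
#' @param resp A [make_responsivity()] object.
#' @return A `drs_spectrum` on the channel centers, or an
#'   `n x length(centers)` matrix.
#' @export
downsample <- function(spec, resp) {
  if (inherits(spec, "drs_spectrum")) {
    if (length(spec$values) != length(resp$grid) ||
        max(abs(spec$wavelengths - resp$grid)) > 1e-9)
      stop_domain("spectrum grid does not match the responsivity grid")
    return(new_spectrum(resp$centers,
                        as.vector(resp$weights %*% spec$values)))
  }
  if (ncol(spec) != length(resp$grid))
    stop_domain("spectra matrix must have one column per grid wavelength")
  spec %*% t(resp$weights)
}

#' Generate the full simulated study dataset
#'
#' Builds the full factorial design of `levels` linearly spaced values per
#' physiological parameter over the study ranges, forward-models every
#' combination through the lookup table on the 100-wavelength grid, applies
#' multiplicative Gaussian noise, down-samples to the six sensor channels,
#' and draws a randomized train/test split. At the study scale (10 levels,
#' 100,000 rows) the split is 30,000 test rows and a 10,000-row training
#' subsample of the remaining 70,000; reduced designs scale the split
#' proportionally (30% test, 10% train) and record the scale in `meta`.
#'
#' Before synthesis the absorption and scattering envelopes of the design are
#' checked against the lookup-table axes; any parameter combination whose
#' coefficients leave the grid is reported as an error (never clamped).
#'
#' @param lut A [build_lut()] lookup table.
#' @param table A [load_chromophores()] table.
#' @param resp A [make_responsivity()] object.
#' @param sigma_rel Relative Gaussian noise level (default 0.01).
#' @param seed Master seed; noise and split use derived streams.
#' @param levels Grid levels per parameter (default 10; `levels^5` rows).
#' @param grid Wavelength grid.
#' @param keep_full Keep the `N x 100` spectra matrix in the result
#'   (`spectra100`); disable to save memory when only the six-channel data
#'   are needed.
#' @return A `drs_dataset`: list with `params` (data frame, columns `bvf`,
#'   `mus630`, `b`, `mel`, `so2`), `spectra100`, `spectra6`, `split`
#'   (factor: train/test/unused), `seed`, `meta`.
#' @export
generate_dataset <- function(lut, table, resp, sigma_rel = 0.01, seed = 1,
                             levels = 10, grid = spectral_grid(),
                             keep_full = TRUE) {
  rng <- param_ranges()
  lev <- lapply(rng, function(r) seq(r[1], r[2], length.out = levels))
  params <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE)
  names(params) <- param_names()
  n <- nrow(params)

  # envelope check against the LUT axes (unique optical-property combos)
  mua_env <- mua_matrix(unique(params[c("bvf", "mel", "so2")]), grid, table)
  musp_env <- musp_matrix(unique(params[c("mus630", "b")]), grid)
  bad_mua <- mua_env < min(lut$mua_axis) | mua_env > max(lut$mua_axis)
  bad_musp <- musp_env < min(lut$musp_axis) | musp_env > max(lut$musp_axis)
  if (any(bad_mua) || any(bad_musp))
    stop_domain("design not representable in the lookup table: ",
                sum(bad_mua), " absorption and ", sum(bad_musp),
                " scattering values fall outside the axes; ",
                "worst mua=", signif(max(mua_env), 4),
                ", worst musp=", signif(max(musp_env), 4), " cm^-1")

  clean <- forward_matrix(params, lut, table, grid)
  spectra100 <- add_noise(clean, sigma_rel, seed = derive_seed(seed, 101))
  spectra6 <- downsample(spectra100, resp)

  if (n >= 100000) { n_test <- 30000L; n_train <- 10000L }
  else { n_test <- max(1L, round(0.3 * n)); n_train <- max(1L, round(0.1 * n)) }
  idx <- with_seed(derive_seed(seed, 202), sample.int(n))
  test_idx <- idx[seq_len(n_test)]
  pool <- idx[-seq_len(n_test)]
  train_idx <- with_seed(derive_seed(seed, 303),
                         sample(pool, n_train, replace = FALSE))
  split <- rep("unused", n)
  split[test_idx] <- "test"
  split[train_idx] <- "train"

  structure(list(params = params,
                 spectra100 = if (keep_full) spectra100 else NULL,
                 spectra6 = spectra6,
                 split = factor(split, levels = c("train", "test", "unused")),
                 seed = as.integer(seed),
                 meta = list(levels = levels, n = n, sigma_rel = sigma_rel,
                             fwhm = resp$fwhm, n_train = n_train,
                             n_test = n_test,
                             grid = range(grid), n_wavelengths = length(grid))),
            class = "drs_dataset")
}

#' @export
print.drs_dataset <- function(x, ...) {
  cat(sprintf("simulated DRS dataset: %d spectra (%d levels^5), noise %.3g\n",
              x$meta$n, x$meta$levels, x$meta$sigma_rel))
  cat(sprintf("  split: %d train / %d test / %d unused, seed %d\n",
              sum(x$split == "train"), sum(x$split == "test"),
              sum(x$split == "unused"), x$seed))
  invisible(x)
}

#' Save / load a simulated dataset as delimited text
#'
#' Writes `<prefix>.tsv` with the parameter columns, six channel
#' reflectances (`r450` ... `r650`) and the split label, plus a JSON sidecar
#' `<prefix>.json` with seed, noise level and design metadata. The
#' 100-wavelength block, when present, goes to `<prefix>_full.tsv`.
#'
#' @param dataset A `drs_dataset`.
#' @param prefix Output path prefix.
#' @param full Also write the 100-wavelength matrix.
#' @return `prefix`, invisibly.
#' @export
write_dataset <- function(dataset, prefix, full = FALSE) {
  six <- as.data.frame(dataset$spectra6)
  names(six) <- paste0("r", channel_centers())
  out <- cbind(dataset$params, six, split = as.character(dataset$split))
  write.table(out, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(dataset$meta, list(seed = dataset$seed)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (full && !is.null(dataset$spectra100))
    write.table(dataset$spectra100, paste0(prefix, "_full.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  tab <- read.delim(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pn <- param_names()
  structure(list(params = tab[pn],
                 spectra100 = NULL,
                 spectra6 = as.matrix(tab[paste0("r", channel_centers())]),
                 split = factor(tab$split,
                                levels = c("train", "test", "unused")),
                 seed = as.integer(meta$seed),
                 meta = meta[setdiff(names(meta), "seed")]),
            class = "drs_dataset")
}
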