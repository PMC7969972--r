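#' Tissue physiological parameters
#'
#' Bundle the five physiological parameters that drive the forward model:
#' blood volume fraction, reduced scattering coefficient at 630 nm,
#' scattering power-law exponent, melanin concentration, and hemoglobin
#' oxygen saturation.
#'
#' @param bvf Blood volume fraction (dimensionless fraction, study range
#'   0.01-0.05).
#' @param mus630 Reduced scattering coefficient at 630 nm (cm^-1, study range
#'   10-30).
#' @param b Scattering power-law exponent (dimensionless, study range
#'   1.3-2.5).
#' @param mel Melanin concentration (mg/ml, study range 0-2).
#' @param so2 Oxygen saturation (dimensionless fraction, study range
#'   0.60-1.00).
#' @return An object of class `tissue_params` (a named list).
#' @examples
#' tissue_params(bvf = 0.02, mus630 = 20, b = 1.6, mel = 0.5, so2 = 0.9)
#' @export
tissue_params <- function(bvf, mus630, b, mel, so2) {
  vals <- c(bvf = bvf, mus630 = mus630, b = b, mel = mel, so2 = so2)
  if (!all(is.finite(vals)))
    stop_domain("all tissue parameters must be finite")
  if (bvf < 0 || mel < 0 || so2 < 0 || mus630 < 0)
    stop_domain("bvf, mus630, mel and so2 must be non-negative")
  if (so2 > 1)
    stop_domain("so2 is a fraction and must not exceed 1")
  structure(as.list(vals), class = "tissue_params")
}

#' Study parameter ranges
#'
#' The physiological ranges for skin tissue used to draw the simulation grid
#' and as default bounds for the inverse fit.
#'
#' @return A named list of `c(lower, upper)` pairs for `bvf`, `mus630`, `b`,
#'   `mel`, `so2`.
#' @export
param_ranges <- function() {
  list(bvf = c(0.01, 0.05), mus630 = c(10, 30), b = c(1.3, 2.5),
       mel = c(0, 2), so2 = c(0.60, 1.00))
}

#' Names of the five physiological parameters
#' @return Character vector `c("bvf", "mus630", "b", "mel", "so2")`.
#' @export
param_names <- function() c("bvf", "mus630", "b", "mel", "so2")

#' Load a chromophore absorption table
#'
#' Reads a wavelength-resolved table of whole-blood absorption (oxygenated
#' and deoxygenated, assuming 150 g/L total hemoglobin) and melanin
#' absorption per unit concentration. The packaged default
#' (`chromophores_synthetic.tsv`) is a synthetic compilation: sums of
#' Gaussian bands anchored at the canonical visible-band hemoglobin features
#' (Soret bands, oxy Q-bands at 542/577 nm, deoxy Q-band at 555 nm,
#' isosbestic crossings between 500 and 590 nm) with Soret amplitudes
#' compressed so that every study parameter combination stays inside the
#' lookup-table absorption domain, plus a `(lambda/550)^-3` melanin power
#' law.
#'
#' @param path Path to a tab-delimited file with header columns
#'   `wavelength_nm`, `mua_oxy_cm1`, `mua_deoxy_cm1`,
#'   `mel_ext_cm1_per_mg_ml`. Defaults to the packaged synthetic table.
#' @return A `chromophore_table`: data frame with the four columns above,
#'   wavelengths strictly ascending.
#' @export
load_chromophores <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chromophores_synthetic.tsv",
                        package = "drsml", mustWork = TRUE)
  tab <- read.delim(path, check.names = TRUE)
  need <- c("wavelength_nm", "mua_oxy_cm1", "mua_deoxy_cm1",
            "mel_ext_cm1_per_mg_ml")
  if (!all(need %in% names(tab)))
    stop_domain("chromophore table must have columns: ",
                paste(need, collapse = ", "))
  tab <- tab[need]
  if (any(diff(tab$wavelength_nm) <= 0))
    stop_domain("chromophore wavelengths must be strictly ascending")
  if (any(tab$mua_oxy_cm1 <= 0) || any(tab$mua_deoxy_cm1 <= 0) ||
      any(tab$mel_ext_cm1_per_mg_ml <= 0))
    stop_domain("chromophore coefficients must be positive")
  class(tab) <- c("chromophore_table", "data.frame")
  tab
}

chrom_interp <- function(table, column, lam) {
  w <- table$wavelength_nm
  if (any(lam < w[1]) || any(lam > w[length(w)]))
    stop_domain("wavelength outside chromophore table coverage [",
                w[1], ", ", w[length(w)], "] nm")
  stats::approx(w, table[[column]], xout = lam, method = "linear")$y
}

#' Reduced scattering coefficient at a wavelength
#'
#' Power-law scattering spectrum anchored at 630 nm:
#' `musp(lambda) = mus630 * (lambda/630)^(-b)`.
#'
#' @param params A [tissue_params()] object (only `mus630` and `b` are used).
#' @param lam Wavelength(s) in nm, within 410-650.
#' @return Reduced scattering coefficient(s), cm^-1.
#' @examples
#' musp_at(tissue_params(0.02, 10, 1.3, 0, 0.9), 630)  # == 10
#' @export
musp_at <- function(params, lam) {
  if (any(lam < 410) || any(lam > 650))
    stop_domain("wavelength outside the supported band [410, 650] nm")
  params$mus630 * (lam / 630)^(-params$b)
}

#' Absorption coefficient at a wavelength
#'
#' Linear chromophore combination:
#' `mua(lambda) = bvf * (so2 * mua_oxy + (1 - so2) * mua_deoxy) +
#' mel * mel_ext`, with table values linearly interpolated in wavelength.
#'
#' @param params A [tissue_params()] object.
#' @param lam Wavelength(s) in nm, inside the table grid.
#' @param table A [load_chromophores()] table.
#' @return Absorption coefficient(s), cm^-1.
#' @export
mua_at <- function(params, lam, table) {
  oxy <- chrom_interp(table, "mua_oxy_cm1", lam)
  deoxy <- chrom_interp(table, "mua_deoxy_cm1", lam)
  mel <- chrom_interp(table, "mel_ext_cm1_per_mg_ml", lam)
  params$bvf * (params$so2 * oxy + (1 - params$so2) * deoxy) +
    params$mel * mel
}

# Vectorised versions over an n-row parameter data.frame and an m-wavelength
# grid; return n x m matrices. Used by dataset generation and the inverse fit.
mua_matrix <- function(params_df, lam, table) {
  oxy <- chrom_interp(table, "mua_oxy_cm1", lam)
  deoxy <- chrom_interp(table, "mua_deoxy_cm1", lam)
  mel <- chrom_interp(table, "mel_ext_cm1_per_mg_ml", lam)
  blood <- outer(params_df$bvf * params_df$so2, oxy) +
    outer(params_df$bvf * (1 - params_df$so2), deoxy)
  blood + outer(params_df$mel, mel)
}

musp_matrix <- function(params_df, lam) {
  # mus630 * exp(-b * log(lam/630)), vectorised over rows and wavelengths
  params_df$mus630 * exp(outer(-params_df$b, log(lam / 630)))
}
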