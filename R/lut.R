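#' Default lookup-table axes
#'
#' 40 evenly spaced absorption coefficients over 0-50 cm^-1 and 40 evenly
#' spaced reduced scattering coefficients over 0-90 cm^-1. The scattering
#' axis extends beyond 50 cm^-1 because the study parameter envelope reaches
#' `30 * (410/630)^-2.5 = 87.9 cm^-1` at the blue end of the band; a 0-50
#' scattering grid could not represent its own forward model there.
#'
#' @param n Number of nodes per axis.
#' @param mua_max,musp_max Upper axis limits, cm^-1.
#' @return List with `mua` and `musp` numeric axes.
#' @export
default_lut_axes <- function(n = 40, mua_max = 50, musp_max = 90) {
  list(mua = seq(0, mua_max, length.out = n),
       musp = seq(0, musp_max, length.out = n))
}

#' Build the Monte Carlo lookup table
#'
#' Runs one seeded [simulate_reflectance()] per `(mua, musp)` grid node and
#' assembles the reflectance matrix with its per-node standard errors.
#' `musp = 0` nodes are stored as exact zeros without simulation: with no
#' scattering and a collimated launch, no photon returns to a separated
#' detector.
#'
#' @param mua_axis,musp_axis Ascending non-negative axes, cm^-1.
#' @param geom A [probe_geometry()].
#' @param cfg An [mc_config()]; `cfg$seed` fans out to one independent stream
#'   per node, so a rebuild with the same seed is bit-identical.
#' @param verbose Print progress every few rows.
#' @return A `drs_lut`: list with `mua_axis`, `musp_axis`, `reflectance`
#'   (rows index `mua`, columns index `musp`), `se`, and `meta`.
#' @export
build_lut <- function(mua_axis = default_lut_axes()$mua,
                      musp_axis = default_lut_axes()$musp,
                      geom = probe_geometry(), cfg = mc_config(),
                      verbose = FALSE) {
  if (any(diff(mua_axis) <= 0) || any(diff(musp_axis) <= 0))
    stop_domain("axes must be strictly ascending")
  if (mua_axis[1] < 0 || musp_axis[1] < 0)
    stop_domain("axes must be non-negative")
  nr <- length(mua_axis); nc <- length(musp_axis)
  refl <- matrix(0, nr, nc)
  se <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    if (musp_axis[j] == 0) next
    for (i in seq_len(nr)) {
      est <- simulate_reflectance(mua_axis[i], musp_axis[j], geom, cfg,
                                  stream = (j - 1L) * nr + (i - 1L))
      refl[i, j] <- est$value
      se[i, j] <- est$se
    }
    if (verbose && j %% 5 == 0)
      message(sprintf("lut build: column %d/%d", j, nc))
  }
  if (any(refl < 0 | refl > 1)) {
    bad <- which(refl < 0 | refl > 1, arr.ind = TRUE)
    stop_domain("reflectance outside [0, 1] at ", nrow(bad), " node(s), ",
                "first at mua=", mua_axis[bad[1, 1]],
                ", musp=", musp_axis[bad[1, 2]])
  }
  structure(list(mua_axis = mua_axis, musp_axis = musp_axis,
                 reflectance = refl, se = se,
                 meta = list(geometry = unclass(geom), config = unclass(cfg),
                             built = format(Sys.time(), tz = "UTC"))),
            class = "drs_lut")
}

#' @export
print.drs_lut <- function(x, ...) {
  cat(sprintf("Monte Carlo lookup table: %d x %d nodes\n",
              length(x$mua_axis), length(x$musp_axis)))
  cat(sprintf("  mua  axis: %.3g .. %.3g cm^-1\n",
              min(x$mua_axis), max(x$mua_axis)))
  cat(sprintf("  musp axis: %.3g .. %.3g cm^-1\n",
              min(x$musp_axis), max(x$musp_axis)))
  cat(sprintf("  photons/node: %d, seed %d\n",
              x$meta$config$n_photons, x$meta$config$seed))
  invisible(x)
}

# vectorised bilinear interpolation; mua and musp are equal-length vectors
bilinear <- function(axis_x, axis_y, z, x, y) {
  if (any(x < axis_x[1] - 1e-12) || any(x > axis_x[length(axis_x)] + 1e-12) ||
      any(y < axis_y[1] - 1e-12) || any(y > axis_y[length(axis_y)] + 1e-12))
    stop_domain("lookup-table query outside the grid (no extrapolation): ",
                "mua in [", axis_x[1], ", ", axis_x[length(axis_x)],
                "], musp in [", axis_y[1], ", ", axis_y[length(axis_y)], "]")
  i <- findInterval(x, axis_x, all.inside = TRUE)
  j <- findInterval(y, axis_y, all.inside = TRUE)
  tx <- (x - axis_x[i]) / (axis_x[i + 1] - axis_x[i])
  ty <- (y - axis_y[j]) / (axis_y[j + 1] - axis_y[j])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  nr <- length(axis_x)
  z00 <- z[cbind(i, j)]
  z10 <- z[cbind(i + 1, j)]
  z01 <- z[cbind(i, j + 1)]
  z11 <- z[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

#' Query the lookup table at arbitrary optical properties
#'
#' Bilinear interpolation over the `(mua, musp)` grid; exact at the nodes,
#' continuous across cell boundaries, no extrapolation.
#'
#' @param lut A [build_lut()] object.
#' @param mua,musp Query coordinates (vectors of equal length, cm^-1), inside
#'   the axis ranges.
#' @return Interpolated reflectance values.
#' @export
lut_reflectance <- function(lut, mua, musp) {
  if (length(mua) != length(musp) && length(mua) != 1 && length(musp) != 1)
    stop_domain("mua and musp must have matching lengths")
  n <- max(length(mua), length(musp))
  bilinear(lut$mua_axis, lut$musp_axis, lut$reflectance,
           rep_len(mua, n), rep_len(musp, n))
}

#' Save / load a lookup table
#'
#' The portable container is JSON holding both axes, the reflectance matrix,
#' the per-node standard errors and the build metadata (geometry,
#' configuration, seed).
#'
#' @param lut A `drs_lut`.
#' @param path Output file path.
#' @return `write_lut` returns `path` invisibly; `read_lut` returns the
#'   `drs_lut`.
#' @export
write_lut <- function(lut, path) {
  obj <- unclass(lut)
  # flatten matrices column-major; read_lut restores the dimensions
  obj$reflectance <- as.vector(obj$reflectance)
  obj$se <- as.vector(obj$se)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mua_axis <- as.numeric(obj$mua_axis)
  obj$musp_axis <- as.numeric(obj$musp_axis)
  obj$reflectance <- matrix(as.numeric(obj$reflectance),
                            length(obj$mua_axis), length(obj$musp_axis),
                            byrow = FALSE)
  obj$se <- matrix(as.numeric(obj$se), length(obj$mua_axis),
                   length(obj$musp_axis), byrow = FALSE)
  structure(obj, class = "drs_lut")
}

#' Export the lookup table as a long-format delimited table
#'
#' @param lut A `drs_lut`.
#' @param path Output TSV path.
#' @return `path`, invisibly. Columns: `mua`, `musp`, `R`, `se`.
#' @export
export_lut_table <- function(lut, path) {
  long <- expand.grid(mua = lut$mua_axis, musp = lut$musp_axis,
                      KEEP.OUT.ATTRS = FALSE)
  long$R <- as.vector(lut$reflectance)
  long$se <- as.vector(lut$se)
  # %.17g keeps every double bit-exact through the text round trip
  long[] <- lapply(long, function(x) sprintf("%.17g", x))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
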