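#' Fiber-probe geometry
#'
#' Geometry of the surface probe used to score detected reflectance: a source
#' aperture launching photons into the tissue and a detector aperture
#' collecting photons that re-emerge within its footprint and acceptance cone.
#' Defaults describe a chip-style multispectral detector rather than a
#' collection fiber: a 200 um radius source spot, a 300 um radius detector
#' window at 0.45 mm center-to-center separation, and no angular cut
#' (`numerical_aperture = n_above`), since a sensor die glued behind a window
#' accepts essentially every escaping angle. Wide-angle collection matters at
#' reduced photon budgets: a fiber-style NA of 0.22 would discard about 97
#' percent of the escaping light and multiply the per-node Monte Carlo noise
#' by roughly six, which would dominate the 1 percent measurement-noise
#' budget of the synthetic study. The separation balances two structural
#' identifiability regimes of a single-distance six-channel measurement
#' (see the methods vignette): shorter separations resolve the scattering
#' exponent but lose melanin; longer ones do the reverse. Pass a small
#' `numerical_aperture` to model a fiber probe instead.
#'
#' @param source_radius Source fiber radius, cm.
#' @param detector_radius Detector fiber radius, cm. `Inf` scores every exit
#'   location (used by energy-conservation checks).
#' @param center_separation Source-detector center separation, cm.
#' @param numerical_aperture Detector NA (dimensionless). Values `>= n_above`
#'   disable the angular cut.
#' @param n_tissue Tissue refractive index.
#' @param n_above Refractive index of the medium above the surface.
#' @return A `probe_geometry` object.
#' @export
probe_geometry <- function(source_radius = 0.02, detector_radius = 0.03,
                           center_separation = 0.045,
                           numerical_aperture = 1.45,
                           n_tissue = 1.4, n_above = 1.45) {
  if (source_radius <= 0 || (!is.infinite(detector_radius) && detector_radius <= 0))
    stop_domain("fiber radii must be positive")
  if (center_separation < 0) stop_domain("separation must be >= 0")
  if (numerical_aperture <= 0) stop_domain("numerical aperture must be > 0")
  if (n_tissue < 1 || n_above < 1) stop_domain("refractive indices must be >= 1")
  structure(list(source_radius = source_radius,
                 detector_radius = detector_radius,
                 center_separation = center_separation,
                 numerical_aperture = numerical_aperture,
                 n_tissue = n_tissue, n_above = n_above),
            class = "probe_geometry")
}

#' Monte Carlo configuration
#'
#' @param n_photons Photons launched per simulation.
#' @param g Scattering anisotropy (Henyey-Greenstein), in (-1, 1).
#' @param weight_threshold Photon weight below which Russian roulette starts.
#' @param roulette_survival Roulette survival probability.
#' @param seed Integer seed for the simulator's own RNG stream.
#' @param max_steps Scattering events after which an unbiased step-count
#'   roulette terminates very long walks (relevant only for non-absorbing
#'   media, where the weight never decays).
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_photons = 20000, g = 0.9, weight_threshold = 1e-4,
                      roulette_survival = 0.1, seed = 1, max_steps = 5000) {
  if (n_photons < 1) stop_domain("n_photons must be >= 1")
  if (g <= -1 || g >= 1) stop_domain("g must lie in (-1, 1)")
  if (weight_threshold <= 0 || weight_threshold >= 1)
    stop_domain("weight_threshold must lie in (0, 1)")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop_domain("roulette_survival must lie in (0, 1)")
  structure(list(n_photons = as.integer(n_photons), g = g,
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 seed = as.integer(seed), max_steps = max_steps),
            class = "mc_config")
}

#' Simulate probe reflectance at one optical-property pair
#'
#' Monte Carlo estimate of the detected diffuse reflectance for a
#' semi-infinite homogeneous medium: photons launched uniformly over the
#' source fiber face, propagated with Henyey-Greenstein scattering
#' (`mus = musp / (1 - g)` via the similarity relation), implicit-capture
#' absorption weighting with Russian roulette, Fresnel-weighted transmission
#' at the surface, and scoring of the transmitted weight that exits inside
#' the detector footprint within its acceptance cone. Specular reflection at
#' launch is excluded (photons start below the surface), so the estimate is a
#' diffuse reflectance.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, cm^-1. `musp = 0` returns 0
#'   without simulating (no scattering, nothing returns to the surface).
#' @param geom A [probe_geometry()].
#' @param cfg An [mc_config()].
#' @param stream Integer stream label mixed into the seed; used by
#'   [build_lut()] to give every grid node its own reproducible stream.
#' @return List with `value` (reflectance in `[0, 1]`), `se` (Monte Carlo
#'   standard error) and `n_photons`.
#' @export
simulate_reflectance <- function(mua, musp, geom = probe_geometry(),
                                 cfg = mc_config(), stream = 0) {
  if (mua < 0 || musp < 0) stop_domain("optical coefficients must be >= 0")
  est <- mc_reflectance_cpp(mua, musp, cfg$g, geom$source_radius,
                            geom$detector_radius, geom$center_separation,
                            geom$numerical_aperture, geom$n_tissue,
                            geom$n_above, cfg$n_photons,
                            cfg$weight_threshold, cfg$roulette_survival,
                            as.double(cfg$seed), as.double(stream),
                            cfg$max_steps)
  list(value = est[1], se = est[2], n_photons = cfg$n_photons)
}
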