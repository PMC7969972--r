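# Shared fixtures, built once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, envir = .fixture_env)
}

# Smooth analytic lookup table on the full axis ranges: monotone decreasing
# in mua, increasing in musp, values well inside [0, 1]. Exercises the
# interpolation, forward-model and inverse-fit plumbing without Monte Carlo
# noise, and makes exactness assertions meaningful.
analytic_lut <- function(n = 60) {
  memo(paste0("alut", n), function() {
    mua_axis <- seq(0, 50, length.out = n)
    musp_axis <- seq(0, 90, length.out = n)
    refl <- outer(mua_axis, musp_axis,
                  function(a, s) 0.05 * (s / (s + 15)) * exp(-a / 12))
    structure(list(mua_axis = mua_axis, musp_axis = musp_axis,
                   reflectance = refl, se = refl * 0,
                   meta = list(geometry = list(), config = list(
                     n_photons = NA, seed = NA), built = "analytic")),
              class = "drs_lut")
  })
}

# Small genuinely simulated lookup table (coarse axes, few photons) for
# tests that need real Monte Carlo output.
small_mc_lut <- function() {
  memo("mclut_small", function()
    drsml::build_lut(seq(0, 50, length.out = 8), seq(0, 90, length.out = 8),
                     cfg = drsml::mc_config(n_photons = 4000, seed = 42)))
}

chrom_table <- function() memo("chrom", function() drsml::load_chromophores())

default_resp <- function() memo("resp", function() drsml::make_responsivity())

# Reduced-design dataset (5 levels -> 3125 rows) over the analytic table.
small_dataset <- function(sigma_rel = 0.01, seed = 9) {
  memo(paste0("ds", sigma_rel, seed), function()
    drsml::generate_dataset(analytic_lut(), chrom_table(), default_resp(),
                            sigma_rel = sigma_rel, seed = seed, levels = 5))
}
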