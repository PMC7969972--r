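---
title: "Methods: simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical design of the `drsml`
simulation study: what is being modeled, which quantities are computed by
standard methods, and where the package makes choices that a reader should
know about before interpreting results. All chunks are `eval = FALSE`
because the full study takes tens of minutes; every command shown is the
one actually used.

## 1. The physical model

Skin-like tissue is modeled as a semi-infinite homogeneous turbid medium
described at each wavelength $\lambda$ by an absorption coefficient
$\mu_a(\lambda)$ and a reduced scattering coefficient $\mu_s'(\lambda)$,
both in cm$^{-1}$. Five physiological parameters generate these spectra:

* `bvf` — blood volume fraction (0.01–0.05),
* `mus630` — reduced scattering at 630 nm (10–30 cm$^{-1}$),
* `b` — scattering power-law exponent (1.3–2.5),
* `mel` — melanin concentration (0–2 mg/ml),
* `so2` — hemoglobin oxygen saturation (0.6–1.0),

via

$$\mu_s'(\lambda) = \mathrm{mus630}\,(\lambda/630)^{-b}, \qquad
\mu_a(\lambda) = \mathrm{bvf}\,[\mathrm{so2}\,\epsilon_{\mathrm{oxy}}(\lambda)
 + (1-\mathrm{so2})\,\epsilon_{\mathrm{deoxy}}(\lambda)]
 + \mathrm{mel}\,\epsilon_{\mathrm{mel}}(\lambda).$$

The chromophore spectra $\epsilon(\lambda)$ ship as a **synthetic**
compilation (`inst/extdata/chromophores_synthetic.tsv`, generated by
`tools/make_chromophores.R`): sums of Gaussian bands reproducing the
qualitative features of whole blood and melanin — Soret bands near 415 nm
(oxygenated) and 432 nm (deoxygenated), the oxygenated Q-band doublet at
542/577 nm against the single deoxygenated 555 nm band, isosbestic
crossings in the green, and a $\lambda^{-3}$ melanin decay. The Soret
amplitudes are compressed so that the most absorbing design combination
peaks at $\mu_a = 43.8$ cm$^{-1}$, inside the lookup-table domain. Real
extinction compilations are stronger and more structured in the blue;
absolute error levels reported by this package therefore depend on this
fixture and should not be quoted as properties of real tissue.

## 2. Monte Carlo transport and the lookup table

`simulate_reflectance()` is a weighted photon random walk implemented in
C++: Henyey–Greenstein scattering with anisotropy $g = 0.9$ under the
similarity relation $\mu_s = \mu_s'/(1-g)$, implicit-capture weighting,
Russian roulette below weight $10^{-4}$ (survival 0.1), Fresnel-weighted
partial transmission at the surface, and scoring of transmitted weight
that exits inside the detector footprint within its acceptance cone. The
per-node standard error is reported from the detected-weight variance.
Two oracle properties anchor the implementation: a non-absorbing matched
medium returns total reflectance exactly 1, and a naive analog
(non-weighted) simulator kept in the test suite agrees node-by-node
within combined standard errors.

The lookup table (`build_lut()`) is a 40×40 grid, bilinearly
interpolated, $\mu_a \in [0, 50]$ cm$^{-1}$ and $\mu_s' \in [0, 90]$
cm$^{-1}$. The $\mu_s'$ axis is wider than the $\mu_a$ axis because the
design itself demands it: `mus630 = 30` with `b = 2.5` gives
$\mu_s'(410) = 87.9$ cm$^{-1}$. Dataset generation refuses (rather than
clamps) any design point whose spectrum leaves the grid.

```{r lut}
library(drsml)
lut <- build_lut(cfg = mc_config(n_photons = 20000, seed = 1),
                 verbose = TRUE)   # ~3 minutes
```

## 3. Probe geometry: an identifiability-driven design

The probe geometry is the one part of the instrument that the package had
to design rather than copy, and it materially decides which parameters
are recoverable. The default —

```{r geom}
probe_geometry()
# source spot 200 um, detector window 300 um, separation 0.45 mm,
# no angular cut (chip-style detector), n_tissue 1.4 / n_above 1.45
```

— came out of an explicit sensitivity analysis, summarized here because
its trade-offs are scientifically interesting:

* **Collection efficiency.** A fiber-style numerical aperture of 0.22
  keeps only ~1–3% of escaping photons; at the reduced budget of
  $2\times10^4$ photons/node this pushes per-node Monte Carlo noise to
  10–24%, which swamps the study's 1% measurement noise and destroys the
  absorption parameters. A chip-style detector (no angular cut) brings
  per-node noise to ~2–3%.
* **Source–detector separation** sets the photon path length and thereby
  which parameters are identifiable from six broad channels. At touching
  separation (0.25 mm) the scattering tilt `b` is well conditioned
  (MAPE ≈ 9%) but melanin collapses (≈ 45%): the melanin absorption tilt
  is almost a linear combination of the scattering-tilt and
  blood-absorption responses (Jacobian collinearity $R^2 \approx
  0.97$–0.99). At 1 mm separation the roles reverse (melanin ≈ 4–5%,
  `b` ≈ 15%): long paths imprint absorption strongly, but the
  reflectance response to $\mu_s'$ flattens and the tilt information
  dies. These limits are structural — they survive noiseless spectra and
  a noise-free smoothed lookup table — so no estimator can undo them.
* The default separation of 0.45 mm sits on the short side of the
  crossover: it keeps the scattering exponent, blood volume fraction,
  scattering amplitude and oxygen saturation well conditioned and
  accepts that melanin is the sacrificed parameter at this instrument
  (its error is roughly three times the reference level). The reverse
  choice — melanin excellent, scattering exponent sacrificed — is one
  argument away (`center_separation = 0.1`). No setting of this
  instrument recovers both at once; see the limitations section.

A fiber probe remains one argument away
(`probe_geometry(numerical_aperture = 0.22, ...)`), and every result in
the package is reported relative to whichever lookup table was built.

## 4. Dataset synthesis

`generate_dataset()` walks the full $10^5$-point factorial design (10
levels per parameter), evaluates the forward model on a 100-wavelength
grid over 410–650 nm, adds 1% multiplicative Gaussian noise (floored at
zero), and integrates each spectrum against six Gaussian channel
responsivities (centers 450–650 nm, FWHM 40 nm, rows normalized to unit
sum). Splits are drawn by seeded sampling: 10,000 training and 30,000
test rows, disjoint. Every stage derives its RNG stream from one master
seed (`derive_seed()`), so the dataset is bit-reproducible.

```{r dataset}
tab <- load_chromophores()
resp <- make_responsivity()
ds <- generate_dataset(lut, tab, resp, sigma_rel = 0.01, seed = 1,
                       levels = 10)
```

## 5. The two inverse routes

**Lookup-table inversion** (`fit_spectrum()`): bound-constrained
least squares of the six measured channel values against the forward
model evaluated at the channel centers (`point_sample` mode; a
`weighted` mode integrates the model spectrum against the responsivities
instead). The optimizer is L-BFGS-B on unit-scaled parameters with an
analytic Jacobian assembled from the bilinear cell gradients, and five
multi-starts (the supplied/default start plus four seeded random
in-bounds starts). The returned fit never has a residual above the
residual of the starting point.

**Learned extractors** (`train_extractors()`): one regressor per
parameter on the six channels. Four families with framework-style
defaults: a two-hidden-layer 200-neuron rectifier network trained 10
epochs with ADADELTA ($\rho = 0.99$, $\epsilon = 10^{-8}$); a
50-tree random forest of depth 20; a 50-round depth-5 gradient-boosting
model; and an ordinary linear model. Features (and for the network the
target) are standardized on the training split for the network and the
linear model; tree families see raw features. Predictions are never
clipped. The network's batch size of 8 approximates the per-sample
update semantics of the reference deep-learning framework at tractable
cost: on the study dataset, batch 2 improves test MAPE by less than half
a point over batch 8 at four times the runtime, while batch 32 is
visibly undertrained after the fixed 10 epochs.

The deep-learning trainer is hand-written (`R/mlp.R`) because no neural
network framework is assumed at runtime; it is ~150 lines of
matrix algebra and is exercised by the same acceptance suite as
everything else.

## 6. Evaluation

`evaluate_predictions()` reports, per model and parameter: MAE, MAPE
(zero-truth rows — possible only for melanin — excluded and counted),
the 5×5 truth-versus-prediction Pearson crosstalk matrix, per-level win
rates against a reference model (strict improvement; ties are not
wins), and paired bootstrap confidence intervals on MAE differences
(shared resample indices across models, percentile intervals, at least
1,000 replicates). The bootstrap replaces a mixed-effects significance
analysis whose specification is not reproducible; it addresses the same
question — which model's errors are smaller — without guessing a
random-effects structure.

The lookup-table inverse is evaluated on a seeded 1,000-row subsample of
the test split (a nonlinear optimization per spectrum makes the full
30,000 rows cost ~45 minutes); the model-versus-inverse comparison is
made pairwise on exactly those rows.

## 7. Problem sizes and runtime

On a single CPU core: lookup table at $2\times10^4$ photons/node ≈ 3.5
minutes; dataset generation ≈ 1 minute; the four model families ≈ 3
minutes (the network dominates); 1,000 lookup-table inversions ≈ 4
minutes; evaluation with 2,000 bootstrap replicates < 1 minute.
`run_study()` chains all stages from one seed.

```{r study}
res <- run_study(seed = 1, photons_per_node = 20000, levels = 10)
print(res$report)
```

## 8. Limitations

* The chromophore fixture is synthetic; absolute errors depend on it.
* One homogeneous layer; no vascular packaging, no layered epidermis.
* The six-channel sensor is an idealized Gaussian-responsivity model;
  real sensor electronics (dark counts, quantization) are out of scope.
* The scattering-exponent/melanin trade-off described in §3 bounds what
  any extractor can do at a single source–detector separation; claims
  about one family "solving" a parameter should be read against that
  instrument limit.
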