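# Builds inst/extdata/chromophores_synthetic.tsv: a synthetic stand-in for a
# whole-blood (150 g/L hemoglobin) + melanin absorption compilation, modeled
# as sums of Gaussian bands anchored at well-known visible-band features
# (Soret bands near 415/432 nm, oxy Q-bands at 542/577 nm, deoxy Q-band at
# 555 nm, oxy-deoxy crossings in the 500-590 nm isosbestic region, deoxy >>
# oxy beyond 600 nm). The Soret amplitudes are compressed relative to real
# whole blood so that every parameter combination in the study design maps to
# an absorption coefficient inside the 0-50 cm^-1 lookup-table domain.
# Run from the repository root: Rscript tools/make_chromophores.R

grid <- seq(410, 650, length.out = 100)

gband <- function(lam, center, sigma) exp(-0.5 * ((lam - center) / sigma)^2)

mua_oxy <- function(lam) {
  560 * gband(lam, 415, 18) +
   70 * gband(lam, 495, 45) +
  235 * gband(lam, 542, 11) +
  255 * gband(lam, 577, 10) +
   55 * gband(lam, 560, 30) +
    1.5
}

mua_deoxy <- function(lam) {
  600 * gband(lam, 432, 19) +
   80 * gband(lam, 500, 45) +
  250 * gband(lam, 555, 16) +
   48 * gband(lam, 605, 50) +
    2.0
}

mel_ext <- function(lam) 3.0 * (lam / 550)^(-3)

tab <- data.frame(
  wavelength_nm = grid,
  mua_oxy_cm1 = mua_oxy(grid),
  mua_deoxy_cm1 = mua_deoxy(grid),
  mel_ext_cm1_per_mg_ml = mel_ext(grid)
)

# --- design checks -----------------------------------------------------------
stopifnot(all(tab$mua_oxy_cm1 > 0), all(tab$mua_deoxy_cm1 > 0),
          all(tab$mel_ext_cm1_per_mg_ml > 0))

# oxy and deoxy must cross inside the isosbestic region (500-590 nm)
d <- tab$mua_oxy_cm1 - tab$mua_deoxy_cm1
in_band <- tab$wavelength_nm >= 500 & tab$wavelength_nm <= 590
stopifnot(any(diff(sign(d[in_band])) != 0))

# worst-case mua over the full factorial envelope must stay below 50 cm^-1
worst <- pmax(0.05 * tab$mua_oxy_cm1, 0.05 * tab$mua_deoxy_cm1) +
  2 * tab$mel_ext_cm1_per_mg_ml
cat(sprintf("max envelope mua = %.2f cm^-1 at %.1f nm\n",
            max(worst), tab$wavelength_nm[which.max(worst)]))
stopifnot(max(worst) < 50)

out <- "inst/extdata/chromophores_synthetic.tsv"
write.table(format(tab, digits = 8, trim = TRUE), out, sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
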