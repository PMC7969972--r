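# Independent analog (non-weighted) Monte Carlo oracle. Every random event
# is sampled outright: absorption kills the photon with probability mua/mut
# at each collision, the surface reflects or transmits the whole photon by a
# Fresnel draw, and a detected photon scores 1. No implicit capture, no
# roulette, R's own RNG. Vectorised over photons. Used to cross-check the
# weighted production simulator at a few lookup-table nodes.
analog_reflectance <- function(mua, musp, geom = drsml::probe_geometry(),
                               g = 0.9, n_photons = 50000, seed = 1,
                               max_iter = 20000) {
  mus <- musp / (1 - g)
  mut <- mua + mus
  p_abs <- mua / mut
  na_cut <- geom$numerical_aperture < geom$n_above
  set.seed(seed)

  n <- n_photons
  r0 <- geom$source_radius * sqrt(runif(n))
  phi0 <- 2 * pi * runif(n)
  px <- r0 * cos(phi0); py <- r0 * sin(phi0); pz <- rep(0, n)
  ux <- rep(0, n); uy <- rep(0, n); uz <- rep(1, n)
  alive <- rep(TRUE, n)
  detected <- 0L

  fresnel_r <- function(ci, n1, n2) {
    ci <- pmin(ci, 1)
    si <- sqrt(pmax(0, 1 - ci^2))
    st <- n1 / n2 * si
    R <- rep(1, length(ci))
    ok <- st < 1
    ct <- sqrt(pmax(0, 1 - st[ok]^2))
    rs <- (n1 * ci[ok] - n2 * ct) / (n1 * ci[ok] + n2 * ct)
    rp <- (n1 * ct - n2 * ci[ok]) / (n1 * ct + n2 * ci[ok])
    R[ok] <- 0.5 * (rs^2 + rp^2)
    near <- si < 1e-9
    R[near] <- ((n1 - n2) / (n1 + n2))^2
    R
  }

  iter <- 0
  while (any(alive) && iter < max_iter) {
    iter <- iter + 1
    ia <- which(alive)
    m <- length(ia)
    s <- -log(runif(m)) / mut

    cross <- uz[ia] < 0 & pz[ia] + uz[ia] * s < 0
    ic <- ia[cross]
    if (length(ic)) {
      db <- -pz[ic] / uz[ic]
      px[ic] <- px[ic] + ux[ic] * db
      py[ic] <- py[ic] + uy[ic] * db
      pz[ic] <- 0
      ci <- -uz[ic]
      R <- fresnel_r(ci, geom$n_tissue, geom$n_above)
      refl <- runif(length(ic)) < R
      # transmitted photons: score if inside detector footprint and cone
      it <- ic[!refl]
      if (length(it)) {
        hit <- (px[it] - geom$center_separation)^2 + py[it]^2 <=
          geom$detector_radius^2
        if (na_cut) {
          si <- sqrt(pmax(0, 1 - uz[it]^2))
          hit <- hit & (geom$n_tissue * si <= geom$numerical_aperture)
        }
        detected <- detected + sum(hit)
        alive[it] <- FALSE
      }
      # reflected photons: flip and finish the remaining substep
      ir <- ic[refl]
      if (length(ir)) {
        rs_rem <- (s[cross])[refl] - db[refl]
        uz[ir] <- -uz[ir]
        px[ir] <- px[ir] + ux[ir] * rs_rem
        py[ir] <- py[ir] + uy[ir] * rs_rem
        pz[ir] <- pz[ir] + uz[ir] * rs_rem
      }
    }
    im <- ia[!cross]
    if (length(im)) {
      sm <- s[!cross]
      px[im] <- px[im] + ux[im] * sm
      py[im] <- py[im] + uy[im] * sm
      pz[im] <- pz[im] + uz[im] * sm
    }

    # collision for photons still alive: absorb or scatter
    ia <- which(alive)
    if (!length(ia)) break
    dead <- runif(length(ia)) < p_abs
    alive[ia[dead]] <- FALSE
    is <- ia[!dead]
    if (length(is)) {
      u1 <- runif(length(is))
      if (abs(g) < 1e-6) ct <- 2 * u1 - 1
      else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
        ct <- pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
      }
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- 2 * pi * runif(length(is))
      cph <- cos(phi); sph <- sin(phi)
      uzs <- uz[is]; uxs <- ux[is]; uys <- uy[is]
      vertical <- abs(uzs) > 0.99999
      den <- sqrt(pmax(1e-12, 1 - uzs^2))
      nux <- ifelse(vertical, st * cph,
                    st * (uxs * uzs * cph - uys * sph) / den + uxs * ct)
      nuy <- ifelse(vertical, st * sph,
                    st * (uys * uzs * cph + uxs * sph) / den + uys * ct)
      nuz <- ifelse(vertical, ct * sign(uzs), -st * cph * den + uzs * ct)
      ux[is] <- nux; uy[is] <- nuy; uz[is] <- nuz
    }
  }
  p <- detected / n
  list(value = p, se = sqrt(p * (1 - p) / n))
}
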