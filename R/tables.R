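# Embedded physics tables.
#
# Water mass-attenuation coefficients (cm^2/g) on a 50-2300 keV support:
# total (with coherent) for building mu maps, and the photoelectric component
# used by the photon Monte Carlo (Compton is computed from the Klein-Nishina
# cross section and the electron density of water, 3.343e23 e-/g).

.water_mu_energies_keV <- c(50, 60, 80, 100, 150, 200, 300, 400, 500, 600,
                            800, 1000, 1250, 1500, 2000, 2300)

# NIST-style total mass attenuation of liquid water, cm^2/g
.water_mu_total <- c(0.2269, 0.2059, 0.1837, 0.1707, 0.1505, 0.1370,
                     0.1186, 0.1061, 0.0969, 0.0896, 0.0786, 0.0707,
                     0.0632, 0.0575, 0.0494, 0.0462)

# photoelectric component of the above (negligible above ~300 keV)
.water_mu_photo <- c(4.37e-3, 2.41e-3, 9.63e-4, 4.78e-4, 1.28e-4, 5.10e-5,
                     1.40e-5, 5.80e-6, 3.00e-6, 1.80e-6, 8.0e-7, 4.5e-7,
                     2.7e-7, 1.9e-7, 1.1e-7, 9.0e-8)

#' Mass-attenuation coefficient of water
#'
#' Log-log interpolation of the embedded water table.
#'
#' @param energy_keV photon energy, must lie in [50, 2300] keV.
#' @param component "total" (with coherent) or "photoelectric".
#' @return cm^2/g at the requested energy.
#' @export
water_mass_attenuation <- function(energy_keV, component = c("total", "photoelectric")) {
  component <- match.arg(component)
  if (any(energy_keV < 50 | energy_keV > 2300))
    stop("water_mass_attenuation: energy outside tabulated range [50, 2300] keV")
  tab <- if (component == "total") .water_mu_total else .water_mu_photo
  exp(stats::approx(log(.water_mu_energies_keV), log(tab),
                    xout = log(energy_keV))$y)
}

# Klein-Nishina total cross section per electron, cm^2; k = E/m_e c^2
kn_total_cross_section <- function(energy_keV) {
  re <- 2.8179403e-13 # classical electron radius, cm
  k <- energy_keV / 511.0
  t <- 1 + 2 * k
  2 * pi * re^2 * ((1 + k) / k^2 * (2 * (1 + k) / t - log(t) / k) +
                     log(t) / (2 * k) - (1 + 3 * k) / t^2)
}

# Compton mass attenuation of water from Klein-Nishina, cm^2/g
water_compton_mass_mu <- function(energy_keV) {
  3.343e23 * kn_total_cross_section(energy_keV)
}

#' 90Y bremsstrahlung emission spectrum
#'
#' Thick-target analytic shape I(E) proportional to (Emax - E)/E on
#' [50, 2280] keV, tabulated at 1 keV and normalised. This is the photon
#' emission model behind the continuous bremsstrahlung spectrum that extends
#' to the beta endpoint; 90Y has no gamma line, so the whole acquisition
#' window is fed by this continuum and its downscatter.
#'
#' @param e_min_keV,e_max_keV tabulation support (defaults 50 and 2280 keV).
#' @param step_keV tabulation step.
#' @return object of class `brems_spectrum` with `energies_keV`,
#'   `intensities` (sum 1) and `cdf`.
#' @export
brems_spectrum <- function(e_min_keV = 50, e_max_keV = 2280, step_keV = 1) {
  e <- seq(e_min_keV, e_max_keV, by = step_keV)
  w <- (e_max_keV - e) / e
  w[w < 0] <- 0
  w <- w / sum(w)
  structure(list(energies_keV = e, intensities = w, cdf = cumsum(w)),
            class = "brems_spectrum")
}

#' Sample photon energies from a tabulated spectrum
#'
#' Inverse-CDF sampling over the discrete table.
#'
#' @param spec a `brems_spectrum` (or any list with `energies_keV`, `cdf`).
#' @param n number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return numeric vector of energies in keV.
#' @export
sample_spectrum <- function(spec, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, spec$cdf) + 1L
    idx[idx > length(spec$energies_keV)] <- length(spec$energies_keV)
    spec$energies_keV[idx]
  })
}

#' 90Y beta-decay kinetic-energy spectrum
#'
#' Allowed-transition (Fermi) shape N(E) ~ p * E_tot * (Q - E)^2 * F(Z, E)
#' with a non-relativistic Coulomb factor for the Z = 40 daughter, tabulated
#' at 10 keV steps up to the 2.28 MeV endpoint. The derived mean energy is
#' close to the accepted 0.93-0.94 MeV for 90Y.
#'
#' @param step_MeV tabulation step (default 0.01 MeV).
#' @return object of class `beta_spectrum` with `energies_MeV`, `intensities`
#'   (sum 1), `cdf` and `mean_MeV`.
#' @export
beta_spectrum <- function(step_MeV = 0.01) {
  q <- 2.28; me <- 0.510999; z <- 40; alpha <- 1 / 137.036
  e <- seq(step_MeV, q, by = step_MeV)
  etot <- e + me
  p <- sqrt(pmax(etot^2 - me^2, 0))
  beta <- p / etot
  eta <- z * alpha / pmax(beta, 1e-6)
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  w <- p * etot * (q - e)^2 * fermi
  w <- w / sum(w)
  structure(list(energies_MeV = e, intensities = w, cdf = cumsum(w),
                 mean_MeV = sum(w * e)),
            class = "beta_spectrum")
}

#' Sample 90Y beta kinetic energies
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param spec optionally a precomputed [beta_spectrum()].
#' @return energies in MeV, all <= 2.28.
#' @export
sample_beta_spectrum <- function(n, seed, spec = beta_spectrum()) {
  stopifnot(n >= 1)
  with_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, spec$cdf) + 1L
    idx[idx > length(spec$energies_MeV)] <- length(spec$energies_MeV)
    spec$energies_MeV[idx]
  })
}
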