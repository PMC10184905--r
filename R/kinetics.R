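#' Local environment seen by a cell
#'
#' Bundle the local nutrient concentrations (kg/m^3) and the global inducer
#' level (mM) into a validated list. All concentration arguments may be
#' vectors (recycled to a common length), which is how the simulation driver
#' evaluates kinetics per voxel.
#'
#' @param light,co2,o2,sucrose local concentrations, kg/m^3, `>= 0`.
#' @param iptg inducer concentration, mM, `>= 0`. The inducer is a global
#'   per-simulation scalar, not a diffusing field.
#' @return A list of class `local_env`.
#' @examples
#' local_env(light = 0.1, co2 = 0.03)
#' @export
local_env <- function(light = 0, co2 = 0, o2 = 0, sucrose = 0, iptg = 0) {
  vals <- list(light = light, co2 = co2, o2 = o2, sucrose = sucrose,
               iptg = iptg)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("'", nm, "' must be numeric and >= 0")
    }
  }
  structure(vals, class = "local_env")
}

# Coefficients of the empirical inducer-response terms.
# Growth attenuation: factor = a * exp(-iptg / tau) + b  (dimensionless)
.iptg_growth <- c(a = 0.141, tau = 0.063, b = 0.9)
# Secretion: psi = mu * (A * exp(-iptg / tau) + B), clamped at zero
.iptg_secretion <- c(A = -3.4897, tau = 0.048, B = 3.4092)

iptg_growth_factor <- function(iptg, coef = .iptg_growth) {
  coef[["a"]] * exp(-iptg / coef[["tau"]]) + coef[["b"]]
}

iptg_secretion_factor <- function(iptg, coef = .iptg_secretion) {
  coef[["A"]] * exp(-iptg / coef[["tau"]]) + coef[["B"]]
}

#' Cyanobacterial specific growth rate
#'
#' Monod growth on light and CO2, attenuated by an empirical inducer-response
#' term describing the metabolic burden of expressing the sucrose-secretion
#' machinery:
#' \deqn{\mu = \mu_{max} \frac{[light]}{K_{light}+[light]}
#'   \frac{[CO_2]}{K_{CO_2}+[CO_2]} (0.141 e^{-[IPTG]/0.063} + 0.9)}
#' The inducer factor ranges from 1.041 (uninduced) down to 0.9 (full
#' induction), so \eqn{0 \le \mu \le 1.041\,\mu_{max}}.
#'
#' @param env a [local_env()] (fields `light`, `co2`, `iptg` used).
#' @param p [species_params()] for the cyanobacterium.
#' @return Specific growth rate, 1/s (vectorized over `env` concentrations).
#' @examples
#' p <- species_params("cyanobacterium")
#' growth_rate_cyano(local_env(light = 0.1, co2 = 0.03), p)  # ~1.952e-5
#' @export
growth_rate_cyano <- function(env, p) {
  stopifnot(inherits(env, "local_env"))
  if (p$species_id != "cyanobacterium") {
    stop("growth_rate_cyano() needs cyanobacterium parameters")
  }
  p$mu_max * monod(env$light, p$K_light) * monod(env$co2, p$K_CO2) *
    iptg_growth_factor(env$iptg)
}

#' Sucrose secretion flux
#'
#' Specific metabolic flux diverted to extracellular sucrose, proportional to
#' the growth rate with an empirical inducer response:
#' \deqn{\Psi = \mu\,(-3.4897 e^{-[IPTG]/0.048} + 3.4092)}
#' The raw factor is slightly negative for near-zero inducer; negative
#' secretion (sucrose uptake by the phototroph) is not part of the model, so
#' the flux is clamped at zero with a one-time warning.
#'
#' @param mu specific growth rate, 1/s, `>= 0`.
#' @param iptg inducer level, mM, `>= 0`.
#' @return Secretion flux Psi, 1/s, `>= 0` (vectorized).
#' @examples
#' secretion_flux_cyano(1.687e-5, iptg = 1)   # ~5.75e-5
#' secretion_flux_cyano(1e-5, iptg = 0)       # clamps to 0
#' @export
secretion_flux_cyano <- function(mu, iptg) {
  if (any(mu < 0)) stop("mu must be >= 0")
  if (any(iptg < 0)) stop("iptg must be >= 0")
  raw <- mu * iptg_secretion_factor(iptg)
  if (any(raw < 0 & mu > 0)) {
    warning("secretion factor negative at low inducer; flux clamped to 0",
            call. = FALSE)
  }
  pmax(raw, 0)
}

#' Heterotrophic specific growth rate
#'
#' Double-Monod growth on sucrose and oxygen:
#' \deqn{\mu = \mu_{max} \frac{[sucrose]}{K_{sucrose}+[sucrose]}
#'   \frac{[O_2]}{K_{O_2}+[O_2]}}
#'
#' @param env a [local_env()] (fields `sucrose`, `o2` used).
#' @param p [species_params()] for the heterotroph.
#' @return Specific growth rate, 1/s (vectorized).
#' @examples
#' p <- species_params("heterotroph")
#' growth_rate_hetero(local_env(sucrose = 3.6, o2 = 9e-3), p)
#' @export
growth_rate_hetero <- function(env, p) {
  stopifnot(inherits(env, "local_env"))
  if (p$species_id != "heterotroph") {
    stop("growth_rate_hetero() needs heterotroph parameters")
  }
  p$mu_max * monod(env$sucrose, p$K_sucrose) * monod(env$o2, p$K_O2)
}

monod <- function(S, K) S / (K + S)

#' Cyanobacterial source/sink terms
#'
#' Volumetric nutrient production (`R > 0`) and consumption (`R < 0`) rates
#' for a local cyanobacterial biomass density `rho`:
#' \deqn{R_{CO_2} = -\frac{1}{Y}(\mu+\Psi)\rho,\quad
#'       R_{O_2} = +\frac{0.727}{Y}(\mu+\Psi)\rho,\quad
#'       R_{sucrose} = +\frac{0.65}{Y}\Psi\rho}
#' The light sink (same form as CO2) is computed for completeness but is
#' never applied by the driver: light is a fixed, non-depletable field.
#'
#' @param mu growth rate 1/s; @param psi secretion flux 1/s.
#' @param rho local biomass density kg/m^3 (= fg/um^3 numerically).
#' @param p cyanobacterium [species_params()].
#' @return list of class `rate_set` with elements `co2`, `o2`, `sucrose`,
#'   `light` (all kg m^-3 s^-1, vectorized).
#' @examples
#' consumption_terms_cyano(1.687e-5, 5.753e-5, rho = 100,
#'                         species_params("cyanobacterium"))
#' @export
consumption_terms_cyano <- function(mu, psi, rho, p) {
  if (any(rho < 0)) stop("rho must be >= 0")
  Y <- p$yield_Y
  structure(list(
    co2     = -(1 / Y) * (mu + psi) * rho,
    o2      = +(0.727 / Y) * (mu + psi) * rho,
    sucrose = +(0.65 / Y) * psi * rho,
    light   = -(1 / Y) * (mu + psi) * rho   # computed, never applied
  ), class = "rate_set")
}

#' Heterotrophic source/sink terms
#'
#' \deqn{R_{sucrose} = -\frac{1}{Y}\mu\rho,\quad
#'       R_{O_2} = -0.399(\mu+m)\rho,\quad
#'       R_{CO_2} = +0.2(\mu+m)\rho}
#' where `m` is the cellular maintenance coefficient: respiration (O2 sink,
#' CO2 source) continues even when growth stalls.
#'
#' @inheritParams consumption_terms_cyano
#' @param p heterotroph [species_params()].
#' @return list of class `rate_set` with elements `co2`, `o2`, `sucrose`.
#' @examples
#' consumption_terms_hetero(3.02e-5, rho = 50, species_params("heterotroph"))
#' @export
consumption_terms_hetero <- function(mu, rho, p) {
  if (any(rho < 0)) stop("rho must be >= 0")
  m <- p$maintenance_m
  structure(list(
    co2     = +0.2 * (mu + m) * rho,
    o2      = -0.399 * (mu + m) * rho,
    sucrose = -(1 / p$yield_Y) * mu * rho
  ), class = "rate_set")
}
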