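#' Species parameter sets
#'
#' Construct the per-species physical and growth constants used throughout the
#' simulator. Defaults are the measured/literature values for the two members
#' of the consortium: a sucrose-secreting cyanobacterium (*S. elongatus*-type,
#' `"cyanobacterium"`) and a sucrose-consuming heterotroph (*E. coli*-type,
#' `"heterotroph"`).
#'
#' Units follow the simulator conventions: rates 1/s, concentrations and
#' affinity constants kg/m^3, lengths and diameters micrometres, densities
#' fg/um^3 (numerically equal to g/L), biomass femtograms.
#'
#' @param species `"cyanobacterium"` or `"heterotroph"`.
#' @param ... named overrides of any default field (e.g. `mu_max = 2e-5`).
#'
#' @return An object of class `species_params`: a list with fields
#'   `species_id`, `mu_max`, `yield_Y`, `K_light`, `K_CO2`, `K_sucrose`,
#'   `K_O2`, `maintenance_m`, `length_min`, `length_max`, `diameter`,
#'   `veq_diameter_min`, `veq_diameter_max`, `density`.
#'
#' @examples
#' p <- species_params("cyanobacterium")
#' p$mu_max                      # 1.89e-5 1/s
#' species_params("heterotroph", mu_max = 1e-4)$mu_max
#' @export
species_params <- function(species = c("cyanobacterium", "heterotroph"), ...) {
  species <- match.arg(species)
  defaults <- .species_defaults[[species]]
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown species parameter(s): ", paste(bad, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  validate_species_params(structure(defaults, class = "species_params"))
}

# Physical (Table-1-type) and growth (Table-2-type) constants.
# maintenance_m applies to the heterotroph only; the cyanobacterium has no
# maintenance term in its model. Affinity constants not used by a species'
# growth law are NA.
.species_defaults <- list(
  cyanobacterium = list(
    species_id = "cyanobacterium",
    mu_max = 1.89e-5,          # 1/s
    yield_Y = 0.55,            # g-dw per g-CO2
    K_light = 3.5e-4,          # kg/m^3
    K_CO2 = 1.38e-4,           # kg/m^3
    K_sucrose = NA_real_,
    K_O2 = NA_real_,
    maintenance_m = 0,
    length_min = 2.5,          # um (rod form; recorded, unused for spheres)
    length_max = 5,
    diameter = 1,              # um rod diameter
    veq_diameter_min = 1.37,   # um volume-equivalent sphere
    veq_diameter_max = 1.94,
    density = 370              # fg/um^3 == g/L
  ),
  heterotroph = list(
    species_id = "heterotroph",
    mu_max = 6.71e-5,
    yield_Y = 0.43,            # g-dw per g-sucrose
    K_light = NA_real_,
    K_CO2 = NA_real_,
    K_sucrose = 3.6,           # kg/m^3
    K_O2 = 1e-3,               # kg/m^3
    maintenance_m = 9.5e-7,    # 1/s
    length_min = 1.6,
    length_max = 4,
    diameter = 0.8,
    veq_diameter_min = 0.88,
    veq_diameter_max = 1.39,
    density = 230
  )
)

validate_species_params <- function(p) {
  stopifnot(p$species_id %in% c("cyanobacterium", "heterotroph"))
  pos <- c("mu_max", "yield_Y", "density", "veq_diameter_min",
           "veq_diameter_max", "diameter")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("species parameter '", f, "' must be > 0")
    }
  }
  for (f in c("K_light", "K_CO2", "K_sucrose", "K_O2")) {
    if (!is.na(p[[f]]) && p[[f]] <= 0) {
      stop("affinity constant '", f, "' must be > 0")
    }
  }
  if (p$yield_Y > 1) stop("yield_Y must lie in (0, 1]")
  if (p$maintenance_m < 0) stop("maintenance_m must be >= 0")
  if (p$veq_diameter_min >= p$veq_diameter_max) {
    stop("veq_diameter_min must be < veq_diameter_max")
  }
  p
}

#' @export
#' @method print species_params
print.species_params <- function(x, ...) {
  cat("Species parameters:", x$species_id, "\n")
  cat(sprintf("  mu_max      %.4g 1/s   yield Y %.3g\n", x$mu_max, x$yield_Y))
  ks <- c(K_light = x$K_light, K_CO2 = x$K_CO2,
          K_sucrose = x$K_sucrose, K_O2 = x$K_O2)
  ks <- ks[!is.na(ks)]
  cat("  affinities  ",
      paste(sprintf("%s=%.3g", names(ks), ks), collapse = "  "), " kg/m^3\n")
  if (x$maintenance_m > 0) {
    cat(sprintf("  maintenance %.3g 1/s\n", x$maintenance_m))
  }
  cat(sprintf("  sphere diameter %.3g-%.3g um, density %.4g fg/um^3\n",
              x$veq_diameter_min, x$veq_diameter_max, x$density))
  invisible(x)
}

#' Default nutrient table
#'
#' Default bulk concentrations, boundary conditions and aqueous diffusion
#' coefficients for the four nutrient fields. Light and the dissolved gases
#' are held at the chamber boundary (Dirichlet: an optically transparent,
#' gas-permeable microfluidic chamber); sucrose can only leave by consumption
#' (zero-flux Neumann walls). Light is a fixed, non-depletable field and has
#' no diffusion coefficient.
#'
#' @return A data.frame with columns `nutrient`, `concentration` (kg/m^3),
#'   `bc_type` (`"dirichlet"`/`"neumann"`), `D` (m^2/s, NA for light).
#' @examples
#' nutrient_defaults()
#' @export
nutrient_defaults <- function() {
  data.frame(
    nutrient = c("light", "co2", "o2", "sucrose"),
    concentration = c(1e-1, 3e-2, 9e-3, 1e-20),
    bc_type = c("dirichlet", "dirichlet", "dirichlet", "neumann"),
    D = c(NA_real_, 1.9e-9, 2.3e-9, 5.2e-10),
    stringsAsFactors = FALSE
  )
}

#' Full default parameter configuration
#'
#' @return A list with elements `cyanobacterium`, `heterotroph` (both
#'   [species_params()]) and `nutrients` (the [nutrient_defaults()] table).
#' @export
default_params <- function() {
  list(
    cyanobacterium = species_params("cyanobacterium"),
    heterotroph = species_params("heterotroph"),
    nutrients = nutrient_defaults()
  )
}

#' Read a parameter configuration from YAML
#'
#' Reads a structured YAML file with optional `cyanobacterium`,
#' `heterotroph` and `nutrients` sections and merges it over the defaults.
#' The shipped default config (`system.file("extdata",
#' "default_params.yaml", package = "consortsim")`) carries the default
#' parameter tables verbatim.
#'
#' @param path YAML file path.
#' @return A parameter list as from [default_params()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- default_params()
  for (sp in c("cyanobacterium", "heterotroph")) {
    if (!is.null(cfg[[sp]])) {
      out[[sp]] <- do.call(species_params, c(list(species = sp), cfg[[sp]]))
    }
  }
  if (!is.null(cfg$nutrients)) {
    nut <- out$nutrients
    for (nm in names(cfg$nutrients)) {
      i <- match(nm, nut$nutrient)
      if (is.na(i)) stop("unknown nutrient in config: ", nm)
      entry <- cfg$nutrients[[nm]]
      for (f in names(entry)) {
        if (!f %in% c("concentration", "bc_type", "D")) {
          stop("unknown nutrient field in config: ", f)
        }
        nut[[f]][i] <- entry[[f]]
      }
    }
    out$nutrients <- nut
  }
  out
}
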