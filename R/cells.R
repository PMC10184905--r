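#' @useDynLib consortsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sphere mass/diameter conversions
#'
#' Cells are spheres of fixed species density, so mass (fg) and
#' volume-equivalent diameter (um) are interchangeable:
#' `mass = density * (pi/6) * diameter^3`.
#'
#' @param diameter diameter, um.
#' @param mass mass, fg.
#' @param density fg/um^3.
#' @return Mass in fg, or diameter in um.
#' @examples
#' mass_from_diameter(1.94, 370)   # largest cyanobacterium, ~1414.5 fg
#' @export
mass_from_diameter <- function(diameter, density) {
  density * (pi / 6) * diameter^3
}

#' @rdname mass_from_diameter
#' @export
diameter_from_mass <- function(mass, density) {
  (6 * mass / (pi * density))^(1 / 3)
}

#' Seeding specification
#'
#' Describes the initial condition of a simulation: how many founder cells of
#' each species to scatter uniformly in the domain box, the inducer level,
#' and the RNG seed that makes the seeding (and the whole trajectory)
#' reproducible.
#'
#' @param n_cyano,n_hetero founder cell counts (either may be 0, not both).
#' @param iptg inducer level, mM.
#' @param rng_seed integer seed.
#' @param domain box (Lx, Ly, Lz), um.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(n_cyano, n_hetero, iptg = 0, rng_seed = 1,
                      domain = c(100, 100, 10)) {
  stopifnot(n_cyano >= 0, n_hetero >= 0, n_cyano + n_hetero >= 1,
            iptg >= 0, length(domain) == 3, all(domain > 0))
  structure(list(n_cyano = as.integer(n_cyano),
                 n_hetero = as.integer(n_hetero),
                 iptg = iptg, rng_seed = as.integer(rng_seed),
                 domain = domain),
            class = "seed_spec")
}

#' Seed a simulation with founder cells
#'
#' Places `n_cyano + n_hetero` founder cells uniformly at random in the
#' domain box, with initial volume-equivalent diameters drawn uniformly
#' between each species' size bounds and masses derived from the species
#' density. Placements that overlap an already-placed cell are rejected and
#' re-drawn; each founder is its own colony (`founder_id = id`).
#'
#' @param spec a [seed_spec()].
#' @param params parameter list from [default_params()].
#' @param max_retries re-draws allowed per cell before a seeding error.
#' @return A cell table: data.frame with columns `id`, `species`,
#'   `founder_id`, `x`, `y`, `z`, `mass` (fg), `diameter` (um),
#'   `birth_time` (s).
#' @examples
#' cells <- seed_simulation(seed_spec(5, 5, rng_seed = 42))
#' nrow(cells)
#' @export
seed_simulation <- function(spec, params = default_params(),
                            max_retries = 200) {
  stopifnot(inherits(spec, "seed_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_cyano + spec$n_hetero
  species <- c(rep("cyanobacterium", spec$n_cyano),
               rep("heterotroph", spec$n_hetero))
  d <- numeric(n)
  for (sp in unique(species)) {
    p <- params[[sp]]
    k <- species == sp
    d[k] <- stats::runif(sum(k), p$veq_diameter_min, p$veq_diameter_max)
  }
  dens <- vapply(species, function(sp) params[[sp]]$density, numeric(1))
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- stats::runif(3) * spec$domain
      if (i == 1) { placed <- TRUE }
      else {
        dd <- sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        placed <- all(dd >= (d[seq_len(i - 1)] + d[i]) / 2)
      }
      if (placed) { pos[i, ] <- cand; break }
    }
    if (!placed) stop("seeding failed: could not place cell ", i,
                      " without overlap after ", max_retries, " retries")
  }
  data.frame(
    id = seq_len(n), species = species, founder_id = seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    mass = mass_from_diameter(d, dens), diameter = d,
    birth_time = 0, stringsAsFactors = FALSE
  )
}

#' Grow cells over one biological step
#'
#' Exact exponential mass update for a constant per-cell growth rate over
#' the step: `m <- m * exp(mu * dt)`; diameters are recomputed from mass.
#'
#' @param cells cell table (see [seed_simulation()]).
#' @param mu per-cell specific growth rates, 1/s (recycled if scalar).
#' @param dt step, s.
#' @param params parameter list (for densities).
#' @return Updated cell table.
#' @export
grow_cells <- function(cells, mu, dt, params = default_params()) {
  stopifnot(dt > 0, all(mu >= 0))
  cells$mass <- cells$mass * exp(mu * dt)
  dens <- ifelse(cells$species == "cyanobacterium",
                 params$cyanobacterium$density, params$heterotroph$density)
  cells$diameter <- diameter_from_mass(cells$mass, dens)
  cells
}

#' Divide cells that reached the division size
#'
#' Any cell whose volume-equivalent diameter reached its species' maximum is
#' split into two daughters with mass fractions `f` and `1 - f`,
#' `f ~ Uniform(0.45, 0.55)` (a stochastic near-even split avoids artificial
#' division synchrony). Daughters are placed along a uniformly random
#' direction with centres separated by the sum of their radii, clamped to
#' the domain box, and inherit the parent's colony label (`founder_id`).
#' Total mass is conserved exactly.
#'
#' @param cells cell table.
#' @param params parameter list.
#' @param domain box (Lx, Ly, Lz), um.
#' @param time current simulation time, s (daughters' `birth_time`).
#' @return Updated cell table (possibly with more rows).
#' @export
divide_cells <- function(cells, params = default_params(),
                         domain = c(100, 100, 10), time = 0) {
  dmax <- ifelse(cells$species == "cyanobacterium",
                 params$cyanobacterium$veq_diameter_max,
                 params$heterotroph$veq_diameter_max)
  k <- which(cells$diameter >= dmax)
  if (!length(k)) return(cells)
  parent <- cells[k, , drop = FALSE]
  dens <- ifelse(parent$species == "cyanobacterium",
                 params$cyanobacterium$density, params$heterotroph$density)
  f <- stats::runif(length(k), 0.45, 0.55)
  m1 <- parent$mass * f
  m2 <- parent$mass - m1
  d1 <- diameter_from_mass(m1, dens)
  d2 <- diameter_from_mass(m2, dens)
  # uniform random direction
  u <- matrix(stats::rnorm(3 * length(k)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sep <- (d1 + d2) / 2
  off1 <- -u * sep / 2
  off2 <- +u * sep / 2
  clamp <- function(v, L) pmin(pmax(v, 0), L)
  a <- parent; b <- parent
  a$mass <- m1; a$diameter <- d1
  b$mass <- m2; b$diameter <- d2
  a$x <- clamp(parent$x + off1[, 1], domain[1])
  a$y <- clamp(parent$y + off1[, 2], domain[2])
  a$z <- clamp(parent$z + off1[, 3], domain[3])
  b$x <- clamp(parent$x + off2[, 1], domain[1])
  b$y <- clamp(parent$y + off2[, 2], domain[2])
  b$z <- clamp(parent$z + off2[, 3], domain[3])
  a$birth_time <- time
  b$birth_time <- time
  b$id <- max(cells$id) + seq_along(k)
  out <- rbind(cells[-k, , drop = FALSE], a, b)
  rownames(out) <- NULL
  out
}

#' Resolve overlaps between cells
#'
#' Iteratively displaces every overlapping sphere pair along its centre line
#' by half the overlap each (a simple shoving relaxation), with positions
#' clamped to the domain box, until the largest overlap falls below `tol` or
#' the pass budget is exhausted. Uses a uniform-grid neighbour search, so
#' cost is near-linear in cell count.
#'
#' @param cells cell table.
#' @param domain box (Lx, Ly, Lz), um.
#' @param tol overlap tolerance, um.
#' @param max_pass maximum relaxation passes.
#' @return Updated cell table with attributes `passes` and `max_overlap`.
#' @export
relax_overlaps <- function(cells, domain = c(100, 100, 10), tol = 1e-3,
                           max_pass = 50) {
  if (nrow(cells) < 2) return(cells)
  res <- relax_overlaps_cpp(cells$x, cells$y, cells$z, cells$diameter / 2,
                            as.numeric(domain), tol, as.integer(max_pass))
  cells$x <- res$x
  cells$y <- res$y
  cells$z <- res$z
  attr(cells, "passes") <- res$passes
  attr(cells, "max_overlap") <- res$max_overlap
  cells
}

#' Write a cell table to CSV
#'
#' @param cells cell table; @param path file path; @param time time stamp, s.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, time = NA_real_) {
  out <- cbind(time = time, cells)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
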