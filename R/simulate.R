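#' Simulation configuration
#'
#' Bundles the driver settings. Defaults reflect the study conditions: a
#' 100 x 100 x 10 um chamber, runs of up to 100 h stopped early once total
#' biomass reaches 1.5e7 fg (so the volume never fills), and a 600 s
#' biological step, which is much shorter than the ~10 h division timescale
#' so the per-step exponential growth update is essentially exact.
#'
#' @param domain box (Lx, Ly, Lz), um; each dimension must be a multiple of
#'   `h`.
#' @param h voxel edge for the nutrient grids, um.
#' @param dt_bio biological time step, s.
#' @param t_max maximum simulated time, s.
#' @param biomass_cap total-biomass stop threshold, fg.
#' @param output_interval trajectory recording interval, s.
#' @param iptg inducer level, mM (used when no [seed_spec()] is supplied).
#' @param rng_seed seed (used when initial cells are supplied directly).
#' @param field_tol relative tolerance for quasi-steady field relaxation.
#' @param max_field_iters sweep budget per relaxation.
#' @param relax_max_pass overlap-relaxation pass budget per step.
#' @param relax_tol overlap tolerance for the per-step mechanical
#'   relaxation, um. The default (5e-3 um, well under 1% of a cell
#'   diameter) is below mechanical relevance; tighter tolerances make
#'   shoving cascades in dense colonies disproportionately expensive.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(domain = c(100, 100, 10), h = 2,
                              dt_bio = 600, t_max = 100 * 3600,
                              biomass_cap = 1.5e7,
                              output_interval = 600, iptg = 0,
                              rng_seed = 1, field_tol = 1e-6,
                              max_field_iters = 50, relax_max_pass = 50,
                              relax_tol = 5e-3) {
  stopifnot(dt_bio > 0, t_max > 0, biomass_cap > 0, h > 0,
            length(domain) == 3)
  if (any(abs(domain / h - round(domain / h)) > 1e-9)) {
    stop("domain dimensions must be positive multiples of the voxel size h")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Run the individual-based consortium simulation
#'
#' Orchestrates the coupled loop for one simulation: per biological step the
#' driver (1) bins cells into voxels and accumulates per-species biomass
#' density, (2) evaluates growth and secretion kinetics at the current local
#' concentrations to obtain per-voxel source/sink terms, (3) brings the
#' dissolved-gas fields to their quasi-steady diffusion balance and
#' time-integrates sucrose (whose zero-flux walls plus net secretion admit
#' no steady state), (4) re-evaluates growth rates at the relaxed
#' concentrations and grows every cell exponentially over the step,
#' (5) divides cells that reached their division diameter, and (6) relaxes
#' cell-cell overlaps. The run stops at `t_max` or when total biomass
#' reaches `biomass_cap`, whichever comes first.
#'
#' @param config a [simulation_config()].
#' @param spec a [seed_spec()]; its `iptg` and `domain` override the
#'   config's. If `NULL`, `init_cells` must be given.
#' @param params parameter list from [default_params()].
#' @param init_cells optional explicit initial cell table (bypasses
#'   seeding).
#' @return An object of class `consortium_sim` with elements:
#'   `trajectory` (data.frame: `time_s`, `time_h`, `biomass_cyano`,
#'   `biomass_hetero`, `n_cyano`, `n_hetero`, `mean_sucrose`, `ratio` =
#'   heterotroph:cyanobacterium biomass), `cells_final`, `cells_initial`,
#'   `stop_reason` (`"t_max"` or `"biomass_cap"`), `iptg`, `config`,
#'   `params`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(t_max = 2 * 3600)
#' sim <- simulate_consortium(cfg, seed_spec(5, 5, iptg = 1, rng_seed = 1))
#' print(sim)
#' }
#' @export
simulate_consortium <- function(config = simulation_config(), spec = NULL,
                                params = default_params(),
                                init_cells = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  domain <- config$domain
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "seed_spec"))
    if (!isTRUE(all.equal(spec$domain, domain))) {
      stop("seed_spec domain must match the simulation domain")
    }
    iptg <- spec$iptg
    cells <- seed_simulation(spec, params)
  } else {
    if (is.null(init_cells)) stop("provide a seed_spec or init_cells")
    set.seed(config$rng_seed)
    iptg <- config$iptg
    cells <- init_cells
  }
  cells0 <- cells

  nut <- params$nutrients
  mkfield <- function(nm) {
    i <- match(nm, nut$nutrient)
    nutrient_field(nm, domain = domain, h = config$h, D = nut$D[i],
                   bc_type = nut$bc_type[i], bc_value = nut$concentration[i],
                   initial_value = nut$concentration[i])
  }
  co2 <- mkfield("co2")
  o2 <- mkfield("o2")
  sucrose <- mkfield("sucrose")
  light_conc <- nut$concentration[match("light", nut$nutrient)]
  dims <- co2$dims
  nvox <- prod(dims)
  vol_vox <- config$h^3                    # um^3; fg/um^3 == kg/m^3

  pc <- params$cyanobacterium
  ph <- params$heterotroph

  # stability cap on the biological step: the operator splitting evaluates
  # consumption from step-start rates, so the per-step mass turnover
  # (mu + Psi) * dt must stay small or fast growers consume more through
  # growth than the fields are debited. Inactive at the default parameters
  # (cap ~2300 s > default 600 s); engages for growth-rate sweeps.
  rate_scale <- max(
    pc$mu_max * 1.041 * (1 + max(0, iptg_secretion_factor(iptg))),
    ph$mu_max + ph$maintenance_m)
  dt_bio <- min(config$dt_bio, 0.2 / rate_scale)
  n_sub <- ceiling(config$dt_bio / dt_bio)
  dt_bio <- config$dt_bio / n_sub

  voxel_of <- function(cells) {
    ix <- pmin.int(dims[1], pmax.int(1L, as.integer(cells$x / config$h) + 1L))
    iy <- pmin.int(dims[2], pmax.int(1L, as.integer(cells$y / config$h) + 1L))
    iz <- pmin.int(dims[3], pmax.int(1L, as.integer(cells$z / config$h) + 1L))
    ix + dims[1] * (iy - 1L) + dims[1] * dims[2] * (iz - 1L)
  }

  t <- 0
  next_out <- 0
  rec <- list()
  rec_i <- 0L
  record <- function(t) {
    cy <- cells$species == "cyanobacterium"
    b_c <- sum(cells$mass[cy])
    b_h <- sum(cells$mass[!cy])
    rec_i <<- rec_i + 1L
    rec[[rec_i]] <<- c(time_s = t, biomass_cyano = b_c, biomass_hetero = b_h,
                       n_cyano = sum(cy), n_hetero = sum(!cy),
                       mean_sucrose = mean(sucrose$grid),
                       ratio = if (b_c > 0) b_h / b_c else NA_real_)
  }
  record(0)
  next_out <- config$output_interval
  stop_reason <- "t_max"

  while (t < config$t_max - 1e-9) {
    vix <- voxel_of(cells)
    cy <- cells$species == "cyanobacterium"

    # per-voxel biomass density by species (kg/m^3)
    rho_c <- rho_h <- numeric(nvox)
    if (any(cy)) {
      s <- rowsum(cells$mass[cy], vix[cy])
      rho_c[as.integer(rownames(s))] <- s / vol_vox
    }
    if (any(!cy)) {
      s <- rowsum(cells$mass[!cy], vix[!cy])
      rho_h[as.integer(rownames(s))] <- s / vol_vox
    }
    occ_c <- which(rho_c > 0)
    occ_h <- which(rho_h > 0)

    # Kinetics at the step-start concentrations drive the field updates,
    # and cells then grow at exactly the rates (and limiter scalings) that
    # debited the fields, so nutrient bookkeeping is closed: consumption
    # uses the effective per-step rate (e^(mu dt) - 1)/dt, making the
    # sucrose a voxel loses exactly Y^-1 times the biomass its cells gain,
    # and where the solver scales sinks back to keep a voxel non-negative
    # the cells' growth is reduced by the same factor.
    mu_vox_c <- mu_vox_h <- numeric(nvox)
    exp_rate <- function(mu) expm1(mu * dt_bio) / dt_bio
    R_co2 <- R_o2 <- numeric(nvox)
    R_suc_prod <- R_suc_cons <- numeric(nvox)
    if (length(occ_c)) {
      env_c <- local_env(light = rep(light_conc, length(occ_c)),
                         co2 = co2$grid[occ_c], iptg = iptg)
      mu_c <- growth_rate_cyano(env_c, pc)
      mu_vox_c[occ_c] <- mu_c
      psi_c <- suppressWarnings(secretion_flux_cyano(mu_c, iptg))
      psi_eff <- ifelse(mu_c > 0, psi_c * exp_rate(mu_c) / mu_c, 0)
      Rc <- consumption_terms_cyano(exp_rate(mu_c), psi_eff,
                                    rho_c[occ_c], pc)
      R_co2[occ_c] <- R_co2[occ_c] + Rc$co2
      R_o2[occ_c] <- R_o2[occ_c] + Rc$o2
      R_suc_prod[occ_c] <- Rc$sucrose
    }
    if (length(occ_h)) {
      env_h <- local_env(sucrose = sucrose$grid[occ_h],
                         o2 = o2$grid[occ_h], iptg = iptg)
      mu_h <- growth_rate_hetero(env_h, ph)
      mu_vox_h[occ_h] <- mu_h
      Rh <- consumption_terms_hetero(exp_rate(mu_h), rho_h[occ_h], ph)
      R_co2[occ_h] <- R_co2[occ_h] + Rh$co2
      R_o2[occ_h] <- R_o2[occ_h] + Rh$o2
      R_suc_cons[occ_h] <- Rh$sucrose
    }
    co2 <- solve_to_quasi_steady(co2, array(R_co2, dims),
                                 tol = config$field_tol,
                                 max_iters = config$max_field_iters)
    o2 <- solve_to_quasi_steady(o2, array(R_o2, dims),
                                tol = config$field_tol,
                                max_iters = config$max_field_iters)
    sc_co2 <- as.numeric(attr(co2, "sink_scale"))
    # secretion scales with any CO2 limitation before entering the field
    sucrose <- advance_field(sucrose,
                             array(R_suc_prod * sc_co2 + R_suc_cons, dims),
                             dt = dt_bio)
    sc_suc <- as.numeric(attr(sucrose, "sink_scale"))

    # grow each cell at the (possibly limiter-reduced) rate its voxel was
    # debited at: scale acts on the per-step mass gain e^(mu dt) - 1
    scale_cell <- ifelse(cy, sc_co2[vix], sc_suc[vix])
    mu_raw <- ifelse(cy, mu_vox_c[vix], mu_vox_h[vix])
    mu_cell <- log1p(scale_cell * expm1(mu_raw * dt_bio)) / dt_bio
    cells <- grow_cells(cells, mu_cell, dt_bio, params)
    cells <- divide_cells(cells, params, domain, time = t + dt_bio)
    cells <- relax_overlaps(cells, domain, tol = config$relax_tol,
                            max_pass = config$relax_max_pass)

    t <- t + dt_bio
    if (t >= next_out - 1e-9 || t >= config$t_max - 1e-9) {
      record(t)
      next_out <- next_out + config$output_interval
    }
    if (sum(cells$mass) >= config$biomass_cap) {
      if (rec[[rec_i]][["time_s"]] < t) record(t)
      stop_reason <- "biomass_cap"
      break
    }
  }

  traj <- as.data.frame(do.call(rbind, rec))
  traj$time_h <- traj$time_s / 3600
  traj <- traj[, c("time_s", "time_h", "biomass_cyano", "biomass_hetero",
                   "n_cyano", "n_hetero", "mean_sucrose", "ratio")]
  structure(list(trajectory = traj, cells_final = cells,
                 cells_initial = cells0, stop_reason = stop_reason,
                 iptg = iptg, config = config, params = params,
                 spec = spec),
            class = "consortium_sim")
}

#' @export
#' @method print consortium_sim
print.consortium_sim <- function(x, ...) {
  tr <- x$trajectory
  n <- nrow(tr)
  cat(sprintf("<consortium_sim> %.1f h simulated, stopped by %s\n",
              tr$time_h[n], x$stop_reason))
  cat(sprintf("  IPTG %.3g mM; founders %d cyano + %d hetero\n", x$iptg,
              sum(x$cells_initial$species == "cyanobacterium"),
              sum(x$cells_initial$species == "heterotroph")))
  cat(sprintf("  final biomass %.3g fg (%d cells); hetero:cyano ratio %.3g\n",
              tr$biomass_cyano[n] + tr$biomass_hetero[n],
              nrow(x$cells_final), tr$ratio[n]))
  invisible(x)
}

#' @export
#' @method summary consortium_sim
summary.consortium_sim <- function(object, ...) {
  tr <- object$trajectory
  n <- nrow(tr)
  out <- list(
    time_h = tr$time_h[n], stop_reason = object$stop_reason,
    iptg = object$iptg,
    biomass_cyano = tr$biomass_cyano[n],
    biomass_hetero = tr$biomass_hetero[n],
    n_cells = nrow(object$cells_final),
    final_ratio = tr$ratio[n],
    peak_mean_sucrose = max(tr$mean_sucrose),
    final_mean_sucrose = tr$mean_sucrose[n],
    time_to_steady_h = time_to_steady_state(object)
  )
  class(out) <- "summary.consortium_sim"
  out
}

#' @export
#' @method print summary.consortium_sim
print.summary.consortium_sim <- function(x, ...) {
  cat(sprintf("Consortium simulation: %.1f h (%s), IPTG %.3g mM\n",
              x$time_h, x$stop_reason, x$iptg))
  cat(sprintf("  biomass: cyano %.3g fg, hetero %.3g fg (%d cells)\n",
              x$biomass_cyano, x$biomass_hetero, x$n_cells))
  cat(sprintf("  hetero:cyano ratio %.3g; steady after %.1f h\n",
              x$final_ratio, x$time_to_steady_h))
  cat(sprintf("  mean sucrose: peak %.3g, final %.3g kg/m^3\n",
              x$peak_mean_sucrose, x$final_mean_sucrose))
  invisible(x)
}

#' @export
#' @method plot consortium_sim
plot.consortium_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tr$time_h, cbind(tr$biomass_cyano, tr$biomass_hetero),
                    type = "l", lty = 1, lwd = 2,
                    col = c("darkgreen", "tan3"),
                    xlab = "time (h)", ylab = "biomass (fg)", log = "y", ...)
  graphics::legend("bottomright", c("cyanobacterium", "heterotroph"),
                   col = c("darkgreen", "tan3"), lwd = 2, bty = "n")
  graphics::plot(tr$time_h, tr$mean_sucrose, type = "l", lwd = 2,
                 xlab = "time (h)", ylab = "mean sucrose (kg/m^3)")
  invisible(x)
}

#' Time for the population ratio to reach steady state
#'
#' Finds the first time after which the heterotroph:cyanobacterium biomass
#' ratio stays within `+- tol_frac` of its final value, where the final
#' value is the mean ratio over the trailing `window_h` hours. Returns `NA`
#' (with attribute `reached = FALSE`) if the ratio is still drifting at the
#' end of the trajectory or is undefined.
#'
#' @param x a `consortium_sim` or a trajectory data.frame with columns
#'   `time_h` and `ratio`.
#' @param tol_frac tolerance band around the final ratio (default 5%).
#' @param window_h trailing window used to define the final value, h.
#' @return Time in hours, or `NA` if steady state was not reached.
#' @examples
#' tr <- data.frame(time_h = 0:5, ratio = c(1, 1, 1, 2, 2, 2))
#' time_to_steady_state(tr, window_h = 2)   # 3
#' @export
time_to_steady_state <- function(x, tol_frac = 0.05, window_h = 5) {
  tr <- if (inherits(x, "consortium_sim")) x$trajectory else x
  if (is.null(tr) || nrow(tr) == 0) stop("empty trajectory")
  t <- tr$time_h
  r <- tr$ratio
  ok <- is.finite(r)
  if (!any(ok)) {
    return(structure(NA_real_, reached = FALSE))
  }
  t <- t[ok]; r <- r[ok]
  n <- length(r)
  ref <- mean(r[t >= t[n] - window_h])
  if (!is.finite(ref) || ref == 0) {
    dev <- abs(r - ref) > tol_frac          # absolute band around zero ratio
  } else {
    dev <- abs(r - ref) > tol_frac * abs(ref)
  }
  k <- which(dev)
  if (!length(k)) return(structure(t[1], reached = TRUE))
  last_dev <- max(k)
  if (last_dev >= n) return(structure(NA_real_, reached = FALSE))
  structure(t[last_dev + 1], reached = TRUE)
}

#' Run metadata as JSON-ready list
#'
#' @param sim a `consortium_sim`.
#' @return List with stop criterion, seeds and package version.
#' @export
run_metadata <- function(sim) {
  list(stop_reason = sim$stop_reason,
       iptg = sim$iptg,
       rng_seed = if (!is.null(sim$spec)) sim$spec$rng_seed
                  else sim$config$rng_seed,
       simulated_hours = max(sim$trajectory$time_h),
       package_version = as.character(utils::packageVersion("consortsim")))
}
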