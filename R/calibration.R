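# Calibration of the inducer-dependent growth and secretion terms by
# parameter recovery on synthetic time series. The generator emulates a
# well-stirred batch culture under saturating light and CO2: every cell
# grows exponentially at the inducer-attenuated rate and secreted sucrose
# accumulates in the medium, with run-to-run stochasticity from the random
# initial cell sizes (the same stochasticity the individual-based model
# has at seeding).

#' Simulate a well-mixed batch culture
#'
#' Fast closed-form surrogate for an axenic phototroph culture: `n0` cells
#' with random initial sizes grow exponentially at
#' \eqn{\mu = \mu_{max} f_{light} f_{CO_2} g(IPTG)} and divert the
#' secretion flux \eqn{\Psi = \mu s(IPTG)} to extracellular sucrose, so
#' cumulative sucrose is `(0.65/Y) * s * (B(t) - B(0))`.
#'
#' @param iptg inducer level, mM.
#' @param times_h sampling times, hours.
#' @param n0 initial cell count.
#' @param params parameter list ([default_params()]).
#' @param growth_coef named vector `(a, tau, b)` of the inducer growth
#'   factor `a * exp(-iptg/tau) + b`.
#' @param secretion_coef named vector `(A, tau, B)` of the secretion factor
#'   `A * exp(-iptg/tau) + B` (clamped at 0).
#' @param light,co2 bulk concentrations, kg/m^3.
#' @param seed RNG seed for the initial size draw.
#' @return data.frame with columns `time_h`, `biomass` (fg), `sucrose`
#'   (cumulative secreted mass, fg).
#' @export
simulate_batch_culture <- function(iptg, times_h, n0 = 50,
                                   params = default_params(),
                                   growth_coef = NULL,
                                   secretion_coef = NULL,
                                   light = 1e-1, co2 = 3e-2, seed = 1) {
  p <- params$cyanobacterium
  if (is.null(growth_coef)) growth_coef <- .iptg_growth
  if (is.null(secretion_coef)) secretion_coef <- .iptg_secretion
  set.seed(seed)
  d0 <- stats::runif(n0, p$veq_diameter_min, p$veq_diameter_max)
  B0 <- sum(mass_from_diameter(d0, p$density))
  mu <- p$mu_max * monod(light, p$K_light) * monod(co2, p$K_CO2) *
    iptg_growth_factor(iptg, coef = growth_coef)
  sfac <- max(0, iptg_secretion_factor(iptg, coef = secretion_coef))
  B <- B0 * exp(mu * times_h * 3600)
  suc <- (0.65 / p$yield_Y) * sfac * (B - B0)
  data.frame(time_h = times_h, biomass = B, sucrose = suc)
}

#' Generate synthetic calibration curves
#'
#' Builds observation tables for the two calibration observables (biomass
#' or sucrose time series across inducer levels) from known generating
#' coefficients, with optional multiplicative lognormal noise.
#'
#' @param observable `"biomass_timeseries"` or `"sucrose_timeseries"`.
#' @param iptg_levels inducer conditions, mM.
#' @param times_h sampling times, hours.
#' @param noise_frac multiplicative noise coefficient of variation
#'   (0 = noiseless).
#' @param seed RNG seed.
#' @inheritParams simulate_batch_culture
#' @return A `calibration_target`: list with `observable` and `data`
#'   (data.frame `condition`, `time_h`, `value`).
#' @export
synthesize_curves <- function(observable = c("biomass_timeseries",
                                             "sucrose_timeseries"),
                              iptg_levels = c(0.01, 0.025, 0.05, 0.1,
                                              0.25, 1),
                              times_h = seq(0, 24, by = 3),
                              growth_coef = NULL, secretion_coef = NULL,
                              n0 = 50, noise_frac = 0, seed = 1,
                              params = default_params()) {
  observable <- match.arg(observable)
  rows <- lapply(seq_along(iptg_levels), function(i) {
    sim <- simulate_batch_culture(iptg_levels[i], times_h, n0 = n0,
                                  params = params,
                                  growth_coef = growth_coef,
                                  secretion_coef = secretion_coef,
                                  seed = seed + i)
    val <- if (observable == "biomass_timeseries") sim$biomass else sim$sucrose
    data.frame(condition = iptg_levels[i], time_h = times_h, value = val)
  })
  data <- do.call(rbind, rows)
  if (noise_frac > 0) {
    set.seed(seed + 1000)
    data$value <- data$value * exp(stats::rnorm(nrow(data), 0, noise_frac))
  }
  calibration_target(observable, data)
}

#' @rdname synthesize_curves
#' @param data data.frame with columns `condition`, `time_h`, `value`.
#' @export
calibration_target <- function(observable, data) {
  stopifnot(all(c("condition", "time_h", "value") %in% names(data)),
            all(data$time_h >= 0))
  for (cond in unique(data$condition)) {
    tt <- data$time_h[data$condition == cond]
    if (is.unsorted(tt, strictly = FALSE)) {
      stop("times must be increasing within each condition")
    }
  }
  structure(list(observable = observable, data = data),
            class = "calibration_target")
}

# Relative sum-of-squared residuals between a simulated batch-culture
# prediction (averaged over n_replicates stochastic replicates with fixed
# seeds: common random numbers keep the objective deterministic) and the
# observed curves. Biomass curves are normalized by their initial value
# (fold growth over inoculum), which removes the latent random inoculum
# size from the comparison; sucrose curves are compared on their absolute
# scale, relative to the condition's mean level.
.calibration_loss <- function(target, growth_coef, secretion_coef,
                              n_replicates, seed, n0, params) {
  obs <- target$data
  biomass <- target$observable == "biomass_timeseries"
  total <- 0
  for (cond in unique(obs$condition)) {
    sub <- obs[obs$condition == cond, ]
    sims <- sapply(seq_len(n_replicates), function(r) {
      sim <- simulate_batch_culture(cond, sub$time_h, n0 = n0,
                                    params = params,
                                    growth_coef = growth_coef,
                                    secretion_coef = secretion_coef,
                                    seed = seed + 7 * r)
      if (biomass) sim$biomass else sim$sucrose
    })
    pred <- rowMeans(sims)
    val <- sub$value
    if (biomass && sub$time_h[1] == 0 && val[1] > 0) {
      pred <- pred / pred[1]
      val <- val / val[1]
    }
    scale <- ifelse(val != 0, abs(val), mean(abs(val)) + 1e-30)
    total <- total + sum(((pred - val) / scale)^2)
  }
  total
}

#' Two-step calibration of growth and secretion terms
#'
#' Sequential bounded minimization mirroring the model's fitting procedure:
#' step 1 fits the growth-side coefficients to biomass time series, step 2
#' fits the secretion-side coefficients to sucrose time series with the
#' step-1 result frozen. Every objective evaluation averages
#' `n_replicates` stochastic batch-culture simulations (random initial cell
#' sizes) with fixed per-replicate seeds, so the objective is deterministic
#' given `seed`. The optimizer is seeded bounded Nelder-Mead (out-of-bounds
#' proposals are penalized); it is deliberately black-box so it can be
#' swapped for any other derivative-free minimizer.
#'
#' @param growth_target a `calibration_target` with
#'   `observable = "biomass_timeseries"`.
#' @param sucrose_target a `calibration_target` with
#'   `observable = "sucrose_timeseries"`.
#' @param growth_init,secretion_init named starting vectors `(a, tau, b)` /
#'   `(A, tau, B)`.
#' @param growth_bounds,secretion_bounds list with `lower`/`upper` named
#'   vectors.
#' @param n_replicates stochastic replicates averaged per evaluation.
#' @param budget function-evaluation budget per step.
#' @param seed RNG seed.
#' @param n0 cells per replicate simulation.
#' @param params parameter list.
#' @return Object of class `calibration_fit`: fitted `growth_coef` and
#'   `secretion_coef`, per-step losses, evaluation counts and loss traces.
#' @export
fit_two_step <- function(growth_target, sucrose_target,
                         growth_init = c(a = 0.2, tau = 0.1, b = 0.8),
                         secretion_init = c(A = -2, tau = 0.1, B = 2),
                         growth_bounds = list(
                           lower = c(a = 0.01, tau = 0.005, b = 0.5),
                           upper = c(a = 1, tau = 1, b = 1.5)),
                         secretion_bounds = list(
                           lower = c(A = -10, tau = 0.005, B = 0.5),
                           upper = c(A = -0.1, tau = 1, B = 10)),
                         n_replicates = 3, budget = 200, seed = 1,
                         n0 = 50, params = default_params()) {
  stopifnot(growth_target$observable == "biomass_timeseries",
            sucrose_target$observable == "sucrose_timeseries")

  step <- function(target, init, bounds, fixed_growth = NULL) {
    trace <- numeric(0)
    evals <- 0
    obj <- function(par) {
      evals <<- evals + 1
      if (any(par < bounds$lower) || any(par > bounds$upper)) {
        pen <- sum(pmax(bounds$lower - par, 0) + pmax(par - bounds$upper, 0))
        return(1e6 * (1 + pen))
      }
      names(par) <- names(init)
      loss <- if (is.null(fixed_growth)) {
        .calibration_loss(target, growth_coef = par,
                          secretion_coef = .iptg_secretion,
                          n_replicates, seed, n0, params)
      } else {
        .calibration_loss(target, growth_coef = fixed_growth,
                          secretion_coef = par,
                          n_replicates, seed, n0, params)
      }
      trace <<- c(trace, loss)
      loss
    }
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = budget,
                                       reltol = 1e-10))
    if (length(trace) > 1 && min(trace[-1]) >= trace[1] - 1e-12) {
      warning("optimization budget exhausted without improvement; ",
              "returning best parameters found", call. = FALSE)
    }
    list(par = stats::setNames(fit$par, names(init)), loss = fit$value,
         evals = evals, trace = trace)
  }

  s1 <- step(growth_target, growth_init, growth_bounds)
  s2 <- step(sucrose_target, secretion_init, secretion_bounds,
             fixed_growth = s1$par)
  structure(list(growth_coef = s1$par, secretion_coef = s2$par,
                 growth_loss = s1$loss, sucrose_loss = s2$loss,
                 evals = c(growth = s1$evals, sucrose = s2$evals),
                 trace = list(growth = s1$trace, sucrose = s2$trace)),
            class = "calibration_fit")
}

#' @export
#' @method print calibration_fit
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> two-step recovery\n")
  cat("  growth coef:   ",
      paste(sprintf("%s=%.4g", names(x$growth_coef), x$growth_coef),
            collapse = "  "),
      sprintf("  (loss %.3g, %d evals)\n", x$growth_loss, x$evals["growth"]))
  cat("  secretion coef:",
      paste(sprintf("%s=%.4g", names(x$secretion_coef), x$secretion_coef),
            collapse = "  "),
      sprintf("  (loss %.3g, %d evals)\n", x$sucrose_loss,
              x$evals["sucrose"]))
  invisible(x)
}

#' Fit a single-substrate Monod half-velocity constant
#'
#' Least-squares fit of \eqn{\mu = \mu_{max} S / (K + S)} to
#' rate-versus-concentration data (Levenberg-Marquardt). With
#' `mu_max` supplied, only `K` is free (the normalized-data case uses
#' `mu_max = 1`).
#'
#' @param S substrate concentrations (>= 3 distinct values).
#' @param mu observed specific growth rates.
#' @param mu_max fix the maximal rate at this value; `NULL` to fit it too.
#' @return Named vector with `K` (and `mu_max` if fitted).
#' @examples
#' S <- c(0.001, 0.004, 0.008, 0.02, 0.05)
#' fit_monod_K(S, S / (8.1e-3 + S), mu_max = 1)
#' @export
fit_monod_K <- function(S, mu, mu_max = NULL) {
  if (length(unique(S)) < 3) stop("need >= 3 distinct concentrations")
  df <- data.frame(S = S, mu = mu)
  K0 <- stats::median(S)
  if (is.null(mu_max)) {
    fit <- minpack.lm::nlsLM(mu ~ mumax * S / (K + S), data = df,
                             start = list(mumax = max(mu) * 1.2, K = K0),
                             lower = c(1e-12, 1e-12))
    c(K = unname(stats::coef(fit)["K"]),
      mu_max = unname(stats::coef(fit)["mumax"]))
  } else {
    fit <- minpack.lm::nlsLM(mu ~ mu_max * S / (K + S), data = df,
                             start = list(K = K0), lower = 1e-12)
    c(K = unname(stats::coef(fit)["K"]))
  }
}
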