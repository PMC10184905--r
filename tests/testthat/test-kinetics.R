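# Kinetic laws: growth, secretion, and nutrient source/sink terms.

pc <- species_params("cyanobacterium")
ph <- species_params("heterotroph")

test_that("cyanobacterial growth reproduces hand-evaluated Monod values", {
  # zero light shuts growth down entirely
  expect_equal(growth_rate_cyano(local_env(light = 0, co2 = 1), pc), 0)
  # default bulk concentrations, uninduced: factors 0.99651 * 0.99542 * 1.041
  mu0 <- growth_rate_cyano(local_env(light = 0.1, co2 = 0.03, iptg = 0), pc)
  expect_equal(mu0, 1.89e-5 * (0.1 / (0.1 + 3.5e-4)) *
                 (0.03 / (0.03 + 1.38e-4)) * 1.041, tolerance = 1e-12)
  expect_equal(mu0, 1.952e-5, tolerance = 1e-4)
  # fully induced: the inducer factor collapses to 0.9
  mu1 <- growth_rate_cyano(local_env(light = 0.1, co2 = 0.03, iptg = 1), pc)
  expect_equal(mu1, 1.687e-5, tolerance = 1e-4)
  # bounded by 1.041 * mu_max
  expect_lte(mu0, 1.041 * pc$mu_max)
  expect_error(local_env(light = -1), ">= 0")
})

test_that("secretion flux follows the inducer response and clamps at zero", {
  # uninduced: raw factor is slightly negative -> clamped, with a warning
  expect_warning(ps0 <- secretion_flux_cyano(1e-5, 0), "clamped")
  expect_equal(ps0, 0)
  # full induction: factor ~3.4092
  expect_equal(secretion_flux_cyano(1.687e-5, 1), 5.753e-5, tolerance = 1e-4)
  # one e-folding of the inducer response
  expect_equal(secretion_flux_cyano(1e-5, 0.048),
               1e-5 * (3.4092 - 3.4897 / exp(1)), tolerance = 1e-12)
  expect_equal(secretion_flux_cyano(1e-5, 0.048), 2.1253e-5,
               tolerance = 1e-4)
})

test_that("heterotrophic growth reproduces hand-evaluated values", {
  expect_equal(growth_rate_hetero(local_env(sucrose = 0, o2 = 1), ph), 0)
  # sucrose at half saturation, O2 at 0.9 saturation
  expect_equal(growth_rate_hetero(local_env(sucrose = 3.6, o2 = 9e-3), ph),
               0.5 * 0.9 * 6.71e-5, tolerance = 1e-12)
  # saturating both substrates approaches mu_max
  expect_equal(growth_rate_hetero(local_env(sucrose = 1e9, o2 = 1e9), ph),
               6.71e-5, tolerance = 1e-6)
})

test_that("carbon partitioned to sucrose at full induction is ~77%", {
  mu <- growth_rate_cyano(local_env(light = 0.1, co2 = 0.03, iptg = 1), pc)
  psi <- secretion_flux_cyano(mu, 1)
  expect_equal(psi / (mu + psi), 3.4092 / 4.4092, tolerance = 1e-6)
  expect_equal(psi / (mu + psi), 0.773, tolerance = 1e-3)
})

test_that("cyanobacterial source/sink terms match hand-computed values", {
  r0 <- consumption_terms_cyano(1e-5, 1e-5, rho = 0, pc)
  expect_true(all(unlist(r0) == 0))
  r <- consumption_terms_cyano(1.687e-5, 5.753e-5, rho = 100, pc)
  expect_equal(r$co2, -(1 / 0.55) * (1.687e-5 + 5.753e-5) * 100,
               tolerance = 1e-12)
  expect_equal(r$co2, -1.353e-2, tolerance = 1e-3)
  expect_equal(r$sucrose, (0.65 / 0.55) * 5.753e-5 * 100, tolerance = 1e-12)
  expect_equal(r$sucrose, 6.799e-3, tolerance = 1e-3)
  # signs: CO2 (and light) sinks, O2 and sucrose sources
  expect_lt(r$co2, 0); expect_lt(r$light, 0)
  expect_gt(r$o2, 0); expect_gt(r$sucrose, 0)
})

test_that("heterotrophic source/sink terms match hand-computed values", {
  r <- consumption_terms_hetero(3.0195e-5, rho = 50, ph)
  expect_equal(r$sucrose, -(1 / 0.43) * 3.0195e-5 * 50, tolerance = 1e-12)
  expect_equal(r$sucrose, -3.511e-3, tolerance = 1e-3)
  # starvation: maintenance respiration persists
  r_starved <- consumption_terms_hetero(0, rho = 50, ph)
  expect_equal(r_starved$o2, -0.399 * 9.5e-7 * 50, tolerance = 1e-12)
  expect_equal(r_starved$o2, -1.895e-5, tolerance = 1e-3)
  expect_gt(r_starved$co2, 0)
})

test_that("growth rates are monotone in substrates and inducer", {
  set.seed(42)
  for (rep in 1:20) {
    s <- sort(runif(2, 0, 0.2))
    base <- runif(1, 1e-4, 0.1)
    # non-decreasing in each substrate
    expect_lte(growth_rate_cyano(local_env(light = s[1], co2 = base), pc),
               growth_rate_cyano(local_env(light = s[2], co2 = base), pc))
    expect_lte(growth_rate_hetero(local_env(sucrose = s[1], o2 = base), ph),
               growth_rate_hetero(local_env(sucrose = s[2], o2 = base), ph))
    # cyano growth non-increasing in inducer; secretion factor non-decreasing
    i2 <- sort(runif(2, 0, 2))
    expect_gte(growth_rate_cyano(local_env(light = 0.1, co2 = 0.03,
                                           iptg = i2[1]), pc),
               growth_rate_cyano(local_env(light = 0.1, co2 = 0.03,
                                           iptg = i2[2]), pc))
    expect_lte(suppressWarnings(secretion_flux_cyano(1e-5, i2[1])),
               suppressWarnings(secretion_flux_cyano(1e-5, i2[2])))
  }
})

test_that("source/sink terms are linear in biomass density", {
  set.seed(7)
  for (rep in 1:10) {
    mu <- runif(1, 0, 1e-4); psi <- runif(1, 0, 2e-4)
    rho <- runif(1, 1, 500)
    r1 <- consumption_terms_cyano(mu, psi, rho, pc)
    r2 <- consumption_terms_cyano(mu, psi, 2 * rho, pc)
    expect_equal(unlist(r2), 2 * unlist(r1), tolerance = 1e-12)
    h1 <- consumption_terms_hetero(mu, rho, ph)
    h2 <- consumption_terms_hetero(mu, 2 * rho, ph)
    expect_equal(unlist(h2), 2 * unlist(h1), tolerance = 1e-12)
  }
})

test_that("half-saturation of one limiting substrate exactly halves growth", {
  sat <- growth_rate_hetero(local_env(sucrose = 1e12, o2 = 9e-3), ph)
  half <- growth_rate_hetero(local_env(sucrose = ph$K_sucrose, o2 = 9e-3), ph)
  expect_equal(half, sat / 2, tolerance = 1e-9)
  satc <- growth_rate_cyano(local_env(light = 1e12, co2 = 0.03), pc)
  halfc <- growth_rate_cyano(local_env(light = pc$K_light, co2 = 0.03), pc)
  expect_equal(halfc, satc / 2, tolerance = 1e-9)
})

test_that("species parameters validate and the shipped config round-trips", {
  expect_error(species_params("cyanobacterium", mu_max = -1), "> 0")
  expect_error(species_params("heterotroph", yield_Y = 1.5), "\\(0, 1\\]")
  expect_error(species_params("cyanobacterium", veq_diameter_min = 2), "<")
  cfg_path <- system.file("extdata", "default_params.yaml",
                          package = "consortsim")
  cfg <- load_config(cfg_path)
  expect_equal(cfg$cyanobacterium$mu_max, 1.89e-5)
  expect_equal(cfg$heterotroph$K_sucrose, 3.6)
  expect_equal(cfg$nutrients$concentration[cfg$nutrients$nutrient == "o2"],
               9e-3)
  # overrides merge over the defaults
  tmp <- tempfile(fileext = ".yaml")
  writeLines("cyanobacterium:\n  K_CO2: 8.1e-3", tmp)
  expect_equal(load_config(tmp)$cyanobacterium$K_CO2, 8.1e-3)
  expect_equal(load_config(tmp)$heterotroph$mu_max, 6.71e-5)
})
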