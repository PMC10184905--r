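# Cell agents: seeding, exponential growth, division, overlap relaxation.

params <- default_params()

test_that("seeding is deterministic and draws masses in the geometric bounds", {
  sp <- seed_spec(20, 15, iptg = 0.5, rng_seed = 42)
  c1 <- seed_simulation(sp, params)
  c2 <- seed_simulation(sp, params)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 35)
  expect_equal(c1$founder_id, c1$id)
  # positions inside the box
  expect_true(all(c1$x >= 0 & c1$x <= 100))
  expect_true(all(c1$z >= 0 & c1$z <= 10))
  # mass bounds follow from density * (pi/6) d^3 at the diameter bounds
  cy <- c1$species == "cyanobacterium"
  expect_true(all(c1$mass[cy] >= 498.2 & c1$mass[cy] <= 1414.5))
  expect_true(all(c1$mass[!cy] >= 82.1 & c1$mass[!cy] <= 323.4))
  # no initial overlaps
  d <- as.matrix(dist(c1[, c("x", "y", "z")]))
  rsum <- outer(c1$diameter, c1$diameter, "+") / 2
  diag(d) <- Inf
  expect_true(all(d >= rsum - 1e-9))
  # mass and diameter stay consistent
  dens <- ifelse(cy, 370, 230)
  expect_equal(c1$mass, mass_from_diameter(c1$diameter, dens),
               tolerance = 1e-9)
})

test_that("an impossible seeding density raises a seeding error", {
  sp <- seed_spec(200, 200, rng_seed = 1, domain = c(6, 6, 6))
  expect_error(seed_simulation(sp, params, max_retries = 20), "seeding failed")
})

test_that("mass growth is the exact exponential update", {
  cells <- seed_simulation(seed_spec(5, 5, rng_seed = 1), params)
  m0 <- cells$mass
  # mu = 0 leaves mass untouched
  expect_equal(grow_cells(cells, 0, 600, params)$mass, m0)
  # e^{mu dt} factor for one step
  g <- grow_cells(cells, 1e-4, 600, params)
  expect_equal(g$mass, m0 * exp(0.06), tolerance = 1e-12)
  # doubling time ln2 / mu under constant mu
  mu <- 1.952e-5
  td <- log(2) / mu
  expect_equal(td, 35511, tolerance = 1e-3)
  steps <- 50
  g2 <- cells
  for (i in seq_len(steps)) g2 <- grow_cells(g2, mu, td / steps, params)
  expect_equal(g2$mass, 2 * m0, tolerance = 1e-9)
})

test_that("division conserves mass, splits near-evenly and inherits lineage", {
  # a cyanobacterium exactly at the division diameter
  m_max <- mass_from_diameter(1.94, 370)
  expect_equal(m_max, 1414.5, tolerance = 1e-4)
  cell <- data.frame(id = 1L, species = "cyanobacterium", founder_id = 7L,
                     x = 50, y = 50, z = 5, mass = m_max, diameter = 1.94,
                     birth_time = 0, stringsAsFactors = FALSE)
  set.seed(99)
  out <- divide_cells(cell, params, time = 600)
  expect_equal(nrow(out), 2)
  expect_equal(sum(out$mass), m_max, tolerance = 1e-12)
  expect_true(all(out$founder_id == 7L))
  expect_true(all(out$mass / m_max >= 0.45 & out$mass / m_max <= 0.55))
  # daughters touch: centre separation equals the sum of radii
  sep <- sqrt(sum((out[1, c("x", "y", "z")] - out[2, c("x", "y", "z")])^2))
  expect_equal(sep, sum(out$diameter) / 2, tolerance = 1e-9)
  # an exactly even split gives d_max / 2^(1/3) daughters
  expect_equal(diameter_from_mass(m_max / 2, 370), 1.94 / 2^(1 / 3),
               tolerance = 1e-12)
  expect_equal(1.94 / 2^(1 / 3), 1.540, tolerance = 1e-3)
  # below the division diameter nothing happens
  small <- cell
  small$mass <- mass_from_diameter(1.5, 370); small$diameter <- 1.5
  expect_identical(divide_cells(small, params), small)
})

test_that("division keeps the whole population's mass ledger intact", {
  set.seed(5)
  cells <- seed_simulation(seed_spec(30, 30, rng_seed = 5), params)
  # inflate some cells past the division threshold
  cells$mass <- cells$mass * 1.9
  dens <- ifelse(cells$species == "cyanobacterium", 370, 230)
  cells$diameter <- diameter_from_mass(cells$mass, dens)
  total0 <- sum(cells$mass)
  out <- divide_cells(cells, params, time = 0)
  expect_gt(nrow(out), nrow(cells))
  expect_equal(sum(out$mass), total0, tolerance = 1e-9)
  # founder labels still partition the population
  expect_true(all(out$founder_id %in% cells$founder_id))
})

test_that("overlap relaxation separates spheres and is identity without overlap", {
  two <- data.frame(id = 1:2, species = "cyanobacterium", founder_id = 1:2,
                    x = c(40, 41), y = 50, z = 5, mass = 1,
                    diameter = 1.4, birth_time = 0,
                    stringsAsFactors = FALSE)
  out <- relax_overlaps(two, tol = 1e-6, max_pass = 10)
  gap <- sqrt(sum((out[1, c("x", "y", "z")] - out[2, c("x", "y", "z")])^2))
  expect_equal(gap, 1.4, tolerance = 1e-9)    # pushed from 1.0 to r1 + r2
  far <- two; far$x <- c(10, 90)
  expect_equal(relax_overlaps(far)[, c("x", "y", "z")],
               far[, c("x", "y", "z")])
})

test_that("a dense cluster relaxes below tolerance within the pass budget", {
  set.seed(8)
  n <- 20
  dense <- data.frame(id = 1:n, species = "heterotroph", founder_id = 1:n,
                      x = runif(n, 48, 52), y = runif(n, 48, 52),
                      z = runif(n, 4, 6), mass = 1, diameter = 1.2,
                      birth_time = 0, stringsAsFactors = FALSE)
  out <- relax_overlaps(dense, tol = 1e-3, max_pass = 200)
  d <- as.matrix(dist(out[, c("x", "y", "z")]))
  diag(d) <- Inf
  max_overlap <- max(1.2 - d)
  expect_true(max_overlap < 1e-3 || attr(out, "passes") >= 200)
  expect_lt(max_overlap, 1e-3)
  # positions stay inside the box
  expect_true(all(out$x >= 0 & out$x <= 100 & out$z >= 0 & out$z <= 10))
})
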