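# Colony spatial metrics: worked examples, sentinels, brute-force and
# rasterized oracles, invariances.

mk_layout <- function(x, y, z, species = NULL, domain = c(100, 100, 10)) {
  n <- length(x)
  if (is.null(species)) species <- rep("cyanobacterium", n)
  cells <- data.frame(id = seq_len(n), species = species,
                      founder_id = seq_len(n), x = x, y = y, z = z,
                      mass = 500, diameter = 1, birth_time = 0,
                      stringsAsFactors = FALSE)
  colony_layout(cells, domain)
}

test_that("neighbour distances reproduce the 3-4-5 worked example", {
  lay <- mk_layout(c(0, 3, 6), c(0, 4, 8), c(5, 5, 5))
  expect_equal(nn_distance(lay, 1), 5)
  expect_equal(mean_ic_distance(lay, 1), 7.5)
  expect_equal(relative_neighbor_distance(lay, 1), 5 / 7.5)
  expect_equal(inverse_neighbor_distance(lay, 1), 1 / 5 + 1 / 10)
  expect_equal(log_inv_sq_neighbor_distance(lay, 1), log(0.05))
  expect_equal(log(0.05), -2.9957, tolerance = 1e-4)
})

test_that("degenerate neighbourhoods return undefined sentinels", {
  solo <- mk_layout(50, 50, 5)
  expect_true(is.na(nn_distance(solo, 1)))
  # species restriction with no eligible neighbour
  lay <- mk_layout(c(10, 50), c(10, 50), c(5, 5),
                   species = c("cyanobacterium", "heterotroph"))
  expect_true(is.na(nn_distance(lay, 1, species = "cyanobacterium")))
  expect_equal(nn_distance(lay, 1, species = "heterotroph"),
               sqrt(2 * 40^2))
  # two colonies: relative neighbour distance is exactly 1
  expect_equal(relative_neighbor_distance(lay), c(1, 1))
})

test_that("simple closed-form cases hold", {
  # equilateral triangle: relative NN distance 1 for all
  tri <- mk_layout(c(0, 10, 5), c(0, 0, 5 * sqrt(3)), c(5, 5, 5))
  expect_equal(relative_neighbor_distance(tri), rep(1, 3))
  # collinear equally spaced: middle founder mean distance 1
  col3 <- mk_layout(c(10, 11, 12), c(50, 50, 50), c(5, 5, 5))
  expect_equal(mean_ic_distance(col3, 2), 1)
  # two colonies at distance 2: inverse neighbour distance 0.5
  two <- mk_layout(c(10, 12), c(50, 50), c(5, 5))
  expect_equal(inverse_neighbor_distance(two, 1), 0.5)
  # single neighbour at distance e: log inverse squared = -2
  le <- mk_layout(c(10, 10 + exp(1)), c(50, 50), c(5, 5))
  expect_equal(log_inv_sq_neighbor_distance(le, 1), -2)
})

test_that("scaled inter-colony distance follows the diffusion-length scaling", {
  # IC = 50 um, sucrose D and heterotroph mu_max
  lay <- mk_layout(c(25, 75), c(50, 50), c(5, 5),
                   species = c("heterotroph", "heterotroph"))
  z <- scaled_ic_distance(lay, 1, D = 5.2e-10, mu_max = 6.71e-5)
  expect_equal(z, 5e-5 / sqrt(5.2e-10 / 6.71e-5), tolerance = 1e-12)
  expect_equal(z, 0.01796, tolerance = 1e-3)
  # linear in IC
  lay2 <- mk_layout(c(0, 100), c(50, 50), c(5, 5),
                    species = c("heterotroph", "heterotroph"))
  expect_equal(scaled_ic_distance(lay2, 1, D = 5.2e-10, mu_max = 6.71e-5),
               2 * z, tolerance = 1e-12)
  # species-specific defaults pick sucrose/hetero vs CO2/cyano
  mixed <- mk_layout(c(25, 75), c(50, 50), c(5, 5),
                     species = c("heterotroph", "cyanobacterium"))
  zz <- scaled_ic_distance(mixed)
  expect_equal(zz[1], 5e-5 / sqrt(5.2e-10 / 6.71e-5), tolerance = 1e-9)
  expect_equal(zz[2], 5e-5 / sqrt(1.9e-9 / 1.89e-5), tolerance = 1e-9)
})

test_that("distance from the domain centre matches hand geometry", {
  lay <- mk_layout(c(50, 0, 0), c(50, 0, 0), c(5, 5, 0))
  expect_equal(distance_from_center(lay, 1), 0)
  expect_equal(distance_from_center(lay, 2), sqrt(50^2 + 50^2))
  expect_equal(distance_from_center(lay, 3), sqrt(50^2 + 50^2 + 5^2))
  expect_equal(distance_from_center(lay, 3), 70.89, tolerance = 1e-3)
})

test_that("Voronoi areas at quarter-centres split the domain evenly", {
  lay <- mk_layout(c(25, 75, 25, 75), c(25, 25, 75, 75), rep(5, 4))
  expect_equal(voronoi_areas(lay), rep(2500, 4))
})

test_that("Voronoi areas partition the domain for random layouts", {
  for (seed in 1:5) {
    lay <- random_layout(40, seed)
    a <- voronoi_areas(lay)
    expect_false(anyNA(a))
    expect_equal(sum(a), 100 * 100, tolerance = 1e-6)
    expect_true(all(a > 0))
  }
})

test_that("Voronoi areas agree with a pixel-assignment oracle", {
  # perturbed regular grid, as in the reference construction
  set.seed(13)
  base <- expand.grid(x = c(25, 75), y = c(25, 75))
  lay <- mk_layout(base$x + runif(4, -1, 1), base$y + runif(4, -1, 1),
                   rep(5, 4))
  a <- voronoi_areas(lay)
  oracle <- raster_voronoi(lay, resolution = 0.5)
  expect_lt(max(abs(a - oracle) / oracle), 0.01)
})

test_that("degenerate Voronoi inputs give sentinels or errors", {
  expect_true(all(is.na(voronoi_areas(mk_layout(c(1, 2, 3), c(1, 2, 3),
                                                c(5, 5, 5))))))
  collin <- mk_layout(c(10, 20, 30, 40), c(10, 20, 30, 40), rep(5, 4))
  expect_true(all(is.na(voronoi_areas(collin))))
  dup <- mk_layout(c(10, 10, 30, 40), c(10, 10, 30, 80), rep(5, 4))
  expect_error(voronoi_areas(dup), "coincident")
})

test_that("pairwise metrics match the brute-force oracle exactly", {
  for (seed in 1:6) {
    lay <- random_layout(60, seed + 100)
    subj <- sample(60, 8)
    for (i in subj) {
      o <- brute_metrics(lay, i)
      expect_equal(nn_distance(lay, i), o$nn, tolerance = 1e-12)
      expect_equal(mean_ic_distance(lay, i), o$ic, tolerance = 1e-12)
      expect_equal(relative_neighbor_distance(lay, i), o$rel,
                   tolerance = 1e-12)
      expect_equal(inverse_neighbor_distance(lay, i), o$inv,
                   tolerance = 1e-12)
      expect_equal(log_inv_sq_neighbor_distance(lay, i), o$loginvsq,
                   tolerance = 1e-12)
      os <- brute_metrics(lay, i, species = "heterotroph")
      expect_equal(nn_distance(lay, i, species = "heterotroph"), os$nn,
                   tolerance = 1e-12)
      expect_equal(mean_ic_distance(lay, i, species = "heterotroph"), os$ic,
                   tolerance = 1e-12)
    }
  }
})

test_that("neighbour metrics are translation invariant", {
  lay <- random_layout(25, 7, domain = c(100, 100, 10))
  shifted <- lay
  shifted$x <- lay$x - min(lay$x)
  shifted$y <- lay$y - min(lay$y)
  shifted$z <- lay$z - min(lay$z)
  for (f in list(nn_distance, mean_ic_distance, relative_neighbor_distance,
                 inverse_neighbor_distance, log_inv_sq_neighbor_distance)) {
    expect_equal(f(shifted), f(lay), tolerance = 1e-9)
  }
  # distance-from-centre is domain anchored, not translation invariant
  expect_false(isTRUE(all.equal(distance_from_center(shifted),
                                distance_from_center(lay))))
})

test_that("the feature table exposes the documented schema", {
  lay <- random_layout(12, 3)
  ft <- colony_features(lay, iptg = 0.3)
  expect_equal(names(ft),
               c("founder_id", "species", "initial_biomass", "iptg",
                 "nn_all", "nn_se", "nn_ec", "ic_all", "ic_se", "ic_ec",
                 "rel_nn", "inv_nn", "log_inv_sq_nn", "zeta",
                 "voronoi_area", "dist_center"))
  expect_equal(nrow(ft), 12)
  expect_true(all(ft$iptg == 0.3))
})
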