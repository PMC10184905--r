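# Independent oracles used across the suite. These deliberately use naive
# direct constructions (dense linear algebra, O(n^2) enumeration, pixel
# rasterization) so they share no code path with the package internals.

# Direct dense steady-state solve of D * lap(S) + R = 0 on a 3D grid.
# Dirichlet: face voxels pinned at bc_value and removed from the unknowns.
# Neumann: zero-flux mirror walls; R must be compatible (sum to ~0) and the
# solution's mean is pinned to `mean_value` (the conserved quantity).
dense_steady_oracle <- function(dims, h_um, D, R, bc_type, bc_value = 0,
                                mean_value = 0) {
  n <- prod(dims)
  h <- h_um * 1e-6
  idx <- function(i, j, k) i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1)
  is_face <- function(i, j, k) {
    i == 1 || i == dims[1] || j == 1 || j == dims[2] || k == 1 || k == dims[3]
  }
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
    for (i in seq_len(dims[1])) {
      row <- idx(i, j, k)
      if (bc_type == "dirichlet" && is_face(i, j, k)) {
        A[row, row] <- 1
        b[row] <- bc_value
        next
      }
      nb <- list(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                 c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
      for (p in nb) {
        if (p[1] < 1 || p[1] > dims[1] || p[2] < 1 || p[2] > dims[2] ||
            p[3] < 1 || p[3] > dims[3]) next   # mirror wall: no flux
        A[row, row] <- A[row, row] - D / h^2
        A[row, idx(p[1], p[2], p[3])] <- A[row, idx(p[1], p[2], p[3])] +
          D / h^2
      }
      b[row] <- -R[i, j, k]
    }
  }
  if (bc_type == "neumann") {
    # singular system: append the mean constraint via least squares
    A <- rbind(A, rep(1 / n, n))
    b <- c(b, mean_value)
    sol <- qr.solve(A, b)
  } else {
    sol <- solve(A, b)
  }
  array(sol, dim = dims)
}

# O(n^2) brute-force spatial metrics from first principles.
brute_metrics <- function(layout, subject, species = NULL) {
  n <- nrow(layout)
  d <- numeric(0)
  for (j in seq_len(n)) {
    if (j == subject) next
    if (!is.null(species) && layout$species[j] != species) next
    d <- c(d, sqrt((layout$x[subject] - layout$x[j])^2 +
                   (layout$y[subject] - layout$y[j])^2 +
                   (layout$z[subject] - layout$z[j])^2))
  }
  if (!length(d)) {
    return(list(nn = NA_real_, ic = NA_real_, rel = NA_real_,
                inv = NA_real_, loginvsq = NA_real_))
  }
  list(nn = min(d), ic = mean(d), rel = min(d) / mean(d),
       inv = sum(1 / d), loginvsq = log(sum(1 / d^2)))
}

# Rasterized Voronoi areas: assign every pixel of the domain rectangle to
# its nearest founder.
raster_voronoi <- function(layout, resolution = 0.5) {
  dom <- attr(layout, "domain")
  gx <- seq(resolution / 2, dom[1] - resolution / 2, by = resolution)
  gy <- seq(resolution / 2, dom[2] - resolution / 2, by = resolution)
  counts <- numeric(nrow(layout))
  for (yy in gy) {
    d2 <- outer(gx, layout$x, function(a, b) (a - b)^2) +
      matrix((yy - layout$y)^2, length(gx), nrow(layout), byrow = TRUE)
    nearest <- max.col(-d2, ties.method = "first")
    tab <- tabulate(nearest, nbins = nrow(layout))
    counts <- counts + tab
  }
  counts * resolution^2
}

# Central-difference numerical gradient of a scalar function of a
# parameter list (used to verify MLP backpropagation).
numeric_gradient <- function(fn, theta, eps = 1e-5) {
  lapply(theta, function(p) {
    g <- p
    for (i in seq_along(p)) {
      th_p <- p; th_m <- p
      th_p[i] <- th_p[i] + eps
      th_m[i] <- th_m[i] - eps
      g[i] <- (fn(th_p, i, p) - fn(th_m, i, p)) / (2 * eps)
    }
    g
  })
}

# Build a random but overlap-free colony layout for metric tests.
random_layout <- function(n, seed, domain = c(100, 100, 10)) {
  set.seed(seed)
  sp <- sample(c("cyanobacterium", "heterotroph"), n, replace = TRUE)
  cells <- data.frame(
    id = seq_len(n), species = sp, founder_id = seq_len(n),
    x = runif(n, 0, domain[1]), y = runif(n, 0, domain[2]),
    z = runif(n, 0, domain[3]),
    mass = runif(n, 100, 1400), diameter = 1, birth_time = 0,
    stringsAsFactors = FALSE
  )
  colony_layout(cells, domain)
}
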