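#' Colony layout at seeding time
#'
#' Snapshot of founder-cell positions, species and initial biomass, from
#' which all colony spatial metrics are computed. All metrics are evaluated
#' at t = 0: the layout of the founders determines the local competition and
#' cross-feeding environment each colony will experience.
#'
#' @param cells an initial cell table (one row per founder), e.g.
#'   `sim$cells_initial`.
#' @param domain box (Lx, Ly, Lz), um.
#' @return data.frame of class `colony_layout` with columns `founder_id`,
#'   `species`, `x`, `y`, `z`, `biomass`, and a `domain` attribute.
#' @export
colony_layout <- function(cells, domain = c(100, 100, 10)) {
  stopifnot(nrow(cells) >= 1)
  out <- data.frame(founder_id = cells$founder_id, species = cells$species,
                    x = cells$x, y = cells$y, z = cells$z,
                    biomass = cells$mass, stringsAsFactors = FALSE)
  attr(out, "domain") <- domain
  class(out) <- c("colony_layout", "data.frame")
  out
}

.pair_dists <- function(layout) {
  as.matrix(stats::dist(cbind(layout$x, layout$y, layout$z)))
}

# Distances from each founder to its eligible neighbours: all other
# founders, optionally restricted to one species. Returns a list of
# numeric vectors (possibly empty).
.neighbor_dists <- function(layout, species = NULL) {
  D <- .pair_dists(layout)
  n <- nrow(layout)
  lapply(seq_len(n), function(i) {
    elig <- setdiff(seq_len(n), i)
    if (!is.null(species)) elig <- elig[layout$species[elig] == species]
    D[i, elig]
  })
}

.metric_over <- function(layout, subject, species, fun) {
  nd <- .neighbor_dists(layout, species)
  vals <- vapply(nd, function(d) if (length(d)) fun(d) else NA_real_,
                 numeric(1))
  if (is.null(subject)) vals else vals[subject]
}

#' Nearest-neighbour distance
#'
#' Minimum 3D Euclidean distance from a founder colony to its neighbours,
#' optionally restricted to neighbours of one species (the
#' species-specific variants "nearest neighbour s.e." / "e.c."). A founder
#' with no eligible neighbour gets `NA` (recorded and excluded from the
#' regression table).
#'
#' @param layout a [colony_layout()].
#' @param subject founder row index (or vector); `NULL` for all founders.
#' @param species optional species restriction (`"cyanobacterium"` or
#'   `"heterotroph"`).
#' @return Distance(s) in um.
#' @export
nn_distance <- function(layout, subject = NULL, species = NULL) {
  .metric_over(layout, subject, species, min)
}

#' Mean inter-colony distance
#'
#' Arithmetic mean of a founder's distances to all eligible neighbours
#' (per-colony inter-colony distance, IC-bar), optionally species
#' restricted.
#'
#' @inheritParams nn_distance
#' @return Distance(s) in um.
#' @export
mean_ic_distance <- function(layout, subject = NULL, species = NULL) {
  .metric_over(layout, subject, species, mean)
}

#' Relative neighbour distance
#'
#' Nearest-neighbour distance over the mean inter-colony distance for the
#' same founder; lies in (0, 1].
#'
#' @inheritParams nn_distance
#' @export
relative_neighbor_distance <- function(layout, subject = NULL) {
  nn_distance(layout, subject) / mean_ic_distance(layout, subject)
}

#' Inverse neighbour distance
#'
#' Sum of reciprocal distances to all neighbours, 1/um. Emphasises crowding
#' by close neighbours.
#'
#' @inheritParams nn_distance
#' @export
inverse_neighbor_distance <- function(layout, subject = NULL) {
  .metric_over(layout, subject, NULL, function(d) sum(1 / d))
}

#' Log inverse squared neighbour distance
#'
#' Natural logarithm of the sum of inverse squared neighbour distances,
#' `log(sum(1/d^2))` (dimensionless up to the log's unit convention; the
#' base only shifts the feature by a constant factor).
#'
#' @inheritParams nn_distance
#' @export
log_inv_sq_neighbor_distance <- function(layout, subject = NULL) {
  .metric_over(layout, subject, NULL, function(d) log(sum(1 / d^2)))
}

#' Scaled inter-colony distance
#'
#' Mean inter-colony distance expressed in units of the diffusion length of
#' the species' primary nutrient: `zeta = IC / sqrt(D / mu_max)` with IC
#' converted to metres. For the heterotroph the primary nutrient is sucrose;
#' for the cyanobacterium, CO2. Dimensionless; `zeta << 1` means neighbours
#' sit well inside one diffusion length.
#'
#' @inheritParams nn_distance
#' @param D diffusion coefficient, m^2/s; `NULL` picks the species-specific
#'   default per founder.
#' @param mu_max maximal growth rate, 1/s; `NULL` likewise.
#' @param params parameter list (for the species-specific defaults).
#' @export
scaled_ic_distance <- function(layout, subject = NULL, D = NULL,
                               mu_max = NULL, params = default_params()) {
  ic <- mean_ic_distance(layout, NULL)
  if (is.null(D) || is.null(mu_max)) {
    nut <- params$nutrients
    is_h <- layout$species == "heterotroph"
    D_sp <- ifelse(is_h, nut$D[match("sucrose", nut$nutrient)],
                   nut$D[match("co2", nut$nutrient)])
    mu_sp <- ifelse(is_h, params$heterotroph$mu_max,
                    params$cyanobacterium$mu_max)
    if (is.null(D)) D <- D_sp
    if (is.null(mu_max)) mu_max <- mu_sp
  }
  zeta <- (ic * 1e-6) / sqrt(D / mu_max)
  if (is.null(subject)) zeta else zeta[subject]
}

#' Distance from the domain centre
#'
#' 3D Euclidean distance from a founder to the centroid of the simulation
#' volume (Lx/2, Ly/2, Lz/2). Together with Voronoi clipping this is the
#' only domain-anchored metric; all neighbour distances are translation
#' invariant.
#'
#' @inheritParams nn_distance
#' @export
distance_from_center <- function(layout, subject = NULL) {
  ctr <- attr(layout, "domain") / 2
  d <- sqrt((layout$x - ctr[1])^2 + (layout$y - ctr[2])^2 +
            (layout$z - ctr[3])^2)
  if (is.null(subject)) d else d[subject]
}

#' Voronoi tessellation areas
#'
#' Planar Voronoi areas of the founder positions projected onto the xy
#' plane (the domain is thin in z), with each region clipped to the domain
#' rectangle so the areas partition the chamber footprint exactly:
#' `sum(areas) == Lx * Ly`. Each region is computed by half-plane clipping
#' of the domain rectangle against the perpendicular bisectors to every
#' other founder.
#'
#' @param layout a [colony_layout()].
#' @return Numeric vector of areas, um^2; all `NA` if fewer than 4
#'   founders or if the xy-projection is degenerate (collinear points).
#' @export
voronoi_areas <- function(layout) {
  n <- nrow(layout)
  pts <- cbind(layout$x, layout$y)
  if (n < 4) return(rep(NA_real_, n))
  if (anyDuplicated(round(pts, 9))) {
    stop("coincident founder positions: Voronoi tessellation undefined")
  }
  ctr <- colMeans(pts)
  if (qr(sweep(pts, 2, ctr))$rank < 2) return(rep(NA_real_, n))
  dom <- attr(layout, "domain")
  rect <- list(x = c(0, dom[1], dom[1], 0), y = c(0, 0, dom[2], dom[2]))
  vapply(seq_len(n), function(i) {
    poly <- rect
    for (j in seq_len(n)[-i]) {
      poly <- .clip_halfplane(poly, pts[i, ], pts[j, ])
      if (length(poly$x) == 0) break
    }
    .polygon_area(poly)
  }, numeric(1))
}

# Sutherland-Hodgman clip of polygon `poly` to the half-plane of points
# closer to `a` than to `b` (boundary = perpendicular bisector).
.clip_halfplane <- function(poly, a, b) {
  nx <- b[1] - a[1]
  ny <- b[2] - a[2]
  m <- (a + b) / 2
  # inside: (p - m) . (b - a) <= 0
  side <- function(px, py) (px - m[1]) * nx + (py - m[2]) * ny
  xs <- poly$x; ys <- poly$y
  np <- length(xs)
  if (np == 0) return(poly)
  ox <- numeric(0); oy <- numeric(0)
  s_prev <- side(xs[np], ys[np])
  px <- xs[np]; py <- ys[np]
  for (k in seq_len(np)) {
    cx <- xs[k]; cy <- ys[k]
    s_cur <- side(cx, cy)
    if (s_cur <= 0) {
      if (s_prev > 0) {                 # entering: add intersection
        tt <- s_prev / (s_prev - s_cur)
        ox <- c(ox, px + tt * (cx - px)); oy <- c(oy, py + tt * (cy - py))
      }
      ox <- c(ox, cx); oy <- c(oy, cy)
    } else if (s_prev <= 0) {           # leaving: add intersection
      tt <- s_prev / (s_prev - s_cur)
      ox <- c(ox, px + tt * (cx - px)); oy <- c(oy, py + tt * (cy - py))
    }
    px <- cx; py <- cy; s_prev <- s_cur
  }
  list(x = ox, y = oy)
}

.polygon_area <- function(poly) {
  xs <- poly$x; ys <- poly$y
  np <- length(xs)
  if (np < 3) return(0)
  j <- c(np, seq_len(np - 1))
  abs(sum(xs[j] * ys - xs * ys[j])) / 2
}

#' Per-colony spatial feature table
#'
#' Computes every spatial feature for all founders of a layout, in the
#' fixed documented column order used by the fitness regression.
#'
#' @param layout a [colony_layout()].
#' @param iptg inducer level of the simulation, mM.
#' @param params parameter list.
#' @return data.frame with one row per founder and columns `founder_id`,
#'   `species`, `initial_biomass`, `iptg`, `nn_all`, `nn_se`, `nn_ec`,
#'   `ic_all`, `ic_se`, `ic_ec`, `rel_nn`, `inv_nn`, `log_inv_sq_nn`,
#'   `zeta`, `voronoi_area`, `dist_center` (the `_se` suffix = distances
#'   measured to cyanobacterial neighbours, `_ec` = to heterotroph
#'   neighbours). Undefined metrics are `NA`.
#' @export
colony_features <- function(layout, iptg = 0, params = default_params()) {
  data.frame(
    founder_id = layout$founder_id,
    species = layout$species,
    initial_biomass = layout$biomass,
    iptg = iptg,
    nn_all = nn_distance(layout),
    nn_se = nn_distance(layout, species = "cyanobacterium"),
    nn_ec = nn_distance(layout, species = "heterotroph"),
    ic_all = mean_ic_distance(layout),
    ic_se = mean_ic_distance(layout, species = "cyanobacterium"),
    ic_ec = mean_ic_distance(layout, species = "heterotroph"),
    rel_nn = relative_neighbor_distance(layout),
    inv_nn = inverse_neighbor_distance(layout),
    log_inv_sq_nn = log_inv_sq_neighbor_distance(layout),
    zeta = scaled_ic_distance(layout, params = params),
    voronoi_area = voronoi_areas(layout),
    dist_center = distance_from_center(layout),
    stringsAsFactors = FALSE
  )
}
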