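#' Nutrient concentration field
#'
#' A 3D concentration grid on cubic voxels with a per-nutrient diffusion
#' coefficient and boundary condition. Dirichlet fields hold their boundary
#' voxel layer at `bc_value` (a well-stirred, gas-permeable chamber wall);
#' Neumann fields have zero-flux (mirror) walls.
#'
#' @param name one of `"light"`, `"co2"`, `"o2"`, `"sucrose"` (any other
#'   name is allowed for custom fields if all constants are given).
#' @param domain domain box (Lx, Ly, Lz) in micrometres.
#' @param h voxel edge, micrometres; must divide every domain dimension.
#' @param D diffusion coefficient, m^2/s. Defaults from [nutrient_defaults()].
#' @param bc_type `"dirichlet"` or `"neumann"`.
#' @param bc_value boundary concentration (Dirichlet), kg/m^3.
#' @param initial_value initial uniform concentration, kg/m^3.
#' @return An object of class `nutrient_field` with the concentration array
#'   in `$grid` (dimensions `domain / h`).
#' @examples
#' f <- nutrient_field("co2", domain = c(40, 40, 10), h = 2)
#' dim(f$grid)
#' @export
nutrient_field <- function(name, domain = c(100, 100, 10), h = 2,
                           D = NULL, bc_type = NULL, bc_value = NULL,
                           initial_value = NULL) {
  defs <- nutrient_defaults()
  i <- match(name, defs$nutrient)
  if (is.null(D)) D <- if (!is.na(i)) defs$D[i] else stop("D required")
  if (is.null(bc_type)) {
    bc_type <- if (!is.na(i)) defs$bc_type[i] else stop("bc_type required")
  }
  bc_type <- match.arg(bc_type, c("dirichlet", "neumann"))
  if (is.null(bc_value)) {
    bc_value <- if (!is.na(i)) defs$concentration[i] else 0
  }
  if (is.null(initial_value)) {
    initial_value <- if (!is.na(i)) defs$concentration[i] else bc_value
  }
  dims <- domain / h
  if (any(abs(dims - round(dims)) > 1e-9) || any(round(dims) < 1)) {
    stop("voxel size h must divide every domain dimension")
  }
  dims <- as.integer(round(dims))
  f <- structure(list(
    name = name, domain = domain, h = h, dims = dims,
    D = D, bc_type = bc_type, bc_value = bc_value,
    initial_value = initial_value,
    grid = array(initial_value, dim = dims),
    .cache = new.env(parent = emptyenv())
  ), class = "nutrient_field")
  apply_boundary(f)
}

#' @export
#' @method print nutrient_field
print.nutrient_field <- function(x, ...) {
  cat(sprintf("<nutrient_field '%s'> %dx%dx%d voxels (h = %g um), %s BC\n",
              x$name, x$dims[1], x$dims[2], x$dims[3], x$h, x$bc_type))
  cat(sprintf("  D = %.3g m^2/s; concentration range [%.4g, %.4g] kg/m^3\n",
              x$D, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Apply the field's boundary condition
#'
#' Dirichlet: every face voxel is set to `bc_value` exactly. Neumann: no-op
#' (zero flux is enforced inside the solver by mirroring), so total mass is
#' conserved by this call.
#'
#' @param field a [nutrient_field()].
#' @return The field with boundaries applied.
#' @export
apply_boundary <- function(field) {
  if (field$bc_type == "dirichlet") {
    field$grid[.face_mask(field$dims)] <- field$bc_value
  }
  field
}

.face_mask <- function(dims) {
  ix <- slice.index(array(0L, dims), 1)
  iy <- slice.index(array(0L, dims), 2)
  iz <- slice.index(array(0L, dims), 3)
  ix == 1L | ix == dims[1] | iy == 1L | iy == dims[2] |
    iz == 1L | iz == dims[3]
}

# Assemble the 7-point Laplacian over "free" voxels (all voxels for Neumann;
# interior voxels for Dirichlet, whose face layer is held fixed). Returns the
# free-voxel index set, the sparse Laplacian L (units 1/m^2 after the 1/h^2
# scaling) and the fixed-boundary RHS contribution per unit D.
.field_operator <- function(field) {
  cache <- field$.cache
  if (!is.null(cache$op)) return(cache$op)
  dims <- field$dims
  n <- prod(dims)
  h_m <- field$h * 1e-6
  free <- if (field$bc_type == "dirichlet") which(!.face_mask(dims)) else seq_len(n)
  nfree <- length(free)
  op <- list(free = free, nfree = nfree)
  if (nfree == 0) {
    cache$op <- op
    return(op)
  }
  pos <- integer(n)          # voxel linear index -> free index (0 if fixed)
  pos[free] <- seq_len(nfree)
  ar <- array(seq_len(n), dim = dims)
  ii <- jj <- integer(0)
  diag_deg <- numeric(nfree)
  rhs_fix <- numeric(nfree)  # boundary coupling, to be multiplied by D/h^2 * bc
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- arrayInd(free, dims)
  for (s in shifts) {
    nb <- sweep(idx, 2, s, "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_lin <- rep(NA_integer_, nfree)
    nb_lin[inside] <- ar[nb[inside, , drop = FALSE]]
    nb_free <- inside & pos[ifelse(inside, nb_lin, 1L)] > 0
    # coupling to a free neighbour
    ii <- c(ii, which(nb_free))
    jj <- c(jj, pos[nb_lin[nb_free]])
    # any in-domain neighbour contributes to the diagonal; fixed neighbours
    # push their (Dirichlet) value to the RHS; out-of-domain = mirror (no term)
    diag_deg <- diag_deg + as.numeric(inside)
    fixed_nb <- inside & !nb_free
    rhs_fix[fixed_nb] <- rhs_fix[fixed_nb] + 1
  }
  L <- Matrix::sparseMatrix(
    i = c(ii, seq_len(nfree)), j = c(jj, seq_len(nfree)),
    x = c(rep(1, length(ii)), -diag_deg), dims = c(nfree, nfree)
  ) / h_m^2
  op$L <- L
  op$rhs_fix <- rhs_fix / h_m^2
  cache$op <- op
  op
}

.field_factor <- function(field, dt) {
  cache <- field$.cache
  key <- sprintf("f_%.8g", dt)
  if (!is.null(cache[[key]])) return(cache[[key]])
  op <- .field_operator(field)
  A <- Matrix::Diagonal(op$nfree, 1 / dt) - field$D * op$L
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  cache[[key]] <- fac
  fac
}

# One implicit-Euler step of dS/dt = D lap S + R on the free voxels, with
# consumption limiting: sinks in voxels that would be driven negative are
# scaled back so no voxel consumes more mass than is available.
.implicit_step <- function(field, R_free, dt, fac, op) {
  S_old <- field$grid[op$free]
  bc_term <- if (field$bc_type == "dirichlet") {
    field$D * op$rhs_fix * field$bc_value
  } else 0
  scale <- rep(1, op$nfree)
  sinks <- R_free < 0
  for (pass in 1:8) {
    R_lim <- ifelse(sinks, R_free * scale, R_free)
    rhs <- S_old / dt + R_lim + bc_term
    S_new <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
    neg <- S_new < -1e-14 * max(abs(S_old), 1)
    if (!any(neg & sinks)) break
    frac <- pmax(0, pmin(1, S_old / (S_old - S_new)))
    scale[neg & sinks] <- scale[neg & sinks] * frac[neg & sinks]
  }
  list(S = pmax(S_new, 0), scale = scale)
}

#' Relax a field to its quasi-steady state
#'
#' Iterates implicit pseudo-time steps of the mass balance
#' \eqn{\partial S/\partial t = \nabla\cdot(D \nabla S) + R} until the maximum
#' relative change per sweep drops below `tol` or `max_iters` is reached.
#' Each sweep is a sparse direct solve with a cached Cholesky factorization,
#' so for Dirichlet fields convergence to the steady diffusion balance takes
#' a handful of sweeps. Sinks are limited so that no voxel goes negative.
#'
#' @param field a [nutrient_field()].
#' @param R volumetric source/sink array, kg m^-3 s^-1, same dimensions as
#'   the grid (`R > 0` production, `R < 0` consumption).
#' @param tol relative-change convergence tolerance per sweep.
#' @param max_iters maximum sweeps.
#' @param dt_relax pseudo-time step, s; default is the domain diffusion time
#'   \eqn{L^2/D}, large enough that a sweep is close to a direct steady solve.
#' @return The relaxed field, with attributes `converged` (logical), `iters`
#'   and `rel_change`.
#' @export
solve_to_quasi_steady <- function(field, R = NULL, tol = 1e-6,
                                  max_iters = 100, dt_relax = NULL) {
  field <- apply_boundary(field)
  op <- .field_operator(field)
  if (op$nfree == 0) {                     # fully boundary-pinned grid
    attr(field, "converged") <- TRUE
    attr(field, "iters") <- 0L
    attr(field, "rel_change") <- 0
    attr(field, "sink_scale") <- array(1, dim = field$dims)
    return(field)
  }
  if (is.null(R)) R <- array(0, dim = field$dims)
  R_free <- as.numeric(R)[op$free]
  if (is.null(dt_relax)) {
    dt_relax <- (max(field$domain) * 1e-6)^2 / field$D
  }
  fac <- .field_factor(field, dt_relax)
  prev_change <- Inf
  n_growing <- 0L
  converged <- FALSE
  change <- NA_real_
  scale <- rep(1, op$nfree)
  for (it in seq_len(max_iters)) {
    S_old <- field$grid[op$free]
    step <- .implicit_step(field, R_free, dt_relax, fac, op)
    S_new <- step$S
    scale <- step$scale
    ref <- max(abs(S_old), abs(S_new), 1e-30)
    change <- max(abs(S_new - S_old)) / ref
    field$grid[op$free] <- S_new
    if (change < tol) {
      converged <- TRUE
      iters <- it
      break
    }
    if (change > prev_change * (1 + 1e-12)) {
      n_growing <- n_growing + 1L
      if (n_growing >= 10L) {
        stop("diffusion solver diverging for nutrient '", field$name,
             "' (residual grew over 10 consecutive sweeps)")
      }
    } else {
      n_growing <- 0L
    }
    prev_change <- change
    iters <- it
  }
  attr(field, "converged") <- converged
  attr(field, "iters") <- iters
  attr(field, "rel_change") <- change
  attr(field, "sink_scale") <- .full_scale(field, op, scale)
  field
}

# Expand a free-voxel sink-limiting vector to a full-grid array (fixed
# boundary voxels are never limited).
.full_scale <- function(field, op, scale) {
  full <- array(1, dim = field$dims)
  full[op$free] <- scale
  full
}

#' Advance a field in time
#'
#' Integrates the mass balance over a fixed interval with implicit-Euler
#' substeps (unconditionally stable; exactly mass-conserving for Neumann
#' walls up to the applied source term). Used by the driver for fields that
#' have no steady state, such as sucrose with zero-flux walls and a net
#' secretion source.
#'
#' @inheritParams solve_to_quasi_steady
#' @param dt interval to integrate over, s.
#' @param n_substeps number of implicit substeps.
#' @return The advanced field.
#' @export
advance_field <- function(field, R = NULL, dt, n_substeps = 1) {
  field <- apply_boundary(field)
  op <- .field_operator(field)
  if (op$nfree == 0) {
    attr(field, "sink_scale") <- array(1, dim = field$dims)
    return(field)
  }
  if (is.null(R)) R <- array(0, dim = field$dims)
  R_free <- as.numeric(R)[op$free]
  dt_sub <- dt / n_substeps
  fac <- .field_factor(field, dt_sub)
  scale <- rep(1, op$nfree)
  for (k in seq_len(n_substeps)) {
    step <- .implicit_step(field, R_free, dt_sub, fac, op)
    field$grid[op$free] <- step$S
    scale <- pmin(scale, step$scale)
  }
  attr(field, "sink_scale") <- .full_scale(field, op, scale)
  field
}

#' Total nutrient mass in the field
#'
#' @param field a [nutrient_field()].
#' @return Mass in kg (voxel volume times concentration, summed).
#' @export
field_mass <- function(field) {
  sum(field$grid) * (field$h * 1e-6)^3
}

#' Write a field snapshot as a VTK rectilinear grid
#'
#' Plain-text legacy VTK `STRUCTURED_POINTS` output, loadable by standard
#' scientific visualization tools.
#'
#' @param field a [nutrient_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  d <- field$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("consortsim field", field$name),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", field$h, field$h, field$h),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", field$name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(field$grid), digits = 10), con)
  invisible(path)
}
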