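#' Seed set for front initialization
#'
#' @param points integer matrix (n x 3) of 1-based voxel coordinates, or a
#'   length-3 vector for a single seed.
#' @param sphere_radius radius (voxels, >= 1) of the sphere grown around each
#'   seed.
#' @return object of class `seed_set`
#' @export
seed_set <- function(points, sphere_radius = 2) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L, sphere_radius >= 1)
  structure(list(points = points, sphere_radius = sphere_radius),
            class = "seed_set")
}

#' Level-set state
#'
#' The evolving function phi on the grid (signed distance convention:
#' negative inside) plus evolution bookkeeping.
#'
#' @param phi 3D numeric array.
#' @param iteration iteration counter.
#' @param time_step last time step used.
#' @param band_width narrow-band half-width in voxels.
#' @return object of class `levelset_state`
#' @export
levelset_state <- function(phi, iteration = 0L, time_step = NA_real_,
                           band_width = 3) {
  stopifnot(is.array(phi), length(dim(phi)) == 3L, all(is.finite(phi)))
  structure(list(phi = phi, iteration = as.integer(iteration),
                 time_step = time_step, band_width = band_width),
            class = "levelset_state")
}

#' Initialize phi as the signed distance to a union of seed spheres
#'
#' Exact Euclidean signed distance to the nearest sphere surface (the
#' distance to a union is the minimum of the per-sphere distances); negative
#' inside.
#'
#' @param seeds a [seed_set()].
#' @param grid_shape integer length-3.
#' @return a [levelset_state()]
#' @export
init_phi <- function(seeds, grid_shape) {
  stopifnot(inherits(seeds, "seed_set"))
  pts <- seeds$points
  if (nrow(pts) == 0L) stop("empty seed list")
  if (any(pts < 1) || any(t(pts) > grid_shape))
    stop("seed outside grid bounds")
  ax <- seq_len(grid_shape[1]); ay <- seq_len(grid_shape[2]); az <- seq_len(grid_shape[3])
  phi <- array(Inf, grid_shape)
  for (i in seq_len(nrow(pts))) {
    dx2 <- (ax - pts[i, 1])^2
    dy2 <- (ay - pts[i, 2])^2
    dz2 <- (az - pts[i, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - seeds$sphere_radius
    phi <- pmin(phi, d)
  }
  levelset_state(phi)
}

#' Godunov upwind gradient magnitude (5th-order WENO one-sided differences)
#'
#' Selects forward/backward stencils per the sign of the speed so information
#' flows outward for F > 0.
#'
#' @param phi 3D numeric array.
#' @param speed_sign +1 for an expanding front (F > 0), -1 for contraction.
#' @return 3D array of `|grad phi|`.
#' @export
upwind_gradient <- function(phi, speed_sign = 1) {
  stopifnot(all(is.finite(phi)))
  array(cpp_weno_gradmag(as.numeric(phi), as.integer(dim(phi)), speed_sign),
        dim(phi))
}

#' Mean curvature of the level sets of phi
#'
#' `kappa = div(grad phi / |grad phi|)` by central differences, with an
#' epsilon guard on degenerate gradients and values clamped to one inverse
#' voxel.
#'
#' @param phi 3D numeric array.
#' @return 3D array of curvature values.
#' @export
mean_curvature <- function(phi) {
  array(cpp_curvature(as.numeric(phi), as.integer(dim(phi))), dim(phi))
}

#' One explicit evolution step of the level-set PDE
#'
#' Updates `phi <- phi - dt * (F * |grad phi|_upwind - w * kappa *
#' |grad phi|_central)` with the CFL-bounded step
#' `dt = 0.5 / max(F + 6 w max|kappa|)` in voxel units. The curvature term
#' opposes growth (smoothing).
#'
#' @param state a [levelset_state()].
#' @param F_grid nonnegative 3D speed array matching `phi`.
#' @param curvature_weight nonnegative curvature weight `w` (default 0.1).
#' @return updated [levelset_state()]
#' @export
evolve_step <- function(state, F_grid, curvature_weight = 0.1) {
  phi <- state$phi
  stopifnot(all(dim(F_grid) == dim(phi)))
  if (any(F_grid < 0)) stop("speed must be nonnegative")
  w <- curvature_weight
  if (max(F_grid) == 0 && w == 0) {
    warning("zero speed and zero curvature weight: no-op step")
    state$iteration <- state$iteration + 1L
    state$time_step <- 0
    return(state)
  }
  dims <- as.integer(dim(phi))
  res <- cpp_evolve_step(as.numeric(phi), dims, as.numeric(F_grid), w,
                         state$band_width, 0L)
  state$phi <- array(res$phi, dim(phi))
  state$iteration <- state$iteration + 1L
  state$time_step <- res$dt
  state
}

#' Reinitialize phi toward a signed distance function
#'
#' Sign-preserving PDE redistancing (Sussman scheme): relaxes `|grad phi|`
#' back to 1 near the interface without moving the zero crossing set; the
#' sign of phi at every voxel is preserved exactly.
#'
#' @param state a [levelset_state()].
#' @param iterations number of redistancing sweeps (default 20).
#' @return updated [levelset_state()]
#' @export
reinitialize <- function(state, iterations = 20) {
  phi <- state$phi
  stopifnot(all(is.finite(phi)))
  out <- cpp_reinit(as.numeric(phi), as.integer(dim(phi)), as.integer(iterations))
  state$phi <- array(out, dim(phi))
  state
}

#' Extract the zero level set as a binary mask
#'
#' Inside is `phi < 0` (strict): voxels at exactly zero are outside.
#'
#' @param state a [levelset_state()] (or a bare phi array).
#' @return 3D logical array
#' @export
extract_zero_levelset <- function(state) {
  phi <- if (inherits(state, "levelset_state")) state$phi else state
  phi < 0
}
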