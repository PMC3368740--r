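#' Speed-function parameters
#'
#' The four gate thresholds and the neighbor-selection cone governing front
#' propagation. Defaults are the working set reported for corpus callosum
#' segmentation: PDD-x 0.55, collinearity 0.7, FA 0.1, speed floor 0.05.
#'
#' @param pdd_x_threshold minimum `|PDD_x(r)|` (left-right component) at the
#'   surface voxel, in `[0, 1]`.
#' @param collinearity_threshold minimum `|PDD(r) . PDD(n_r)|`, in `[0, 1]`.
#' @param fa_threshold minimum FA of the gated neighbor, in `[0, 1]`.
#' @param f_threshold speeds at or below this value are zeroed (>= 0).
#' @param normal_collinearity_cos cosine cutoff selecting 26-neighborhood
#'   offsets collinear with the surface normal (default cos 60 deg = 0.5).
#' @return object of class `speed_params`
#' @export
speed_params <- function(pdd_x_threshold = 0.55,
                         collinearity_threshold = 0.7,
                         fa_threshold = 0.1,
                         f_threshold = 0.05,
                         normal_collinearity_cos = 0.5) {
  p <- list(pdd_x_threshold = pdd_x_threshold,
            collinearity_threshold = collinearity_threshold,
            fa_threshold = fa_threshold,
            f_threshold = f_threshold,
            normal_collinearity_cos = normal_collinearity_cos)
  for (nm in c("pdd_x_threshold", "collinearity_threshold", "fa_threshold",
               "normal_collinearity_cos"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (p$f_threshold < 0) stop("f_threshold must be nonnegative")
  structure(p, class = "speed_params")
}

#' Outward unit normals of the zero level set
#'
#' `n = grad phi / |grad phi|` by central differences (outward because phi is
#' negative inside). Voxels with a degenerate gradient return NA rows and are
#' skipped by the speed computation.
#'
#' @param phi 3D numeric array.
#' @param surface_voxels integer matrix (n x 3) of 1-based voxel coordinates.
#' @return n x 3 matrix of unit normals (NA rows where degenerate).
#' @export
surface_normals <- function(phi, surface_voxels) {
  v <- as.matrix(surface_voxels)
  d <- dim(phi)
  grad_axis <- function(ax) {
    up <- v; up[, ax] <- pmin(v[, ax] + 1L, d[ax])
    dn <- v; dn[, ax] <- pmax(v[, ax] - 1L, 1L)
    (phi[up] - phi[dn]) / 2
  }
  g <- cbind(grad_axis(1), grad_axis(2), grad_axis(3))
  nrm <- sqrt(rowSums(g^2))
  out <- g / nrm
  out[nrm < 1e-8, ] <- NA_real_
  out
}

# the 26-neighborhood offsets with unit vectors, fixed ordering
neighborhood26 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  list(offsets = o, units = o / sqrt(rowSums(o^2)))
}

#' Neighbors collinear with the surface normal
#'
#' Returns the subset of the 26-neighborhood whose unit offset vector `o`
#' satisfies `o . normal > normal_collinearity_cos`; out-of-bounds neighbors
#' are dropped.
#'
#' @param voxel integer length-3, 1-based coordinate.
#' @param normal unit 3-vector.
#' @param params a [speed_params()].
#' @param grid_shape integer length-3 (bounds; `NULL` skips bounds checks).
#' @return integer matrix of neighbor coordinates (possibly 0 rows).
#' @export
collinear_neighbors <- function(voxel, normal, params = speed_params(),
                                grid_shape = NULL) {
  nb <- neighborhood26()
  keep <- drop(nb$units %*% normal) > params$normal_collinearity_cos
  nbrs <- sweep(nb$offsets[keep, , drop = FALSE], 2, as.integer(voxel), "+")
  if (!is.null(grid_shape)) {
    inb <- nbrs[, 1] >= 1 & nbrs[, 2] >= 1 & nbrs[, 3] >= 1 &
      nbrs[, 1] <= grid_shape[1] & nbrs[, 2] <= grid_shape[2] &
      nbrs[, 3] <= grid_shape[3]
    nbrs <- nbrs[inb, , drop = FALSE]
  }
  dimnames(nbrs) <- NULL
  nbrs
}

#' Propagation gate between a surface voxel and one neighbor
#'
#' True iff `|PDD(r) . PDD(n_r)| > collinearity_threshold`, `FA(n_r) >
#' fa_threshold`, and `|PDD_x(r)| > pdd_x_threshold`. Absolute values make
#' the test independent of the arbitrary eigenvector sign. An undefined PDD
#' (zero vector) at either voxel fails.
#'
#' @param pdd_r,pdd_n unit PDD vectors at the surface voxel and neighbor.
#' @param fa_n FA at the neighbor.
#' @param params a [speed_params()].
#' @return logical scalar
#' @export
gate <- function(pdd_r, pdd_n, fa_n, params = speed_params()) {
  if (all(pdd_r == 0) || all(pdd_n == 0)) return(FALSE)
  abs(sum(pdd_r * pdd_n)) > params$collinearity_threshold &&
    fa_n > params$fa_threshold &&
    abs(pdd_r[1]) > params$pdd_x_threshold
}

#' Tensor-trace similarity speed at one voxel
#'
#' `F(r) = sum over gated neighbors of FA(r) FA(n_r) tr(D(r) D(n_r)) /
#' (tr D(r) tr D(n_r))`, with terms whose trace product is below 1e-20
#' contributing zero, followed by the speed floor: `F <= f_threshold` is set
#' to 0. Each summand lies in `[0, 1]` for positive-semidefinite tensors.
#'
#' @param r integer length-3 voxel coordinate.
#' @param neighbors integer matrix of (already gate-filtered) neighbor
#'   coordinates.
#' @param tensors a [tensor_volume()].
#' @param fa 3D FA array.
#' @param params a [speed_params()].
#' @return nonnegative scalar speed
#' @export
similarity_speed <- function(r, neighbors, tensors, fa, params = speed_params()) {
  Dr <- tensor_at(tensors, r)
  tr_r <- sum(diag(Dr))
  fa_r <- fa[r[1], r[2], r[3]]
  acc <- 0
  for (i in seq_len(nrow(neighbors))) {
    nb <- neighbors[i, ]
    Dn <- tensor_at(tensors, nb)
    den <- tr_r * sum(diag(Dn))
    if (den < 1e-20) next
    acc <- acc + fa_r * fa[nb[1], nb[2], nb[3]] * sum(Dr * Dn) / den
  }
  if (acc <= params$f_threshold) 0 else acc
}

#' Speed field on the narrow band
#'
#' Computes the gated similarity speed at surface voxels (inside voxels with
#' an outside face-neighbor, so the gated neighbors in the outward-normal
#' cone are the prospective voxels) and extends it constantly along normals
#' to all narrow-band voxels (`|phi| <= band`) by nearest-surface-voxel fill.
#' Everywhere else the speed is zero.
#'
#' @param state a [levelset_state()].
#' @param tensors a [tensor_volume()].
#' @param features feature fields from [compute_feature_fields()].
#' @param params a [speed_params()].
#' @return list with `values` (3D array >= 0) and `support` (logical array of
#'   surface voxels where the speed was computed directly).
#' @export
compute_speed_field <- function(state, tensors, features, params = speed_params()) {
  phi <- state$phi
  d <- as.integer(dim(phi))
  Fv <- cpp_speed_field(as.numeric(phi), d, as.numeric(features$fa),
                        matrix(features$pdd, ncol = 3L),
                        tensor_flat(tensors),
                        params$pdd_x_threshold, params$collinearity_threshold,
                        params$fa_threshold, params$f_threshold,
                        params$normal_collinearity_cos, state$band_width)
  inside <- phi < 0
  shift_ge0 <- function(ax, dir) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- if (dir > 0) c(2:n, n) else c(1, 1:(n - 1))
    idx[[ax]] <- src
    do.call(`[`, c(list(phi >= 0), idx))
  }
  surf <- inside & (shift_ge0(1, 1) | shift_ge0(1, -1) | shift_ge0(2, 1) |
                      shift_ge0(2, -1) | shift_ge0(3, 1) | shift_ge0(3, -1))
  list(values = array(Fv, dim(phi)), support = surf)
}
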