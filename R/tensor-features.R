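#' Eigen-decomposition of a symmetric 3x3 tensor
#'
#' @param tensor symmetric 3x3 matrix.
#' @return list with `values` (descending eigenvalues) and `vectors`
#'   (orthonormal columns forming a right-handed set).
#' @export
eigendecompose <- function(tensor) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3, 3)))
  if (max(abs(tensor - t(tensor))) > 1e-10 * max(1, max(abs(tensor))))
    stop("tensor is not symmetric")
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]  # make right-handed
  list(values = e$values, vectors = V)
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((l_i - mean)^2)) / sqrt(sum(l_i^2))`, the
#' standard normalized eigenvalue dispersion in `[0, 1]`. An all-zero input
#' returns 0 by convention.
#'
#' @param lambda numeric length-3, nonnegative eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fractional_anisotropy <- function(lambda) {
  stopifnot(length(lambda) == 3L)
  if (any(lambda < 0)) stop("eigenvalues must be nonnegative")
  s2 <- sum(lambda^2)
  if (s2 == 0) return(0)
  min(1, sqrt(1.5 * sum((lambda - mean(lambda))^2) / s2))
}

#' Principal diffusion direction of a tensor
#'
#' Unit eigenvector of the largest eigenvalue, with the sign canonicalized so
#' the x-component is nonnegative (ties broken on y, then z). The zero tensor
#' returns the zero vector, flagging the direction as undefined.
#'
#' @param tensor symmetric positive-semidefinite 3x3 matrix.
#' @return unit 3-vector, or the zero vector for the zero tensor.
#' @export
principal_direction <- function(tensor) {
  if (all(tensor == 0)) return(c(0, 0, 0))
  e <- eigendecompose(tensor)
  canonical_sign(e$vectors[, 1])
}

canonical_sign <- function(v) {
  s <- 1
  if (v[1] < -1e-12) s <- -1
  else if (abs(v[1]) <= 1e-12) {
    if (v[2] < -1e-12) s <- -1
    else if (abs(v[2]) <= 1e-12 && v[3] < 0) s <- -1
  }
  s * v
}

#' Per-voxel FA and principal-direction fields
#'
#' Vectorized eigen-analysis of a whole tensor volume. Voxels whose leading
#' eigenvalue is degenerate with the second (within `degen_tol`, relative) or
#' non-positive get a zero direction vector: the PDD is undefined there and
#' downstream gates treat it as failing.
#'
#' @param volume a [tensor_volume()].
#' @param degen_tol relative eigenvalue gap below which the PDD is flagged
#'   unstable (default 1e-9).
#' @return list with `fa` (3D array in `[0, 1]`), `pdd` (4D array, last dim 3,
#'   canonical sign), `evals` (4D array, descending), `unstable` (3D logical).
#' @export
compute_feature_fields <- function(volume, degen_tol = 1e-9) {
  d <- tensor_dim(volume)
  res <- cpp_eig3_fields(tensor_flat(volume), d, degen_tol)
  list(fa = array(res$fa, d),
       pdd = array(res$pdd, c(d, 3L)),
       evals = array(res$evals, c(d, 3L)),
       unstable = array(res$unstable, d))
}
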