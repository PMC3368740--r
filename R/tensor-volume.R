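#' Diffusion tensor volume
#'
#' A 3D grid of symmetric 3x3 diffusion tensors stored as a 4D array whose
#' fourth dimension holds the six unique components in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the common NIfTI tensor dialect. Units are
#' mm^2/s. Axis 1 is left-right (x), axis 2 anterior-posterior (y), axis 3
#' inferior-superior (z).
#'
#' @param tensors 4D numeric array, `dim = c(nx, ny, nz, 6)`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(tensors, voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(tensors), length(dim(tensors)) == 4L, dim(tensors)[4] == 6L)
  if (!all(is.finite(tensors))) stop("tensor components must be finite")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(tensors = tensors, voxel_size = voxel_size),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf("<tensor_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.tensor_volume <- function(x) dim(x$tensors)[1:3]

#' Grid dimensions of a tensor volume
#' @param volume a `tensor_volume`
#' @return integer length-3 grid shape
#' @export
grid_shape <- function(volume) dim(volume$tensors)[1:3]

# flatten to the n x 6 / length-n*6 layout the C++ kernels expect
tensor_flat <- function(volume) as.numeric(volume$tensors)

tensor_dim <- function(volume) as.integer(dim(volume$tensors)[1:3])

#' Extract one tensor as a 3x3 symmetric matrix
#'
#' @param volume a `tensor_volume`
#' @param voxel integer length-3, 1-based voxel index
#' @return 3x3 symmetric matrix
#' @export
tensor_at <- function(volume, voxel) {
  v <- volume$tensors[voxel[1], voxel[2], voxel[3], ]
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

#' Build a tensor volume from a per-voxel constructor
#'
#' Convenience for tests and phantoms: `f(x, y, z)` returns a 3x3 symmetric
#' matrix (or NULL for the zero tensor) for each voxel.
#' @param shape integer length-3 grid shape
#' @param f function of (x, y, z) voxel indices returning a 3x3 matrix
#' @param voxel_size voxel size in mm
#' @return a `tensor_volume`
#' @export
tensor_volume_from_function <- function(shape, f, voxel_size = c(1, 1, 1)) {
  a <- array(0, c(shape, 6L))
  for (z in seq_len(shape[3])) for (y in seq_len(shape[2])) for (x in seq_len(shape[1])) {
    M <- f(x, y, z)
    if (!is.null(M)) a[x, y, z, ] <- sym_to_six(M)
  }
  tensor_volume(a, voxel_size)
}

# 3x3 symmetric matrix -> 6 components (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
sym_to_six <- function(M) c(M[1, 1], M[1, 2], M[2, 2], M[1, 3], M[2, 3], M[3, 3])

six_to_sym <- function(v) matrix(c(v[1], v[2], v[4],
                                   v[2], v[3], v[5],
                                   v[4], v[5], v[6]), 3, 3)

# anisotropic tensor with principal direction `dir` and eigenvalues `ev`
# (descending); the two minor axes are an arbitrary orthonormal completion.
tensor_from_direction <- function(dir, ev) {
  e1 <- dir / sqrt(sum(dir^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  V <- cbind(e1, e2, e3)
  V %*% diag(ev) %*% t(V)
}
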