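#' Diffusion gradient table
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions in the scanner
#' frame. At least one b = 0 reference volume is required and every nonzero
#' direction must have unit norm.
#'
#' @param bvals numeric vector of b-values.
#' @param bvecs numeric matrix, one row per volume, 3 columns.
#' @return An object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns")
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs describe different numbers of volumes")
  if (!any(bvals == 0)) stop("gradient table has no b = 0 reference volume")
  nz <- bvals > 0
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("nonzero gradient directions must be unit vectors (tolerance 1e-6)")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' Read an FSL-style bval/bvec pair
#'
#' bvals: one row of whitespace-separated values; bvecs: three rows (x, y, z)
#' with one column per volume.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return a [gradient_table()]
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3L) stop("bvec file must have exactly 3 rows")
  gradient_table(bvals, t(bv))
}

#' Read a 4D diffusion-weighted NIfTI volume with its gradient table
#'
#' @param path NIfTI file (.nii or .nii.gz) with one volume per gradient.
#' @param bval_path,bvec_path FSL-style gradient table files.
#' @return list with `dwi` (4D array), `gradients` (a [gradient_table()]),
#'   and `voxel_size` (mm).
#' @export
read_dwi <- function(path, bval_path, bvec_path) {
  if (!file.exists(path)) stop("DWI file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L) stop("expected a 4D DWI volume")
  gt <- read_gradient_table(bval_path, bvec_path)
  if (length(gt$bvals) != dim(a)[4])
    stop(sprintf("gradient table has %d rows but the DWI has %d volumes",
                 length(gt$bvals), dim(a)[4]))
  vox <- RNifti::pixdim(img)[1:3]
  list(dwi = a, gradients = gt, voxel_size = as.numeric(vox))
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves `log(S_i / S0) = -b_i g_i' D g_i` in the least-squares
#' sense with a single design-matrix pseudo-inverse shared by all voxels. S0
#' is the mean of the b = 0 volumes. Negative fitted eigenvalues are clamped
#' to zero; voxels with S0 <= 0 get the zero tensor.
#'
#' @param dwi 4D intensity array (nx, ny, nz, nvol).
#' @param gradients a [gradient_table()].
#' @param voxel_size voxel size in mm for the returned volume.
#' @return a [tensor_volume()]
#' @export
fit_tensors <- function(dwi, gradients, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(dwi)) == 4L)
  b <- gradients$bvals
  g <- gradients$bvecs
  nz <- which(b > 0)
  gn <- g[nz, , drop = FALSE]
  if (qr(gn)$rank < 3L || nrow(unique(round(gn, 10))) < 6L)
    stop("at least 6 distinct nonzero gradient directions are required")
  # design row: b * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2)
  B <- cbind(gn[, 1]^2, 2 * gn[, 1] * gn[, 2], gn[, 2]^2,
             2 * gn[, 1] * gn[, 3], 2 * gn[, 2] * gn[, 3], gn[, 3]^2) * b[nz]
  pinv <- solve(crossprod(B), t(B))
  d <- dim(dwi)
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nrow = nvox)
  s0 <- if (sum(b == 0) == 1L) S[, b == 0] else rowMeans(S[, b == 0, drop = FALSE])
  ok <- s0 > 0
  logr <- matrix(0, nvox, length(nz))
  Si <- S[ok, nz, drop = FALSE]
  Si[Si <= 0] <- .Machine$double.eps
  logr[ok, ] <- log(Si / s0[ok])
  D <- -logr %*% t(pinv)
  D[!ok, ] <- 0
  dim6 <- as.integer(d[1:3])
  flat <- cpp_clamp_psd(as.numeric(D), dim6)
  tensor_volume(array(flat, c(d[1:3], 6L)), voxel_size)
}

#' Resample a volume onto an isotropic grid
#'
#' Component-wise trilinear interpolation onto a grid with cubic voxels of
#' edge `target_voxel_mm` (default 1.9 mm). Output grid dimensions default to
#' `round(field_of_view / target)` per axis and can be overridden with
#' `out_shape` (some acquisition protocols quote a nominal grid, e.g. 128 in
#' plane, that does not exactly match the field of view). Tensor outputs are
#' re-symmetrized by construction (components are interpolated independently).
#'
#' @param volume a [tensor_volume()] or a 3D scalar array with attribute-free
#'   unit voxel spacing given in `voxel_size`.
#' @param target_voxel_mm positive scalar, target isotropic spacing.
#' @param out_shape optional integer length-3 output grid shape.
#' @param voxel_size input spacing when `volume` is a plain array.
#' @return same kind of object as the input, on the new grid.
#' @export
resample_isotropic <- function(volume, target_voxel_mm = 1.9, out_shape = NULL,
                               voxel_size = NULL) {
  if (target_voxel_mm <= 0) stop("target voxel size must be positive")
  is_tv <- inherits(volume, "tensor_volume")
  vox <- if (is_tv) volume$voxel_size else as.numeric(voxel_size)
  if (is.null(vox)) stop("voxel_size required for plain arrays")
  a <- if (is_tv) volume$tensors else volume
  din <- dim(a)[1:3]
  if (is.null(out_shape)) {
    if (all(abs(vox - target_voxel_mm) < 1e-12)) out_shape <- din
    else out_shape <- pmax(1L, as.integer(round(din * vox / target_voxel_mm)))
  }
  ncomp <- if (is_tv) 6L else 1L
  flat <- cpp_trilinear_resample(as.numeric(a), as.integer(din), vox,
                                 as.integer(out_shape), rep(target_voxel_mm, 3),
                                 ncomp)
  if (is_tv)
    tensor_volume(array(flat, c(out_shape, 6L)), rep(target_voxel_mm, 3))
  else
    array(flat, out_shape)
}

#' Write a tensor volume as a 6-component NIfTI
#' @param volume a [tensor_volume()]
#' @param path output .nii or .nii.gz path
#' @return `path`, invisibly
#' @export
write_tensor_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$tensors)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 6-component tensor NIfTI written by [write_tensor_volume()]
#' @param path input NIfTI path
#' @return a [tensor_volume()]
#' @export
read_tensor_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L || dim(a)[4] != 6L)
    stop("expected a 4D NIfTI with 6 tensor components")
  a <- array(as.numeric(a), dim(a))  # drop NIfTI image attributes
  tensor_volume(a, as.numeric(RNifti::pixdim(img)[1:3]))
}

#' Write a binary mask or label volume as uint8 NIfTI
#' @param mask 3D array (logical or small integer)
#' @param path output path
#' @param voxel_size voxel size in mm
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  a <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a mask/label NIfTI as an integer array
#' @param path input path
#' @return 3D integer array
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.integer(round(a)), dim(a))
}
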