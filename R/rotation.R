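#' Euler rotation matrix R = Rx(azimuth) Ry(elevation) Rz(skew)
#'
#' Product of standard right-handed rotations about the x, y, and z axes, in
#' that order, with angles in degrees.
#'
#' @param azimuth_deg rotation about x (left-right axis).
#' @param elevation_deg rotation about y (anterior-posterior axis).
#' @param skew_deg rotation about z (inferior-superior axis).
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
euler_rotation_matrix <- function(azimuth_deg = 0, elevation_deg = 0, skew_deg = 0) {
  stopifnot(is.finite(azimuth_deg), is.finite(elevation_deg), is.finite(skew_deg))
  a <- azimuth_deg * pi / 180
  b <- elevation_deg * pi / 180
  c <- skew_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Rotate a masked region of a tensor volume (tumor mass-effect surrogate)
#'
#' Rotates the content of `mask` dilated by `margin_voxels` about `center`:
#' each output voxel whose inverse-rotated coordinate falls inside the
#' dilated region samples the input tensor there (nearest neighbor) and
#' reorients it as `T' = R T R'`, so principal directions co-rotate
#' (`PDD' = R PDD`). Voxels outside the rotated region keep their original
#' values. Errors if the region would rotate outside the grid.
#'
#' @param tensors a [tensor_volume()].
#' @param mask 3D logical array (the structure to rotate).
#' @param R 3x3 rotation matrix (see [euler_rotation_matrix()]).
#' @param center rotation center in 1-based voxel coordinates; defaults to
#'   the mask centroid.
#' @param margin_voxels dilation margin (default 5 voxels, Chebyshev).
#' @return list with `tensors` (rotated [tensor_volume()]), `rotated`
#'   (logical array of voxels whose content was replaced), `center`, `region`
#'   (the dilated input-space region).
#' @export
rotate_region <- function(tensors, mask, R, center = NULL, margin_voxels = 5L) {
  stopifnot(inherits(tensors, "tensor_volume"))
  d <- tensor_dim(tensors)
  stopifnot(all(dim(mask) == d))
  if (sum(mask) == 0) stop("mask is empty")
  if (is.null(center)) {
    ci <- arrayInd(which(mask), d)
    center <- colMeans(ci)
  }
  region <- array(cpp_dilate(as.logical(mask), d, as.integer(margin_voxels)), d)
  res <- cpp_rotate_region(tensor_flat(tensors), d, as.logical(region),
                           R, as.numeric(center) - 1)  # 0-based centers in C++
  if (isTRUE(res$out_of_bounds))
    stop("rotation maps the region outside the grid")
  list(tensors = tensor_volume(array(res$tensors, c(d, 6L)), tensors$voxel_size),
       rotated = array(res$rotated, d),
       center = center, region = region)
}

#' Rotate a mask/label volume by nearest-neighbor pullback
#'
#' @param vol 3D array (logical or integer labels).
#' @param R 3x3 rotation matrix.
#' @param center rotation center, 1-based voxel coordinates.
#' @return rotated array of the same storage mode (out-of-grid samples are 0).
#' @export
rotate_volume_nn <- function(vol, R, center) {
  d <- dim(vol)
  out <- cpp_rotate_volume_nn(as.numeric(vol), as.integer(d), R,
                              as.numeric(center) - 1, 0)
  out <- array(out, d)
  if (is.logical(vol)) out > 0.5
  else if (is.integer(vol)) array(as.integer(round(out)), d)
  else out
}

#' Rotation-reproducibility experiment
#'
#' For each angle about the given axis: rotate the corpus callosum and its
#' neighborhood, rotate the seeds, re-segment, pull the re-segmentation back
#' to the original frame, and compute per-subdivision Dice against the
#' baseline Witelson labels. At angle 0 the Dice is 1 by construction.
#'
#' @param tensors a [tensor_volume()].
#' @param baseline_labels a `witelson_labels` for the baseline segmentation.
#' @param mask baseline binary mask (defines the rotated region and center).
#' @param seeds a [seed_set()].
#' @param params a [speed_params()].
#' @param angles_deg rotation angles in degrees (default 5-30 by 5).
#' @param axis one of "azimuth" (x), "elevation" (y), "skew" (z).
#' @param margin_voxels neighborhood margin (default 5).
#' @param ... passed to [segment_corpus_callosum()] (e.g. `max_iters`).
#' @return data.frame with columns axis, angle_deg, subdivision, dice.
#' @export
rotation_reproducibility_experiment <- function(tensors, baseline_labels, mask,
                                                seeds, params = speed_params(),
                                                angles_deg = seq(5, 30, by = 5),
                                                axis = c("azimuth", "elevation", "skew"),
                                                margin_voxels = 5L, ...) {
  axis <- match.arg(axis)
  d <- tensor_dim(tensors)
  ci <- arrayInd(which(mask), d)
  center <- colMeans(ci)
  nm <- names(witelson_label_names())
  rows <- list()
  for (ang in angles_deg) {
    args <- c(azimuth_deg = 0, elevation_deg = 0, skew_deg = 0)
    args[[paste0(switch(axis, azimuth = "azimuth", elevation = "elevation",
                        skew = "skew"), "_deg")]] <- ang
    R <- do.call(euler_rotation_matrix, as.list(args))
    if (ang == 0) {
      seg_mask <- mask
    } else {
      rot <- rotate_region(tensors, mask, R, center, margin_voxels)
      spts <- sweep(seeds$points, 2, center)
      spts <- round(spts %*% t(R))
      spts <- sweep(spts, 2, center, "+")
      spts[, 1] <- pmin(pmax(spts[, 1], 1), d[1])
      spts[, 2] <- pmin(pmax(spts[, 2], 1), d[2])
      spts[, 3] <- pmin(pmax(spts[, 3], 1), d[3])
      seg <- segment_corpus_callosum(rot$tensors,
                                     seed_set(spts, seeds$sphere_radius),
                                     params, ...)
      # pull the re-segmentation back to the baseline frame for comparison
      seg_mask <- rotate_volume_nn(seg$mask, t(R), center)
    }
    for (k in seq_along(nm)) {
      ref_k <- baseline_labels$labels == k
      # per-subdivision: auto voxels restricted to the subdivision's bin
      dice_k <- dice(seg_mask & bin_of(baseline_labels, k), ref_k)$dice
      rows[[length(rows) + 1L]] <- data.frame(axis = axis, angle_deg = ang,
                                              subdivision = nm[k],
                                              dice = dice_k)
    }
  }
  do.call(rbind, rows)
}

# all voxels that would carry label k under the baseline parcellation
# (the subdivision's y-bin extended over the grid, plus the geometric
# rostrum/genu rules); used to parcel a re-segmentation consistently.
bin_of <- function(w, k) {
  d <- dim(w$labels)
  y_max <- w$extent["y_max"]
  N <- w$extent["y_max"] - w$extent["y_min"] + 1L
  ygrid <- array(rep(seq_len(d[2]), each = d[1]), d)
  a <- pmin(pmax(y_max - ygrid + 1L, 1L), N)
  cuts <- w$cuts
  if (k >= 4L) {
    lo <- c(0L, cuts)[k - 2L]
    hi <- c(cuts, N)[k - 2L]
    return(a > lo & a <= hi)
  }
  ant <- a <= cuts[1]
  if (is.null(w$critical_point)) {
    genu_cut <- round(N / 6)
    if (k == 1L) return(array(FALSE, d))
    if (k == 2L) return(ant & a <= genu_cut)
    return(ant & a > genu_cut)
  }
  yc <- w$critical_point[1]; zc <- w$critical_point[2]
  zgrid <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  rostrum <- ant & zgrid < zc & ygrid < yc
  genu_cut <- round(N / 6)
  genu <- ant & !rostrum & (a <= genu_cut | zgrid <= zc)
  switch(k, rostrum, genu, ant & !rostrum & !genu)
}

#' Summarize a rotation experiment across replicates
#'
#' @param reports data.frame rbind of [rotation_reproducibility_experiment()]
#'   results over replicates (an extra `replicate` column is allowed).
#' @return data.frame with mean and sd of Dice per axis/angle/subdivision.
#' @export
summarize_rotation_reports <- function(reports) {
  agg <- stats::aggregate(dice ~ axis + angle_deg + subdivision, data = reports,
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(agg[, 1:3], dice_mean = agg$dice[, "mean"],
                    dice_sd = agg$dice[, "sd"])
  out[order(out$axis, out$angle_deg, out$subdivision), ]
}
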