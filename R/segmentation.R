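#' Segment the corpus callosum by gated level-set front propagation
#'
#' Top-level driver: initializes phi as spheres around the seeds, then
#' iterates speed-field computation and level-set evolution (with periodic
#' redistancing) until the zero-level-set voxel set is unchanged for
#' `stable_iters` consecutive iterations or `max_iters` is reached.
#'
#' @param tensors a [tensor_volume()].
#' @param seeds a [seed_set()] (1-based voxel coordinates). Seeds should lie
#'   in voxels passing the FA and PDD-x gates; a warning is issued otherwise.
#' @param params a [speed_params()].
#' @param max_iters iteration cap (default 500).
#' @param curvature_weight smoothing weight (default 0.1).
#' @param stable_iters consecutive unchanged-mask iterations defining
#'   convergence (default 5).
#' @param reinit_every redistance the level-set function every this many
#'   iterations (default 20).
#' @param features optional precomputed [compute_feature_fields()] result.
#' @param verbose print progress every 10 iterations.
#' @return object of class `segmentation_result`: list with `mask` (logical
#'   array), `iterations_run`, `converged`, `params_used`, `state`.
#' @export
segment_corpus_callosum <- function(tensors, seeds, params = speed_params(),
                                    max_iters = 500L, curvature_weight = 0.1,
                                    stable_iters = 5L, reinit_every = 20L,
                                    features = NULL, verbose = FALSE) {
  stopifnot(inherits(tensors, "tensor_volume"), inherits(seeds, "seed_set"))
  d <- grid_shape(tensors)
  if (is.null(features)) features <- compute_feature_fields(tensors)
  for (i in seq_len(nrow(seeds$points))) {
    p <- seeds$points[i, ]
    fa_ok <- features$fa[p[1], p[2], p[3]] > params$fa_threshold
    px_ok <- abs(features$pdd[p[1], p[2], p[3], 1]) > params$pdd_x_threshold
    if (!fa_ok || !px_ok)
      warning(sprintf("seed (%d,%d,%d) does not pass the FA/PDD-x gates",
                      p[1], p[2], p[3]))
  }
  state <- init_phi(seeds, d)
  # flat views reused across iterations
  dims <- as.integer(d)
  phi <- as.numeric(state$phi)
  band <- state$band_width
  fa_v <- as.numeric(features$fa)
  pdd_m <- matrix(features$pdd, ncol = 3L)
  tens_v <- tensor_flat(tensors)
  prev_mask <- phi < 0
  stable <- 0L
  iters <- 0L
  converged <- FALSE
  dt <- NA_real_
  while (iters < max_iters) {
    Fv <- cpp_speed_field(phi, dims, fa_v, pdd_m, tens_v,
                          params$pdd_x_threshold, params$collinearity_threshold,
                          params$fa_threshold, params$f_threshold,
                          params$normal_collinearity_cos, band)
    # smoothing regularizes the moving front only: a stalled front stays put
    res <- cpp_evolve_step(phi, dims, Fv, curvature_weight, band, 1L)
    phi <- res$phi
    dt <- res$dt
    iters <- iters + 1L
    if (iters %% reinit_every == 0L) phi <- cpp_reinit(phi, dims, 10L)
    mask <- phi < 0
    if (identical(mask, prev_mask)) {
      stable <- stable + 1L
      if (stable >= stable_iters) { converged <- TRUE; break }
    } else stable <- 0L
    prev_mask <- mask
    if (verbose && iters %% 10L == 0L)
      message(sprintf("iter %d: %d voxels inside", iters, sum(mask)))
  }
  state <- levelset_state(array(phi, d), iteration = iters, time_step = dt,
                          band_width = band)
  mask <- extract_zero_levelset(state)
  if (converged && sum(mask) == 0)
    stop("segmentation converged to an empty mask: check seed placement")
  structure(list(mask = mask, iterations_run = iters, converged = converged,
                 params_used = params, state = state),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d voxels, %d iterations, %s\n",
              sum(x$mask), x$iterations_run,
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}

#' Propose seed voxels on a sagittal slice
#'
#' Convenience extension (off the manual-seeding path): ranks voxels on the
#' given sagittal slice by `|PDD_x| * FA` and returns the top `n` spread at
#' least `min_dist` voxels apart.
#'
#' @param features feature fields from [compute_feature_fields()].
#' @param slice_x 1-based sagittal slice index.
#' @param n number of seeds.
#' @param min_dist minimum separation between proposed seeds (voxels).
#' @return a [seed_set()]
#' @export
propose_seeds <- function(features, slice_x, n = 5L, min_dist = 6) {
  score <- abs(features$pdd[slice_x, , , 1]) * features$fa[slice_x, , ]
  ord <- order(score, decreasing = TRUE)
  picked <- matrix(integer(0), 0, 3)
  for (k in ord) {
    if (score[k] <= 0) break
    yz <- arrayInd(k, dim(score))
    cand <- c(slice_x, yz[1], yz[2])
    if (nrow(picked) == 0 ||
        min(sqrt(rowSums(sweep(picked, 2, cand)^2))) >= min_dist)
      picked <- rbind(picked, cand)
    if (nrow(picked) >= n) break
  }
  if (nrow(picked) == 0) stop("no voxel on the slice passes the gates")
  seed_set(picked)
}

#' JSON-able run report for a segmentation
#' @param result a `segmentation_result`
#' @param voxel_size voxel size in mm (for the volume in mm^3)
#' @return list suitable for `jsonlite::toJSON`
#' @export
segmentation_report <- function(result, voxel_size = c(1, 1, 1)) {
  nv <- sum(result$mask)
  list(voxels = nv,
       volume_mm3 = nv * prod(voxel_size),
       iterations = result$iterations_run,
       converged = result$converged,
       params = unclass(result$params_used))
}
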