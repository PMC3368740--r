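#' Specification of the synthetic corpus-callosum tensor phantom
#'
#' The phantom emulates, on a voxel grid, the diffusion geometry the
#' segmentation exploits: an arch-shaped commissural bundle whose principal
#' diffusion direction is dominantly left-right (x) through the body and
#' rotates toward an anterior/posterior fan at the genu and splenium ends
#' (staying above the PDD-x gate inside the bundle), a rostrum recurve at
#' the anterior-inferior end, and labeled distractor bundles: cingulum
#' (anterior-posterior tubes two voxels superior, blocked by the
#' collinearity gate), forceps (fanning lobes continuing past both ends
#' whose `|PDD_x|` falls below the 0.55 gate, blocked by the PDD-x gate),
#' and a tapetum-like low-FA sheet lateral to the splenium (blocked by the
#' FA gate). The background is isotropic.
#'
#' @param grid_shape integer length-3 (default 64 x 96 x 64).
#' @param arch_radius arch radius in voxels (default scales with the grid).
#' @param tube_radius bundle cross-section radius in voxels (>= 2, default 3).
#' @param cc_eigenvalues descending tensor eigenvalues of the bundle in
#'   mm^2/s (default (1.7, 0.3, 0.3) x 1e-3, FA 0.799).
#' @param background_eigenvalue isotropic background diffusivity
#'   (default 0.8e-3 mm^2/s, FA 0).
#' @param distractors subset of c("cingulum", "forceps", "tapetum").
#' @param noise_sd sd of the per-component tensor perturbation (mm^2/s);
#'   default 0 (noise-free).
#' @param seed integer random seed for the noise.
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(64L, 96L, 64L),
                         arch_radius = round(0.23 * grid_shape[2]),
                         tube_radius = 3,
                         cc_eigenvalues = c(1.7, 0.3, 0.3) * 1e-3,
                         background_eigenvalue = 0.8e-3,
                         distractors = c("cingulum", "forceps", "tapetum"),
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(tube_radius >= 2, noise_sd >= 0,
            all(diff(cc_eigenvalues) <= 0), all(cc_eigenvalues > 0))
  if (length(distractors))
    distractors <- match.arg(distractors,
                             c("cingulum", "forceps", "tapetum"),
                             several.ok = TRUE)
  structure(list(grid_shape = as.integer(grid_shape),
                 arch_radius = arch_radius, tube_radius = tube_radius,
                 cc_eigenvalues = cc_eigenvalues,
                 background_eigenvalue = background_eigenvalue,
                 distractors = distractors, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the corpus-callosum tensor phantom with ground truth
#'
#' See [phantom_spec()] for the emulated geometry. All bundle tensors are
#' axially symmetric (`lambda2 = lambda3`), so the tensor at a voxel is
#' `lambda2 I + (lambda1 - lambda2) v v'` with `v` the local fiber
#' direction. Gaussian noise of sd `noise_sd` is added to every tensor
#' component and eigenvalues are re-clamped to be nonnegative. Reproducible
#' from `spec$seed`; the caller's random-number state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: list with `tensors`
#'   ([tensor_volume()]), `cc_mask`, `witelson_truth` (labels built from the
#'   constructed critical point), `distractor_labels` (1 cingulum, 2
#'   forceps, 3 tapetum), `seeds_suggested` ([seed_set()]),
#'   `midsagittal_slice`, `critical_point`, `spec`.
#' @export
generate_cc_phantom <- function(spec = phantom_spec()) {
  gs <- spec$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  R <- spec$arch_radius
  r <- spec$tube_radius
  x_mid <- as.integer(round(nx / 2))
  W <- max(3L, round(nx / 6.4))          # lateral half-width of the bundle
  yc <- ny / 2
  zc <- round(0.42 * nz)
  th_g <- -30; th_s <- 210               # arch span, degrees
  fan_span <- 40                         # degrees over which the fan builds
  tau_max <- acos(0.78) * 180 / pi       # max in-bundle tilt: |PDD_x| >= 0.78
  fan_g <- c(0.862, -0.507)              # (y, z) fan direction at the genu
  fan_s <- c(-0.862, -0.507)             # and at the splenium
  forceps_len <- max(5, round(R / 3))
  if (2 * R + 2 * r + 2 > min(ny, nz) || zc - R * sin(30 * pi / 180) - r < 2)
    stop("phantom geometry exceeds the grid")

  X <- array(rep(seq_len(nx), times = ny * nz), gs)
  Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), gs)
  Z <- array(rep(seq_len(nz), each = nx * ny), gs)
  dy <- Y - yc; dz <- Z - zc
  rad <- sqrt(dy^2 + dz^2)
  th <- atan2(dz, dy) * 180 / pi
  th2 <- ifelse(th < th_g, th + 360, th)
  in_span <- th2 <= th_s
  Eg <- c(yc + R * cos(th_g * pi / 180), zc + R * sin(th_g * pi / 180))
  Es <- c(yc + R * cos(th_s * pi / 180), zc + R * sin(th_s * pi / 180))
  d_g <- sqrt((Y - Eg[1])^2 + (Z - Eg[2])^2)
  d_s <- sqrt((Y - Es[1])^2 + (Z - Es[2])^2)
  d_arc <- ifelse(in_span, abs(rad - R), pmin(d_g, d_s))
  lat <- abs(X - x_mid)
  cc_inplane <- d_arc <= r
  cc <- cc_inplane & lat <= W

  # rostrum spur: straight tube from the genu end toward posterior-inferior
  spur_dir <- c(-0.94, -0.342)
  spur_len <- max(4, round(0.3 * R))
  t_proj <- (Y - Eg[1]) * spur_dir[1] + (Z - Eg[2]) * spur_dir[2]
  tcl <- pmin(pmax(t_proj, 0), spur_len)
  d_spur <- sqrt((Y - (Eg[1] + tcl * spur_dir[1]))^2 +
                   (Z - (Eg[2] + tcl * spur_dir[2]))^2)
  spur <- d_spur <= max(2, r - 1) & lat <= max(2L, round(0.7 * W)) & t_proj > 0
  cc <- cc | spur
  critical_point <- c(round(Eg[1] - 1), round(Eg[2] + 1))

  # In-bundle fiber direction: purely left-right on the mid-sagittal plane
  # (the diffusivity premise the gates rely on), fanning toward the local
  # anterior/posterior direction with increasing laterality near the ends.
  # The fan's y-tilt follows the hemisphere (left fibers curve toward the
  # left frontal/occipital pole, right fibers mirror it).
  ang_g <- pmin(abs(th2 - th_g), 360 - abs(th2 - th_g))
  ang_s <- pmin(abs(th2 - th_s), 360 - abs(th2 - th_s))
  s_g <- pmax(0, 1 - ang_g / fan_span)
  s_s <- pmax(0, 1 - ang_s / fan_span)
  use_g <- s_g >= s_s
  hemi <- sign(X - x_mid)
  lat_frac <- pmin(1, lat / W)
  tau <- tau_max * pmin(1, pmax(s_g, s_s)) * lat_frac * (pi / 180)
  ay <- ifelse(use_g, fan_g[1], fan_s[1]) * hemi
  az <- ifelse(use_g, fan_g[2], fan_s[2])
  vx <- cos(tau); vy <- sin(tau) * ay; vz <- sin(tau) * az
  # spur fibers follow the x axis
  vx[spur] <- 1; vy[spur] <- 0; vz[spur] <- 0

  # distractors
  dl <- array(0L, gs)
  if ("forceps" %in% spec$distractors) {
    depth_g <- d_g - r; depth_s <- d_s - r
    proj_g <- (Y - Eg[1]) * fan_g[1] + (Z - Eg[2]) * fan_g[2]
    proj_s <- (Y - Es[1]) * fan_s[1] + (Z - Es[2]) * fan_s[2]
    # lateral lobes only: near the mid-sagittal plane the region beyond the
    # ends is interhemispheric background, not fiber
    fg <- !cc & lat >= 2 & lat <= W + 4 & depth_g > 0 & depth_g <= forceps_len & proj_g > 0
    fs <- !cc & lat >= 2 & lat <= W + 4 & depth_s > 0 & depth_s <= forceps_len & proj_s > 0
    fmask <- fg | fs
    dl[fmask] <- 2L
    # |PDD_x| drops from just below the 0.55 gate toward a fully
    # anterior-posterior orientation in the far fan
    tau_f <- (57 + 33 * pmin(1, ifelse(fg, depth_g, depth_s) / forceps_len)) * pi / 180
    vx[fmask] <- cos(tau_f[fmask])
    fay <- ifelse(fg, fan_g[1], fan_s[1]) * hemi
    faz <- ifelse(fg, fan_g[2], fan_s[2])
    vy[fmask] <- (sin(tau_f) * fay)[fmask]
    vz[fmask] <- (sin(tau_f) * faz)[fmask]
  }
  if ("cingulum" %in% spec$distractors) {
    z_cing <- zc + R + r + 2 + 2          # 2-voxel gap above the arch top
    x_off <- max(3L, round(0.6 * W))
    cing <- (abs(X - (x_mid - x_off)) <= 2 | abs(X - (x_mid + x_off)) <= 2) &
      sqrt((Z - z_cing)^2) <= 2 & abs(Y - yc) <= 0.6 * R & !cc
    cing <- cing & (Z <= nz)
    dl[cing] <- 1L
    vx[cing] <- 0; vy[cing] <- 1; vz[cing] <- 0
  }
  tap <- array(FALSE, gs)
  if ("tapetum" %in% spec$distractors) {
    tap <- !cc & cc_inplane & lat > W & lat <= W + 3 & in_span & th2 >= 150
    dl[tap] <- 3L
    vx[tap] <- 1; vy[tap] <- 0; vz[tap] <- 0
  }

  # assemble axially-symmetric tensors: lam2 I + (lam1 - lam2) v v'
  lam1 <- spec$cc_eigenvalues[1]; lam2 <- spec$cc_eigenvalues[2]
  tap_ev <- c(0.88, 0.765) * 1e-3        # FA 0.083, below the FA gate
  n <- prod(gs)
  fib <- cc | dl == 1L | dl == 2L
  l1 <- rep(spec$background_eigenvalue, n); l2 <- l1
  l1[fib] <- lam1; l2[fib] <- lam2
  l1[tap] <- tap_ev[1]; l2[tap] <- tap_ev[2]
  nrmv <- sqrt(vx^2 + vy^2 + vz^2)
  vx <- vx / nrmv; vy <- vy / nrmv; vz <- vz / nrmv
  dlt <- l1 - l2
  tens <- array(0, c(gs, 6L))
  tens[, , , 1] <- l2 + dlt * vx^2
  tens[, , , 2] <- dlt * vx * vy
  tens[, , , 3] <- l2 + dlt * vy^2
  tens[, , , 4] <- dlt * vx * vz
  tens[, , , 5] <- dlt * vy * vz
  tens[, , , 6] <- l2 + dlt * vz^2

  if (spec$noise_sd > 0) {
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    tens <- tens + array(rnorm(length(tens), sd = spec$noise_sd), dim(tens))
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else rm(list = ".Random.seed", envir = globalenv())
    flat <- cpp_clamp_psd(as.numeric(tens), gs)
    tens <- array(flat, c(gs, 6L))
  }
  volume <- tensor_volume(tens, c(1.9, 1.9, 1.9))

  seed_angles <- seq(th_g + 40, th_s - 40, length.out = 5)
  spts <- cbind(x_mid,
                round(yc + R * cos(seed_angles * pi / 180)),
                round(zc + R * sin(seed_angles * pi / 180)))
  wit <- witelson_subdivide(cc, x_mid, critical_point)
  structure(list(tensors = volume, cc_mask = cc, witelson_truth = wit,
                 distractor_labels = dl,
                 seeds_suggested = seed_set(spts, 2),
                 midsagittal_slice = x_mid,
                 critical_point = critical_point,
                 spec = spec),
            class = "phantom_truth")
}

#' Write a phantom as a fixture bundle on disk
#'
#' Writes the tensor volume, corpus-callosum mask, Witelson truth labels,
#' and distractor labels as NIfTI, the suggested seeds as a 0-based
#' `seeds.txt`, the Witelson label map as JSON, and the generating spec as
#' JSON. Errors if `directory` already exists.
#'
#' @param truth a `phantom_truth`.
#' @param directory output directory (must not exist).
#' @return the directory, invisibly.
#' @export
write_fixture_bundle <- function(truth, directory) {
  if (dir.exists(directory)) stop("directory already exists: ", directory)
  dir.create(directory, recursive = TRUE)
  vx <- truth$tensors$voxel_size
  write_tensor_volume(truth$tensors, file.path(directory, "tensors.nii.gz"))
  write_mask(truth$cc_mask, file.path(directory, "cc_mask.nii.gz"), vx)
  write_mask(truth$witelson_truth$labels,
             file.path(directory, "witelson_truth.nii.gz"), vx)
  write_mask(truth$distractor_labels,
             file.path(directory, "distractor_labels.nii.gz"), vx)
  write.table(truth$seeds_suggested$points - 1L,
              file.path(directory, "seeds.txt"),
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(as.list(witelson_label_names()),
                       file.path(directory, "label_map.json"),
                       auto_unbox = TRUE)
  sp <- truth$spec
  jsonlite::write_json(unclass(sp), file.path(directory, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' A reduced-size phantom specification for simulation studies
#'
#' Same geometry and tissue parameters as [phantom_spec()] on a
#' 40 x 64 x 40 grid (arch radius 15), sized so that the many repeated
#' segmentations of threshold sweeps and rotation experiments stay cheap.
#'
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()]
#' @export
phantom_spec_compact <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(44L, 68L, 56L), arch_radius = 14)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}
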