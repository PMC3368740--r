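test_that("gradient tables are validated", {
  g <- matrix(rnorm(75), 25)
  g <- g / sqrt(rowSums(g^2))
  gt <- gradient_table(c(0, rep(1000, 25)), rbind(c(0, 0, 0), g))
  expect_length(gt$bvals, 26L)
  # row-count mismatch
  expect_error(gradient_table(rep(1000, 25), rbind(c(0, 0, 0), g)),
               "different numbers")
  # no b = 0 reference
  expect_error(gradient_table(rep(1000, 26), rbind(c(1, 0, 0), g)), "b = 0")
  # non-unit direction
  gb <- g; gb[3, ] <- gb[3, ] * 2
  expect_error(gradient_table(c(0, rep(1000, 25)), rbind(c(0, 0, 0), gb)),
               "unit vectors")
})

test_that("DWI volumes round-trip through NIfTI with table validation", {
  set.seed(1)
  D <- diag(c(1.5, 0.4, 0.4)) * 1e-3
  sim <- simulate_dwi(D)
  dir <- withr::local_tempdir()
  nii <- file.path(dir, "dwi.nii.gz")
  img <- RNifti::asNifti(sim$dwi)
  RNifti::pixdim(img) <- c(2, 2, 2, 1)
  RNifti::writeNifti(img, nii)
  bval <- file.path(dir, "dwi.bval")
  bvec <- file.path(dir, "dwi.bvec")
  writeLines(paste(sim$gradients$bvals, collapse = " "), bval)
  write.table(t(sim$gradients$bvecs), bvec, row.names = FALSE, col.names = FALSE)
  rd <- read_dwi(nii, bval, bvec)
  expect_equal(dim(rd$dwi), dim(sim$dwi))
  expect_equal(rd$gradients$bvals, sim$gradients$bvals)
  expect_equal(rd$voxel_size, c(2, 2, 2))
  # 25-row table against a 26-volume image errors
  writeLines(paste(sim$gradients$bvals[-2], collapse = " "), bval)
  write.table(t(sim$gradients$bvecs[-2, ]), bvec, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_dwi(nii, bval, bvec), "26 volumes")
  expect_error(read_dwi(file.path(dir, "nope.nii"), bval, bvec), "not found")
})

test_that("log-linear tensor fit inverts the forward model", {
  set.seed(7)
  # rotated anisotropic tensor recovered to numerical precision
  R <- random_rotation()
  D <- R %*% diag(c(1.7, 0.3, 0.3) * 1e-3) %*% t(R)
  sim <- simulate_dwi(D)
  tv <- fit_tensors(sim$dwi, sim$gradients)
  expect_lt(max(abs(tensor_at(tv, c(1, 1, 1)) - D)), 1e-8 * max(abs(D)))

  # isotropic signal gives an isotropic tensor with FA 0
  iso <- simulate_dwi(diag(3) * 0.8e-3)
  tvi <- fit_tensors(iso$dwi, iso$gradients)
  ev <- eigendecompose(tensor_at(tvi, c(2, 2, 2)))$values
  expect_lt(fractional_anisotropy(ev), 1e-8)

  # principal direction recovered along x to angular precision
  simx <- simulate_dwi(diag(c(1.7, 0.3, 0.3) * 1e-3))
  tvx <- fit_tensors(simx$dwi, simx$gradients)
  pdd <- principal_direction(tensor_at(tvx, c(1, 1, 1)))
  expect_lt(acos(min(1, abs(pdd[1]))), 1e-6)

  # too few directions
  g5 <- sim$gradients$bvecs[1:6, ]
  expect_error(fit_tensors(sim$dwi[, , , 1:6],
                           gradient_table(c(0, rep(1000, 5)), g5)),
               "6 distinct")
})

test_that("fitted volumes satisfy tensor invariants", {
  set.seed(11)
  D <- random_psd() * 1e-3
  sim <- simulate_dwi(D)
  noisy <- sim$dwi * exp(array(rnorm(length(sim$dwi), sd = 0.05),
                               dim(sim$dwi)))
  tv <- fit_tensors(noisy, sim$gradients)
  for (v in list(c(1, 1, 1), c(2, 2, 1))) {
    M <- tensor_at(tv, v)
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gte(min(eigendecompose(M)$values), -1e-12)
  }
})

test_that("isotropic resampling interpolates trilinearly", {
  set.seed(3)
  a <- array(rnorm(16 * 16 * 8 * 6), c(16, 16, 8, 6))
  tv <- tensor_volume(a, c(1, 1, 1))
  # identity resample
  same <- resample_isotropic(tv, 1)
  expect_identical(same$tensors, tv$tensors)
  # constant volume stays constant
  const <- tensor_volume(array(2.5, c(8, 8, 8, 6)), c(1, 1, 2))
  rc <- resample_isotropic(const, 1.5)
  expect_true(all(abs(rc$tensors - 2.5) < 1e-12))
  # convex combination preserves per-component range
  rs <- resample_isotropic(tv, 0.7)
  for (k in 1:6) {
    expect_gte(min(rs$tensors[, , , k]), min(a[, , , k]) - 1e-12)
    expect_lte(max(rs$tensors[, , , k]), max(a[, , , k]) + 1e-12)
  }
  # acquisition-protocol shapes: FOV-derived dims by default, nominal grid
  # (e.g. 128 in plane at 1.9 mm) only when requested explicitly
  big <- tensor_volume(array(1, c(256, 256, 4, 6)), c(0.98, 0.98, 2.5))
  out <- resample_isotropic(big, 1.9)
  expect_equal(dim(out$tensors)[1:2], c(132L, 132L))
  nom <- resample_isotropic(big, 1.9, out_shape = c(128L, 128L, 5L))
  expect_equal(dim(nom$tensors)[1:3], c(128L, 128L, 5L))
  expect_error(resample_isotropic(tv, -1), "positive")
})

test_that("tensor volumes and masks round-trip through NIfTI", {
  set.seed(5)
  tv <- tensor_volume(array(rnorm(4 * 5 * 6 * 6) * 1e-3, c(4, 5, 6, 6)),
                      c(1.9, 1.9, 1.9))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.nii.gz")
  write_tensor_volume(tv, p)
  tv2 <- read_tensor_volume(p)
  expect_equal(tv2$tensors, tv$tensors, tolerance = 1e-6)
  expect_equal(tv2$voxel_size, tv$voxel_size, tolerance = 1e-6)
  m <- array(c(TRUE, FALSE), c(4, 5, 6))
  pm <- file.path(dir, "m.nii.gz")
  write_mask(m, pm, tv$voxel_size)
  expect_identical(read_mask(pm) > 0, m)
})
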