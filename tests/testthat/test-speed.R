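test_that("speed parameters are validated", {
  p <- speed_params()
  expect_equal(p$pdd_x_threshold, 0.55)
  expect_equal(p$collinearity_threshold, 0.7)
  expect_equal(p$fa_threshold, 0.1)
  expect_equal(p$f_threshold, 0.05)
  expect_error(speed_params(pdd_x_threshold = 1.2), "\\[0, 1\\]")
  expect_error(speed_params(f_threshold = -1), "nonnegative")
})

test_that("surface normals follow the phi gradient", {
  pl <- array(0, c(12, 12, 12))
  for (x in 1:12) pl[x, , ] <- x - 6.5
  n <- surface_normals(pl, rbind(c(6, 6, 6), c(7, 3, 9)))
  expect_equal(n, rbind(c(1, 0, 0), c(1, 0, 0)))
  sph <- sphere_phi(c(30, 30, 30), c(15.5, 15.5, 15.5), 8)
  vox <- rbind(c(23, 15, 15), c(15, 23, 16), c(10, 10, 12))
  n <- surface_normals(sph, vox)
  for (i in 1:3) {
    radial <- vox[i, ] - c(15.5, 15.5, 15.5)
    radial <- radial / sqrt(sum(radial^2))
    expect_lt(sqrt(sum((n[i, ] - radial)^2)), 1e-2)
  }
  flat <- array(1, c(8, 8, 8))
  expect_true(all(is.na(surface_normals(flat, rbind(c(4, 4, 4))))))
})

test_that("collinear neighbor selection enumerates the 26-neighborhood", {
  p <- speed_params()
  nb <- collinear_neighbors(c(5, 5, 5), c(1, 0, 0), p)
  expect_equal(nrow(nb), 9L)  # face, 4 edge diagonals, 4 corner diagonals
  expect_true(all(nb[, 1] == 6L))
  strict <- collinear_neighbors(c(5, 5, 5), c(1, 0, 0),
                                speed_params(normal_collinearity_cos = 0.99))
  expect_equal(strict, rbind(c(6L, 5L, 5L)))
  # bounds: at a grid face only in-bounds neighbors remain
  edge <- collinear_neighbors(c(10, 5, 5), c(1, 0, 0), p, grid_shape = c(10, 10, 10))
  expect_equal(nrow(edge), 0L)
  part <- collinear_neighbors(c(10, 1, 5), c(0, -1, 0), p, grid_shape = c(10, 10, 10))
  expect_equal(nrow(part), 0L)
})

test_that("the propagation gate applies all three conditions", {
  p <- speed_params()
  ex <- c(1, 0, 0)
  expect_true(gate(ex, ex, fa_n = 0.8, p))
  expect_false(gate(ex, c(0, 1, 0), fa_n = 0.8, p))       # orthogonal PDDs
  expect_false(gate(c(0.5, sqrt(1 - 0.25), 0), ex, 0.8, p))  # |PDD_x| = 0.5
  expect_false(gate(ex, ex, fa_n = 0.05, p))               # neighbor FA low
  expect_false(gate(c(0, 0, 0), ex, 0.8, p))               # undefined PDD
  # sign safety: anti-parallel PDDs are collinear
  expect_true(gate(ex, -ex, fa_n = 0.8, p))
})

test_that("the similarity speed matches the trace formula and the floor", {
  # rank-1 unit tensors along x: FA = 1, tr(D D) / (trD trD) = 1
  a <- array(0, c(3, 1, 1, 6))
  a[, , , 1] <- 1  # Dxx = 1
  tv <- tensor_volume(a)
  fa <- array(1, c(3, 1, 1))
  p <- speed_params()
  expect_equal(similarity_speed(c(2, 1, 1), rbind(c(3, 1, 1)), tv, fa, p), 1)
  expect_equal(similarity_speed(c(2, 1, 1), rbind(c(1, 1, 1), c(3, 1, 1)),
                                tv, fa, p), 2)
  # isotropic tensors: FA = 0 so F = 0
  iso <- tensor_volume(array(rep(c(1, 0, 1, 0, 0, 1) * 1e-3, each = 3),
                             c(3, 1, 1, 6)))
  expect_equal(similarity_speed(c(2, 1, 1), rbind(c(3, 1, 1)), iso,
                                array(0, c(3, 1, 1)), p), 0)
  # speeds at or below the floor are zeroed
  fa_small <- array(0.2, c(3, 1, 1))  # term = 0.04 * 1 = 0.04 <= 0.05
  expect_equal(similarity_speed(c(2, 1, 1), rbind(c(3, 1, 1)), tv, fa_small, p), 0)
  expect_gt(similarity_speed(c(2, 1, 1), rbind(c(3, 1, 1)), tv, fa_small,
                             speed_params(f_threshold = 0.01)), 0)
})

test_that("every similarity summand lies in [0, 1] for PSD tensor pairs", {
  set.seed(123)
  summand <- function(A, B) {
    faA <- fractional_anisotropy(pmax(0, eigendecompose(A)$values))
    faB <- fractional_anisotropy(pmax(0, eigendecompose(B)$values))
    faA * faB * sum(A * B) / (sum(diag(A)) * sum(diag(B)))
  }
  s <- vapply(1:10000, function(i) summand(random_psd(), random_psd()), 0)
  expect_gte(min(s), 0)
  expect_lte(max(s), 1)
  # symmetry under swapping the pair
  for (i in 1:50) {
    A <- random_psd(); B <- random_psd()
    expect_equal(summand(A, B), summand(B, A), tolerance = 1e-14)
  }
})

test_that("the speed field is positive inside the bundle and zero at blocked interfaces", {
  ph <- get_compact_phantom()
  f <- compute_feature_fields(ph$tensors)
  st <- init_phi(ph$seeds_suggested, dim(ph$cc_mask))
  sf <- compute_speed_field(st, ph$tensors, f)
  expect_true(all(sf$values >= 0))
  expect_lte(max(sf$values), 26)
  # positive on the seed-sphere surface inside the bundle
  expect_gt(max(sf$values[ph$cc_mask]), 0)
  # a converged front has zero speed against background and distractors
  seg <- get_compact_segmentation()
  sf2 <- compute_speed_field(seg$state, ph$tensors, f)
  expect_true(all(sf2$values[ph$distractor_labels > 0] == 0))
  bg <- !ph$cc_mask & ph$distractor_labels == 0
  expect_true(all(sf2$values[bg] == 0))
})

test_that("a front abutting an orthogonal tube or background is blocked", {
  # two parallel slabs: x-oriented fibers (left half), y-oriented (right half)
  gs <- c(9, 9, 9)
  a <- array(0, c(gs, 6))
  lam <- c(1.7, 0.3) * 1e-3
  a[1:4, , , 1] <- lam[1]; a[1:4, , , 3] <- lam[2]; a[1:4, , , 6] <- lam[2]
  a[5:9, , , 1] <- lam[2]; a[5:9, , , 3] <- lam[1]; a[5:9, , , 6] <- lam[2]
  tv <- tensor_volume(a)
  f <- compute_feature_fields(tv)
  st <- init_phi(seed_set(c(2, 5, 5), 1.5), gs)
  suppressWarnings(for (i in 1:30) {
    sf <- compute_speed_field(st, tv, f)
    st <- evolve_step(st, sf$values, 0)
  })
  m <- extract_zero_levelset(st)
  expect_gt(sum(m[1:4, , ]), sum(init_phi(seed_set(c(2, 5, 5), 1.5), gs)$phi < 0))
  expect_equal(sum(m[5:9, , ]), 0L)  # collinearity gate blocks the y-tube
})
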