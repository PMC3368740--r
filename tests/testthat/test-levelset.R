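test_that("phi initialization is the exact distance to the seed spheres", {
  st <- init_phi(seed_set(c(10, 10, 10), sphere_radius = 2), c(20, 20, 20))
  expect_equal(st$phi[10, 10, 10], -2)
  expect_equal(st$phi[10, 10, 13], 1)
  # union of overlapping spheres = min of distances
  st2 <- init_phi(seed_set(rbind(c(10, 10, 10), c(12, 10, 10)), 2), c(20, 20, 20))
  expect_equal(st2$phi[11, 10, 10], -1)
  expect_true(all(st2$phi <= st$phi + 1e-12))
  expect_error(init_phi(seed_set(c(0, 5, 5), 2), c(20, 20, 20)), "bounds")
  expect_error(seed_set(matrix(numeric(0), 0, 3), 2))
})

test_that("upwind gradient magnitude is exact on planes and accurate on spheres", {
  pl <- array(0, c(20, 20, 20))
  for (x in 1:20) pl[x, , ] <- x - 10.5
  g <- upwind_gradient(pl)
  expect_lt(max(abs(g[4:17, , ] - 1)), 1e-10)
  gs <- c(44, 44, 44)
  sph <- sphere_phi(gs, c(22.5, 22.5, 22.5), 14)
  g <- upwind_gradient(sph)
  r <- sph + 14
  sel <- r > 6 & r < 20
  expect_lt(max(abs(g[sel] - 1)), 1e-3)
})

test_that("mean curvature matches analytic values", {
  pl <- array(0, c(16, 16, 16))
  for (x in 1:16) pl[x, , ] <- x - 8.5
  expect_lt(max(abs(mean_curvature(pl)[3:14, 3:14, 3:14])), 1e-10)
  sph <- sphere_phi(c(40, 40, 40), c(20.5, 20.5, 20.5), 10)
  k <- mean_curvature(sph)
  surf <- abs(sph) < 0.5
  expect_true(all(abs(k[surf] - 0.2) < 0.02))  # 2/R = 0.2 within 10%
  expect_true(all(mean_curvature(array(3, c(8, 8, 8))) == 0))
})

test_that("evolution is stationary, advective, and curvature-driven as expected", {
  sph <- sphere_phi(c(30, 30, 30), c(15.5, 15.5, 15.5), 8)
  st <- levelset_state(sph)
  # F = 0, w = 0: warned no-op
  expect_warning(st0 <- evolve_step(st, array(0, dim(sph)), 0), "no-op")
  expect_equal(st0$phi, sph)
  # F = 1, w = 0: the front moves outward by dt (phi drops by dt everywhere
  # the distance field is exact)
  st1 <- evolve_step(st, array(1, dim(sph)), 0)
  expect_equal(st1$time_step, 0.5)
  iface <- abs(sph) < 1
  expect_lt(max(abs((sph - st1$phi)[iface] - st1$time_step)), 0.05 * st1$time_step)
  # curvature-only flow shrinks a small sphere
  sm <- sphere_phi(c(30, 30, 30), c(15.5, 15.5, 15.5), 5)
  stc <- levelset_state(sm)
  v0 <- sum(extract_zero_levelset(stc))
  for (i in 1:50) stc <- evolve_step(stc, array(0, dim(sm)), 1)
  expect_lt(sum(extract_zero_levelset(stc)), v0)
})

test_that("the inside region grows monotonically under nonnegative speed", {
  st <- init_phi(seed_set(c(15, 15, 15), 3), c(30, 30, 30))
  Fg <- array(1, c(30, 30, 30))
  prev <- extract_zero_levelset(st)
  for (i in 1:40) {
    st <- evolve_step(st, Fg, 0)
    m <- extract_zero_levelset(st)
    expect_equal(sum(prev & !m), 0L)
    prev <- m
  }
  expect_true(all(is.finite(st$phi)))
  expect_error(evolve_step(st, -Fg, 0), "nonnegative")
})

test_that("reinitialization restores the distance property without moving the front", {
  sph <- sphere_phi(c(36, 36, 36), c(18.5, 18.5, 18.5), 10)
  st <- levelset_state(sph * 3)
  st2 <- reinitialize(st, 40)
  band <- abs(sph) < 3
  central_gradmag <- function(phi) {
    d <- dim(phi)
    sh <- function(ax, k) {
      i <- pmin(pmax(seq_len(d[ax]) + k, 1L), d[ax])
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      idx[[ax]] <- i
      do.call(`[`, c(list(phi), idx))
    }
    sqrt(((sh(1, 1) - sh(1, -1)) / 2)^2 + ((sh(2, 1) - sh(2, -1)) / 2)^2 +
           ((sh(3, 1) - sh(3, -1)) / 2)^2)
  }
  g <- central_gradmag(st2$phi)
  expect_true(all(abs(g[band] - 1) < 0.15))
  expect_true(all(sign(st2$phi) == sign(sph)))
  expect_identical(st2$phi < 0, sph < 0)
  # a plane distance field is a fixed point
  pl <- array(0, c(16, 16, 16))
  for (x in 1:16) pl[x, , ] <- x - 8.5
  stp <- reinitialize(levelset_state(pl), 10)
  expect_lt(max(abs(stp$phi - pl)[3:14, , ]), 1e-6)
})

test_that("zero level-set extraction uses the strict-inside convention", {
  sph <- sphere_phi(c(30, 30, 30), c(15.5, 15.5, 15.5), 6)
  m <- extract_zero_levelset(levelset_state(sph))
  expect_equal(sum(m), 4 / 3 * pi * 6^3, tolerance = 0.1)
  expect_equal(sum(extract_zero_levelset(levelset_state(abs(sph) + 1))), 0L)
  expect_equal(sum(extract_zero_levelset(levelset_state(-abs(sph) - 1))),
               27000L)
  # exact zeros are outside
  z <- array(0, c(4, 4, 4))
  expect_equal(sum(extract_zero_levelset(levelset_state(z))), 0L)
})

test_that("long CFL-bounded evolutions remain finite", {
  ph <- get_compact_phantom()
  f <- compute_feature_fields(ph$tensors)
  st <- init_phi(ph$seeds_suggested, dim(ph$cc_mask))
  for (i in 1:40) {
    sf <- compute_speed_field(st, ph$tensors, f)
    st <- evolve_step(st, sf$values, 0.1)
    if (i %% 20 == 0) st <- reinitialize(st, 10)
  }
  expect_true(all(is.finite(st$phi)))
})
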