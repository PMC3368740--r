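# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# exact signed distance to a sphere
sphere_phi <- function(gs, center, radius) {
  phi <- array(0, gs)
  for (z in seq_len(gs[3])) for (y in seq_len(gs[2]))
    phi[, y, z] <- sqrt((seq_len(gs[1]) - center[1])^2 +
                          (y - center[2])^2 + (z - center[3])^2) - radius
  phi
}

# random symmetric positive-semidefinite 3x3 matrix
random_psd <- function() {
  A <- matrix(rnorm(9), 3)
  crossprod(A)
}

# random rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

get_compact_phantom <- function() {
  if (is.null(.fixture_env$compact))
    .fixture_env$compact <- generate_cc_phantom(phantom_spec_compact())
  .fixture_env$compact
}

get_compact_segmentation <- function() {
  if (is.null(.fixture_env$compact_seg)) {
    ph <- get_compact_phantom()
    .fixture_env$compact_seg <-
      segment_corpus_callosum(ph$tensors, ph$seeds_suggested, max_iters = 300)
  }
  .fixture_env$compact_seg
}

# tiny anisotropic single-direction DWI simulation
simulate_dwi <- function(D, bval = 1000, ndir = 25, shape = c(2, 2, 2), s0 = 1000) {
  g <- matrix(rnorm(3 * ndir), ndir)
  g <- g / sqrt(rowSums(g^2))
  gt <- gradient_table(c(0, rep(bval, ndir)), rbind(c(0, 0, 0), g))
  att <- apply(g, 1, function(v) exp(-bval * drop(v %*% D %*% v)))
  sig <- c(1, att) * s0
  dwi <- array(rep(sig, each = prod(shape)), c(shape, ndir + 1))
  list(dwi = dwi, gradients = gt)
}
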