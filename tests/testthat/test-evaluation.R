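test_that("Dice identities hold exactly", {
  m <- array(FALSE, c(10, 10, 10))
  a <- m; a[2:5, 2:5, 2:5] <- TRUE
  r <- dice(a, a)
  expect_equal(r$dice, 1)
  expect_equal(r$false_positives, 0L)
  expect_equal(r$false_negatives, 0L)
  b <- m; b[7:9, 7:9, 7:9] <- TRUE
  expect_equal(dice(a, b)$dice, 0)
  # |A| = |B| = 100, |A intersect B| = 50
  a2 <- array(FALSE, c(20, 10, 1)); a2[1:10, 1:10, 1] <- TRUE
  b2 <- array(FALSE, c(20, 10, 1)); b2[6:15, 1:10, 1] <- TRUE
  r2 <- dice(a2, b2)
  expect_equal(r2$dice, 0.5)
  expect_equal(r2$true_positives, 50L)
  expect_equal(r2$false_positives, 50L)
  expect_equal(r2$false_negatives, 50L)
  # symmetry of the coefficient
  expect_equal(dice(a2, b2)$dice, dice(b2, a2)$dice)
  # identity dice = 2 TP / (2 TP + FP + FN)
  expect_equal(r2$dice, 2 * r2$true_positives /
                 (2 * r2$true_positives + r2$false_positives + r2$false_negatives))
  expect_warning(re <- dice(m, m), "empty")
  expect_equal(re$dice, 1)
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "shapes differ")
})

test_that("the exact Wilcoxon p matches full sign enumeration", {
  brute_force_p <- function(a, b) {
    d <- a - b; d <- d[d != 0]
    n <- length(d); r <- rank(abs(d)); w <- sum(r[d > 0])
    W <- vapply(0:(2^n - 1), function(m)
      sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0]), 0)
    min(1, 2 * min(mean(W >= w), mean(W <= w)))
  }
  set.seed(99)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # force ties
    if (all(a == b)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p_value, brute_force_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon edge cases follow the signed-rank conventions", {
  expect_equal(wilcoxon_signed_rank(6:10, 1:5)$p_value, 0.0625)  # 2/2^5
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "all differences")
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  # antisymmetry in the arguments
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
  # agreement with the reference implementation when ties are absent
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank(c(a, 1), c(b, 1))$n_effective, 12L)
  # large-sample path
  set.seed(8)
  big <- wilcoxon_signed_rank(rnorm(40, 0.5), rnorm(40))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p_value, 0.05)
})

test_that("inner-outer comparison pairs group means per cell", {
  nm <- names(witelson_label_names())
  mk <- function(rep, dice_outer, dice_inner) {
    d <- data.frame(axis = "azimuth", angle_deg = 30, subdivision = nm,
                    dice = ifelse(nm %in% c("rostrum", "genu", "splenium"),
                                  dice_outer, dice_inner))
    d$replicate <- rep
    d
  }
  set.seed(2)
  # outer uniformly worse over 11 replicates: minimal exact p = 2/2^11
  rep11 <- do.call(rbind, lapply(1:11, function(r)
    mk(r, 0.85 + r * 1e-4, 0.95 + r * 1e-4)))
  res <- inner_outer_comparison(rep11)
  expect_equal(res$p_value, 2 / 2^11, tolerance = 1e-12)
  expect_true(res$significant)
  expect_lt(res$outer_mean, res$inner_mean)
  # identical groups: undefined, reported NA
  same <- do.call(rbind, lapply(1:5, function(r) mk(r, 0.9, 0.9)))
  res2 <- inner_outer_comparison(same)
  expect_true(is.na(res2$p_value))
  expect_false(res2$significant)
  expect_error(inner_outer_comparison(rep11[rep11$subdivision != "genu", ]),
               "missing")
})

test_that("a single-value sweep equals a direct segmentation run", {
  ph <- get_compact_phantom()
  sw <- threshold_sweep(ph$tensors, ph$seeds_suggested, ph$witelson_truth,
                        "pdd_x_threshold", 0.55, max_iters = 300)
  seg <- get_compact_segmentation()
  ref <- dice(seg$mask, ph$witelson_truth$labels > 0)
  all_row <- sw[sw$subdivision == "all", ]
  expect_equal(all_row$tp, ref$true_positives)
  expect_equal(all_row$fp, ref$false_positives)
  expect_equal(all_row$dice, ref$dice)
  expect_equal(nrow(sw), 8L)  # "all" + 7 subdivisions
})
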