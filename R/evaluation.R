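#' Dice overlap between two binary masks
#'
#' `dice = |A intersect B| / ((|A| + |B|) / 2)` together with the
#' true-positive, false-positive, and false-negative counts (`B` is the
#' reference). Two empty masks give Dice 1 with a warning (the 0/0 case:
#' both agree nothing is present).
#'
#' @param mask_auto,mask_ref same-shape binary arrays (automatic, reference).
#' @return object of class `dice_report`: list with `true_positives`,
#'   `false_positives`, `false_negatives`, `dice`.
#' @export
dice <- function(mask_auto, mask_ref) {
  if (!all(dim(mask_auto) == dim(mask_ref))) stop("mask shapes differ")
  a <- as.logical(mask_auto); b <- as.logical(mask_ref)
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  d <- if (tp + fp + fn == 0L) {
    warning("both masks empty: Dice defined as 1")
    1
  } else 2 * tp / (2 * tp + fp + fn)
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, dice = d),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice %.4f (TP %d, FP %d, FN %d)\n", x$dice,
              x$true_positives, x$false_positives, x$false_negatives))
  invisible(x)
}

#' Threshold sensitivity sweep
#'
#' Re-runs segmentation over a grid of values for one gate threshold and
#' reports per-Witelson-subdivision true positives, false positives, and
#' Dice against reference labels, plus a whole-structure row
#' (`subdivision == "all"`).
#'
#' @param tensors a [tensor_volume()].
#' @param seeds a [seed_set()].
#' @param ref_labels reference `witelson_labels` (its nonzero support is the
#'   reference mask).
#' @param param_name one of the [speed_params()] threshold names.
#' @param value_grid numeric vector of threshold values in `[0, 1]`.
#' @param fixed_params baseline [speed_params()] for the other thresholds.
#' @param ... passed to [segment_corpus_callosum()].
#' @return data.frame: param_name, value, subdivision, tp, fp, dice.
#' @export
threshold_sweep <- function(tensors, seeds, ref_labels, param_name,
                            value_grid, fixed_params = speed_params(), ...) {
  stopifnot(param_name %in% c("pdd_x_threshold", "collinearity_threshold",
                              "fa_threshold", "f_threshold"))
  if (param_name != "f_threshold" && any(value_grid < 0 | value_grid > 1))
    stop("threshold values must lie in [0, 1]")
  features <- compute_feature_fields(tensors)
  nm <- names(witelson_label_names())
  ref_mask <- ref_labels$labels > 0L
  rows <- list()
  for (v in value_grid) {
    p <- unclass(fixed_params)
    p[[param_name]] <- v
    p <- do.call(speed_params, p)
    seg <- segment_corpus_callosum(tensors, seeds, p, features = features, ...)
    r <- dice(seg$mask, ref_mask)
    rows[[length(rows) + 1L]] <-
      data.frame(param = param_name, value = v, subdivision = "all",
                 tp = r$true_positives, fp = r$false_positives, dice = r$dice)
    for (k in seq_along(nm)) {
      rk <- dice(seg$mask & bin_of(ref_labels, k), ref_labels$labels == k)
      rows[[length(rows) + 1L]] <-
        data.frame(param = param_name, value = v, subdivision = nm[k],
                   tp = rk$true_positives, fp = rk$false_positives,
                   dice = rk$dice)
    }
  }
  do.call(rbind, rows)
}

#' Exact Wilcoxon signed-rank test (paired, two-sided)
#'
#' Tests the null that `a - b` is symmetric about zero. Zero differences are
#' dropped (Wilcoxon's rule); tied absolute differences receive mid-ranks.
#' For n <= 25 the p-value is exact over all 2^n sign assignments (computed
#' by the count-distribution recursion, identical to full enumeration);
#' above that a normal approximation with continuity and tie corrections is
#' used.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with `p_value`, `statistic` (W+, sum of positive ranks),
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of 2*W+ over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    counts <- numeric(tot + 1L)
    counts[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(tot + 1L - rk)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(counts[(w2 + 1L):(tot + 1L)])
    p_le <- sum(counts[1:(w2 + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w, n_effective = n, method = method)
}

#' Compare outer and inner Witelson subdivisions under rotation
#'
#' For each axis/angle cell, pairs per-replicate mean Dice of the outer
#' group (rostrum, genu, splenium) against the inner group (rostral body,
#' anterior and posterior mid-body, isthmus) and applies the exact Wilcoxon
#' signed-rank test. Cells whose differences are all zero are reported as
#' NA. P-values below 0.01 are flagged significant.
#'
#' @param reports data.frame from [rotation_reproducibility_experiment()]
#'   with an added `replicate` column.
#' @return data.frame: axis, angle_deg, outer_mean, inner_mean, p_value,
#'   significant.
#' @export
inner_outer_comparison <- function(reports) {
  nm <- names(witelson_label_names())
  if (!all(nm %in% reports$subdivision)) stop("missing subdivisions in report")
  outer_nm <- c("rostrum", "genu", "splenium")
  inner_nm <- setdiff(nm, outer_nm)
  cells <- unique(reports[, c("axis", "angle_deg")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- reports[reports$axis == cells$axis[i] &
                     reports$angle_deg == cells$angle_deg[i], ]
    reps <- sort(unique(sub$replicate))
    outer_v <- vapply(reps, function(r)
      mean(sub$dice[sub$replicate == r & sub$subdivision %in% outer_nm]), 0)
    inner_v <- vapply(reps, function(r)
      mean(sub$dice[sub$replicate == r & sub$subdivision %in% inner_nm]), 0)
    p <- if (all(outer_v == inner_v)) NA_real_
         else wilcoxon_signed_rank(outer_v, inner_v)$p_value
    out[[i]] <- data.frame(axis = cells$axis[i], angle_deg = cells$angle_deg[i],
                           outer_mean = mean(outer_v), inner_mean = mean(inner_v),
                           p_value = p,
                           significant = !is.na(p) && p < 0.01)
  }
  do.call(rbind, out)
}
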