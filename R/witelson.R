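#' Witelson region labels
#'
#' @return named integer vector mapping region names to label values 1-7.
#' @export
witelson_label_names <- function() {
  c(rostrum = 1L, genu = 2L, rostral_body = 3L, anterior_midbody = 4L,
    posterior_midbody = 5L, isthmus = 6L, splenium = 7L)
}

#' Detect the mid-sagittal plane from an FA map
#'
#' Chooses the sagittal (x) slice maximizing left-right mirror symmetry:
#' the Pearson correlation between the FA volume and its reflection about the
#' candidate slice, searched over the central third of the x-range. A user
#' override is returned as-is with `user_confirmed = TRUE`.
#'
#' @param fa 3D FA array.
#' @param mask optional mask; if supplied it must be nonempty.
#' @param user_slice optional integer slice override (1-based).
#' @return list of class `midsagittal_plane` with `axis` (always 1),
#'   `slice_index`, `user_confirmed`.
#' @export
detect_midsagittal_plane <- function(fa, mask = NULL, user_slice = NULL) {
  if (!is.null(mask) && sum(mask) == 0) stop("mask is empty")
  nx <- dim(fa)[1]
  if (!is.null(user_slice)) {
    if (user_slice < 1 || user_slice > nx) stop("slice outside grid bounds")
    return(structure(list(axis = 1L, slice_index = as.integer(user_slice),
                          user_confirmed = TRUE), class = "midsagittal_plane"))
  }
  lo <- max(2L, floor(nx / 3))
  hi <- min(nx - 1L, ceiling(2 * nx / 3))
  score <- rep(-Inf, nx)
  for (s in lo:hi) {
    w <- min(s - 1L, nx - s)  # symmetric window around the candidate slice
    if (w < 1L) next
    a <- fa[(s - w):(s + w), , , drop = FALSE]
    b <- a[(2 * w + 1):1, , , drop = FALSE]
    va <- as.numeric(a)
    if (sd(va) == 0) { score[s] <- 0; next }
    score[s] <- cor(va, as.numeric(b))
  }
  structure(list(axis = 1L, slice_index = which.max(score),
                 user_confirmed = FALSE), class = "midsagittal_plane")
}

# Moore-neighbor boundary tracing of the first 8-connected contour of a 2D
# mask (scan order: rows within columns). Returns an n x 2 matrix of
# (row, col) coordinates in traversal order.
trace_boundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    m[p[1], p[2]]
  # clockwise directions, 0-based indices 0..7 starting "up" (row - 1)
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  dir_index <- function(v) which(dirs[, 1] == v[1] & dirs[, 2] == v[2]) - 1L
  start <- NULL
  for (cl in seq_len(nc)) {
    rw <- which(m[, cl])
    if (length(rw)) { start <- c(rw[1], cl); break }
  }
  if (is.null(start)) stop("empty slice mask")
  b0 <- 0L  # the pixel before `start` in scan order (one row up) is background
  contour <- matrix(start, 1, 2)
  p <- start
  b <- b0
  seen <- paste(start[1], start[2], b0)
  maxsteps <- 4L * nr * nc
  for (step in seq_len(maxsteps)) {
    moved <- FALSE
    for (k in 0:7) {
      d <- (b + 1L + k) %% 8L
      q <- p + dirs[d + 1L, ]
      if (at(q)) {
        dprev <- (d + 7L) %% 8L  # last background neighbor examined
        b <- dir_index(dirs[dprev + 1L, ] - dirs[d + 1L, ])
        p <- q
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel
    key <- paste(p[1], p[2], b)
    if (key %in% seen) break  # tracer state repeats: contour closed
    seen <- c(seen, key)
    contour <- rbind(contour, p)
  }
  contour
}

#' Find the rostrum-genu critical point on the mid-sagittal slice
#'
#' Traverses the boundary contour of the slice mask, smooths it with a
#' 5-point window, and returns the boundary point in the anterior-inferior
#' quadrant where the curvature sign changes most sharply (the
#' concave-to-convex transition at the rostrum-genu junction). A manually
#' supplied point is passed through unchanged.
#'
#' @param slice_mask logical matrix (y rows, z columns) of the mid-sagittal
#'   corpus callosum cross-section; anterior = larger row index, superior =
#'   larger column index.
#' @param manual_point optional length-2 (y, z) override.
#' @return length-2 numeric (y, z); attribute `manual` records the source.
#' @export
find_rostrum_genu_critical_point <- function(slice_mask, manual_point = NULL) {
  if (!is.null(manual_point)) {
    out <- as.numeric(manual_point)
    attr(out, "manual") <- TRUE
    return(out)
  }
  ct <- trace_boundary(slice_mask)
  if (nrow(ct) > 1L && all(ct[nrow(ct), ] == ct[1L, ]))
    ct <- ct[-nrow(ct), , drop = FALSE]
  n <- nrow(ct)
  if (n < 15L) stop("slice contour too small for curvature analysis")
  # circular 5-point smoothing
  sm <- ct
  for (j in 1:2) {
    v <- ct[, j]
    sm[, j] <- (v[((seq_len(n) - 3) %% n) + 1] + v[((seq_len(n) - 2) %% n) + 1] +
                  v + v[(seq_len(n) %% n) + 1] + v[(((seq_len(n) + 1) %% n)) + 1]) / 5
  }
  k <- 3L  # chord half-length for turning angles
  im <- ((seq_len(n) - 1L - k) %% n) + 1L
  ip <- ((seq_len(n) - 1L + k) %% n) + 1L
  v1y <- sm[, 1] - sm[im, 1]; v1z <- sm[, 2] - sm[im, 2]
  v2y <- sm[ip, 1] - sm[, 1]; v2z <- sm[ip, 2] - sm[, 2]
  turn <- atan2(v1y * v2z - v1z * v2y, v1y * v2y + v1z * v2z)
  cen <- colMeans(ct)
  quad <- ct[, 1] >= cen[1] & ct[, 2] <= cen[2]  # anterior-inferior
  # orientation of the traversal: convex turns carry the sign of the total
  # turning; the rostrum-genu notch is the strongest concave kink
  conc_sign <- -sign(sum(turn))
  min_concavity <- 0.15  # rad; filters discretization noise and shallow arcs
  cand <- which(quad & sign(turn) == conc_sign & abs(turn) > min_concavity)
  if (length(cand) == 0L)
    stop("no concave curvature-sign change in the anterior-inferior quadrant; ",
         "select the critical point manually")
  best <- cand[which.max(abs(turn[cand]))]
  out <- as.numeric(ct[best, ])
  attr(out, "manual") <- FALSE
  out
}

#' Witelson subdivision of a segmented corpus callosum
#'
#' Partitions the mask into the seven Witelson regions using fractional
#' cut-points of the anterior-posterior extent measured on the mid-sagittal
#' slice: the anterior third holds rostrum, genu, and rostral body; then
#' anterior mid-body to the midpoint, posterior mid-body to two thirds,
#' isthmus to four fifths, and splenium in the posterior fifth. Within the
#' anterior third the rostrum is the part inferior-posterior to the critical
#' point, the genu is the anterior sixth plus the inferior curl, and the
#' rostral body is the remainder. Every 3D mask voxel inherits the label of
#' its y-bin (labels extended laterally along x).
#'
#' @param mask 3D logical array.
#' @param plane a `midsagittal_plane` or integer slice index.
#' @param critical_point optional (y, z) rostrum-genu point; without it the
#'   rostrum label is empty.
#' @return object of class `witelson_labels`: list with `labels` (3D integer
#'   array, 0 background), `names`, `cuts` (anterior-offset cut positions),
#'   `extent` (y_min, y_max on the mid-sagittal slice).
#' @export
witelson_subdivide <- function(mask, plane, critical_point = NULL) {
  if (sum(mask) == 0) stop("mask is empty")
  s <- if (inherits(plane, "midsagittal_plane")) plane$slice_index else as.integer(plane)
  sl <- mask[s, , ]
  ys <- which(apply(sl, 1, any))
  if (length(ys) == 0) stop("mask does not intersect the mid-sagittal slice")
  y_min <- min(ys); y_max <- max(ys)
  N <- y_max - y_min + 1L
  if (N < 7L) stop("anterior-posterior extent below 7 voxels: too degenerate to subdivide")
  cuts <- round(N * c(1 / 3, 1 / 2, 2 / 3, 4 / 5))
  genu_cut <- round(N / 6)
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  coords <- arrayInd(idx, d)
  a <- pmin(pmax(y_max - coords[, 2] + 1L, 1L), N)  # anterior offset 1..N
  lab <- integer(length(idx))
  lab[a > cuts[4]] <- 7L
  lab[a > cuts[3] & a <= cuts[4]] <- 6L
  lab[a > cuts[2] & a <= cuts[3]] <- 5L
  lab[a > cuts[1] & a <= cuts[2]] <- 4L
  ant <- a <= cuts[1]
  if (!is.null(critical_point)) {
    yc <- critical_point[1]; zc <- critical_point[2]
    rostrum <- ant & coords[, 3] < zc & coords[, 2] < yc
    genu <- ant & !rostrum & (a <= genu_cut | coords[, 3] <= zc)
  } else {
    rostrum <- rep(FALSE, length(idx))
    genu <- ant & a <= genu_cut
  }
  lab[ant] <- 3L
  lab[genu] <- 2L
  lab[rostrum] <- 1L
  labels[idx] <- lab
  structure(list(labels = labels, names = witelson_label_names(),
                 cuts = cuts, extent = c(y_min = y_min, y_max = y_max),
                 plane = s, critical_point = critical_point),
            class = "witelson_labels")
}

#' Per-region voxel counts of a Witelson labeling
#' @param w a `witelson_labels`
#' @return named integer vector of voxel counts for labels 1-7
#' @export
witelson_counts <- function(w) {
  nm <- witelson_label_names()
  cnt <- tabulate(w$labels[w$labels > 0], nbins = 7L)
  names(cnt) <- names(nm)
  cnt
}
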