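# Per-point analyses that produce a new column (local density) or an
# entirely new point cloud (blinking-localization merge).

# pairwise squared distances, block-wise to bound memory
pairwise_d2_block <- function(P, rows) {
  q <- P[rows, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(P^2), `+`) - 2 * tcrossprod(q, P)
  d2[d2 < 0] <- 0
  d2
}

#' Local point density
#'
#' Estimates a per-localization density (points per unit volume), either
#' from the distance to the k-th nearest neighbour
#' (`d_i = k / ((4/3) pi r_k^3)`) or by counting neighbours inside a fixed
#' ball (`d_i = n_i / ((4/3) pi R^3)`). The point itself is excluded from
#' its own neighbourhood in both modes. No boundary correction is applied:
#' densities near the cloud edge are biased low (documented behaviour,
#' mirroring the in-VR colouring tool).
#'
#' @param cloud a [point_cloud].
#' @param mode `"knn"` or `"radius"`.
#' @param k neighbour count for knn mode (>= 1, < N).
#' @param r ball radius for radius mode (> 0).
#' @param strict if `TRUE`, a duplicated point making `r_k = 0` (infinite
#'   density) raises an error instead of returning `Inf`.
#' @param block row-block size for the distance computation.
#' @return object of class `density_result`: `density` (length N), `mode`,
#'   and the parameter used.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
#' local_density(pc, "radius", r = 1.5)$density  # both 1 / ((4/3)*pi*1.5^3)
#' @export
local_density <- function(cloud, mode = c("knn", "radius"), k = 10, r = NULL,
                          strict = FALSE, block = 512L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$positions
  n <- nrow(P)
  if (mode == "knn") {
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    if (n <= k) stop(sprintf("knn density needs N > k (N = %d, k = %d)", n, k))
    rk <- numeric(n)
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(start + block - 1L, n)
      d2 <- pairwise_d2_block(P, rows)
      rk[rows] <- sqrt(apply(d2, 1, function(z) sort(z, partial = k + 1)[k + 1]))
    }
    if (strict && any(rk == 0)) {
      stop("duplicate points give r_k = 0 (infinite density) in strict mode")
    }
    dens <- k / ((4 / 3) * pi * rk^3)
    structure(list(density = dens, mode = "knn", k = k),
              class = "density_result")
  } else {
    if (is.null(r) || r <= 0) stop("radius mode requires r > 0")
    cnt <- integer(n)
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(start + block - 1L, n)
      d2 <- pairwise_d2_block(P, rows)
      cnt[rows] <- rowSums(d2 <= r^2) - 1L  # self excluded
    }
    structure(list(density = cnt / ((4 / 3) * pi * r^3), mode = "radius", r = r),
              class = "density_result")
  }
}

#' @export
print.density_result <- function(x, ...) {
  par <- if (x$mode == "knn") sprintf("k = %d", x$k) else sprintf("R = %g", x$r)
  cat(sprintf("<density_result> %s (%s): median %.4g per unit volume\n",
              x$mode, par, stats::median(x$density)))
  invisible(x)
}

#' Merge blinking localizations into single molecules
#'
#' A blinking fluorophore yields several localizations of the same molecule
#' spread over frames. Two localizations are linked when their spatial
#' distance is at most `eps` and their time gap is positive and at most
#' `max_gap` (two localizations in the same frame are never linked: they
#' are distinct molecules by construction). Merged molecules are the
#' connected components of the link graph (transitive closure), so a slowly
#' drifting blink chain still merges into one point. The merged position is
#' the centroid of the component members, optionally intensity-weighted.
#'
#' @param cloud a [point_cloud]; `cloud$time` carries the frame index or
#'   time stamp (`max_gap` is in the same units).
#' @param eps spatial linking distance (> 0, length units).
#' @param max_gap maximum time gap between linked localizations (>= 0).
#' @param weight_by_intensity if `TRUE` and an `intensity` column exists,
#'   centroids are intensity-weighted.
#' @return object of class `merged_cloud`: `cloud` (a [point_cloud] of the
#'   merged points with columns `count`, `t_first`, `t_last`, and
#'   `mean_intensity` when available), and `members` (list of source index
#'   vectors, one per merged point).
#' @export
merge_blinking <- function(cloud, eps, max_gap, weight_by_intensity = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  if (!is.finite(max_gap) || max_gap < 0) stop("max_gap must be >= 0")
  n <- npoints(cloud)
  P <- cloud$positions
  tt <- cloud$time
  # union-find with path halving
  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    o <- order(tt)
    # sliding time window over time-sorted points
    lo <- 1L
    for (a in seq_len(n)) {
      i <- o[a]
      while (tt[i] - tt[o[lo]] > max_gap) lo <- lo + 1L
      if (lo < a) {
        js <- o[lo:(a - 1L)]
        js <- js[tt[i] - tt[js] > 0]  # same-frame pairs never link
        if (length(js)) {
          d2 <- rowSums(sweep(P[js, , drop = FALSE], 2, P[i, ])^2)
          for (j in js[d2 <= eps^2]) {
            ri <- uf_find(i); rj <- uf_find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
  }
  root <- vapply(seq_len(n), uf_find, integer(1))
  # label components in order of first appearance (input order), so the
  # partition is a pure function of the point set
  comp <- match(root, unique(root))
  members <- split(seq_len(n), comp)
  inten <- cloud$columns$intensity
  w <- if (weight_by_intensity && !is.null(inten)) inten else rep(1, n)
  m <- length(members)
  pos <- matrix(0, m, 3)
  cnt <- integer(m); tf <- numeric(m); tl <- numeric(m); mi <- numeric(m)
  for (ci in seq_len(m)) {
    idx <- members[[ci]]
    wi <- w[idx] / sum(w[idx])
    pos[ci, ] <- colSums(P[idx, , drop = FALSE] * wi)
    cnt[ci] <- length(idx)
    tf[ci] <- min(tt[idx]); tl[ci] <- max(tt[idx])
    mi[ci] <- if (!is.null(inten)) mean(inten[idx]) else NA_real_
  }
  cols <- list(count = as.numeric(cnt), t_first = tf, t_last = tl)
  if (!is.null(inten)) cols$mean_intensity <- mi
  merged <- point_cloud(pos, time = tf, columns = cols,
                        metadata = cloud$metadata)
  structure(list(cloud = merged, members = unname(members),
                 eps = eps, max_gap = max_gap),
            class = "merged_cloud")
}

#' @export
print.merged_cloud <- function(x, ...) {
  cat(sprintf(
    "<merged_cloud> %d molecules from %d localizations (eps = %g, max_gap = %g)\n",
    npoints(x$cloud), sum(x$cloud$columns$count), x$eps, x$max_gap))
  invisible(x)
}
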