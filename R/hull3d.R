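# Incremental 3D convex hull (quickhull-style point insertion).
#
# No hull library is available in the target environment, so the hull is
# built here from first principles: seed tetrahedron from extreme points,
# then for each remaining point find the visible faces, delete them, and
# stitch new faces along the horizon. Face normals point outward; the
# interior reference point is the centroid of the seed tetrahedron.

#' Convex hull of a 3D point set
#'
#' @param points numeric `M x 3` matrix, `M >= 4`, not all coplanar.
#' @param tol relative degeneracy tolerance.
#' @return object of class `hull3d`: `faces` (`F x 3` indices into `points`,
#'   counter-clockwise seen from outside), `normals` (`F x 3` outward unit
#'   normals), `offsets` (`F`, with face plane `n . p = offset`),
#'   `vertices` (indices of points on the hull), and `points`.
#' @export
convex_hull_3d <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("'points' must be M x 3")
  n <- nrow(pts)
  if (n < 4L) stop("convex hull in 3D needs at least 4 points")
  scale <- max(1, max(abs(pts)))
  eps <- tol * scale

  # seed simplex: two extremes on the widest axis, then farthest from the
  # line, then farthest from the plane
  rng <- apply(pts, 2, range)
  ax <- which.max(rng[2, ] - rng[1, ])
  i1 <- which.min(pts[, ax]); i2 <- which.max(pts[, ax])
  if (vnorm(pts[i2, ] - pts[i1, ]) < eps) stop("degenerate point set (all coincident)")
  d <- pts[i2, ] - pts[i1, ]; d <- d / vnorm(d)
  rel <- sweep(pts, 2, pts[i1, ])
  perp2 <- rowSums(rel^2) - (rel %*% d)^2
  i3 <- which.max(perp2)
  if (perp2[i3] < eps^2) stop("degenerate point set (all collinear)")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / vnorm(nrm)
  h <- abs(rel %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < eps) stop("hull landmarks are coplanar or degenerate")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; cc <- pts[f[3], ]
    nv <- cross3(b - a, cc - a)
    if (sum(nv * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  face_plane <- function(f) {
    a <- pts[f[1], ]
    nv <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    nl <- vnorm(nv)
    nv <- nv / nl
    c(nv, sum(nv * a))
  }
  planes <- t(apply(faces, 1, face_plane))

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (ip in remaining) {
    p <- pts[ip, ]
    dist <- planes[, 1:3, drop = FALSE] %*% p - planes[, 4]
    vis <- which(dist > eps)
    if (length(vis) == 0L) next
    # horizon: edges of visible faces shared with at most one visible face
    edges <- do.call(rbind, lapply(vis, function(fi) {
      f <- faces[fi, ]
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    planes <- planes[-vis, , drop = FALSE]
    newf <- t(apply(horizon, 1, function(e) orient(c(e[1], e[2], ip))))
    newp <- t(apply(newf, 1, face_plane))
    faces <- rbind(faces, newf)
    planes <- rbind(planes, newp)
  }

  structure(list(faces = faces,
                 normals = planes[, 1:3, drop = FALSE],
                 offsets = planes[, 4],
                 vertices = sort(unique(as.vector(faces))),
                 points = pts),
            class = "hull3d")
}

#' Test points for membership in a convex hull
#'
#' Closed membership: points on the boundary count as inside. Each candidate
#' is checked against every facet half-space with an absolute tolerance of
#' `tol` times the hull scale on the inner side.
#'
#' @param points `N x 3` matrix of query points.
#' @param hull a [convex_hull_3d()] result.
#' @param tol boundary tolerance (relative to hull scale).
#' @return logical vector of length `N`.
#' @export
points_in_hull <- function(points, hull, tol = 1e-9) {
  pts <- as.matrix(points)
  eps <- tol * max(1, max(abs(hull$points)))
  d <- pts %*% t(hull$normals) - rep(hull$offsets, each = nrow(pts))
  apply(d <= eps, 1, all)
}

#' Volume enclosed by a convex hull
#' @param hull a [convex_hull_3d()] result.
#' @return enclosed volume (length units cubed).
#' @export
hull_volume <- function(hull) {
  v <- 0
  for (i in seq_len(nrow(hull$faces))) {
    f <- hull$faces[i, ]
    v <- v + det(rbind(hull$points[f[1], ], hull$points[f[2], ],
                       hull$points[f[3], ])) / 6
  }
  abs(v)
}

#' @export
print.hull3d <- function(x, ...) {
  cat(sprintf("<hull3d> %d vertices, %d triangular faces, volume %.6g\n",
              length(x$vertices), nrow(x$faces), hull_volume(x)))
  invisible(x)
}
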