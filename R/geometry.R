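# Geometric selection and measurement tools. These are the headless
# counterparts of the in-VR tools: the selection sphere, landmark convex
# hulls, clipping planes and column thresholding, plus length/angle
# measurement and segment profiling.

#' Selection shapes
#'
#' Four shape variants select subsets of a point cloud: a closed ball, the
#' convex hull of user-placed landmarks, a clipping half-space, and a value
#' threshold on a named column. All selections are closed sets: boundary
#' points are kept.
#'
#' @param center,radius ball center (3-vector) and radius (> 0).
#' @param landmarks `M x 3` matrix of hull landmarks, `M >= 4`, not all
#'   coplanar.
#' @param point,normal a point on the clipping plane and the plane normal
#'   (normalized internally; must be nonzero).
#' @param keep_side which half-space survives: `"+"` keeps points with
#'   `(p - point) . normal >= 0`, `"-"` the opposite.
#' @param column,min,max column threshold: keep `min <= value <= max`.
#' @return an object of class `selection_shape` (subclass per variant).
#' @name selection_shapes
NULL

#' @rdname selection_shapes
#' @export
sphere_shape <- function(center, radius) {
  center <- as_vec3(center)
  if (!is.finite(radius) || radius <= 0) stop("sphere radius must be > 0")
  structure(list(type = "sphere", center = center, radius = radius),
            class = c("sphere_shape", "selection_shape"))
}

#' @rdname selection_shapes
#' @export
hull_shape <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) < 4) stop("hull needs at least 4 landmarks")
  hull <- convex_hull_3d(landmarks)  # errors if coplanar/degenerate
  structure(list(type = "hull", landmarks = landmarks, hull = hull),
            class = c("hull_shape", "selection_shape"))
}

#' @rdname selection_shapes
#' @export
plane_shape <- function(point, normal, keep_side = "+") {
  point <- as_vec3(point)
  normal <- as_vec3(normal)
  nl <- vnorm(normal)
  if (nl < 1e-12) stop("plane normal must be nonzero")
  if (!keep_side %in% c("+", "-")) stop("keep_side must be '+' or '-'")
  structure(list(type = "plane", point = point, normal = normal / nl,
                 keep_side = keep_side),
            class = c("plane_shape", "selection_shape"))
}

#' @rdname selection_shapes
#' @export
threshold_shape <- function(column, min = -Inf, max = Inf) {
  stopifnot(is.character(column), length(column) == 1L)
  if (min > max) stop("threshold min must be <= max")
  structure(list(type = "threshold", column = column, min = min, max = max),
            class = c("threshold_shape", "selection_shape"))
}

#' @export
print.selection_shape <- function(x, ...) {
  cat(sprintf("<selection_shape:%s>\n", x$type))
  invisible(x)
}

#' Select point-cloud indices with a shape
#'
#' @param cloud a [point_cloud].
#' @param shape a [selection_shapes] object.
#' @return sorted, duplicate-free integer vector of 1-based indices.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0.5), c(0, 0, 2)))
#' select_points(pc, sphere_shape(c(0, 0, 0), 1))  # -> 1
#' @export
select_points <- function(cloud, shape) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(shape, "selection_shape"))
  p <- cloud$positions
  keep <- switch(shape$type,
    sphere = {
      d2 <- rowSums(sweep(p, 2, shape$center)^2)
      d2 <= shape$radius^2
    },
    hull = points_in_hull(p, shape$hull),
    plane = {
      s <- sweep(p, 2, shape$point) %*% shape$normal
      if (shape$keep_side == "+") s >= 0 else s <= 0
    },
    threshold = {
      v <- cloud$columns[[shape$column]]
      if (is.null(v)) {
        v <- switch(shape$column, x = p[, 1], y = p[, 2], z = p[, 3],
                    t = cloud$time,
                    stop(sprintf("unknown threshold column '%s'", shape$column)))
      }
      v >= shape$min & v <= shape$max
    },
    stop("unknown shape type"))
  which(as.vector(keep))
}

#' Combine index selections with set algebra
#'
#' Clipping planes and other selections can be held in place and combined;
#' this is the corresponding set operation on index sets.
#'
#' @param selections non-empty list of integer index vectors.
#' @param mode `"union"`, `"intersection"` or `"difference"` (first minus
#'   the union of the rest).
#' @return sorted, duplicate-free integer vector.
#' @export
combine_selections <- function(selections,
                               mode = c("union", "intersection", "difference")) {
  mode <- match.arg(mode)
  if (!is.list(selections) || length(selections) == 0L) {
    stop("'selections' must be a non-empty list of index vectors")
  }
  out <- Reduce(switch(mode,
                       union = union,
                       intersection = intersect,
                       difference = setdiff),
                selections)
  sort(unique(as.integer(out)))
}

#' Euclidean distance between two 3D points
#' @param p1,p2 3-vectors.
#' @return distance in the cloud's length units.
#' @export
measure_distance <- function(p1, p2) vnorm(as_vec3(p2) - as_vec3(p1))

#' Angle at a vertex, in degrees
#'
#' Angle between the arms `a - vertex` and `b - vertex`, reported in
#' degrees in `[0, 180]`.
#' @param a,vertex,b 3-vectors; arms must have nonzero length.
#' @return angle in degrees.
#' @export
measure_angle <- function(a, vertex, b) {
  u <- as_vec3(a) - as_vec3(vertex)
  v <- as_vec3(b) - as_vec3(vertex)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-300 || nv < 1e-300) stop("angle arm has zero length")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Count a selection
#' @param selection integer index vector from [select_points()].
#' @return integer cardinality.
#' @export
count_selection <- function(selection) length(unique(selection))

#' Bin-count profile of a point cloud along a segment
#'
#' Each point is projected onto the axis through `p1`-`p2`; points whose
#' projection parameter lies in `[0, 1]` (and, when `radius` is given,
#' whose perpendicular distance to the axis is at most `radius`) are
#' histogrammed into `n_bins` equal intervals along the segment. The last
#' bin is right-closed so no in-range point is lost.
#'
#' @param cloud a [point_cloud].
#' @param p1,p2 distinct segment endpoints (3-vectors).
#' @param n_bins number of bins (>= 1).
#' @param radius optional cylinder radius filter.
#' @return object of class `segment_profile`: `counts`, `edges` (on the
#'   normalized `[0,1]` axis), `p1`, `p2`, `radius`.
#' @export
segment_profile <- function(cloud, p1, p2, n_bins, radius = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  p1 <- as_vec3(p1); p2 <- as_vec3(p2)
  if (n_bins < 1) stop("n_bins must be >= 1")
  axis <- p2 - p1
  L <- vnorm(axis)
  if (L < 1e-300) stop("segment endpoints must differ")
  u <- axis / L
  rel <- sweep(cloud$positions, 2, p1)
  s <- as.vector(rel %*% u) / L          # projection parameter in [0,1]
  keep <- s >= 0 & s <= 1
  if (!is.null(radius)) {
    perp2 <- rowSums(rel^2) - (s * L)^2
    keep <- keep & perp2 <= radius^2
  }
  sk <- s[keep]
  bin <- pmin(floor(sk * n_bins) + 1L, n_bins)  # s == 1 lands in last bin
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(counts = counts,
                 edges = seq(0, 1, length.out = n_bins + 1L),
                 p1 = p1, p2 = p2, radius = radius),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %d bins, %d points in range\n",
              length(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Serialize a selection shape to JSON
#' @param shape a [selection_shapes] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
shape_to_json <- function(shape, path = NULL) {
  stopifnot(inherits(shape, "selection_shape"))
  x <- unclass(shape)
  x$hull <- NULL  # rebuilt on parse
  if (!is.null(x$landmarks)) x$landmarks <- unname(as.matrix(x$landmarks))
  if (is.null(path)) {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Parse a selection shape from JSON
#' @param json JSON string or file path written by [shape_to_json()].
#' @return a `selection_shape`.
#' @export
shape_from_json <- function(json) {
  x <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
       else jsonlite::fromJSON(json)
  switch(x$type,
    sphere = sphere_shape(x$center, x$radius),
    hull = hull_shape(x$landmarks),
    plane = plane_shape(x$point, x$normal, x$keep_side),
    threshold = threshold_shape(x$column, x$min, x$max),
    stop(sprintf("unknown shape type '%s'", x$type)))
}
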