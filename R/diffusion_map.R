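# 3D diffusivity/force mapping: k-means tessellation of the localizations,
# per-region maximum-likelihood (flat-prior posterior-mode) inference of
# (D, v), and colored convex-hull region meshes for export. The stats::kmeans
# Lloyd path can abort on empty clusters and does not use k-means++ style
# seeding, so a small Lloyd loop with deterministic k-means++ initialization
# and farthest-point re-seeding is implemented here; stats::kmeans serves as
# an independent cross-check in the tests.

kmeanspp_init <- function(P, k) {
  n <- nrow(P)
  centers <- matrix(0, k, 3)
  centers[1, ] <- P[sample.int(n, 1), ]
  d2 <- rowSums(sweep(P, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0) prob <- rep(1 / n, n)
    centers[j, ] <- P[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(P, 2, centers[j, ])^2))
  }
  centers
}

nearest_center <- function(P, centers) {
  # squared distance to each center via |p|^2 - 2 p.c + |c|^2
  cross <- tcrossprod(P, centers)
  d2 <- outer(rowSums(P^2), rowSums(centers^2), `+`) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' K-means tessellation of a point cloud
#'
#' Partitions the localizations into `k` compact spatial regions by Lloyd
#' iteration from k-means++ style seeding; the best of `n_init`
#' initializations (by within-cluster sum of squares) is kept. Empty
#' clusters are re-seeded at the point farthest from its current center.
#' Deterministic for a fixed seed.
#'
#' @param positions `N x 3` matrix or a [point_cloud].
#' @param k number of regions (`1 <= k <= N`).
#' @param points_per_region alternative to `k`: target member count, giving
#'   `k = max(1, round(N / points_per_region))`.
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @param n_init number of restarts.
#' @return object of class `region_partition`: `k`, `labels` (1-based,
#'   length N), `centers` (`k x 3`), `wss`, `seed`.
#' @export
partition_kmeans <- function(positions, k = NULL, points_per_region = NULL,
                             seed = 1, max_iter = 100, n_init = 5) {
  if (inherits(positions, "point_cloud")) positions <- positions$positions
  P <- as.matrix(positions)
  n <- nrow(P)
  if (is.null(k)) {
    if (is.null(points_per_region)) stop("give k or points_per_region")
    k <- max(1L, as.integer(round(n / points_per_region)))
  }
  k <- as.integer(k)
  if (k < 1 || k > n) stop(sprintf("need 1 <= k <= N (k = %d, N = %d)", k, n))
  run_once <- function() {
    centers <- kmeanspp_init(P, k)
    labels <- nearest_center(P, centers)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(k)) {
        idx <- which(labels == j)
        if (length(idx) == 0L) {
          # re-seed an empty cluster at the globally farthest point
          d2 <- rowSums((P - centers[labels, , drop = FALSE])^2)
          centers[j, ] <- P[which.max(d2), ]
        } else {
          centers[j, ] <- colMeans(P[idx, , drop = FALSE])
        }
      }
      new_labels <- nearest_center(P, centers)
      if (all(new_labels == labels)) break
      labels <- new_labels
    }
    wss <- sum((P - centers[labels, , drop = FALSE])^2)
    list(labels = labels, centers = centers, wss = wss)
  }
  best <- local_seed(derive_seed(seed, "kmeans"), {
    b <- NULL
    for (i in seq_len(n_init)) {
      cand <- run_once()
      if (is.null(b) || cand$wss < b$wss) b <- cand
    }
    b
  })
  structure(list(k = k, labels = best$labels, centers = best$centers,
                 wss = best$wss, seed = seed),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> k = %d over %d points (wss = %.4g)\n",
              x$k, length(x$labels), x$wss))
  invisible(x)
}

#' Assign translocations to tessellation regions
#'
#' Each translocation is attributed to the region of its starting point
#' (the standard convention in diffusivity mapping); a step crossing a
#' region boundary therefore counts for the region it left. Regions with
#' fewer than `min_translocations` steps are flagged `insufficient_data`.
#'
#' @param trajectories a `trajectory_set`.
#' @param partition a [partition_kmeans()] result (computed on the same
#'   cloud; assignment is by nearest center, which reproduces the k-means
#'   labels at the Lloyd fixed point).
#' @param min_translocations minimum steps for a region to be estimable
#'   (default 20).
#' @return list with one element per region: `dr`, `dt`, `n`, `status`.
#' @export
assign_translocations <- function(trajectories, partition,
                                  min_translocations = 20) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(partition, "region_partition"))
  starts <- do.call(rbind, lapply(trajectories, function(tr) {
    np <- nrow(tr$positions)
    if (np > 1) tr$positions[-np, , drop = FALSE]
    else matrix(numeric(0), ncol = 3)
  }))
  tl <- translocations(trajectories)
  if (is.null(starts) || nrow(starts) == 0L) {
    starts <- matrix(numeric(0), ncol = 3)
  }
  lab <- if (nrow(starts)) nearest_center(starts, partition$centers)
         else integer(0)
  lapply(seq_len(partition$k), function(j) {
    idx <- which(lab == j)
    list(dr = tl$dr[idx, , drop = FALSE],
         dt = tl$dt[idx],
         n = length(idx),
         status = if (length(idx) < min_translocations) "insufficient_data"
                  else "ok")
  })
}

#' Infer a 3D diffusivity/force map
#'
#' Runs [mle_diffusion_drift()] on each region's translocation set and
#' reports per-region diffusivity `D`, drift `v` and the force
#' `F = v kT / D` (in kT/um when `kT = 1`). Per-point `region` and
#' `D_local` columns are appended to the cloud for colour mapping.
#' Regions with too few translocations are flagged, never fatal.
#'
#' @param cloud the [point_cloud] the partition was computed on.
#' @param trajectories a `trajectory_set` built from the same cloud.
#' @param partition a [partition_kmeans()] result.
#' @param sigma static localization precision passed to the estimator.
#' @param kT thermal energy for the force conversion (default 1).
#' @param min_translocations see [assign_translocations()].
#' @return object of class `diffusion_map`: `partition`, `estimates`
#'   (data.frame: region, n, D, vx, vy, vz, Fx, Fy, Fz, logL, status),
#'   `cloud` (with `region` and `D_local` columns), `sigma`, `kT`.
#' @export
infer_map <- function(cloud, trajectories, partition, sigma = 0, kT = 1,
                      min_translocations = 20) {
  stopifnot(inherits(cloud, "point_cloud"))
  sets <- assign_translocations(trajectories, partition, min_translocations)
  rows <- lapply(seq_along(sets), function(j) {
    s <- sets[[j]]
    if (s$status == "insufficient_data" || s$n < 2) {
      return(data.frame(region = j, n = s$n, D = NA_real_,
                        vx = NA_real_, vy = NA_real_, vz = NA_real_,
                        Fx = NA_real_, Fy = NA_real_, Fz = NA_real_,
                        logL = NA_real_, status = "insufficient_data"))
    }
    fit <- mle_diffusion_drift(s$dr, s$dt, sigma = sigma, d = 3)
    Fv <- if (fit$D > 0) fit$v * kT / fit$D else c(NA_real_, NA_real_, NA_real_)
    data.frame(region = j, n = s$n, D = fit$D,
               vx = fit$v[1], vy = fit$v[2], vz = fit$v[3],
               Fx = Fv[1], Fy = Fv[2], Fz = Fv[3],
               logL = fit$logL, status = fit$status)
  })
  est <- do.call(rbind, rows)
  cloud <- set_column(cloud, "region", partition$labels)
  cloud <- set_column(cloud, "D_local", est$D[partition$labels])
  structure(list(partition = partition, estimates = est, cloud = cloud,
                 sigma = sigma, kT = kT),
            class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  ok <- x$estimates$status == "ok"
  cat(sprintf("<diffusion_map> %d regions (%d estimated)\n",
              nrow(x$estimates), sum(ok)))
  if (any(ok)) {
    cat(sprintf("  D range: %.4g - %.4g um^2/s\n",
                min(x$estimates$D[ok]), max(x$estimates$D[ok])))
  }
  invisible(x)
}

#' @export
summary.diffusion_map <- function(object, ...) {
  print(object)
  print(object$estimates)
  invisible(object$estimates)
}

#' Map-record JSON for a diffusion map
#'
#' @param map a [infer_map()] result.
#' @param parameters extra parameters to record (seeds etc.).
#' @return an [analysis_record()] whose outputs hold the per-region table.
#' @export
map_record <- function(map, parameters = list()) {
  stopifnot(inherits(map, "diffusion_map"))
  analysis_record(
    tool = "map3d",
    parameters = c(list(k = map$partition$k, seed = map$partition$seed,
                        sigma = map$sigma, kT = map$kT), parameters),
    outputs = list(regions = map$estimates[,
      c("region", "n", "D", "vx", "vy", "vz", "logL", "status")]))
}

#' Colored convex-hull meshes of tessellation regions
#'
#' Builds the convex hull of each region's member points as a closed
#' triangulated surface, colored by mapping `values` through a colormap
#' normalized min-max over the valid regions (the minimum value maps to
#' the first colormap colour, the maximum to the last). Regions with fewer
#' than 4 points or degenerate (coplanar) geometry are skipped with a
#' warning.
#'
#' @param cloud a [point_cloud].
#' @param partition a [partition_kmeans()] result on the same cloud.
#' @param values numeric vector, one per region (e.g. the mapped `D`);
#'   `NA` regions are skipped.
#' @param colormap palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`, colour-blind safe).
#' @param transparency alpha in `[0, 1]` (1 = opaque).
#' @param render `"surface"` or `"wireframe"` rendering hint.
#' @return list of `region_mesh` objects: `region`, `vertices` (`V x 3`),
#'   `faces` (`F x 3`, 1-based), `value`, `color` (RGBA bytes 0-255),
#'   `render`.
#' @export
build_region_meshes <- function(cloud, partition, values,
                                colormap = "viridis", transparency = 1,
                                render = c("surface", "wireframe")) {
  render <- match.arg(render)
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(partition, "region_partition"))
  if (length(values) != partition$k) {
    stop("'values' must have one entry per region")
  }
  pal <- grDevices::hcl.colors(256L, colormap)
  valid <- which(is.finite(values))
  vmin <- if (length(valid)) min(values[valid]) else 0
  vmax <- if (length(valid)) max(values[valid]) else 1
  meshes <- list()
  for (j in seq_len(partition$k)) {
    if (!j %in% valid) next
    idx <- which(partition$labels == j)
    if (length(idx) < 4) {
      warning(sprintf("region %d has < 4 points; skipped", j))
      next
    }
    hull <- tryCatch(convex_hull_3d(cloud$positions[idx, , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(hull)) {
      warning(sprintf("region %d is degenerate (coplanar); skipped", j))
      next
    }
    vmap <- match(seq_len(nrow(hull$points)), hull$vertices)
    verts <- hull$points[hull$vertices, , drop = FALSE]
    faces <- matrix(vmap[hull$faces], ncol = 3)
    u <- if (vmax > vmin) (values[j] - vmin) / (vmax - vmin) else 0
    col <- grDevices::col2rgb(pal[1L + as.integer(round(u * 255))])
    rgba <- c(as.integer(col), as.integer(round(transparency * 255)))
    meshes[[length(meshes) + 1L]] <- structure(
      list(region = j, vertices = verts, faces = faces,
           value = values[j], color = rgba, render = render),
      class = "region_mesh")
  }
  if (length(meshes) == 0L) stop("all regions degenerate: no mesh to build")
  meshes
}

#' @export
print.region_mesh <- function(x, ...) {
  cat(sprintf("<region_mesh> region %d: %d vertices, %d faces, value %.4g\n",
              x$region, nrow(x$vertices), nrow(x$faces), x$value))
  invisible(x)
}

#' Export region meshes to PLY or OBJ
#'
#' PLY carries per-vertex RGBA colour (`ascii` or `binary_little_endian`);
#' OBJ writes one `g region_<id>` group per mesh with colours appended to
#' the `v` lines (common extension). Re-parsing a PLY with [read_ply()]
#' recovers vertex count, face count and colours exactly.
#'
#' @param meshes non-empty list of `region_mesh` objects.
#' @param path output file path.
#' @param format `"ply"` or `"obj"`.
#' @param mode PLY encoding, `"ascii"` (default) or
#'   `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
export_map <- function(meshes, path, format = c("ply", "obj"),
                       mode = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  if (!is.list(meshes) || length(meshes) == 0L) stop("need at least one mesh")
  if (format == "ply") write_ply(meshes, path, mode = match.arg(mode))
  else write_obj(meshes, path)
}

#' @rdname export_map
#' @export
write_ply <- function(meshes, path, mode = c("ascii", "binary_little_endian")) {
  mode <- match.arg(mode)
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  offs <- cumsum(c(0L, nv[-length(nv)]))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  cols <- do.call(rbind, lapply(seq_along(meshes), function(i) {
    matrix(meshes[[i]]$color, nv[i], 4, byrow = TRUE)
  }))
  Fc <- do.call(rbind, lapply(seq_along(meshes), function(i) {
    meshes[[i]]$faces + offs[i]
  }))
  header <- c(
    "ply",
    sprintf("format %s 1.0", mode),
    "comment smlmkit region meshes",
    sprintf("element vertex %d", nrow(V)),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "property uchar alpha",
    sprintf("element face %d", nrow(Fc)),
    "property list uchar int vertex_indices",
    "end_header")
  if (mode == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%s %s %s %d %d %d %d",
                       fmt_num(V[, 1]), fmt_num(V[, 2]), fmt_num(V[, 3]),
                       cols[, 1], cols[, 2], cols[, 3], cols[, 4]), con)
    writeLines(sprintf("3 %d %d %d", Fc[, 1] - 1L, Fc[, 2] - 1L, Fc[, 3] - 1L),
               con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    for (i in seq_len(nrow(V))) {
      writeBin(as.numeric(V[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(cols[i, ]), con)
    }
    for (i in seq_len(nrow(Fc))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(Fc[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY file written by [write_ply()]
#'
#' Supports ascii and binary_little_endian encodings with the
#' vertex (x, y, z, red, green, blue, alpha) / face layout this package
#' writes.
#'
#' @param path PLY file path.
#' @return list with `vertices` (`V x 3`), `colors` (`V x 4` integer
#'   0-255), `faces` (`F x 3`, 1-based).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(line) == 0L) stop("truncated PLY header")
  }
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE))
  fmt <- strsplit(fmt, " ")[[1]][1]
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face", header, value = TRUE)))
  if (fmt == "ascii") {
    vl <- readLines(con, n = nv)
    vm <- matrix(as.numeric(unlist(strsplit(vl, " "))), nv, 7, byrow = TRUE)
    fl <- readLines(con, n = nf)
    fm <- matrix(as.integer(unlist(strsplit(fl, " "))), nf, 4, byrow = TRUE)
    if (any(fm[, 1] != 3L)) stop("only triangular faces supported")
    list(vertices = vm[, 1:3, drop = FALSE],
         colors = matrix(as.integer(vm[, 4:7]), nv, 4),
         faces = fm[, 2:4, drop = FALSE] + 1L)
  } else if (fmt == "binary_little_endian") {
    V <- matrix(0, nv, 3)
    cols <- matrix(0L, nv, 4)
    for (i in seq_len(nv)) {
      V[i, ] <- readBin(con, "numeric", 3, size = 4, endian = "little")
      cols[i, ] <- as.integer(readBin(con, "raw", 4))
    }
    Fc <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("only triangular faces supported")
      Fc[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little")
    }
    list(vertices = V, colors = cols, faces = Fc + 1L)
  } else {
    stop(sprintf("unsupported PLY format '%s'", fmt))
  }
}

#' @rdname export_map
#' @export
write_obj <- function(meshes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# smlmkit region meshes", con)
  off <- 0L
  for (m in meshes) {
    writeLines(sprintf("g region_%d", m$region), con)
    rgb <- m$color[1:3] / 255
    writeLines(sprintf("v %s %s %s %.6f %.6f %.6f",
                       fmt_num(m$vertices[, 1]), fmt_num(m$vertices[, 2]),
                       fmt_num(m$vertices[, 3]), rgb[1], rgb[2], rgb[3]), con)
    writeLines(sprintf("f %d %d %d", m$faces[, 1] + off, m$faces[, 2] + off,
                       m$faces[, 3] + off), con)
    off <- off + nrow(m$vertices)
  }
  invisible(path)
}
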