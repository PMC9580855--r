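# k-means tessellation, per-region inference, region meshes and export.

test_that("k-means separates well-separated blobs and is deterministic", {
  set.seed(1)
  blob1 <- matrix(rnorm(3 * 150, 0, 0.1), ncol = 3)
  blob2 <- matrix(rnorm(3 * 150, 10, 0.1), ncol = 3)
  P <- rbind(blob1, blob2)
  truth <- rep(1:2, each = 150)
  part <- partition_kmeans(P, k = 2, seed = 3)
  tab <- table(part$labels, truth)
  expect_equal(max(sum(diag(tab)), tab[1, 2] + tab[2, 1]), 300)
  # independent cross-check against stats::kmeans on the same data
  km <- stats::kmeans(P, centers = rbind(colMeans(blob1), colMeans(blob2)))
  expect_equal(sort(table(part$labels)), sort(table(km$cluster)),
               ignore_attr = TRUE)

  part2 <- partition_kmeans(P, k = 2, seed = 3)
  expect_identical(part$labels, part2$labels)
  expect_identical(part$centers, part2$centers)
})

test_that("k = 1 returns the centroid and points_per_region sets k", {
  P <- matrix(rnorm(300), ncol = 3)
  part <- partition_kmeans(P, k = 1, seed = 1)
  expect_equal(part$centers[1, ], colMeans(P), tolerance = 1e-12)
  expect_true(all(part$labels == 1L))
  part2 <- partition_kmeans(P, points_per_region = 25, seed = 1)
  expect_equal(part2$k, 4L)
  expect_error(partition_kmeans(P, k = 200), "k <= N")
})

test_that("Lloyd fixed point: each center is the mean of its members", {
  set.seed(2)
  P <- matrix(runif(3 * 500), ncol = 3)
  part <- partition_kmeans(P, k = 8, seed = 5)
  for (j in seq_len(part$k)) {
    idx <- which(part$labels == j)
    expect_gt(length(idx), 0)
    expect_equal(part$centers[j, ], colMeans(P[idx, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("translocations go to the region of their starting point", {
  # two trajectories fully inside opposite blobs, one crossing step
  P1 <- matrix(rnorm(3 * 20, 0, 0.05), ncol = 3)
  P2 <- matrix(rnorm(3 * 20, 10, 0.05), ncol = 3)
  cloud <- point_cloud(rbind(P1, P2), time = rep(0:19, 2),
                       columns = list(id = rep(1:2, each = 20)))
  trajs <- build_trajectories(cloud)
  part <- partition_kmeans(cloud, k = 2, seed = 1)
  sets <- assign_translocations(trajs, part, min_translocations = 5)
  lab1 <- part$labels[1]
  expect_equal(sets[[lab1]]$n, 19L)
  expect_equal(sets[[3 - lab1]]$n, 19L)
  expect_equal(sets[[1]]$status, "ok")

  # brute-force oracle: nearest center of each start point
  set.seed(6)
  cl2 <- point_cloud(matrix(runif(3 * 200, 0, 5), ncol = 3),
                     time = rep(0:39, 5),
                     columns = list(id = rep(1:5, each = 40)))
  tr2 <- build_trajectories(cl2)
  part2 <- partition_kmeans(cl2, k = 6, seed = 2)
  sets2 <- assign_translocations(tr2, part2, min_translocations = 1)
  tl <- translocations(tr2)
  starts <- do.call(rbind, lapply(tr2, function(tr) {
    tr$positions[-nrow(tr$positions), , drop = FALSE]
  }))
  brute <- apply(starts, 1, function(p) {
    which.min(colSums((t(part2$centers) - p)^2))
  })
  expect_equal(vapply(sets2, `[[`, integer(1), "n"),
               as.integer(tabulate(brute, part2$k)))
})

test_that("a single-region map equals the pooled estimator", {
  trajs <- simulate_brownian(n_trajectories = 10, n_steps = 50, dt = 0.03,
                             D = 0.4, seed = 7)
  cloud <- trajectories_to_cloud(trajs, metadata = list(dt = 0.03))
  part <- partition_kmeans(cloud, k = 1, seed = 1)
  map <- infer_map(cloud, trajs, part)
  tl <- translocations(trajs)
  ref <- mle_diffusion_drift(tl$dr, tl$dt)
  expect_equal(map$estimates$D[1], ref$D, tolerance = 1e-12)
  expect_equal(unlist(map$estimates[1, c("vx", "vy", "vz")]), ref$v,
               ignore_attr = TRUE)
  # per-point columns appended for colour mapping
  expect_true(all(c("region", "D_local") %in% names(map$cloud$columns)))
  expect_equal(unique(map$cloud$columns$D_local), ref$D)
})

test_that("starved regions are flagged insufficient_data without aborting", {
  trajs <- structure(list(list(
    id = 1,
    positions = rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0), c(0.1, 0.1, 0)),
    times = 0:3,
    dr = rbind(c(0.1, 0, 0), c(0.1, 0, 0), c(-0.1, 0.1, 0)),
    dt = rep(1, 3))), class = "trajectory_set")
  cloud <- trajectories_to_cloud(trajs)
  part <- partition_kmeans(cloud, k = 2, seed = 1)
  map <- infer_map(cloud, trajs, part, min_translocations = 20)
  expect_true(all(map$estimates$status == "insufficient_data"))
  expect_true(all(is.na(map$estimates$D)))
})

test_that("map records are reproducible byte-for-byte under a fixed seed", {
  run <- function() {
    trajs <- simulate_brownian(n_trajectories = 20, n_steps = 40, dt = 0.03,
                               D = 0.5, seed = 31)
    cloud <- trajectories_to_cloud(trajs, metadata = list(dt = 0.03))
    part <- partition_kmeans(cloud, k = 4, seed = 2)
    map <- infer_map(cloud, trajs, part)
    f <- tempfile(fileext = ".json")
    save_record(map_record(map), f)
    on.exit(unlink(f))
    # drop the timestamp line: content determinism is what matters
    paste(grep("created", readLines(f), value = TRUE, invert = TRUE),
          collapse = "\n")
  }
  expect_identical(run(), run())
})

test_that("region meshes are hulls colored by min-max normalized values", {
  pos <- rbind(unit_tetrahedron(),                      # region A
               as.matrix(expand.grid(0:1, 0:1, 0:1)) + 5)  # region B: cube
  cloud <- point_cloud(pos)
  part <- structure(list(k = 2L, labels = rep(1:2, c(4, 8)),
                         centers = rbind(colMeans(pos[1:4, ]),
                                         colMeans(pos[5:12, ])),
                         wss = 0, seed = 1),
                    class = "region_partition")
  meshes <- build_region_meshes(cloud, part, values = c(0.1, 1.0))
  expect_length(meshes, 2L)
  expect_equal(nrow(meshes[[1]]$faces), 4L)       # tetrahedron
  expect_equal(nrow(meshes[[2]]$vertices), 8L)    # cube corners
  pal <- grDevices::hcl.colors(256, "viridis")
  expect_equal(meshes[[1]]$color[1:3],
               as.integer(grDevices::col2rgb(pal[1])))    # min -> first
  expect_equal(meshes[[2]]$color[1:3],
               as.integer(grDevices::col2rgb(pal[256])))  # max -> last
  expect_equal(meshes[[1]]$color[4], 255L)

  # degenerate regions are skipped with a warning; all-degenerate errors
  part_bad <- structure(list(k = 2L, labels = rep(1:2, c(3, 9)),
                             centers = part$centers, wss = 0, seed = 1),
                        class = "region_partition")
  expect_warning(m2 <- build_region_meshes(cloud, part_bad, c(0.1, 1)),
                 "skipped")
  expect_length(m2, 1L)
})

test_that("PLY export round-trips exactly in both encodings", {
  cloud <- point_cloud(rbind(unit_tetrahedron(),
                             unit_tetrahedron() + 3))
  part <- structure(list(k = 2L, labels = rep(1:2, each = 4),
                         centers = rbind(c(0, 0, 0), c(3, 3, 3)),
                         wss = 0, seed = 1),
                    class = "region_partition")
  meshes <- build_region_meshes(cloud, part, values = c(1, 2),
                                transparency = 0.5)
  for (mode in c("ascii", "binary_little_endian")) {
    f <- withr::local_tempfile(fileext = ".ply")
    export_map(meshes, f, format = "ply", mode = mode)
    back <- read_ply(f)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 8L)
    expect_equal(back$vertices, rbind(meshes[[1]]$vertices,
                                      meshes[[2]]$vertices),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$colors[1, ],
                 c(meshes[[1]]$color[1:3], 128L))  # RGBA byte-exact
    expect_equal(back$faces[5:8, ], meshes[[2]]$faces + 4L,
                 ignore_attr = TRUE)
  }
})

test_that("an independent parser accepts the exported ascii PLY", {
  # minimal independent reader: header scan + field-by-field parse
  cloud <- point_cloud(unit_tetrahedron() * 2)
  part <- structure(list(k = 1L, labels = rep(1L, 4),
                         centers = rbind(colMeans(cloud$positions)),
                         wss = 0, seed = 1),
                    class = "region_partition")
  meshes <- build_region_meshes(cloud, part, values = 0.7)
  f <- withr::local_tempfile(fileext = ".ply")
  export_map(meshes, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("element face", lines, value = TRUE)))
  expect_equal(length(lines), end + nv + nf)
  vfields <- strsplit(lines[(end + 1):(end + nv)], " ")
  expect_true(all(lengths(vfields) == 7L))
  ffields <- strsplit(lines[(end + nv + 1):(end + nv + nf)], " ")
  expect_true(all(vapply(ffields, `[`, character(1), 1) == "3"))
  idx <- as.integer(unlist(lapply(ffields, `[`, 2:4)))
  expect_true(all(idx >= 0 & idx < nv))
})

test_that("OBJ export writes one group per region with valid face indices", {
  cloud <- point_cloud(rbind(unit_tetrahedron(), unit_tetrahedron() + 2))
  part <- structure(list(k = 2L, labels = rep(1:2, each = 4),
                         centers = rbind(c(0, 0, 0), c(2, 2, 2)),
                         wss = 0, seed = 1),
                    class = "region_partition")
  meshes <- build_region_meshes(cloud, part, values = c(1, 5))
  f <- withr::local_tempfile(fileext = ".obj")
  export_map(meshes, f, format = "obj")
  lines <- readLines(f)
  expect_equal(sum(grepl("^g region_", lines)), 2L)
  v <- grep("^v ", lines); fc <- grep("^f ", lines)
  expect_equal(length(v), 8L)
  expect_equal(length(fc), 8L)
  idx <- as.integer(unlist(strsplit(sub("^f ", "", lines[fc]), " ")))
  expect_true(all(idx >= 1 & idx <= 8))
})
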