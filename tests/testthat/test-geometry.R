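# Selection shapes, set algebra, measurement tools and segment profiles.

test_that("sphere, hull, plane and threshold selections match their definitions", {
  pc <- point_cloud(rbind(c(0, 0, 0.5), c(0, 0, 2)))
  expect_equal(select_points(pc, sphere_shape(c(0, 0, 0), 1)), 1L)

  tet <- unit_tetrahedron()
  pc2 <- point_cloud(rbind(c(0.1, 0.1, 0.1), c(1, 1, 1)))
  expect_equal(select_points(pc2, hull_shape(tet)), 1L)

  pc3 <- point_cloud(rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1)))
  expect_equal(select_points(pc3, plane_shape(c(0, 0, 0), c(0, 0, 1), "+")),
               c(2L, 3L))  # boundary point kept

  pc4 <- point_cloud(matrix(0, 3, 3), columns = list(w = c(1, 5, 9)))
  expect_equal(select_points(pc4, threshold_shape("w", 2, 9)), c(2L, 3L))
  expect_error(select_points(pc4, threshold_shape("missing", 0, 1)),
               "unknown threshold column")
})

test_that("shape constructors validate their geometry", {
  expect_error(sphere_shape(c(0, 0, 0), 0), "radius")
  expect_error(hull_shape(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0),
                                 4, 3, byrow = TRUE)), "coplanar")
  expect_error(plane_shape(c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("selections equal the brute-force per-point predicates", {
  set.seed(7)
  n <- 2000
  P <- matrix(runif(3 * n), ncol = 3)
  pc <- point_cloud(P, columns = list(v = rnorm(n)))

  sph <- sphere_shape(c(0.4, 0.5, 0.6), 0.3)
  expect_equal(select_points(pc, sph),
               which(sqrt(colSums((t(P) - sph$center)^2)) <= 0.3))

  pl <- plane_shape(c(0.5, 0.5, 0.5), c(1, 2, -1) / sqrt(6), "-")
  expect_equal(select_points(pc, pl),
               which(as.vector(sweep(P, 2, pl$point) %*% pl$normal) <= 0))

  th <- threshold_shape("v", -0.5, 0.5)
  expect_equal(select_points(pc, th),
               which(pc$columns$v >= -0.5 & pc$columns$v <= 0.5))

  # hull membership vs an independent tetrahedron-decomposition oracle
  lm <- matrix(runif(3 * 8, 0.2, 0.8), ncol = 3)
  hs <- hull_shape(lm)
  centroid <- colMeans(hs$hull$points[hs$hull$vertices, , drop = FALSE])
  oracle <- vapply(seq_len(n), function(i) {
    any(apply(hs$hull$faces, 1, function(f) {
      in_tetrahedron(P[i, ], rbind(centroid, lm[f[1], ], lm[f[2], ],
                                   lm[f[3], ]))
    }))
  }, logical(1))
  expect_equal(select_points(pc, hs), which(oracle))
})

test_that("set algebra on selections matches base set operations", {
  pc <- point_cloud(matrix(runif(300), ncol = 3))
  a <- select_points(pc, plane_shape(c(0, 0, 0.2), c(0, 0, 1), "+"))
  b <- select_points(pc, plane_shape(c(0, 0, 0.7), c(0, 0, 1), "-"))
  slab <- select_points(pc, threshold_shape("z", 0.2, 0.7))
  expect_equal(combine_selections(list(a, b), "intersection"), slab)
  expect_equal(combine_selections(list(a, integer(0)), "union"), sort(a))
  set.seed(2)
  x <- sample(100, 40); y <- sample(100, 40); z <- sample(100, 40)
  expect_equal(combine_selections(list(x, y, z), "union"),
               sort(union(union(x, y), z)))
  expect_equal(combine_selections(list(x, y, z), "difference"),
               sort(setdiff(setdiff(x, y), z)))
  expect_error(combine_selections(list(), "union"), "non-empty")
})

test_that("distances, angles and counts behave like Euclidean geometry", {
  expect_equal(measure_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(measure_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(measure_angle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
  expect_error(measure_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero")
  expect_equal(count_selection(c(3L, 1L, 3L)), 2L)
  # interior angles of random triangles sum to 180 degrees
  set.seed(5)
  for (i in 1:20) {
    tri <- matrix(rnorm(9), 3, 3)
    s <- measure_angle(tri[2, ], tri[1, ], tri[3, ]) +
      measure_angle(tri[1, ], tri[2, ], tri[3, ]) +
      measure_angle(tri[1, ], tri[3, ], tri[2, ])
    expect_equal(s, 180, tolerance = 1e-9)
  }
})

test_that("segment profiles bin projections onto the axis", {
  s <- seq(0.05, 0.95, by = 0.1)
  pc <- point_cloud(cbind(s * 2, 0, 0))  # segment (0,0,0)-(2,0,0)
  prof <- segment_profile(pc, c(0, 0, 0), c(2, 0, 0), n_bins = 5)
  expect_equal(prof$counts, rep(2L, 5))
  # beyond-endpoint points are excluded; s = 1 lands in the last bin
  pc2 <- point_cloud(rbind(c(2.4, 0, 0), c(2, 0, 0)))
  expect_equal(segment_profile(pc2, c(0, 0, 0), c(2, 0, 0), 5)$counts,
               c(0, 0, 0, 0, 1))
  expect_error(segment_profile(pc, c(0, 0, 0), c(2, 0, 0), 0), "n_bins")
  expect_error(segment_profile(pc, c(1, 1, 1), c(1, 1, 1), 3), "differ")
})

test_that("segment profiles match a brute-force projection histogram", {
  set.seed(11)
  P <- matrix(runif(3 * 500, -1, 2), ncol = 3)
  pc <- point_cloud(P)
  p1 <- c(0, 0, 0); p2 <- c(1, 1, 1)
  for (radius in list(NULL, 0.4)) {
    prof <- segment_profile(pc, p1, p2, 7, radius = radius)
    u <- (p2 - p1) / sqrt(3)
    brute <- integer(7)
    nin <- 0L
    for (i in seq_len(nrow(P))) {
      s <- sum((P[i, ] - p1) * u) / sqrt(3)
      perp <- sqrt(max(sum((P[i, ] - p1)^2) - (s * sqrt(3))^2, 0))
      if (s >= 0 && s <= 1 && (is.null(radius) || perp <= radius)) {
        b <- min(floor(s * 7) + 1, 7)
        brute[b] <- brute[b] + 1L
        nin <- nin + 1L
      }
    }
    expect_equal(prof$counts, brute)
    expect_equal(sum(prof$counts), nin)  # conservation
  }
})

test_that("selections are idempotent and rigid-motion invariant", {
  pc <- random_cloud(800, seed = 21)
  shapes <- list(sphere_shape(c(0.5, 0.5, 0.5), 0.35),
                 hull_shape(unit_tetrahedron() * 0.9 + 0.05))
  mo <- random_rigid_motion(seed = 4)
  for (shape in shapes) {
    idx <- select_points(pc, shape)
    sub <- subset_cloud(pc, idx)
    expect_equal(select_points(sub, shape), seq_along(idx))  # idempotent
    # move cloud and shape together
    pc_m <- point_cloud(mo$apply(pc$positions))
    shape_m <- if (shape$type == "sphere") {
      sphere_shape(mo$apply(rbind(shape$center))[1, ], shape$radius)
    } else {
      hull_shape(mo$apply(shape$landmarks))
    }
    expect_equal(select_points(pc_m, shape_m), idx)
  }
  # measurements are invariant too
  a <- c(0.1, 0.2, 0.3); b <- c(1, -1, 0.5); v <- c(0.4, 0.4, 0.4)
  am <- mo$apply(rbind(a))[1, ]; bm <- mo$apply(rbind(b))[1, ]
  vm <- mo$apply(rbind(v))[1, ]
  expect_equal(measure_distance(am, bm), measure_distance(a, b),
               tolerance = 1e-9)
  expect_equal(measure_angle(am, vm, bm), measure_angle(a, v, b),
               tolerance = 1e-9)
})

test_that("selection shapes serialize to JSON and back", {
  shapes <- list(sphere_shape(c(1, 2, 3), 0.5),
                 hull_shape(unit_tetrahedron()),
                 plane_shape(c(0, 0, 1), c(0, 1, 0), "-"),
                 threshold_shape("intensity", 10, 200))
  pc <- random_cloud(200, seed = 31)
  pc <- set_column(pc, "intensity", runif(200, 0, 300))
  for (s in shapes) {
    back <- shape_from_json(shape_to_json(s))
    expect_equal(back$type, s$type)
    expect_equal(select_points(pc, back), select_points(pc, s))
  }
})
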