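# Shared fixture builders. All fixtures are generated in code at test time.

random_cloud <- function(n, seed = 1, n_extra = 2, box = c(0, 1)) {
  set.seed(seed)
  cols <- if (n_extra > 0) {
    stats::setNames(lapply(seq_len(n_extra), function(i) rnorm(n)),
                    paste0("extra", seq_len(n_extra)))
  } else list()
  point_cloud(matrix(runif(3 * n, box[1], box[2]), ncol = 3),
              time = sort(runif(n, 0, 10)),
              columns = cols)
}

unit_tetrahedron <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# rigid motion: rotation about a random axis plus translation
random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tshift <- rnorm(3, sd = 5)
  list(R = R, t = tshift,
       apply = function(P) sweep(as.matrix(P) %*% t(R), 2, -tshift))
}

# simple brute-force MSD (O(N^2) double loop), independent oracle
msd_brute <- function(P, dt, max_lag) {
  n <- nrow(P)
  vals <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    acc <- 0
    for (i in seq_len(n - lag)) {
      acc <- acc + sum((P[i + lag, ] - P[i, ])^2)
    }
    vals[lag] <- acc / (n - lag)
  }
  vals
}

# barycentric point-in-tetrahedron test (independent of the hull code path)
in_tetrahedron <- function(p, tet, tol = 1e-9) {
  A <- cbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ], tet[4, ] - tet[1, ])
  if (abs(det(A)) < 1e-14) return(FALSE)
  lam <- solve(A, p - tet[1, ])
  all(lam >= -tol) && sum(lam) <= 1 + tol
}
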