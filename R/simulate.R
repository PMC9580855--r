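# Synthetic-data generators emulating the experimental inputs the toolkit
# targets: nanoparticles diffusing in a nucleus-like closed volume tracked
# at video rate (overdamped-Langevin walks, optionally heterogeneous in D
# and subject to harmonic trapping forces), fractional Brownian motion for
# anomalous-exponent validation, and blinking emitters for merge
# validation. Defaults follow the experimental regime the toolkit was
# designed around: 30 ms frame interval, D of order 0.1-1 um^2/s for 50 nm
# particles in the nucleus, localization precision of a few tens of nm.
# All generators restore the caller's RNG state and draw from a stream
# derived from (seed, generator name), so results are reproducible and
# independent across generators.

# Euler-Maruyama stepper shared by the homogeneous and landscape walks so
# a single-region landscape is sample-path identical to simulate_brownian
# under the same seed.
sim_langevin_set <- function(n_trajectories, n_steps, dt, lookup, sigma,
                             box, origin, kT) {
  reflect <- function(x) {
    if (is.null(box)) return(x)
    for (ax in 1:3) {
      lo <- box[1, ax]; hi <- box[2, ax]
      while (x[ax] < lo || x[ax] > hi) {
        if (x[ax] < lo) x[ax] <- 2 * lo - x[ax]
        if (x[ax] > hi) x[ax] <- 2 * hi - x[ax]
      }
    }
    x
  }
  trajs <- vector("list", n_trajectories)
  labels <- vector("list", n_trajectories)
  for (tr in seq_len(n_trajectories)) {
    start <- if (is.null(box)) origin else {
      stats::runif(3, box[1, ], box[2, ])
    }
    P <- matrix(0, n_steps + 1, 3)
    lab <- integer(n_steps + 1)
    P[1, ] <- start
    loc <- lookup(start)
    lab[1] <- loc$region
    for (s in seq_len(n_steps)) {
      drift <- loc$v + loc$D * loc$F / kT
      step <- drift * dt + sqrt(2 * loc$D * dt) * stats::rnorm(3)
      P[s + 1, ] <- reflect(P[s, ] + step)
      loc <- lookup(P[s + 1, ])
      lab[s + 1] <- loc$region
    }
    if (sigma > 0) {
      P <- P + matrix(stats::rnorm(3 * (n_steps + 1), sd = sigma),
                      n_steps + 1, 3)
    }
    tt <- (0:n_steps) * dt
    trajs[[tr]] <- list(id = tr, positions = P, times = tt,
                        dr = P[-1, , drop = FALSE] - P[-(n_steps + 1), , drop = FALSE],
                        dt = diff(tt))
    labels[[tr]] <- lab
  }
  list(trajectories = structure(trajs, class = "trajectory_set"),
       labels = unlist(labels, use.names = FALSE))
}

#' Simulate Brownian trajectories with optional drift and noise
#'
#' Overdamped-Langevin walks: per step
#' `dr = v dt + sqrt(2 D dt) eta` with `eta` standard 3D Gaussian,
#' reflecting boundaries at the box walls, and static localization error
#' added to the recorded positions afterwards (so observed translocations
#' carry the noise difference the estimators correct for).
#'
#' @param n_trajectories number of trajectories.
#' @param n_steps steps per trajectory.
#' @param dt frame interval, seconds (default 0.03 s, video-rate 3D
#'   tracking).
#' @param D diffusion coefficient, um^2/s.
#' @param v constant drift velocity, um/s (3-vector).
#' @param sigma localization precision, um.
#' @param box optional `2 x 3` matrix `rbind(lower, upper)`; when given,
#'   trajectories start uniformly inside it and reflect at its walls.
#' @param origin common start position when no box is given.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a `trajectory_set`.
#' @export
simulate_brownian <- function(n_trajectories = 100, n_steps = 100, dt = 0.03,
                              D = 0.5, v = c(0, 0, 0), sigma = 0,
                              box = NULL, origin = c(0, 0, 0), seed = 1) {
  stopifnot(dt > 0, D >= 0, sigma >= 0)
  v <- as_vec3(v)
  lookup <- function(p) list(D = D, v = v, F = c(0, 0, 0), region = 1L)
  local_seed(derive_seed(seed, "langevin"),
             sim_langevin_set(n_trajectories, n_steps, dt, lookup, sigma,
                              box, as_vec3(origin), kT = 1))$trajectories
}

#' Define a region of a diffusivity/force landscape
#'
#' @param xlim,ylim,zlim closed coordinate bounds of the axis-aligned
#'   region.
#' @param D diffusion coefficient inside the region, um^2/s.
#' @param well_center,well_k optional harmonic well: force
#'   `F = -well_k (r - well_center)` (units kT/um per um), contributing
#'   drift `D F / kT`.
#' @return a `landscape_region` list.
#' @export
landscape_region <- function(xlim, ylim, zlim, D, well_center = NULL,
                             well_k = 0) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2, D >= 0)
  structure(list(xlim = sort(xlim), ylim = sort(ylim), zlim = sort(zlim),
                 D = D,
                 well_center = if (is.null(well_center)) NULL
                               else as_vec3(well_center),
                 well_k = well_k),
            class = "landscape_region")
}

#' Simulate trajectories on a heterogeneous diffusivity/force landscape
#'
#' Each Euler-Maruyama step uses the diffusivity and force of the region
#' containing the current position (first matching region wins on shared
#' boundaries); the walk reflects at the landscape bounding box. Returns
#' the ground-truth region id of every recorded point for recovery tests.
#' A single-region landscape is sample-path identical to
#' [simulate_brownian()] with the same seed and box.
#'
#' @param regions list of [landscape_region()]s; together they must cover
#'   the bounding box (an uncovered position raises an error).
#' @param n_trajectories,n_steps,dt,sigma,seed as in [simulate_brownian()].
#' @param kT thermal energy scale used to convert force to drift
#'   (default 1, so well stiffness is in kT/um^2).
#' @return list with `trajectories` (a `trajectory_set`) and `labels`
#'   (true region id per point, in trajectory-then-time order, matching
#'   [trajectories_to_cloud()]).
#' @export
simulate_landscape <- function(regions, n_trajectories = 100, n_steps = 100,
                               dt = 0.03, sigma = 0, seed = 1, kT = 1) {
  stopifnot(length(regions) >= 1)
  lims <- sapply(regions, function(r) c(r$xlim, r$ylim, r$zlim))
  box <- rbind(c(min(lims[1, ]), min(lims[3, ]), min(lims[5, ])),
               c(max(lims[2, ]), max(lims[4, ]), max(lims[6, ])))
  lookup <- function(p) {
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      if (p[1] >= r$xlim[1] && p[1] <= r$xlim[2] &&
          p[2] >= r$ylim[1] && p[2] <= r$ylim[2] &&
          p[3] >= r$zlim[1] && p[3] <= r$zlim[2]) {
        F <- if (is.null(r$well_center)) c(0, 0, 0)
             else -r$well_k * (p - r$well_center)
        return(list(D = r$D, v = c(0, 0, 0), F = F, region = i))
      }
    }
    stop(sprintf("position (%g, %g, %g) not covered by any region",
                 p[1], p[2], p[3]))
  }
  local_seed(derive_seed(seed, "langevin"),
             sim_langevin_set(n_trajectories, n_steps, dt, lookup, sigma,
                              box, c(0, 0, 0), kT))
}

#' Simulate fractional Brownian motion trajectories
#'
#' Exact fBm per axis (independent axes, isotropic anomalous motion) via
#' Cholesky factorization of the increment covariance
#' `cov(dB_i, dB_j) = (scale^2/2) dt^alpha (|k+1|^a - 2|k|^a + |k-1|^a)`,
#' `k = i - j`, so the ensemble MSD grows as `tau^alpha`. `alpha = 1`
#' reduces to Brownian motion with `2 D dt = scale^2 dt` per axis.
#'
#' @param alpha anomalous exponent in `(0, 2]` (Hurst `H = alpha / 2`).
#' @param n_trajectories number of trajectories (one Cholesky factor is
#'   reused for all of them).
#' @param n_steps steps per trajectory (`<= 5000`; the covariance is dense).
#' @param dt frame interval, seconds.
#' @param scale increment scale: per-axis step standard deviation is
#'   `scale * dt^(alpha/2)`.
#' @param seed integer seed.
#' @return a `trajectory_set`.
#' @export
simulate_fbm <- function(alpha, n_trajectories = 1, n_steps = 500, dt = 1,
                         scale = 1, seed = 1) {
  if (alpha <= 0 || alpha > 2) stop("alpha must be in (0, 2]")
  if (n_steps > 5000) stop("n_steps > 5000: dense covariance too large")
  k <- 0:(n_steps - 1)
  gam <- scale^2 / 2 * dt^alpha *
    (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
  C <- stats::toeplitz(gam)
  U <- tryCatch(chol(C), error = function(e) {
    chol(C + diag(1e-10 * gam[1], n_steps))  # jitter-and-retry
  })
  local_seed(derive_seed(seed, "fbm"), {
    trajs <- vector("list", n_trajectories)
    for (tr in seq_len(n_trajectories)) {
      Z <- matrix(stats::rnorm(3 * n_steps), n_steps, 3)
      inc <- crossprod(U, Z)     # t(U) %*% Z has covariance C per axis
      P <- rbind(c(0, 0, 0), apply(inc, 2, cumsum))
      tt <- (0:n_steps) * dt
      trajs[[tr]] <- list(id = tr, positions = P, times = tt,
                          dr = inc, dt = diff(tt))
    }
    structure(trajs, class = "trajectory_set")
  })
}

#' Simulate blinking emitters
#'
#' Each molecule follows a per-frame two-state on/off Markov chain with an
#' absorbing bleached state: an "on" molecule emits one localization (true
#' position plus isotropic Gaussian noise of standard deviation `sigma`),
#' then bleaches with probability `p_bleach`, otherwise switches off with
#' probability `p_off`; an "off" molecule switches on with probability
#' `p_on`. Localizations are stamped with the frame index.
#'
#' @param molecules `M x 3` matrix of true molecule positions.
#' @param p_on,p_off,p_bleach per-frame transition probabilities in
#'   `[0, 1]`.
#' @param n_frames number of frames.
#' @param sigma localization precision, um.
#' @param start_on if `TRUE` (default) all molecules start in the on
#'   state, else off.
#' @param seed integer seed.
#' @return a [point_cloud] whose time is the frame index (metadata `dt`
#'   unset) with columns `frame` and `molecule` (ground-truth id).
#' @export
simulate_blinking <- function(molecules, p_on = 0.1, p_off = 0.5,
                              p_bleach = 0.05, n_frames = 100, sigma = 0.01,
                              start_on = TRUE, seed = 1) {
  molecules <- as.matrix(molecules)
  stopifnot(ncol(molecules) == 3,
            all(c(p_on, p_off, p_bleach) >= 0),
            all(c(p_on, p_off, p_bleach) <= 1),
            p_off + p_bleach <= 1, sigma >= 0)
  M <- nrow(molecules)
  local_seed(derive_seed(seed, "blinking"), {
    state <- rep(if (start_on) 1L else 0L, M)  # 0 off, 1 on, 2 bleached
    mol <- integer(0); frame <- integer(0)
    for (f in seq_len(n_frames)) {
      on <- which(state == 1L)
      mol <- c(mol, on)
      frame <- c(frame, rep(f, length(on)))
      u <- stats::runif(M)
      nxt <- state
      nxt[state == 1L & u < p_bleach] <- 2L
      nxt[state == 1L & u >= p_bleach & u < p_bleach + p_off] <- 0L
      nxt[state == 0L & u < p_on] <- 1L
      state <- nxt
    }
    pos <- molecules[mol, , drop = FALSE]
    if (length(mol) && sigma > 0) {
      pos <- pos + matrix(stats::rnorm(3 * length(mol), sd = sigma),
                          length(mol), 3)
    }
    point_cloud(pos, time = as.numeric(frame),
                columns = list(frame = as.numeric(frame),
                               molecule = as.numeric(mol)),
                metadata = list(sigma = sigma,
                                provenance = "simulate_blinking"))
  })
}
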