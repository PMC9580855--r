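# Per-trajectory diffusion analysis: time-averaged MSD curves, apparent
# diffusion coefficient from the short-lag MSD slope, anomalous exponent
# from the log-log slope, and the Gaussian translocation maximum-likelihood
# estimator of (D, v) with static localization-noise correction.

#' Time-averaged mean squared displacement of a trajectory
#'
#' `MSD(n dt) = mean_i || r_(i+n) - r_i ||^2` over all overlapping pairs,
#' for lags `n = 1..max_lag`. Requires a uniform frame interval (relative
#' tolerance 1e-6): time averaging mixes lags otherwise.
#'
#' @param trajectory one element of a `trajectory_set` (a list with
#'   `positions` and `times`), or a bare `N x 3` position matrix (then
#'   `dt = 1`).
#' @param max_lag largest lag in frames; must be `< N`. Defaults to `N - 1`.
#' @return object of class `msd_curve`: `lags` (seconds), `values`
#'   (length^2), `counts` (averaging pairs per lag), `dt`.
#' @export
msd <- function(trajectory, max_lag = NULL) {
  if (is.matrix(trajectory)) {
    trajectory <- list(positions = trajectory,
                       times = seq_len(nrow(trajectory)) - 1)
  }
  P <- trajectory$positions
  n <- nrow(P)
  if (n < 2) stop("trajectory must have at least 2 points")
  dts <- diff(trajectory$times)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop("time-averaged MSD requires a uniform frame interval")
  }
  max_lag <- max_lag %||% (n - 1L)
  if (max_lag >= n) stop("max_lag must be smaller than the trajectory length")
  if (max_lag < 1) stop("max_lag must be >= 1")
  vals <- numeric(max_lag)
  cnts <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    d <- P[(1 + lag):n, , drop = FALSE] - P[1:(n - lag), , drop = FALSE]
    vals[lag] <- mean(rowSums(d^2))
    cnts[lag] <- n - lag
  }
  structure(list(lags = seq_len(max_lag) * dt, values = vals, counts = cnts,
                 dt = dt),
            class = "msd_curve")
}

#' Ensemble-averaged MSD over a trajectory set
#'
#' Pools the per-pair squared displacements of every trajectory at each
#' lag (weighting each pair equally).
#'
#' @param trajectories a `trajectory_set`.
#' @param max_lag largest lag in frames.
#' @return an `msd_curve`.
#' @export
msd_ensemble <- function(trajectories, max_lag) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  curves <- lapply(trajectories, function(tr) {
    if (nrow(tr$positions) > max_lag) msd(tr, max_lag) else NULL
  })
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) == 0L) stop("no trajectory long enough for max_lag")
  dt <- curves[[1]]$dt
  vals <- numeric(max_lag); cnts <- integer(max_lag)
  for (cu in curves) {
    vals <- vals + cu$values * cu$counts
    cnts <- cnts + cu$counts
  }
  structure(list(lags = seq_len(max_lag) * dt, values = vals / cnts,
                 counts = cnts, dt = dt),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, dt = %g s\n", length(x$lags), x$dt))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "") {
  graphics::plot(x$lags, x$values, xlab = "lag time (s)",
                 ylab = expression(MSD ~ (mu * m^2)), log = log, ...)
}

#' Apparent diffusion coefficient from the short-lag MSD slope
#'
#' Ordinary least squares of `MSD(tau) = 2 d D tau + b` over the first
#' `n_fit` lags. The intercept `b` absorbs the static localization error
#' (`b = 2 d sigma^2` for precision `sigma`). A negative slope is clamped
#' to `D = 0` and flagged.
#'
#' @param curve an [msd()] curve.
#' @param n_fit number of leading lags to fit (>= 2; default 4, standard
#'   short-lag practice).
#' @param d spatial dimension (1, 2 or 3).
#' @return object of class `diffusion_fit` with `D` (length^2/s), `b`
#'   (length^2), `d`, `n_fit`, `clamped`.
#' @export
fit_diffusion <- function(curve, n_fit = 4, d = 3) {
  stopifnot(inherits(curve, "msd_curve"), d %in% 1:3)
  n_fit <- min(n_fit, length(curve$lags))
  if (n_fit < 2) stop("n_fit must be >= 2 (and the curve long enough)")
  tau <- curve$lags[seq_len(n_fit)]
  y <- curve$values[seq_len(n_fit)]
  fit <- stats::lm.fit(cbind(1, tau), y)
  slope <- fit$coefficients[2]
  b <- fit$coefficients[1]
  D <- slope / (2 * d)
  clamped <- FALSE
  if (D < 0) { D <- 0; clamped <- TRUE }
  structure(list(D = unname(D), b = unname(b), alpha = NA_real_, K = NA_real_,
                 d = d, n_fit = n_fit, lag_range = range(tau),
                 clamped = clamped),
            class = "diffusion_fit")
}

#' Anomalous diffusion exponent from the log-log MSD slope
#'
#' Fits `log MSD = alpha log tau + log(2 d K)` by least squares over the
#' chosen lags: `alpha < 1` indicates sub-diffusion, `alpha = 1` Brownian
#' motion. All fitted MSD values must be positive.
#'
#' @param curve an [msd()] curve.
#' @param lags integer indices of the lags to fit (default: the first
#'   `min(10, length)` lags).
#' @param d spatial dimension.
#' @return a `diffusion_fit` with `alpha` and the generalized coefficient
#'   `K` (length^2 / s^alpha); `D` is `NA`.
#' @export
fit_alpha <- function(curve, lags = NULL, d = 3) {
  stopifnot(inherits(curve, "msd_curve"))
  lags <- lags %||% seq_len(min(10L, length(curve$lags)))
  if (length(lags) < 2) stop("need at least 2 lags to fit alpha")
  tau <- curve$lags[lags]
  y <- curve$values[lags]
  if (any(y <= 0)) stop("MSD must be positive over the fitted lag range")
  fit <- stats::lm.fit(cbind(1, log(tau)), log(y))
  alpha <- unname(fit$coefficients[2])
  K <- exp(unname(fit$coefficients[1])) / (2 * d)
  structure(list(D = NA_real_, b = NA_real_, alpha = alpha, K = K,
                 d = d, n_fit = length(lags), lag_range = range(tau),
                 clamped = FALSE),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  if (!is.na(x$alpha)) {
    cat(sprintf("<diffusion_fit> alpha = %.4g, K = %.4g (d = %d, %d lags)\n",
                x$alpha, x$K, x$d, x$n_fit))
  } else {
    cat(sprintf("<diffusion_fit> D = %.4g um^2/s, b = %.4g um^2 (d = %d, %d lags)%s\n",
                x$D, x$b, x$d, x$n_fit,
                if (x$clamped) " [clamped at 0]" else ""))
  }
  invisible(x)
}

# log-likelihood of translocations under Gaussian steps with drift v,
# diffusivity D and static localization variance sigma^2 per coordinate:
# each coordinate of dr_i ~ N(v dt_i, 2 (D + sigma^2/dt_i) dt_i)
loglik_translocations <- function(D, dr, dt, sigma, d, v = NULL) {
  s2 <- (D + sigma^2 / dt) * dt          # per-axis variance / 2
  if (is.null(v)) {
    w <- 1 / s2
    v <- colSums(dr * (w * dt)) / sum(w * dt^2)
  }
  resid2 <- rowSums((dr - outer(dt, v))^2)
  list(logL = sum(-resid2 / (4 * s2) - (d / 2) * log(4 * pi * s2)), v = v)
}

#' Maximum-likelihood diffusion and drift from translocations
#'
#' Models each translocation `dr_i` over `dt_i` as Gaussian with mean
#' `v dt_i` and per-coordinate variance `2 (D + sigma^2/dt_i) dt_i`, i.e.
#' free diffusion plus drift plus static localization error, and maximizes
#' the joint likelihood in `(D, v)`. With `sigma = 0` the maximum is the
#' closed form `v = sum(dr) / sum(dt)`,
#' `D = sum(|dr_i - v dt_i|^2 / dt_i) / (2 d n)`; with `sigma > 0` the
#' drift is profiled out by a precision-weighted mean and the likelihood
#' maximized over `D` on `[0, D_max]`. With a flat prior on `(D, v)` this
#' maximum is also the posterior mode used in regional diffusivity mapping.
#'
#' @param dr `n x d` matrix of translocation vectors (length units).
#' @param dt translocation intervals, seconds (scalar or length `n`, all
#'   `> 0`).
#' @param sigma static localization precision (length units, >= 0).
#' @param d spatial dimension (default 3; must match `ncol(dr)`).
#' @param D_max upper bound for the numeric search; defaults to 10x the
#'   sigma-naive closed-form estimate (plus `sigma^2/min(dt)` headroom).
#' @param method `"auto"` (closed form when `sigma = 0`, numeric
#'   otherwise), `"closed_form"`, or `"numeric"`.
#' @return object of class `diffusion_mle`: `D`, `v`, `logL`, `n`, `sigma`,
#'   `d`, `status` in `ok | boundary | degenerate`.
#' @examples
#' dr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 0))
#' mle_diffusion_drift(dr, dt = 1)  # v = 0, D = 1/6
#' @export
mle_diffusion_drift <- function(dr, dt, sigma = 0, d = ncol(dr),
                                D_max = NULL,
                                method = c("auto", "closed_form", "numeric")) {
  method <- match.arg(method)
  dr <- as.matrix(dr)
  n <- nrow(dr)
  if (n < 2) stop("need at least 2 translocations")
  if (ncol(dr) != d) stop("ncol(dr) must equal d")
  if (length(dt) == 1L) dt <- rep(dt, n)
  if (length(dt) != n || any(dt <= 0)) stop("dt must be > 0, one per translocation")
  if (sigma < 0) stop("sigma must be >= 0")

  v_cf <- colSums(dr) / sum(dt)
  D_cf <- sum(rowSums((dr - outer(dt, v_cf))^2) / dt) / (2 * d * n)

  if (method == "closed_form" || (method == "auto" && sigma == 0)) {
    if (sigma > 0) stop("closed form only valid for sigma = 0")
    status <- if (D_cf <= 0) "degenerate" else "ok"
    ll <- if (D_cf > 0) loglik_translocations(D_cf, dr, dt, 0, d, v_cf)$logL
          else -Inf
    return(structure(list(D = max(D_cf, 0), v = v_cf, logL = ll, n = n,
                          sigma = sigma, d = d, status = status),
                     class = "diffusion_mle"))
  }

  D_max <- D_max %||% max(10 * D_cf + sigma^2 / min(dt), 1e-6)
  # profile-likelihood gradient in D (v profiled out; by the envelope
  # theorem d v(D)/dD contributes nothing at v = v(D)):
  #   g(D) = sum_i dt_i [ resid2_i / (4 s2_i^2) - (d/2) / s2_i ],
  # with s2_i = (D + sigma^2/dt_i) dt_i. The root of g is the MLE; the
  # likelihood is maximized at the D = 0 boundary when g(0) <= 0.
  grad <- function(D) {
    s2 <- (D + sigma^2 / dt) * dt
    v <- loglik_translocations(D, dr, dt, sigma, d)$v
    resid2 <- rowSums((dr - outer(dt, v))^2)
    sum(dt * (resid2 / (4 * s2^2) - (d / 2) / s2))
  }
  status <- "ok"
  if (sigma == 0) {
    # g is singular at D = 0; the closed form is the root for sigma = 0
    # but keep the numeric path honest by root-finding on [tiny, D_max]
    lo <- 1e-12 * max(D_max, 1)
  } else {
    lo <- 0
  }
  g_lo <- grad(max(lo, 1e-300))
  if (!is.finite(g_lo) || g_lo <= 0) {
    D_hat <- 0
    status <- if (sigma > 0) "boundary" else "degenerate"
  } else {
    hi <- D_max
    while (grad(hi) > 0 && hi < 1e6) hi <- hi * 2
    D_hat <- stats::uniroot(grad, c(max(lo, 1e-300), hi),
                            tol = 1e-13 * max(1, hi))$root
    if (D_hat <= 1e-10 * max(1, D_max)) status <- "boundary"
  }
  fin <- loglik_translocations(D_hat, dr, dt, sigma, d)
  structure(list(D = D_hat, v = fin$v, logL = fin$logL, n = n,
                 sigma = sigma, d = d, status = status),
            class = "diffusion_mle")
}

#' @export
print.diffusion_mle <- function(x, ...) {
  cat(sprintf(
    "<diffusion_mle> D = %.4g um^2/s, |v| = %.4g um/s (n = %d, sigma = %g, %s)\n",
    x$D, vnorm(x$v), x$n, x$sigma, x$status))
  invisible(x)
}
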