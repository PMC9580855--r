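# Camera fly-through paths: timed waypoints parsed from a JSON script and
# interpolated into a uniform pose sequence for any external renderer.
# The waypoint file grammar of the original VR tool is unpublished; this
# JSON schema (a "waypoints" array plus optional global fps) is an explicit
# re-specification of the same data, not a reverse-engineering claim.

#' Construct a camera waypoint
#'
#' @param position camera position (3-vector).
#' @param look_at point the camera faces (3-vector, distinct from
#'   `position`).
#' @param dwell_s time held at this waypoint, seconds (>= 0, default 0).
#' @param transit_s time to travel to the next waypoint, seconds (> 0;
#'   may be `NA` on the final waypoint).
#' @param visual optional named list of visual parameters carried along
#'   (colormap name, thresholds, ...).
#' @return object of class `waypoint`.
#' @export
waypoint <- function(position, look_at, dwell_s = 0, transit_s = NA_real_,
                     visual = NULL) {
  position <- as_vec3(position)
  look_at <- as_vec3(look_at)
  if (vnorm(look_at - position) < 1e-12) {
    stop("look_at must differ from position")
  }
  if (!is.finite(dwell_s) || dwell_s < 0) stop("dwell_s must be >= 0")
  if (!is.na(transit_s) && transit_s <= 0) stop("transit_s must be > 0")
  structure(list(position = position, look_at = look_at,
                 dwell_s = dwell_s, transit_s = transit_s, visual = visual),
            class = "waypoint")
}

#' Parse a waypoint script
#'
#' Reads a JSON file `{"fps": ..., "waypoints": [{"position": [x,y,z],
#' "look_at": [x,y,z], "dwell_s": ..., "transit_s": ..., "visual": {...}},
#' ...]}`. `dwell_s` defaults to 0 when omitted; `transit_s` is required
#' (and must be positive) on every waypoint except the last. Schema
#' violations are reported with the waypoint index and field.
#'
#' @param path JSON file path.
#' @return list of [waypoint()]s, with the file-level `fps` attached as
#'   attribute `"fps"` when present.
#' @export
parse_waypoints <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  wps <- x$waypoints %||% x
  if (length(wps) == 0L) stop("no waypoints in file")
  n <- length(wps)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- wps[[i]]
    fail <- function(field, why) {
      stop(sprintf("waypoint %d, field '%s': %s", i, field, why),
           call. = FALSE)
    }
    if (is.null(w$position) || length(w$position) != 3L) {
      fail("position", "must be a 3-vector")
    }
    if (is.null(w$look_at) || length(w$look_at) != 3L) {
      fail("look_at", "must be a 3-vector")
    }
    transit <- w$transit_s %||% NA_real_
    if (i < n) {
      if (is.na(transit)) fail("transit_s", "required before the last waypoint")
      if (transit <= 0) fail("transit_s", "must be > 0")
    }
    out[[i]] <- tryCatch(
      waypoint(unlist(w$position), unlist(w$look_at),
               dwell_s = w$dwell_s %||% 0, transit_s = transit,
               visual = w$visual),
      error = function(e) fail("(validation)", conditionMessage(e)))
  }
  if (!is.null(x$fps)) attr(out, "fps") <- x$fps
  out
}

#' Write a waypoint script
#' @param waypoints list of [waypoint()]s.
#' @param path output JSON path.
#' @param fps optional global frame rate stored in the file.
#' @return `path`, invisibly.
#' @export
write_waypoints <- function(waypoints, path, fps = NULL) {
  body <- list(waypoints = lapply(waypoints, function(w) {
    x <- unclass(w)
    if (is.na(x$transit_s)) x$transit_s <- NULL
    if (is.null(x$visual)) x$visual <- NULL
    x
  }))
  if (!is.null(fps)) body <- c(list(fps = fps), body)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# orientation quaternion (qw, qx, qy, qz) for a camera at `pos` facing
# `target`, world up = +z with +y fallback when the view is axial
look_quaternion <- function(pos, target) {
  f <- target - pos
  f <- f / vnorm(f)
  up <- c(0, 0, 1)
  r <- cross3(f, up)
  if (vnorm(r) < 1e-9) {
    up <- c(0, 1, 0)
    r <- cross3(f, up)
  }
  r <- r / vnorm(r)
  u <- cross3(r, f)
  R <- cbind(r, u, f)  # camera axes: right, up, forward (columns)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / vnorm(q)
}

# Catmull-Rom with reflected endpoint phantoms (p0 = 2 p1 - p2 at the
# start, symmetric at the end), so collinear evenly spaced waypoints
# reproduce linear interpolation exactly; segment-local parameter
catmull_rom <- function(P, seg, s) {
  n <- nrow(P)
  p1 <- P[seg, ]
  p2 <- P[seg + 1, ]
  p0 <- if (seg > 1) P[seg - 1, ] else 2 * p1 - p2
  p3 <- if (seg + 2 <= n) P[seg + 2, ] else 2 * p2 - p1
  0.5 * ((2 * p1) + (-p0 + p2) * s +
         (2 * p0 - 5 * p1 + 4 * p2 - p3) * s^2 +
         (-p0 + 3 * p1 - 3 * p2 + p3) * s^3)
}

#' Interpolate a camera pose sequence through timed waypoints
#'
#' The timeline is: dwell at waypoint 1, transit to waypoint 2, dwell
#' there, and so on; total duration is the sum of all dwells plus all
#' transits. Frames are placed at `t = (j - 1) / fps` with the final frame
#' snapped to the total duration, so the frame count is exactly
#' `round(duration * fps)` and the first and last poses coincide with the
#' first and last waypoints. Positions (and look-at targets) interpolate
#' linearly or by Catmull-Rom spline (with duplicated endpoint phantom
#' points) across transits and are held fixed during dwells; orientation
#' is the look-at quaternion with a fixed +z up vector (+y fallback for
#' axial views).
#'
#' @param waypoints list of at least 2 [waypoint()]s.
#' @param fps frames per second (> 0).
#' @param mode `"linear"` or `"catmull_rom"`.
#' @return object of class `pose_sequence`: a data.frame with columns
#'   `t, x, y, z, qw, qx, qy, qz`, with `fps` and `duration` attributes.
#' @export
interpolate_path <- function(waypoints, fps, mode = c("linear", "catmull_rom")) {
  mode <- match.arg(mode)
  n <- length(waypoints)
  if (n < 2) stop("need at least 2 waypoints")
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0")
  for (i in seq_len(n - 1)) {
    if (is.na(waypoints[[i]]$transit_s)) {
      stop(sprintf("waypoint %d needs transit_s", i))
    }
  }
  pos <- t(vapply(waypoints, `[[`, numeric(3), "position"))
  tgt <- t(vapply(waypoints, `[[`, numeric(3), "look_at"))
  dwell <- vapply(waypoints, `[[`, numeric(1), "dwell_s")
  transit <- vapply(waypoints[-n], `[[`, numeric(1), "transit_s")
  # piecewise timeline: (dwell_1, transit_1, dwell_2, ..., dwell_n)
  seg_len <- c(rbind(dwell[-n], transit), dwell[n])
  seg_end <- cumsum(seg_len)
  duration <- seg_end[length(seg_end)]
  n_frames <- max(2L, as.integer(round(duration * fps)))
  tf <- (seq_len(n_frames) - 1) / fps
  tf[n_frames] <- duration
  eval_at <- function(t) {
    si <- findInterval(t, seg_end, left.open = TRUE) + 1L
    si <- min(si, length(seg_len))
    wp <- (si + 1L) %/% 2L          # odd segments dwell at waypoint wp
    if (si %% 2L == 1L) {
      p <- pos[wp, ]; g <- tgt[wp, ]
    } else {
      t0 <- seg_end[si] - seg_len[si]
      s <- if (seg_len[si] > 0) (t - t0) / seg_len[si] else 1
      s <- max(0, min(1, s))
      if (mode == "linear") {
        p <- pos[wp, ] + s * (pos[wp + 1, ] - pos[wp, ])
        g <- tgt[wp, ] + s * (tgt[wp + 1, ] - tgt[wp, ])
      } else {
        p <- catmull_rom(pos, wp, s)
        g <- catmull_rom(tgt, wp, s)
      }
    }
    if (vnorm(g - p) < 1e-12) g <- g + c(0, 0, 1e-6)  # degenerate guard
    c(p, look_quaternion(p, g))
  }
  out <- t(vapply(tf, eval_at, numeric(7)))
  df <- data.frame(t = tf, x = out[, 1], y = out[, 2], z = out[, 3],
                   qw = out[, 4], qx = out[, 5], qy = out[, 6],
                   qz = out[, 7])
  structure(df, fps = fps, duration = duration,
            class = c("pose_sequence", "data.frame"))
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames at %g fps (%.3g s)\n",
              nrow(x), attr(x, "fps"), attr(x, "duration")))
  invisible(x)
}

#' Write a pose sequence as CSV
#'
#' Columns `t, x, y, z, qw, qx, qy, qz`, consumable by any renderer.
#' @param poses a [interpolate_path()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(poses, path) {
  utils::write.csv(as.data.frame(poses), path, row.names = FALSE)
  invisible(path)
}
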