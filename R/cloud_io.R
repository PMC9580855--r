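#' Construct a localization point cloud
#'
#' A point cloud holds `N` localizations: 3D positions (micrometres by
#' default), a time stamp per point (seconds, or a frame index with the
#' frame interval recorded in `metadata$dt`), and any number of named
#' auxiliary columns (intensity, trajectory id, computed properties).
#'
#' @param positions numeric `N x 3` matrix (or coercible) of x, y, z.
#' @param time numeric vector of length `N`; defaults to `0:(N-1) * dt`.
#' @param columns named list of numeric vectors, each of length `N`.
#' @param metadata list; recognised entries: `unit` (default `"um"`),
#'   `dt` frame interval in seconds, `sigma` localization precision in
#'   length units, `provenance` free text.
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' npoints(pc)
#' @export
point_cloud <- function(positions, time = NULL, columns = list(),
                        metadata = list()) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), ncol = 3)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns")
  n <- nrow(positions)
  if (any(!is.finite(positions))) stop("positions must be finite")
  colnames(positions) <- c("x", "y", "z")
  metadata$unit <- metadata$unit %||% "um"
  metadata$sigma <- metadata$sigma %||% 0
  if (!is.null(metadata$dt) && !is.na(metadata$dt) && metadata$dt <= 0) {
    stop("metadata$dt must be > 0")
  }
  if (metadata$sigma < 0) stop("metadata$sigma must be >= 0")
  if (is.null(time)) {
    dt <- metadata$dt %||% 1
    if (is.na(dt)) dt <- 1
    time <- if (n > 0) (seq_len(n) - 1) * dt else numeric(0)
  }
  time <- as.numeric(time)
  if (length(time) != n) stop("'time' must have one entry per point")
  if (!is.list(columns)) stop("'columns' must be a named list")
  if (length(columns) > 0 &&
      (is.null(names(columns)) || any(names(columns) == ""))) {
    stop("every extra column must be named")
  }
  for (nm in names(columns)) {
    columns[[nm]] <- as.numeric(columns[[nm]])
    if (length(columns[[nm]]) != n) {
      stop(sprintf("column '%s' has %d entries, expected %d",
                   nm, length(columns[[nm]]), n))
    }
  }
  structure(list(positions = positions, time = time, columns = columns,
                 metadata = metadata),
            class = "point_cloud")
}

#' Number of localizations in a point cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
npoints <- function(cloud) nrow(cloud$positions)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d localizations (%s)\n", npoints(x),
              x$metadata$unit %||% "um"))
  if (length(x$columns)) {
    cat("  columns:", paste(names(x$columns), collapse = ", "), "\n")
  }
  if (!is.null(x$metadata$dt)) cat(sprintf("  dt: %g s\n", x$metadata$dt))
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  df <- data.frame(x$positions, t = x$time)
  for (nm in names(x$columns)) df[[nm]] <- x$columns[[nm]]
  df
}

#' Add or replace a named column on a point cloud
#' @param cloud a `point_cloud`.
#' @param name column name.
#' @param values numeric vector of length `npoints(cloud)`.
#' @return the modified `point_cloud`.
#' @export
set_column <- function(cloud, name, values) {
  stopifnot(inherits(cloud, "point_cloud"))
  values <- as.numeric(values)
  if (length(values) != npoints(cloud)) {
    stop("column length must match number of points")
  }
  cloud$columns[[name]] <- values
  cloud
}

#' Take a subset of a point cloud by index
#' @param cloud a `point_cloud`.
#' @param idx integer indices to keep.
#' @return a `point_cloud` with the selected rows (all columns subset).
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$positions[idx, , drop = FALSE],
              time = cloud$time[idx],
              columns = lapply(cloud$columns, `[`, idx),
              metadata = cloud$metadata)
}

detect_delimiter <- function(line) {
  cands <- c("\t", ",", ";", " ")
  counts <- vapply(cands, function(d) {
    length(strsplit(line, if (d == " ") "[[:blank:]]+" else d,
                    fixed = FALSE)[[1]])
  }, integer(1))
  cands[which.max(counts)]
}

split_fields <- function(lines, delimiter) {
  if (delimiter == " ") {
    strsplit(trimws(lines), "[[:blank:]]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }
}

#' Read a localization table from delimited text
#'
#' Reads any row-organized text table regardless of separator (tab, comma,
#' semicolon or whitespace are auto-detected) and regardless of whether a
#' header row is present: the first row is treated as a header if and only
#' if any of its fields fails numeric parsing. Lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param delimiter optional separator character; auto-detected when `NULL`.
#' @param column_map named integer vector mapping column roles to 1-based
#'   column indices; must assign at least `x`, `y`, `z`. Entries named `t`
#'   (or `time`) feed the time stamp; any other named entry becomes an
#'   auxiliary column. When `NULL` and a header with x/y/z names is present
#'   the map is derived from the header, otherwise columns 1:3 are x,y,z
#'   and remaining columns keep their header names (or `V4`, `V5`, ...).
#' @param dt frame interval in seconds, used to synthesize time stamps when
#'   no time column exists (defaults to 1) and stored in metadata.
#' @param sigma localization precision (length units), stored in metadata.
#' @param scale multiplicative factor applied to coordinates at read time
#'   (e.g. `1e-3` converts nm tables to the default micrometre unit).
#' @param skip_malformed if `TRUE`, rows whose field count differs from the
#'   first data row are dropped with a warning instead of raising an error.
#' @return a [point_cloud].
#' @export
read_point_cloud <- function(path, delimiter = NULL, column_map = NULL,
                             dt = NULL, sigma = NULL, scale = 1,
                             skip_malformed = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:blank:]]*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(point_cloud(matrix(numeric(0), ncol = 3),
                       metadata = list(dt = dt, sigma = sigma %||% 0,
                                       provenance = path)))
  }
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1]])
  fields <- split_fields(lines, delimiter)

  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- anyNA(first)
  header <- NULL
  if (has_header) {
    header <- fields[[1]]
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  n <- length(fields)
  if (n == 0L) {
    cl <- point_cloud(matrix(numeric(0), ncol = 3),
                      metadata = list(dt = dt, sigma = sigma %||% 0,
                                      provenance = path))
    return(cl)
  }
  width <- length(fields[[1]])
  counts <- lengths(fields)
  if (any(counts != width)) {
    bad <- which(counts != width)
    if (skip_malformed) {
      warning(sprintf("dropped %d malformed row(s)", length(bad)))
      fields <- fields[-bad]
      line_no <- line_no[-bad]
      n <- length(fields)
    } else {
      stop(sprintf(
        "row at line %d has %d fields, expected %d",
        line_no[bad[1]], counts[bad[1]], width))
    }
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields, use.names = FALSE))),
                nrow = n, ncol = width, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)
    if (skip_malformed) {
      warning(sprintf("dropped %d non-numeric row(s)", length(bad)))
      mat <- mat[-bad, , drop = FALSE]
      n <- nrow(mat)
    } else {
      stop(sprintf("non-numeric field at line %d", line_no[bad[1]]))
    }
  }

  if (is.null(column_map)) {
    if (!is.null(header) && all(c("x", "y", "z") %in% tolower(header))) {
      column_map <- seq_along(header)
      names(column_map) <- tolower(header)
    } else {
      if (width < 3) stop("table has fewer than 3 columns; cannot map x,y,z")
      column_map <- c(x = 1L, y = 2L, z = 3L)
      extra <- setdiff(seq_len(width), 1:3)
      if (length(extra)) {
        nms <- if (!is.null(header)) header[extra] else paste0("V", extra)
        column_map <- c(column_map, stats::setNames(extra, nms))
      }
    }
  }
  if (!all(c("x", "y", "z") %in% names(column_map))) {
    stop("column_map must assign at least x, y and z")
  }
  if (any(column_map > width)) {
    stop(sprintf("column_map index %d exceeds table width %d",
                 max(column_map), width))
  }
  pos <- mat[, column_map[c("x", "y", "z")], drop = FALSE] * scale
  tname <- intersect(c("t", "time"), names(column_map))
  time <- if (length(tname)) mat[, column_map[[tname[1]]]] else NULL
  extras <- setdiff(names(column_map), c("x", "y", "z", "t", "time"))
  cols <- stats::setNames(
    lapply(extras, function(nm) mat[, column_map[[nm]]]), extras)
  point_cloud(pos, time = time, columns = cols,
              metadata = list(dt = dt, sigma = sigma %||% 0,
                              provenance = path))
}

#' Write a point cloud as delimited text
#'
#' Emits a `#` provenance comment line, a header row (`x,y,z,t,` then the
#' auxiliary column names) and one full-precision row per localization, so
#' that [read_point_cloud()] reproduces positions, times and columns to
#' better than 1e-9 relative.
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @param delimiter separator (default comma).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, delimiter = ",") {
  stopifnot(inherits(cloud, "point_cloud"))
  nms <- c("x", "y", "z", "t", names(cloud$columns))
  body <- cbind(cloud$positions, cloud$time)
  for (nm in names(cloud$columns)) body <- cbind(body, cloud$columns[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# smlmkit point cloud, %d localizations, unit=%s",
                     npoints(cloud), cloud$metadata$unit %||% "um"), con)
  writeLines(paste(nms, collapse = delimiter), con)
  if (nrow(body) > 0) {
    rows <- apply(matrix(fmt_num(body), nrow = nrow(body)), 1,
                  paste, collapse = delimiter)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Group a point cloud into time-ordered trajectories
#'
#' One trajectory per distinct value of `id_column`, with points sorted by
#' time; per-step translocations (displacement `dr` over interval `dt`) are
#' precomputed. Rows with `NA` id are dropped. Singleton trajectories are
#' kept and carry zero translocations.
#'
#' @param cloud a [point_cloud] with a trajectory-id column.
#' @param id_column name of the id column (default `"id"`).
#' @return an object of class `trajectory_set`: a list with one element per
#'   trajectory, each holding `id`, `positions`, `times`, `dr` (steps x 3)
#'   and `dt`.
#' @export
build_trajectories <- function(cloud, id_column = "id") {
  stopifnot(inherits(cloud, "point_cloud"))
  ids <- cloud$columns[[id_column]]
  if (is.null(ids)) stop(sprintf("no column '%s' in cloud", id_column))
  keep <- which(!is.na(ids))
  trajs <- lapply(split(keep, ids[keep]), function(idx) {
    tt <- cloud$time[idx]
    o <- order(tt)
    idx <- idx[o]; tt <- tt[o]
    if (anyDuplicated(tt)) {
      stop(sprintf("trajectory %s has duplicate time stamps (ambiguous order)",
                   ids[idx[1]]))
    }
    p <- cloud$positions[idx, , drop = FALSE]
    np <- length(idx)
    list(id = ids[idx[1]],
         positions = p,
         times = tt,
         dr = if (np > 1) p[-1, , drop = FALSE] - p[-np, , drop = FALSE]
              else matrix(numeric(0), ncol = 3),
         dt = if (np > 1) diff(tt) else numeric(0))
  })
  structure(unname(trajs), class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  np <- vapply(x, function(tr) nrow(tr$positions), integer(1))
  cat(sprintf("<trajectory_set> %d trajectories, %d localizations, %d translocations\n",
              length(x), sum(np), sum(pmax(np - 1L, 0L))))
  invisible(x)
}

#' Pool translocations from a trajectory set
#'
#' @param trajectories a `trajectory_set`.
#' @return list with `dr` (n x 3 matrix), `dt` (length n), and `traj`
#'   (originating trajectory index per translocation).
#' @export
translocations <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  dr <- do.call(rbind, lapply(trajectories, `[[`, "dr"))
  if (is.null(dr)) dr <- matrix(numeric(0), ncol = 3)
  dt <- unlist(lapply(trajectories, `[[`, "dt"), use.names = FALSE)
  traj <- rep(seq_along(trajectories),
              vapply(trajectories, function(tr) length(tr$dt), integer(1)))
  list(dr = dr, dt = dt %||% numeric(0), traj = traj)
}

#' Flatten a trajectory set back into a point cloud
#'
#' @param trajectories a `trajectory_set`.
#' @param metadata metadata list passed to [point_cloud()].
#' @return a [point_cloud] with an `id` column.
#' @export
trajectories_to_cloud <- function(trajectories, metadata = list()) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  pos <- do.call(rbind, lapply(trajectories, `[[`, "positions"))
  if (is.null(pos)) pos <- matrix(numeric(0), ncol = 3)
  point_cloud(
    pos,
    time = unlist(lapply(trajectories, `[[`, "times"), use.names = FALSE),
    columns = list(id = rep(
      vapply(trajectories, function(tr) as.numeric(tr$id), numeric(1)),
      vapply(trajectories, function(tr) nrow(tr$positions), integer(1)))),
    metadata = metadata)
}

#' Create an analysis record
#'
#' Analysis runs are persisted as JSON records holding the tool name, the
#' fully resolved parameters (including seeds, sufficient to reproduce the
#' run) and the outputs.
#'
#' @param tool tool name string.
#' @param parameters named list of parameters.
#' @param outputs named list of scalar or array outputs.
#' @param created timestamp string; defaults to the current UTC time.
#' @return an object of class `analysis_record`.
#' @export
analysis_record <- function(tool, parameters = list(), outputs = list(),
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")) {
  stopifnot(is.character(tool), length(tool) == 1L)
  structure(list(tool = tool, parameters = parameters, outputs = outputs,
                 created = created),
            class = "analysis_record")
}

#' Save an analysis record as JSON
#' @param record an [analysis_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_record <- function(record, path) {
  stopifnot(inherits(record, "analysis_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis record from JSON
#' @param path JSON file written by [save_record()].
#' @return an `analysis_record`.
#' @export
read_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_record(x$tool, as.list(x$parameters), as.list(x$outputs),
                  created = x$created)
}

#' @export
print.analysis_record <- function(x, ...) {
  cat(sprintf("<analysis_record> tool=%s created=%s\n", x$tool, x$created))
  if (length(x$parameters)) {
    cat("  parameters:", paste(names(x$parameters), collapse = ", "), "\n")
  }
  invisible(x)
}
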