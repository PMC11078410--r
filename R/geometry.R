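# Operational volume geometry and measurement-stream segmentation.

EARTH_RADIUS_M <- 6371000

#' Define an operational volume
#'
#' The operational volume is a rectangular cuboid anchored at a geodetic
#' origin, rotated in the horizontal plane, and discretised into a shared
#' 3D grid.  All vehicles in a fleet plan and exchange data against the same
#' volume definition, so the grid dimensions are part of the wire protocol:
#' the total cell count must fit a 16-bit cell number and be at least 256.
#'
#' @param origin_lat,origin_lon Geodetic origin of the volume, decimal degrees.
#' @param theta Orientation of the volume x-axis, degrees counter-clockwise
#'   from east.
#' @param extent Numeric length-3: extents `(V_x, V_y, V_z)` in meters;
#'   `V_z` is the maximum depth (z is positive downward, 0 at the surface).
#' @param grid_dims Integer length-3: grid cell counts `(n_x, n_y, n_z)`.
#' @return An object of class `volume_config`.
#' @examples
#' cfg <- volume_config(78.955, 11.9475, -45, c(1500, 1500, 50), c(15, 15, 10))
#' n_cells(cfg)
#' @export
volume_config <- function(origin_lat, origin_lon, theta, extent, grid_dims) {
  stopifnot(length(extent) == 3, length(grid_dims) == 3)
  extent <- as.numeric(extent)
  grid_dims <- as.integer(grid_dims)
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("all volume extents must be positive and finite")
  if (any(grid_dims < 1L))
    stop("grid dimensions must each be >= 1")
  ncell <- prod(grid_dims)
  if (ncell < 256 || ncell > 65536)
    stop("total cell count n_x*n_y*n_z must lie in [256, 65536] ",
         "(cell numbers are 16-bit on the wire); got ", ncell)
  if (abs(origin_lat) > 90 || abs(origin_lon) > 360)
    stop("origin coordinates are not valid geodetic values")
  structure(
    list(origin_lat = as.numeric(origin_lat),
         origin_lon = as.numeric(origin_lon),
         theta = as.numeric(theta),
         extent = extent,
         grid_dims = grid_dims),
    class = "volume_config")
}

#' @export
print.volume_config <- function(x, ...) {
  cat(sprintf("Operational volume %.0f x %.0f x %.0f m, grid %d x %d x %d (%d cells)\n",
              x$extent[1], x$extent[2], x$extent[3],
              x$grid_dims[1], x$grid_dims[2], x$grid_dims[3], n_cells(x)))
  cat(sprintf("  origin (%.5f, %.5f), x-axis %.1f deg CCW from east\n",
              x$origin_lat, x$origin_lon, x$theta))
  invisible(x)
}

#' Total number of grid cells in a volume
#' @param cfg A `volume_config`.
#' @return Integer cell count `n_x * n_y * n_z`.
#' @export
n_cells <- function(cfg) prod(cfg$grid_dims)

#' Per-axis cell extents in meters
#' @param cfg A `volume_config`.
#' @return Numeric length-3 `(V_x/n_x, V_y/n_y, V_z/n_z)`.
#' @export
cell_size <- function(cfg) cfg$extent / cfg$grid_dims

#' Convert geodetic coordinates to the local volume frame
#'
#' Uses a flat-earth local tangent projection about the volume origin
#' (operational areas are at most a few kilometers, so projection error is
#' far below a cell extent), then rotates into the volume frame whose x-axis
#' points `theta` degrees counter-clockwise from east.  Depth is passed
#' through unchanged (positive down).
#'
#' Out-of-volume positions are returned as-is; use [in_volume()] to screen.
#'
#' @param lat,lon Vectors of decimal degrees.
#' @param cfg A `volume_config`.
#' @param depth Depth in meters (positive down), recycled; default 0.
#' @return A data.frame with columns `x`, `y`, `z` (meters).
#' @export
latlon_to_local <- function(lat, lon, cfg, depth = 0) {
  rad <- pi / 180
  de <- (lon - cfg$origin_lon) * cos(cfg$origin_lat * rad) * EARTH_RADIUS_M * rad
  dn <- (lat - cfg$origin_lat) * EARTH_RADIUS_M * rad
  th <- cfg$theta * rad
  data.frame(x = cos(th) * de + sin(th) * dn,
             y = -sin(th) * de + cos(th) * dn,
             z = rep_len(as.numeric(depth), length(de)))
}

#' Convert local volume-frame coordinates back to geodetic
#'
#' Inverse of [latlon_to_local()]; round trips recover the inputs to well
#' under 1e-6 degrees over operational-scale volumes.
#'
#' @param x,y Local coordinates in meters.
#' @param cfg A `volume_config`.
#' @return A data.frame with columns `lat`, `lon` (degrees).
#' @export
local_to_latlon <- function(x, y, cfg) {
  rad <- pi / 180
  th <- cfg$theta * rad
  de <- cos(th) * x - sin(th) * y
  dn <- sin(th) * x + cos(th) * y
  data.frame(lat = cfg$origin_lat + dn / (EARTH_RADIUS_M * rad),
             lon = cfg$origin_lon + de / (EARTH_RADIUS_M * rad * cos(cfg$origin_lat * rad)))
}

#' Test whether local positions lie inside the operational volume
#' @param x,y,z Local coordinates (meters; z positive down).
#' @param cfg A `volume_config`.
#' @return Logical vector.
#' @export
in_volume <- function(x, y, z, cfg) {
  x >= 0 & x <= cfg$extent[1] &
  y >= 0 & y <= cfg$extent[2] &
  z >= 0 & z <= cfg$extent[3]
}

#' Map local positions to linear cell indices
#'
#' Cells are half-open `[lo, hi)` boxes except the last cell along each axis,
#' which is closed so that the far volume face maps to a valid cell.  The
#' linear index runs x-fastest: `id = ix + n_x * (iy + n_y * iz)`, 0-based.
#' The ordering is shared by every agent and is part of the message format.
#'
#' @param x,y,z Local coordinates (meters).
#' @param cfg A `volume_config`.
#' @return Integer cell ids in `[0, n_cells(cfg) - 1]`; `NA` for positions
#'   outside the volume.
#' @export
cell_index <- function(x, y, z, cfg) {
  cs <- cell_size(cfg)
  nd <- cfg$grid_dims
  ix <- pmin(floor(x / cs[1]), nd[1] - 1)
  iy <- pmin(floor(y / cs[2]), nd[2] - 1)
  iz <- pmin(floor(z / cs[3]), nd[3] - 1)
  id <- as.integer(ix + nd[1] * (iy + nd[2] * iz))
  id[!in_volume(x, y, z, cfg)] <- NA_integer_
  id
}

#' Coordinates of cell centers
#' @param id Integer cell ids (0-based); defaults to all cells.
#' @param cfg A `volume_config`.
#' @return A data.frame with columns `cell`, `x`, `y`, `z`.
#' @export
cell_center <- function(cfg, id = seq_len(n_cells(cfg)) - 1L) {
  if (any(id < 0 | id >= n_cells(cfg))) stop("cell id out of range")
  nd <- cfg$grid_dims
  cs <- cell_size(cfg)
  ix <- id %% nd[1]
  iy <- (id %/% nd[1]) %% nd[2]
  iz <- id %/% (nd[1] * nd[2])
  data.frame(cell = as.integer(id),
             x = (ix + 0.5) * cs[1],
             y = (iy + 0.5) * cs[2],
             z = (iz + 0.5) * cs[3])
}

#' Create an empty grid state
#'
#' A grid state holds, for each cell of the shared grid, the mean channel
#' values and mean acquisition time of the most recent batch of measurements
#' segmented into that cell, or nothing if the cell has never been visited.
#'
#' @param cfg A `volume_config`.
#' @param n_channels Number of sensor channels carried per cell.
#' @return An object of class `grid_state`.
#' @export
grid_state <- function(cfg, n_channels = 1L) {
  nc <- n_cells(cfg)
  structure(
    list(cfg = cfg,
         n_channels = as.integer(n_channels),
         value = matrix(NA_real_, nrow = nc, ncol = n_channels),
         time = rep(NA_real_, nc),
         count = rep(0L, nc),
         dropped = 0L),
    class = "grid_state")
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("grid_state: %d / %d cells occupied, %d channel(s), %d dropped\n",
              sum(!is.na(x$time)), n_cells(x$cfg), x$n_channels, x$dropped))
  invisible(x)
}

#' Segment a batch of measurements into the shared grid
#'
#' Each measurement is assigned to its grid cell.  A cell receiving one or
#' more new measurements takes the arithmetic mean of the *new* measurements
#' only; any value it previously held is discarded (temporal de-correlation
#' makes stale data irrelevant next to fresh data from the same place).
#' Cells receiving no new measurements keep their data intact.  The cell
#' timestamp is the mean acquisition time of the contributing batch.
#'
#' Out-of-volume measurements (routine under field GPS jitter) are dropped
#' and counted in `state$dropped`, with a warning.
#'
#' @param measurements A data.frame with columns `x`, `y`, `z`, `time` and
#'   one column per channel (all remaining numeric columns, in order).
#' @param state A `grid_state` to update.
#' @return The updated `grid_state`.
#' @export
segment_measurements <- function(measurements, state) {
  cfg <- state$cfg
  chan_cols <- setdiff(names(measurements), c("x", "y", "z", "time", "cell"))
  if (length(chan_cols) != state$n_channels)
    stop("measurement batch has ", length(chan_cols),
         " channel column(s) but grid expects ", state$n_channels)
  if (nrow(measurements) == 0) return(state)
  id <- cell_index(measurements$x, measurements$y, measurements$z, cfg)
  out <- is.na(id)
  if (any(out)) {
    warning(sum(out), " out-of-volume measurement(s) dropped")
    state$dropped <- state$dropped + sum(out)
    measurements <- measurements[!out, , drop = FALSE]
    id <- id[!out]
  }
  if (length(id) == 0) return(state)
  idx1 <- id + 1L  # 1-based row into the cell tables
  for (j in seq_along(chan_cols)) {
    m <- tapply(measurements[[chan_cols[j]]], idx1, mean)
    state$value[as.integer(names(m)), j] <- as.numeric(m)
  }
  tm <- tapply(measurements$time, idx1, mean)
  state$time[as.integer(names(tm))] <- as.numeric(tm)
  cnt <- table(idx1)
  state$count[as.integer(names(cnt))] <- as.integer(cnt)
  state
}

#' Extract occupied cells as a data.frame
#'
#' @param state A `grid_state`.
#' @return A data.frame with columns `cell`, `x`, `y`, `z` (cell centers),
#'   `time`, and one column per channel (`chan1`, ...).
#' @export
grid_cells <- function(state) {
  occ <- which(!is.na(state$time))
  ctr <- cell_center(state$cfg, occ - 1L)
  vals <- state$value[occ, , drop = FALSE]
  colnames(vals) <- paste0("chan", seq_len(ncol(vals)))
  cbind(ctr, time = state$time[occ], as.data.frame(vals))
}

#' Read a measurement log CSV into the local frame
#'
#' Field logs arrive as CSV with site-specific column names; the mapping
#' from the package's canonical fields to the file's columns is supplied by
#' the user.
#'
#' @param path CSV file path.
#' @param cfg A `volume_config` used for the geodetic-to-local conversion.
#' @param mapping Named list with entries `time`, `lat`, `lon`, `depth`, and
#'   `channels` (character vector of channel column names, channel 1 being
#'   chlorophyll fluorescence).
#' @return A measurement data.frame (`x`, `y`, `z`, `time`, channels).
#' @export
read_measurements <- function(path, cfg,
                              mapping = list(time = "time", lat = "lat",
                                             lon = "lon", depth = "depth",
                                             channels = "chl")) {
  raw <- utils::read.csv(path)
  need <- c(mapping$time, mapping$lat, mapping$lon, mapping$depth, mapping$channels)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("measurement CSV lacks mapped column(s): ", paste(missing, collapse = ", "))
  loc <- latlon_to_local(raw[[mapping$lat]], raw[[mapping$lon]], cfg,
                         depth = raw[[mapping$depth]])
  out <- data.frame(x = loc$x, y = loc$y, z = loc$z, time = raw[[mapping$time]])
  for (ch in mapping$channels) out[[ch]] <- raw[[ch]]
  out
}
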