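#' Gridded wind field
#'
#' Container for u/v/w wind components on a regular lon x lat x level x time
#' grid, the advecting medium for the particle model. Axes must be strictly
#' increasing and all values finite.
#'
#' @param lon,lat Axis values in degrees, strictly increasing.
#' @param level Heights above ground in metres, strictly increasing.
#' @param time `POSIXct` (UTC) instants, strictly increasing.
#' @param u,v,w Arrays of dimension `c(time, level, lat, lon)` in m/s. `w`
#'   defaults to zero everywhere.
#'
#' @return An object of class `wind_field`.
#' @export
wind_field <- function(lon, lat, level, time, u, v, w = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat); level <- as.numeric(level)
  if (!inherits(time, "POSIXct")) stopf("`time` must be POSIXct (UTC)")
  dims <- c(length(time), length(level), length(lat), length(lon))
  if (is.null(w)) w <- array(0, dims)
  for (ax in list(lon = lon, lat = lat, level = level,
                  time = as.numeric(time))) {
    if (length(ax) < 2 || any(diff(ax) <= 0)) {
      stopf("wind field axes must have length >= 2 and be strictly increasing")
    }
  }
  for (comp in list(u = u, v = v, w = w)) {
    if (!identical(dim(comp), as.integer(dims))) {
      stopf("wind component dimensions must be (time, level, lat, lon) = (%s)",
            paste(dims, collapse = ", "))
    }
    if (!all(is.finite(comp))) stopf("wind components must be finite")
  }
  structure(
    list(lon = lon, lat = lat, level = level, time = time,
         u = u, v = v, w = w),
    class = "wind_field"
  )
}

#' @export
print.wind_field <- function(x, ...) {
  cat(sprintf(
    "<wind_field> %d lon x %d lat x %d level x %d time\n  lon [%g, %g]  lat [%g, %g]  %s .. %s\n",
    length(x$lon), length(x$lat), length(x$level), length(x$time),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat),
    format(min(x$time), "%Y-%m-%d %H:%M", tz = "UTC"),
    format(max(x$time), "%Y-%m-%d %H:%M", tz = "UTC")))
  invisible(x)
}

# Per-axis interpolation bracket: index of the left node (clamped to the
# interior) and the weight of the right node. Queries beyond the axis ends
# are clamped onto the boundary value.
axis_bracket <- function(axis, q) {
  i <- findInterval(q, axis, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(axis) - 1L)
  wt <- (q - axis[i]) / (axis[i + 1L] - axis[i])
  wt <- pmin(pmax(wt, 0), 1)
  list(i = i, w = wt)
}

#' Interpolate wind at arbitrary points
#'
#' Multilinear interpolation of the u/v/w components in lon, lat, level and
#' time. Grid node queries reproduce the stored values exactly. Spatial and
#' vertical queries outside the axes are clamped onto the boundary; query
#' times more than one time step outside the time axis are an error.
#'
#' @param wf A [wind_field()].
#' @param lon,lat,z Numeric vectors of query coordinates (degrees, degrees,
#'   metres above ground). Recycled to a common length.
#' @param t Query time, `POSIXct` or numeric seconds since epoch; scalar or
#'   vector.
#'
#' @return A list with numeric vectors `u`, `v`, `w` (m/s).
#' @export
interpolate_wind <- function(wf, lon, lat, z, t) {
  stopifnot(inherits(wf, "wind_field"))
  tq <- as.numeric(t)
  ta <- as.numeric(wf$time)
  step <- max(diff(ta))
  bad <- tq < ta[1] - step | tq > ta[length(ta)] + step
  if (any(bad)) {
    stopf("query time %s outside the wind time axis by more than one step",
          format(as.POSIXct(tq[which(bad)[1]], origin = "1970-01-01",
                            tz = "UTC")))
  }
  n <- max(length(lon), length(lat), length(z), length(tq))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  z <- rep_len(z, n); tq <- rep_len(tq, n)

  bx <- axis_bracket(wf$lon, lon)
  by <- axis_bracket(wf$lat, lat)
  bz <- axis_bracket(wf$level, z)
  bt <- axis_bracket(ta, tq)

  nt <- length(wf$time); nl <- length(wf$level); ny <- length(wf$lat)
  # flat index into (time, level, lat, lon) arrays
  flat <- function(it, il, iy, ix) {
    it + nt * ((il - 1L) + nl * ((iy - 1L) + ny * (ix - 1L)))
  }
  comp <- function(arr) {
    out <- numeric(n)
    for (dt in 0:1) for (dl in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wgt <- (if (dt) bt$w else 1 - bt$w) * (if (dl) bz$w else 1 - bz$w) *
        (if (dy) by$w else 1 - by$w) * (if (dx) bx$w else 1 - bx$w)
      idx <- flat(bt$i + dt, bz$i + dl, by$i + dy, bx$i + dx)
      out <- out + wgt * arr[idx]
    }
    out
  }
  list(u = comp(wf$u), v = comp(wf$v), w = comp(wf$w))
}

#' Write / read a wind field as a plain-text table
#'
#' Serializes the grid as a long-format CSV (time, level, lat, lon, u, v, w;
#' time as seconds since epoch, UTC) next to a small JSON header recording
#' the axes, so a field round-trips exactly.
#'
#' @param wf A [wind_field()].
#' @param path CSV file path; the header is written to `<path>.json`.
#' @return `path`, invisibly (writer); a [wind_field()] (reader).
#' @export
write_wind_field <- function(wf, path) {
  stopifnot(inherits(wf, "wind_field"))
  grid <- expand.grid(time = as.numeric(wf$time), level = wf$level,
                      lat = wf$lat, lon = wf$lon, KEEP.OUT.ATTRS = FALSE)
  grid$u <- as.vector(wf$u); grid$v <- as.vector(wf$v); grid$w <- as.vector(wf$w)
  readr::write_csv(grid, path)
  hdr <- list(lon = wf$lon, lat = wf$lat, level = wf$level,
              time = as.numeric(wf$time))
  jsonlite::write_json(hdr, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_wind_field
#' @export
read_wind_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dims <- c(length(hdr$time), length(hdr$level), length(hdr$lat),
            length(hdr$lon))
  # expand.grid order in the writer means the table is already in array order
  wind_field(
    lon = hdr$lon, lat = hdr$lat, level = hdr$level,
    time = as.POSIXct(hdr$time, origin = "1970-01-01", tz = "UTC"),
    u = array(tab$u, dims), v = array(tab$v, dims), w = array(tab$w, dims)
  )
}
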