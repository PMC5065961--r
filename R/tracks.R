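#' Read and write bird tracks (Movebank-style CSV)
#'
#' Tracks are tibbles with columns `bird_id`, `group` ("ION" for intact
#' olfaction, "ONS" for olfactory-nerve-sectioned), `time` (`POSIXct`,
#' UTC), `lon`, `lat` (degrees) and `interpolated` (logical). On disk the
#' Movebank-style header names are used: `individual-local-identifier`,
#' `timestamp` (ISO-8601 UTC), `location-long`, `location-lat`, `group`.
#' Rows are validated (coordinate ranges, parseable timestamps), sorted by
#' time, and duplicate timestamps are collapsed to the first occurrence
#' with a warning.
#'
#' @param path CSV file path.
#' @param track A track tibble (writer).
#' @return A track tibble (reader); `path`, invisibly (writer).
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stopf("track file '%s' does not exist", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("individual-local-identifier", "timestamp", "location-long",
            "location-lat")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stopf("track file '%s' is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  time <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(time)) {
    stopf("unparseable timestamp in row %d of '%s'", which(is.na(time))[1], path)
  }
  lon <- suppressWarnings(as.numeric(raw$`location-long`))
  lat <- suppressWarnings(as.numeric(raw$`location-lat`))
  bad <- which(is.na(lon) | is.na(lat) | lon < -180 | lon >= 180 |
                 lat < -90 | lat > 90)
  if (length(bad)) {
    stopf("invalid coordinates in row %d of '%s'", bad[1], path)
  }
  out <- tibble::tibble(
    bird_id = raw$`individual-local-identifier`,
    group = raw$group %||% NA_character_,
    time = time, lon = lon, lat = lat, interpolated = FALSE
  )
  out <- dplyr::arrange(out, .data$time)
  dup <- duplicated(out$time)
  if (any(dup)) {
    warnf("collapsed %d duplicate timestamp(s) in '%s'", sum(dup), path)
    out <- out[!dup, ]
  }
  out
}

#' @rdname read_track
#' @export
write_track <- function(track, path) {
  readr::write_csv(tibble::tibble(
    `individual-local-identifier` = track$bird_id,
    timestamp = format(track$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    `location-long` = track$lon,
    `location-lat` = track$lat,
    group = track$group
  ), path)
  invisible(path)
}

#' Interpolate a track to hourly positions
#'
#' Inserts a position at every whole hour between consecutive observations,
#' linearly interpolated independently in longitude and latitude (straight
#' lines in coordinate space), keeping every original point exactly.
#' Inserted points are flagged `interpolated = TRUE`. Multi-bird tibbles
#' are handled per bird.
#'
#' @param track A track tibble with at least 2 points per bird.
#' @return The densified track tibble.
#' @export
interpolate_hourly <- function(track) {
  one <- function(tr) {
    if (nrow(tr) < 2) stopf("cannot interpolate a track with < 2 points")
    ts <- as.numeric(tr$time)
    hours <- seq(ceiling(ts[1] / 3600), floor(ts[length(ts)] / 3600)) * 3600
    hours <- setdiff(hours, ts)
    if (length(hours)) {
      extra <- tibble::tibble(
        bird_id = tr$bird_id[1], group = tr$group[1],
        time = as.POSIXct(hours, origin = "1970-01-01", tz = "UTC"),
        lon = stats::approx(ts, tr$lon, xout = hours)$y,
        lat = stats::approx(ts, tr$lat, xout = hours)$y,
        interpolated = TRUE
      )
      tr <- dplyr::arrange(dplyr::bind_rows(tr, extra), .data$time)
    }
    tr
  }
  dplyr::group_modify(dplyr::group_by(track, .data$bird_id),
                      ~ dplyr::select(one(dplyr::mutate(.x, bird_id = .y$bird_id)),
                                      -"bird_id")) |>
    dplyr::ungroup() |>
    dplyr::relocate("bird_id")
}

#' Great-circle distance and initial bearing
#'
#' Haversine distance on the 6371 km sphere, and the initial great-circle
#' bearing in degrees clockwise from North in \[0, 360). `gc_bearing()`
#' errors for coincident points (the bearing is undefined there).
#'
#' @param a,b Positions as `c(lon, lat)` vectors or two-column matrices.
#' @return Metres (`gc_distance`) or degrees (`gc_bearing`).
#' @export
gc_distance <- function(a, b) {
  geosphere::distHaversine(a, b, r = EARTH_RADIUS_M)
}

#' @rdname gc_distance
#' @export
gc_bearing <- function(a, b) {
  am <- if (is.matrix(a)) a else matrix(a, ncol = 2)
  bm <- if (is.matrix(b)) b else matrix(b, ncol = 2)
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1) am <- am[rep(1, n), , drop = FALSE]
  if (nrow(bm) == 1) bm <- bm[rep(1, n), , drop = FALSE]
  same <- rowSums(abs(am - bm)) == 0
  if (any(same)) stopf("bearing is undefined for coincident points")
  wrap360(geosphere::bearing(am, bm))
}

#' Flag actively moving track points
#'
#' A point is active when the ground speed from it to the next point is at
#' least `v_min`; the last point inherits the preceding segment's flag.
#' Used to restrict plume sampling to positions the bird actively moved to.
#'
#' @param track A single-bird track tibble (>= 2 points).
#' @param v_min Speed threshold in m/s.
#' @return Logical vector, one flag per point.
#' @export
active_mask <- function(track, v_min = 2) {
  n <- nrow(track)
  if (n < 2) stopf("active_mask needs >= 2 points")
  p <- cbind(track$lon, track$lat)
  d <- gc_distance(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  dt <- diff(as.numeric(track$time))
  speed <- d / dt
  c(speed >= v_min, speed[n - 1] >= v_min)
}

#' Extract an along-path window around an anchor point
#'
#' Walks the track from the anchor accumulating great-circle segment
#' lengths until the cumulative along-path distance first reaches
#' `distance_m`. If the track ends first, the maximal available window is
#' returned with attribute `complete = FALSE`.
#'
#' @param track A single-bird track tibble.
#' @param anchor_index Row index of the anchor point.
#' @param distance_m Along-path distance in metres.
#' @param direction `"before"` or `"after"` the anchor.
#' @return The sub-track tibble (anchor included), attribute `complete`.
#' @export
path_window <- function(track, anchor_index, distance_m,
                        direction = c("before", "after")) {
  direction <- match.arg(direction)
  n <- nrow(track)
  if (anchor_index < 1 || anchor_index > n) stopf("anchor outside the track")
  if (distance_m <= 0) {
    out <- track[anchor_index, ]
    attr(out, "complete") <- TRUE
    return(out)
  }
  idx <- if (direction == "before") anchor_index:1 else anchor_index:n
  p <- cbind(track$lon[idx], track$lat[idx])
  if (length(idx) < 2) {
    out <- track[anchor_index, ]
    attr(out, "complete") <- FALSE
    return(out)
  }
  seg <- gc_distance(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  cum <- cumsum(seg)
  reach <- which(cum >= distance_m)
  if (length(reach)) {
    take <- idx[1:(reach[1] + 1)]
    complete <- TRUE
  } else {
    take <- idx
    complete <- FALSE
  }
  out <- track[sort(take), ]
  attr(out, "complete") <- complete
  out
}
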