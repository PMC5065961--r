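#' Synthetic study scenario specification
#'
#' Describes a complete synthetic displacement experiment: the spatial
#' domain, time span, smooth wind-field parameters, corridor and goal
#' polygons, and the number of agents per treatment group. All downstream
#' generators are deterministic functions of a spec and its seed.
#'
#' @param domain_bounds List with `lon = c(min, max)` and `lat = c(min,
#'   max)` in degrees; both extents must be positive.
#' @param time_span Length-2 `POSIXct` (UTC), start < end.
#' @param wind_params List with `mean_u`, `mean_v` (m/s), `amplitude` (m/s,
#'   perturbation), `wavelength` (degrees), `period` (hours) and `rotation`
#'   (degrees of wind-direction change per hour).
#' @param corridor,goal Polygons as two-column (lon, lat) matrices inside
#'   the domain.
#' @param n_birds_reactive,n_birds_nonreactive Agent counts per group
#'   (reactive = intact olfaction, ION; non-reactive = nerve-sectioned,
#'   ONS).
#' @param seed Integer seed governing every random draw derived from the
#'   spec.
#'
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(domain_bounds, time_span, wind_params,
                          corridor, goal,
                          n_birds_reactive = 10L, n_birds_nonreactive = 10L,
                          seed = 1L) {
  if (diff(domain_bounds$lon) <= 0 || diff(domain_bounds$lat) <= 0) {
    stopf("domain_bounds must have positive extent in both axes")
  }
  time_span <- as.POSIXct(time_span, tz = "UTC")
  if (length(time_span) != 2 || !(time_span[1] < time_span[2])) {
    stopf("time_span start must precede its end")
  }
  corridor <- as_polygon(corridor)
  goal <- as_polygon(goal)
  for (poly in list(corridor = corridor, goal = goal)) {
    if (any(poly[, 1] < domain_bounds$lon[1]) ||
        any(poly[, 1] > domain_bounds$lon[2]) ||
        any(poly[, 2] < domain_bounds$lat[1]) ||
        any(poly[, 2] > domain_bounds$lat[2])) {
      stopf("corridor and goal polygons must lie within domain_bounds")
    }
  }
  if (n_birds_reactive < 0 || n_birds_nonreactive < 0) {
    stopf("agent counts must be >= 0")
  }
  wp <- utils::modifyList(
    list(mean_u = 0, mean_v = 0, amplitude = 0, wavelength = 10,
         period = 24, rotation = 0),
    wind_params
  )
  structure(
    list(domain_bounds = domain_bounds, time_span = time_span,
         wind_params = wp, corridor = corridor, goal = goal,
         n_birds_reactive = as.integer(n_birds_reactive),
         n_birds_nonreactive = as.integer(n_birds_nonreactive),
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Agent flight behaviour
#'
#' The two experimental groups are modelled as agents that either turn
#' toward the plume-arrival bearing after corridor-plume exposure
#' (`reactive = TRUE`, the intact-olfaction group) or ignore exposure
#' entirely (the anosmic group).
#'
#' @param cruise_speed Air speed in m/s, > 0.
#' @param baseline_heading Initial heading, degrees clockwise from North in
#'   \[0, 360).
#' @param reactive Logical; does the agent respond to plume exposure?
#' @param turn_gain Fraction in \[0, 1\] of the remaining angular offset to
#'   the plume-arrival bearing removed per hourly step once exposed.
#' @param exposure_threshold Corridor mass fraction that triggers the
#'   reaction.
#'
#' @return An object of class `agent_behavior`.
#' @export
agent_behavior <- function(cruise_speed = 10, baseline_heading = 180,
                           reactive = TRUE, turn_gain = 0.8,
                           exposure_threshold = 0.05) {
  if (cruise_speed <= 0) stopf("cruise_speed must be > 0")
  if (baseline_heading < 0 || baseline_heading >= 360) {
    stopf("baseline_heading must be in [0, 360)")
  }
  if (turn_gain < 0 || turn_gain > 1) stopf("turn_gain must be in [0, 1]")
  structure(
    list(cruise_speed = cruise_speed, baseline_heading = baseline_heading,
         reactive = isTRUE(reactive), turn_gain = turn_gain,
         exposure_threshold = exposure_threshold),
    class = "agent_behavior"
  )
}

#' Generate a smooth synthetic wind field
#'
#' Builds a wind field over the scenario domain and time span as a constant
#' (optionally slowly rotating) mean flow plus a zero-mean travelling
#' sinusoidal perturbation with the scenario's spatial wavelength and
#' temporal period. Deterministic given the scenario seed (the
#' perturbation phases are
#' the only random draw); an amplitude of zero yields exactly constant
#' fields.
#'
#' @param spec A [scenario_spec()].
#' @param res Grid resolution in degrees.
#' @param levels Vertical axis in metres above ground (wind is constant in
#'   height by construction).
#' @param time_step_h Temporal resolution in hours.
#'
#' @return A [wind_field()].
#' @export
gen_wind_field <- function(spec, res = 0.5, levels = c(0, 5000),
                           time_step_h = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  wp <- spec$wind_params
  lon <- seq(spec$domain_bounds$lon[1], spec$domain_bounds$lon[2], by = res)
  lat <- seq(spec$domain_bounds$lat[1], spec$domain_bounds$lat[2], by = res)
  time <- seq(spec$time_span[1], spec$time_span[2], by = time_step_h * 3600)
  th <- as.numeric(time - time[1], units = "hours")
  nt <- length(time); nl <- length(levels)
  ny <- length(lat); nx <- length(lon)

  phases <- withr::with_seed(spec$seed, stats::runif(4, 0, 2 * pi))

  # mean flow, with the whole vector rotated clockwise at `rotation` deg/h
  a <- deg2rad(wp$rotation * th)
  mu <- wp$mean_u * cos(a) + wp$mean_v * sin(a)
  mv <- wp$mean_v * cos(a) - wp$mean_u * sin(a)

  make_comp <- function(mean_t, phase_lon, phase_lat) {
    # travelling wave in lon/time modulated in lat; zero spatial mean over
    # whole wavelengths
    s <- sin(outer(2 * pi * th / wp$period, 2 * pi * lon / wp$wavelength,
                   "+") + phase_lon)            # nt x nx
    c_lat <- cos(2 * pi * lat / wp$wavelength + phase_lat)  # ny
    pert <- aperm(outer(s, c_lat), c(1, 3, 2))  # nt x ny x nx
    a3 <- wp$amplitude * pert + mean_t          # recycles mean over time dim
    aperm(array(a3, c(nt, ny, nx, nl)), c(1, 4, 2, 3))
  }
  u <- make_comp(mu, phases[1], phases[2])
  v <- make_comp(mv, phases[3], phases[4])
  wind_field(lon, lat, levels, time, u, v)
}

#' Kinematic corridor-exposure oracle
#'
#' Cheap stand-in for the full dispersion model used while generating agent
#' tracks: traces a single pure-advection back-trajectory from a query
#' position with the local wind and reports the fraction of trajectory time
#' spent inside the corridor polygon plus the arrival bearing of the
#' sensed air: the bearing from the agent toward the trace position
#' `trail_m` back along the approach, the same last-stretch reading of
#' "where the wind came from" the analysis stage measures on particle
#' trajectories.
#'
#' @param wf A [wind_field()].
#' @param corridor Polygon matrix (lon, lat).
#' @param horizon_h Look-back horizon in hours.
#' @param dt Trace step in seconds.
#' @param trail_m Approach-trail length for the arrival bearing, metres.
#'
#' @return A function `f(lon, lat, time)` returning
#'   `list(fraction, bearing)`.
#' @export
kinematic_exposure_oracle <- function(wf, corridor, horizon_h = 10,
                                      dt = 1800, trail_m = 30000) {
  corridor <- as_polygon(corridor)
  n_steps <- ceiling(horizon_h * 3600 / dt)
  lon_rng <- range(wf$lon); lat_rng <- range(wf$lat)
  function(lon, lat, time) {
    tcur <- as.numeric(time)
    if (tcur - horizon_h * 3600 < as.numeric(wf$time[1])) {
      return(list(fraction = 0, bearing = NA_real_))
    }
    pts <- matrix(NA_real_, n_steps, 2)
    p <- c(lon, lat)
    for (k in seq_len(n_steps)) {
      wind <- interpolate_wind(wf, p[1], p[2], 15, tcur)
      p[1] <- p[1] - wind$u * dt / (M_PER_DEG * cos(deg2rad(p[2])))
      p[2] <- p[2] - wind$v * dt / M_PER_DEG
      tcur <- tcur - dt
      if (p[1] < lon_rng[1] || p[1] > lon_rng[2] ||
          p[2] < lat_rng[1] || p[2] > lat_rng[2]) break
      pts[k, ] <- p
    }
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) == 0) return(list(fraction = 0, bearing = NA_real_))
    inside <- poly_contains(corridor, pts[, 1], pts[, 2])
    frac <- sum(inside) / n_steps
    brg <- NA_real_
    if (any(inside)) {
      d <- gc_distance(pts, c(lon, lat))
      k <- which(d >= trail_m)[1]
      if (is.na(k)) k <- which.max(d)
      brg <- gc_bearing(c(lon, lat), pts[k, ])
    }
    list(fraction = frac, bearing = brg)
  }
}

#' Generate one behavioural agent track
#'
#' Flies an agent at its cruise speed on hourly great-circle steps from a
#' start position. A reactive agent, once the exposure oracle reports a
#' corridor mass fraction at or above its threshold, rotates its heading
#' toward the reported plume-arrival bearing by `turn_gain` of the
#' remaining offset per step (updating the target whenever the oracle fires
#' again); a non-reactive agent never alters its heading in response to
#' exposure. An agent entering `stop_region` lands and stays put (the
#' migration route has been rejoined); an agent leaving the domain ends its
#' track with the `left_domain` attribute set.
#'
#' @param spec A [scenario_spec()].
#' @param behavior An [agent_behavior()].
#' @param start List with `lon`, `lat` (degrees) and `time` (`POSIXct`).
#' @param exposure_oracle Optional `function(lon, lat, time)` returning
#'   `list(fraction, bearing)`; see [kinematic_exposure_oracle()].
#' @param n_steps Number of hourly steps; defaults to the whole remaining
#'   time span.
#' @param stop_region Optional polygon; agents inside it stop flying.
#'
#' @return A tibble with columns `time`, `lon`, `lat`, `heading`,
#'   `exposed`, `stopped`; attributes `left_domain` and `behavior`.
#' @export
gen_track <- function(spec, behavior, start, exposure_oracle = NULL,
                      n_steps = NULL, stop_region = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(behavior, "agent_behavior"))
  db <- spec$domain_bounds
  if (start$lon < db$lon[1] || start$lon > db$lon[2] ||
      start$lat < db$lat[1] || start$lat > db$lat[2]) {
    stopf("start position lies outside the scenario domain")
  }
  start_time <- as.POSIXct(start$time, tz = "UTC")
  if (is.null(n_steps)) {
    n_steps <- floor(as.numeric(spec$time_span[2] - start_time,
                                units = "hours"))
  }
  if (!is.null(stop_region)) stop_region <- as_polygon(stop_region)

  n <- n_steps + 1L
  lon <- lat <- heading <- numeric(n)
  exposed <- stopped <- logical(n)
  lon[1] <- start$lon; lat[1] <- start$lat
  heading[1] <- behavior$baseline_heading
  hd <- behavior$baseline_heading
  target <- NA_real_
  is_exposed <- FALSE
  is_stopped <- FALSE
  left_domain <- FALSE
  last <- n

  for (i in seq_len(n_steps)) {
    t_i <- start_time + (i - 1) * 3600
    if (!is_stopped) {
      if (behavior$reactive && !is.null(exposure_oracle)) {
        ex <- exposure_oracle(lon[i], lat[i], t_i)
        if (is.finite(ex$fraction) &&
            ex$fraction >= behavior$exposure_threshold &&
            is.finite(ex$bearing %||% NA_real_)) {
          is_exposed <- TRUE
          target <- ex$bearing
        }
      }
      if (is_exposed) hd <- wrap360(hd + behavior$turn_gain * ang_diff(target, hd))
      if (!is.null(stop_region) &&
          poly_contains(stop_region, lon[i], lat[i])) {
        is_stopped <- TRUE
      }
    }
    exposed[i] <- is_exposed
    stopped[i] <- is_stopped
    heading[i] <- hd
    if (is_stopped) {
      lon[i + 1] <- lon[i]; lat[i + 1] <- lat[i]
    } else {
      dest <- geosphere::destPoint(c(lon[i], lat[i]), hd,
                                   behavior$cruise_speed * 3600,
                                   r = EARTH_RADIUS_M)
      if (dest[1] < db$lon[1] || dest[1] > db$lon[2] ||
          dest[2] < db$lat[1] || dest[2] > db$lat[2]) {
        left_domain <- TRUE
        last <- i
        break
      }
      lon[i + 1] <- dest[1]; lat[i + 1] <- dest[2]
    }
  }
  if (last == n) {
    exposed[n] <- is_exposed; stopped[n] <- is_stopped; heading[n] <- hd
  }
  idx <- seq_len(last)
  out <- tibble::tibble(
    time = start_time + (idx - 1) * 3600,
    lon = lon[idx], lat = lat[idx], heading = heading[idx],
    exposed = exposed[idx], stopped = stopped[idx]
  )
  attr(out, "left_domain") <- left_domain
  attr(out, "behavior") <- behavior
  out
}

#' Generate a complete synthetic study
#'
#' Assembles the full synthetic experiment a single spec describes: the
#' wind field, the corridor and goal polygons, one track per agent (reactive
#' agents labelled as the intact-olfaction group "ION", non-reactive as the
#' anosmic group "ONS"), and a manifest recording the scenario and seed. If
#' `dir` is given everything is also written to disk (wind CSV + JSON
#' header, GeoJSON regions, one Movebank-style CSV per track,
#' `manifest.json`).
#'
#' @param spec A [scenario_spec()].
#' @param starts Optional tibble with one row per agent: `lon`, `lat`,
#'   `heading` and optionally `time`. Defaults to seeded uniform draws in
#'   the northern strip of the domain with the behaviours' baseline
#'   headings.
#' @param behavior_reactive,behavior_nonreactive [agent_behavior()] objects
#'   for the two groups.
#' @param track_hours Track length in hourly steps.
#' @param oracle_horizon_h Look-back horizon of the kinematic exposure
#'   oracle.
#' @param stop_on_corridor Should agents land on entering the corridor?
#' @param wind_res,wind_levels Passed to [gen_wind_field()].
#' @param dir Optional output directory.
#'
#' @return A list of class `plume_scenario` with elements `wind`,
#'   `corridor`, `goal`, `tracks` (one long tibble), `groups`, `manifest`
#'   and `spec`.
#' @export
gen_scenario <- function(spec, starts = NULL,
                         behavior_reactive = agent_behavior(reactive = TRUE),
                         behavior_nonreactive = agent_behavior(reactive = FALSE),
                         track_hours = NULL, oracle_horizon_h = 10,
                         stop_on_corridor = TRUE,
                         wind_res = 0.5, wind_levels = c(0, 5000),
                         dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_r <- spec$n_birds_reactive; n_n <- spec$n_birds_nonreactive
  n_all <- n_r + n_n
  wf <- gen_wind_field(spec, res = wind_res, levels = wind_levels)
  oracle <- kinematic_exposure_oracle(wf, spec$corridor,
                                      horizon_h = oracle_horizon_h)
  if (is.null(starts)) {
    db <- spec$domain_bounds
    starts <- withr::with_seed(derive_seed(spec$seed, 17L), tibble::tibble(
      lon = stats::runif(n_all, db$lon[1] + 0.25 * diff(db$lon),
                         db$lon[2] - 0.25 * diff(db$lon)),
      lat = stats::runif(n_all, db$lat[2] - 0.15 * diff(db$lat),
                         db$lat[2] - 0.05 * diff(db$lat)),
      heading = NA_real_
    ))
  }
  if (nrow(starts) != n_all) {
    stopf("`starts` must have one row per agent (%d)", n_all)
  }
  if (!"time" %in% names(starts)) starts$time <- spec$time_span[1]

  groups <- c(rep("ION", n_r), rep("ONS", n_n))
  ids <- c(sprintf("ION%02d", seq_len(n_r)), sprintf("ONS%02d", seq_len(n_n)))
  stop_region <- if (stop_on_corridor) spec$corridor else NULL

  tracks <- purrr::map_dfr(seq_len(n_all), function(i) {
    beh <- if (groups[i] == "ION") behavior_reactive else behavior_nonreactive
    if (!is.na(starts$heading[i])) beh$baseline_heading <- starts$heading[i]
    tr <- gen_track(spec, beh,
                    start = list(lon = starts$lon[i], lat = starts$lat[i],
                                 time = starts$time[i]),
                    exposure_oracle = oracle, n_steps = track_hours,
                    stop_region = stop_region)
    dplyr::mutate(tr, bird_id = ids[i], group = groups[i],
                  interpolated = FALSE, .before = 1)
  })

  manifest <- list(
    seed = spec$seed,
    n_birds_reactive = n_r, n_birds_nonreactive = n_n,
    bird_ids = ids, groups = groups,
    wind_params = spec$wind_params,
    domain_bounds = spec$domain_bounds,
    time_span = format(spec$time_span, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    oracle_horizon_h = oracle_horizon_h,
    stop_on_corridor = stop_on_corridor,
    n_track_points = nrow(tracks)
  )
  out <- structure(
    list(wind = wf, corridor = spec$corridor, goal = spec$goal,
         tracks = tracks, groups = tibble::tibble(bird_id = ids,
                                                  group = groups),
         manifest = manifest, spec = spec),
    class = "plume_scenario"
  )
  if (!is.null(dir)) write_scenario(out, dir)
  out
}

#' @export
print.plume_scenario <- function(x, ...) {
  cat(sprintf("<plume_scenario> %d agents (%d ION / %d ONS), %d track points\n",
              nrow(x$groups), sum(x$groups$group == "ION"),
              sum(x$groups$group == "ONS"), nrow(x$tracks)))
  print(x$wind)
  invisible(x)
}

#' Write a scenario bundle to disk
#'
#' @param scenario A `plume_scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create scenario directory '%s'", dir)
  write_wind_field(scenario$wind, file.path(dir, "wind_field.csv"))
  write_geojson_polygon(scenario$corridor, file.path(dir, "corridor.geojson"))
  write_geojson_polygon(scenario$goal, file.path(dir, "goal.geojson"))
  trdir <- file.path(dir, "tracks")
  dir.create(trdir, showWarnings = FALSE)
  for (id in unique(scenario$tracks$bird_id)) {
    write_track(dplyr::filter(scenario$tracks, .data$bird_id == id),
                file.path(trdir, paste0(id, ".csv")))
  }
  jsonlite::write_json(scenario$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
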