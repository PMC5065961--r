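#' Dispersion simulator configuration
#'
#' Houses every knob of the simplified backward Lagrangian model: particle
#' count, maximum backward travel time, time step, constant horizontal and
#' vertical diffusivities, output grid resolution, altitude layer tops, the
#' receptor reception window and layer, and the uniform emission rate. The
#' defaults mirror the reference configuration of the analysis (3-day
#' maximum travel, 0.2 degree output grid, layer tops at 100/3000/50,000 m,
#' 5-minute reception in the 0-30 m layer) with a test-scale particle
#' count.
#'
#' @param n_particles Particles released per receptor (reference value
#'   100,000; default 10,000 for desk-scale runs).
#' @param max_age_h Maximum backward travel time, hours.
#' @param dt_s Integration step, seconds.
#' @param kh,kz Horizontal / vertical diffusivity, m^2/s.
#' @param out_res Output grid resolution, degrees.
#' @param layer_tops Strictly increasing altitude layer tops, metres.
#' @param reception_window_s Reception period at the receptor, seconds.
#' @param receptor_layer Height range `c(lo, hi)` of particle release at
#'   the receptor, metres above ground.
#' @param emission_rate Uniform surface emission rate, relative units per
#'   second of residence.
#' @param seed Integer seed for the particle random walk.
#'
#' @return An object of class `dispersion_config`.
#' @export
dispersion_config <- function(n_particles = 10000L, max_age_h = 72,
                              dt_s = 600, kh = 5000, kz = 10,
                              out_res = 0.2,
                              layer_tops = c(100, 3000, 50000),
                              reception_window_s = 300,
                              receptor_layer = c(0, 30),
                              emission_rate = 1, seed = 1L) {
  if (n_particles <= 0 || dt_s <= 0 || max_age_h <= 0 || out_res <= 0) {
    stopf("n_particles, dt_s, max_age_h and out_res must all be > 0")
  }
  if (any(diff(layer_tops) <= 0)) stopf("layer_tops must be strictly increasing")
  if (!(receptor_layer[1] < receptor_layer[2])) {
    stopf("receptor_layer must satisfy lo < hi")
  }
  if (kh < 0 || kz < 0) stopf("diffusivities must be >= 0")
  cfg <- structure(
    list(n_particles = as.integer(n_particles), max_age_h = max_age_h,
         dt_s = dt_s, kh = kh, kz = kz, out_res = out_res,
         layer_tops = layer_tops,
         reception_window_s = reception_window_s,
         receptor_layer = receptor_layer,
         emission_rate = emission_rate, seed = as.integer(seed)),
    class = "dispersion_config"
  )
  cfg
}

config_digest <- function(cfg) {
  paste0("pt-", paste(
    cfg$n_particles, cfg$max_age_h, cfg$dt_s, cfg$kh, cfg$kz, cfg$out_res,
    paste(cfg$layer_tops, collapse = "/"), cfg$reception_window_s,
    paste(cfg$receptor_layer, collapse = "/"), cfg$emission_rate, cfg$seed,
    sep = "_"))
}

#' Receptor definition
#'
#' A receptor is the location and time at which arriving particles are
#' evaluated: a bird's (interpolated) position with a short reception
#' window.
#'
#' @param lon,lat Degrees, lon in \[-180, 180), lat in \[-90, 90\].
#' @param time `POSIXct` UTC.
#' @param window Reception window in seconds (defaults to the config value
#'   at simulation time).
#' @return An object of class `receptor`.
#' @export
receptor <- function(lon, lat, time, window = NULL) {
  if (lon < -180 || lon >= 180 || lat < -90 || lat > 90) {
    stopf("receptor coordinates out of range")
  }
  structure(list(lon = lon, lat = lat,
                 time = as.POSIXct(time, tz = "UTC"), window = window),
            class = "receptor")
}

# Output grid registration: cell centres at (k + 0.5) * out_res offsets from
# the wind-domain origin, half-open [west, east) x [south, north) binning.
raster_grid <- function(wf, out_res) {
  lon0 <- min(wf$lon); lat0 <- min(wf$lat)
  nx <- max(1L, ceiling((max(wf$lon) - lon0) / out_res - 1e-9))
  ny <- max(1L, ceiling((max(wf$lat) - lat0) / out_res - 1e-9))
  list(lon0 = lon0, lat0 = lat0, res = out_res, nx = as.integer(nx),
       ny = as.integer(ny),
       lon_centers = lon0 + (seq_len(nx) - 0.5) * out_res,
       lat_centers = lat0 + (seq_len(ny) - 0.5) * out_res)
}

#' Backward particle ensemble from a receptor
#'
#' Releases `n_particles` at the receptor, spread uniformly over the
#' reception window in time and uniformly over the receptor layer in
#' height, and steps each backward in time: horizontal displacement
#' `-(u, v) * dt` plus Gaussian random-walk increments with standard
#' deviation `sqrt(2 * kh * dt)` per horizontal axis and
#' `sqrt(2 * kz * dt)` vertically, with ground reflection. Metres are
#' converted to degrees with the local per-latitude metric. Particles are
#' terminated when they leave the wind domain; all motion stops at age
#' `max_age_h`. Cell residence times are accumulated on the output grid at
#' every backward step. Deterministic given `cfg$seed`.
#'
#' @param rec A [receptor()].
#' @param wf A [wind_field()].
#' @param cfg A [dispersion_config()].
#' @param store_trajectory Keep per-step particle positions (needed for
#'   [plume_bearing()])? Off by default to save memory.
#'
#' @return An object of class `particle_ensemble`: final particle states,
#'   per-particle residence step counts, the accumulated grid counts, and
#'   (optionally) the trajectory arrays.
#' @export
advect_backward <- function(rec, wf, cfg, store_trajectory = FALSE) {
  stopifnot(inherits(rec, "receptor"), inherits(wf, "wind_field"),
            inherits(cfg, "dispersion_config"))
  window <- rec$window %||% cfg$reception_window_s
  t_rec <- as.numeric(rec$time)
  ta <- as.numeric(wf$time)
  if (t_rec - cfg$max_age_h * 3600 - window < ta[1]) {
    stopf("receptor at %s is earlier than the wind data allow (need %g h of look-back)",
          format(rec$time, "%Y-%m-%d %H:%M", tz = "UTC"), cfg$max_age_h)
  }
  if (t_rec > ta[length(ta)]) stopf("receptor time is after the wind data end")
  if (rec$lon < min(wf$lon) || rec$lon > max(wf$lon) ||
      rec$lat < min(wf$lat) || rec$lat > max(wf$lat)) {
    stopf("receptor lies outside the wind domain")
  }

  n <- cfg$n_particles
  dt <- cfg$dt_s
  n_steps <- as.integer(round(cfg$max_age_h * 3600 / dt))
  grid <- raster_grid(wf, cfg$out_res)
  ncell <- grid$nx * grid$ny
  z_top <- max(cfg$layer_tops)
  lon_rng <- range(wf$lon); lat_rng <- range(wf$lat)
  sh <- sqrt(2 * cfg$kh * dt)
  sv <- sqrt(2 * cfg$kz * dt)

  withr::local_seed(cfg$seed)
  lon <- rep(rec$lon, n)
  lat <- rep(rec$lat, n)
  z <- stats::runif(n, cfg$receptor_layer[1], cfg$receptor_layer[2])
  tcur <- t_rec - stats::runif(n, 0, window)
  alive <- rep(TRUE, n)
  residence <- integer(n)
  counts <- numeric(ncell)
  traj_lon <- traj_lat <- NULL
  if (store_trajectory) {
    traj_lon <- matrix(NA_real_, n, n_steps + 1L)
    traj_lat <- matrix(NA_real_, n, n_steps + 1L)
    traj_lon[, 1] <- lon; traj_lat[, 1] <- lat
  }

  for (k in seq_len(n_steps)) {
    ia <- which(alive)
    if (!length(ia)) break
    wind <- interpolate_wind(wf, lon[ia], lat[ia], z[ia], tcur[ia])
    m <- length(ia)
    coslat <- cos(deg2rad(lat[ia]))
    dx_m <- -wind$u * dt + (if (sh > 0) stats::rnorm(m, 0, sh) else 0)
    dy_m <- -wind$v * dt + (if (sh > 0) stats::rnorm(m, 0, sh) else 0)
    dz_m <- -wind$w * dt + (if (sv > 0) stats::rnorm(m, 0, sv) else 0)
    lon[ia] <- lon[ia] + dx_m / (M_PER_DEG * coslat)
    lat[ia] <- lat[ia] + dy_m / M_PER_DEG
    z[ia] <- abs(z[ia] + dz_m)   # ground reflection
    tcur[ia] <- tcur[ia] - dt

    out <- lon[ia] < lon_rng[1] | lon[ia] > lon_rng[2] |
      lat[ia] < lat_rng[1] | lat[ia] > lat_rng[2]
    if (any(out)) alive[ia[out]] <- FALSE
    ia <- ia[!out]
    if (store_trajectory && length(ia)) {
      traj_lon[ia, k + 1L] <- lon[ia]
      traj_lat[ia, k + 1L] <- lat[ia]
    }
    if (length(ia)) {
      keep <- z[ia] <= z_top
      ib <- ia[keep]
      if (length(ib)) {
        ix <- floor((lon[ib] - grid$lon0) / grid$res)
        iy <- floor((lat[ib] - grid$lat0) / grid$res)
        ix <- pmin(pmax(ix, 0), grid$nx - 1L)
        iy <- pmin(pmax(iy, 0), grid$ny - 1L)
        flat <- ix + grid$nx * iy + 1L
        counts <- counts + tabulate(flat, nbins = ncell)
        residence[ib] <- residence[ib] + 1L
      }
    }
  }

  structure(
    list(receptor = rec, cfg = cfg, grid = grid, n_steps = n_steps,
         counts = counts, residence_steps = residence,
         lon = lon, lat = lat, z = z, alive = alive, t = tcur,
         traj_lon = traj_lon, traj_lat = traj_lat),
    class = "particle_ensemble"
  )
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> %d particles, %d backward steps, %.1f%% in domain\n",
              length(x$lon), x$n_steps, 100 * mean(x$alive)))
  invisible(x)
}

#' Source-contribution raster from a backward ensemble
#'
#' Converts accumulated cell residence times into the source-contribution
#' (footprint) raster for the ensemble's receptor: each backward step adds
#' `dt * emission_rate` to the cell containing the particle, and layers up
#' to the highest layer top are summed, so the raster total equals
#' `emission_rate * sum(particle residence times)` exactly.
#'
#' @param ensemble A `particle_ensemble` from [advect_backward()].
#' @param cfg A [dispersion_config()]; defaults to the ensemble's.
#'
#' @return An object of class `source_raster`: matrix `values`
#'   (lon x lat), cell-centre axes, the receptor, and a config digest.
#' @export
source_contribution <- function(ensemble, cfg = ensemble$cfg) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  grid <- ensemble$grid
  vals <- matrix(ensemble$counts * cfg$dt_s * cfg$emission_rate,
                 nrow = grid$nx, ncol = grid$ny)
  structure(
    list(lon = grid$lon_centers, lat = grid$lat_centers, values = vals,
         res = grid$res, receptor = ensemble$receptor,
         config_digest = config_digest(cfg)),
    class = "source_raster"
  )
}

#' @export
print.source_raster <- function(x, ...) {
  cat(sprintf("<source_raster> %d x %d cells at %g deg, total mass %.4g, receptor (%.3f, %.3f) %s\n",
              length(x$lon), length(x$lat), x$res, sum(x$values),
              x$receptor$lon, x$receptor$lat,
              format(x$receptor$time, "%Y-%m-%d %H:%M", tz = "UTC")))
  invisible(x)
}

#' Tidy a source raster into a lon/lat/value tibble
#'
#' @param x A `source_raster`.
#' @param drop_zero Drop empty cells?
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `value`.
#' @export
tidy.source_raster <- function(x, drop_zero = TRUE, ...) {
  out <- tibble::tibble(
    lon = rep(x$lon, times = length(x$lat)),
    lat = rep(x$lat, each = length(x$lon)),
    value = as.vector(x$values)
  )
  if (drop_zero) out <- dplyr::filter(out, .data$value > 0)
  out
}

#' Bilinear or nearest-cell sampling of a source raster
#'
#' @param raster A `source_raster`.
#' @param lon,lat Query coordinates (vectors).
#' @param method `"bilinear"` (continuous, default) or `"nearest"` (exact
#'   cell value).
#' @return Numeric vector of sampled values (0 outside the grid).
#' @export
sample_raster <- function(raster, lon, lat,
                          method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nx <- length(raster$lon); ny <- length(raster$lat)
  if (method == "nearest") {
    ix <- round((lon - raster$lon[1]) / raster$res) + 1
    iy <- round((lat - raster$lat[1]) / raster$res) + 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    out <- numeric(length(lon))
    out[ok] <- raster$values[cbind(ix[ok], iy[ok])]
    return(out)
  }
  fx <- (lon - raster$lon[1]) / raster$res
  fy <- (lat - raster$lat[1]) / raster$res
  i0 <- pmin(pmax(floor(fx), 0), nx - 2)
  j0 <- pmin(pmax(floor(fy), 0), ny - 2)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  v00 <- raster$values[cbind(i0 + 1, j0 + 1)]
  v10 <- raster$values[cbind(i0 + 2, j0 + 1)]
  v01 <- raster$values[cbind(i0 + 1, j0 + 2)]
  v11 <- raster$values[cbind(i0 + 2, j0 + 2)]
  out <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
  inside <- fx >= -0.5 & fx <= nx - 0.5 & fy >= -0.5 & fy <= ny - 0.5
  out[!inside] <- 0
  out
}

#' Run the backward model along a whole track
#'
#' Produces one source-contribution raster per (hourly) track position.
#' Positions whose look-back window is not covered by the wind data are
#' skipped with a warning. Per-receptor seeds are derived deterministically
#' from `(cfg$seed, position index)` so results do not depend on execution
#' order.
#'
#' @param track A single-bird track tibble (see [read_track()]).
#' @param wf A [wind_field()].
#' @param cfg A [dispersion_config()].
#' @param store_trajectory Passed to [advect_backward()].
#'
#' @return A list of `source_raster` objects in track order, with the
#'   used row indices as attribute `track_index`.
#' @export
run_receptor_series <- function(track, wf, cfg, store_trajectory = FALSE) {
  if (nrow(track) == 0) stopf("cannot run an empty track")
  ta <- as.numeric(wf$time)
  window <- cfg$reception_window_s
  lookback <- cfg$max_age_h * 3600 + window
  usable <- which(as.numeric(track$time) - lookback >= ta[1] &
                    as.numeric(track$time) <= ta[length(ta)])
  skipped <- setdiff(seq_len(nrow(track)), usable)
  if (length(skipped)) {
    warnf("skipping %d track position(s) whose look-back window exits the wind data",
          length(skipped))
  }
  rasters <- vector("list", length(usable))
  for (j in seq_along(usable)) {
    i <- usable[j]
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    ens <- advect_backward(
      receptor(track$lon[i], track$lat[i], track$time[i]),
      wf, cfg_i, store_trajectory = store_trajectory)
    rasters[[j]] <- source_contribution(ens, cfg_i)
  }
  attr(rasters, "track_index") <- usable
  rasters
}

#' Independent forward Lagrangian simulator
#'
#' Forward-time counterpart used as the adjoint (source-receptor duality)
#' oracle: particles are released uniformly over a source rectangle and a
#' release time window, advected forward with `+(u, v) * dt` plus the same
#' Gaussian random walk as the backward model, and the mean residence time
#' per particle inside a target rectangle is recorded. Written as a
#' separate code path from [advect_backward()] on purpose.
#'
#' @param source_box,target_box Rectangles `c(lon_min, lon_max, lat_min,
#'   lat_max)` in degrees.
#' @param wf A [wind_field()].
#' @param cfg A [dispersion_config()] (supplies dt, diffusivities,
#'   particle count, max age and seed).
#' @param t_start Release time (`POSIXct`); particles are released
#'   uniformly over `cfg$reception_window_s` after it.
#'
#' @return A list with `residence_s` (mean seconds per particle inside the
#'   target) and `n_particles`.
#' @export
simulate_forward <- function(source_box, target_box, wf, cfg, t_start) {
  n <- cfg$n_particles
  dt <- cfg$dt_s
  n_steps <- as.integer(round(cfg$max_age_h * 3600 / dt))
  lon_rng <- range(wf$lon); lat_rng <- range(wf$lat)
  sh <- sqrt(2 * cfg$kh * dt)
  sv <- sqrt(2 * cfg$kz * dt)
  withr::local_seed(cfg$seed)
  lon <- stats::runif(n, source_box[1], source_box[2])
  lat <- stats::runif(n, source_box[3], source_box[4])
  z <- stats::runif(n, cfg$receptor_layer[1], cfg$receptor_layer[2])
  tcur <- as.numeric(t_start) + stats::runif(n, 0, cfg$reception_window_s)
  alive <- rep(TRUE, n)
  hits <- 0
  for (k in seq_len(n_steps)) {
    ia <- which(alive)
    if (!length(ia)) break
    wind <- interpolate_wind(wf, lon[ia], lat[ia], z[ia], tcur[ia])
    m <- length(ia)
    lon[ia] <- lon[ia] + (wind$u * dt +
                            (if (sh > 0) stats::rnorm(m, 0, sh) else 0)) /
      (M_PER_DEG * cos(deg2rad(lat[ia])))
    lat[ia] <- lat[ia] + (wind$v * dt +
                            (if (sh > 0) stats::rnorm(m, 0, sh) else 0)) / M_PER_DEG
    z[ia] <- abs(z[ia] + wind$w * dt +
                   (if (sv > 0) stats::rnorm(m, 0, sv) else 0))
    tcur[ia] <- tcur[ia] + dt
    gone <- lon[ia] < lon_rng[1] | lon[ia] > lon_rng[2] |
      lat[ia] < lat_rng[1] | lat[ia] > lat_rng[2]
    if (any(gone)) alive[ia[gone]] <- FALSE
    ia <- ia[!gone]
    if (length(ia)) {
      hits <- hits + sum(lon[ia] >= target_box[1] & lon[ia] < target_box[2] &
                           lat[ia] >= target_box[3] & lat[ia] < target_box[4])
    }
  }
  list(residence_s = hits * dt / n, n_particles = n)
}
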