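# Shared fixtures. Heavy objects (the demo pipeline, the correlogram
# scenarios) are built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

T0 <- as.POSIXct("2023-06-01 00:00:00", tz = "UTC")

# small uniform wind field: constant (u, v) everywhere
const_wind <- function(u = 10, v = 0, lon = seq(-5, 5, 0.5),
                       lat = seq(-5, 5, 0.5), hours = 12, t0 = T0) {
  tm <- seq(t0, by = 3600, length.out = hours)
  nd <- c(hours, 2, length(lat), length(lon))
  wind_field(lon = lon, lat = lat, level = c(0, 1000), time = tm,
             u = array(u, nd), v = array(v, nd))
}

# hand-built source raster on a small grid, receptor time t
make_raster <- function(values, t = T0, res = 0.2, lon0 = 0, lat0 = 0) {
  values <- as.matrix(values)
  structure(
    list(lon = lon0 + (seq_len(nrow(values)) - 0.5) * res,
         lat = lat0 + (seq_len(ncol(values)) - 0.5) * res,
         values = values, res = res,
         receptor = receptor(lon0 + 0.1, lat0 + 0.1, t),
         config_digest = "test"),
    class = "source_raster")
}

# straight hourly single-bird track heading south from (lon0, lat0)
straight_track <- function(n = 10, lon0 = 0, lat0 = 5, dlat = -0.3238,
                           t0 = T0, id = "b1", group = "ION") {
  tibble::tibble(
    bird_id = id, group = group,
    time = t0 + (seq_len(n) - 1) * 3600,
    lon = lon0, lat = lat0 + (seq_len(n) - 1) * dlat,
    interpolated = FALSE)
}

demo_fixture <- function() {
  fixture("demo", make_demo(seed = 1, n_particles = 350, quiet = TRUE))
}

null_demo_fixture <- function() {
  fixture("null_demo",
          make_demo(seed = 1, n_particles = 350, turn_gain = 0,
                    quiet = TRUE))
}

# stationary receptors under a frozen (time-constant) wind: rasters differ
# only by Monte-Carlo particle noise
frozen_correlogram_fixture <- function() {
  fixture("frozen_cg", {
    spec <- scenario_spec(
      domain_bounds = list(lon = c(0, 12), lat = c(38, 50)),
      time_span = c(T0, T0 + 60 * 3600),
      wind_params = list(mean_u = 6, mean_v = 0, amplitude = 0,
                         wavelength = 5, period = 30, rotation = 0),
      corridor = rect_polygon(c(5, 6), c(40, 41)),
      goal = rect_polygon(c(5, 6), c(39, 40)),
      seed = 11)
    wf <- gen_wind_field(spec)
    cfg <- dispersion_config(n_particles = 4000, max_age_h = 8, dt_s = 900,
                             kh = 5000, kz = 10, out_res = 0.2, seed = 5)
    mk <- function(lon, lat, id) {
      tr <- tibble::tibble(bird_id = id, group = "ION",
                           time = seq(T0 + 9 * 3600, by = 3600,
                                      length.out = 49),
                           lon = lon, lat = lat, interpolated = FALSE)
      run_receptor_series(tr, wf, cfg)
    }
    correlogram(list(b1 = mk(8, 44, "b1"), b2 = mk(7, 46, "b2"),
                     b3 = mk(9, 42, "b3")), max_lag = 48, seed = 2)
  })
}

# migrating receptors under a wind whose direction rotates 15 deg/h: the
# olfactory landscape decorrelates with lag
rotating_correlogram_fixture <- function() {
  fixture("rotating_cg", {
    spec <- scenario_spec(
      domain_bounds = list(lon = c(0, 16), lat = c(30, 52)),
      time_span = c(T0, T0 + 60 * 3600),
      wind_params = list(mean_u = 8, mean_v = 0, amplitude = 3,
                         wavelength = 5, period = 30, rotation = 15),
      corridor = rect_polygon(c(5, 6), c(40, 41)),
      goal = rect_polygon(c(5, 6), c(39, 40)),
      seed = 11)
    wf <- gen_wind_field(spec)
    cfg <- dispersion_config(n_particles = 2500, max_age_h = 8, dt_s = 900,
                             kh = 5000, kz = 10, out_res = 0.2, seed = 5)
    beh <- agent_behavior(cruise_speed = 10, baseline_heading = 190,
                          reactive = FALSE)
    mk <- function(lon, lat, id) {
      tr <- gen_track(spec, beh,
                      start = list(lon = lon, lat = lat, time = T0 + 9 * 3600),
                      n_steps = 48)
      tr <- dplyr::mutate(tr, bird_id = id, group = "ION",
                          interpolated = FALSE)
      run_receptor_series(tr, wf, cfg)
    }
    correlogram(list(b1 = mk(9, 49.5, "b1"), b2 = mk(10, 50, "b2"),
                     b3 = mk(11, 50.5, "b3")), max_lag = 48, seed = 2)
  })
}
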