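base_spec <- function(seed = 1, amplitude = 2, mean_u = 10, mean_v = 0,
                      n_r = 2, n_n = 2) {
  scenario_spec(
    domain_bounds = list(lon = c(0, 20), lat = c(30, 50)),
    time_span = c(T0, T0 + 48 * 3600),
    wind_params = list(mean_u = mean_u, mean_v = mean_v,
                       amplitude = amplitude, wavelength = 6, period = 30,
                       rotation = 0),
    corridor = rect_polygon(c(14, 16), c(30, 45)),
    goal = rect_polygon(c(14.5, 15.5), c(30, 32)),
    n_birds_reactive = n_r, n_birds_nonreactive = n_n, seed = seed)
}

test_that("scenario_spec rejects degenerate inputs", {
  expect_error(scenario_spec(list(lon = c(0, 0), lat = c(0, 1)),
                             c(T0, T0 + 3600), list(),
                             rect_polygon(c(0, 0.1), c(0.1, 0.2)),
                             rect_polygon(c(0, 0.1), c(0.1, 0.2))),
               "positive extent")
  expect_error(base_spec()$foo, NA)
  sp <- base_spec()
  expect_error(scenario_spec(sp$domain_bounds, c(T0 + 10, T0), sp$wind_params,
                             sp$corridor, sp$goal), "precede")
  expect_error(scenario_spec(sp$domain_bounds, sp$time_span, sp$wind_params,
                             rect_polygon(c(19, 21), c(40, 42)), sp$goal),
               "within domain_bounds")
})

test_that("wind generation is a pure function of spec and seed", {
  w1 <- gen_wind_field(base_spec(seed = 7))
  w2 <- gen_wind_field(base_spec(seed = 7))
  expect_identical(w1$u, w2$u)
  expect_identical(w1$v, w2$v)
  w3 <- gen_wind_field(base_spec(seed = 8))
  expect_false(identical(w1$u, w3$u))
})

test_that("zero perturbation amplitude yields exactly constant fields", {
  wf <- gen_wind_field(base_spec(amplitude = 0, mean_u = 10, mean_v = 0))
  expect_true(all(wf$u == 10))
  expect_true(all(wf$v == 0))
})

test_that("the perturbation is near zero-mean around the mean wind", {
  for (seed in c(1, 5, 9)) {
    wf <- gen_wind_field(base_spec(seed = seed, amplitude = 2, mean_u = 10))
    expect_lt(abs(mean(wf$u) - 10), 0.5)
    expect_lt(abs(mean(wf$v) - 0), 0.5)
  }
})

test_that("generated wind fields satisfy the container invariants", {
  wf <- gen_wind_field(base_spec(seed = 3, amplitude = 3))
  expect_true(all(diff(wf$lon) > 0) && all(diff(wf$lat) > 0))
  expect_true(all(is.finite(wf$u)) && all(is.finite(wf$v)))
})

test_that("non-reactive agents fly constant headings on great circles", {
  sp <- base_spec(amplitude = 0)
  tr <- gen_track(sp, agent_behavior(baseline_heading = 180,
                                     reactive = FALSE),
                  start = list(lon = 10, lat = 48, time = T0), n_steps = 10)
  expect_equal(nrow(tr), 11)
  b <- gc_bearing(cbind(tr$lon[-11], tr$lat[-11]),
                  cbind(tr$lon[-1], tr$lat[-1]))
  expect_true(all(abs(wrap180(b - 180)) < 0.1))
})

test_that("reactive agents ignore an oracle that never fires", {
  sp <- base_spec(amplitude = 0)
  silent <- function(lon, lat, time) list(fraction = 0, bearing = NA_real_)
  tr_r <- gen_track(sp, agent_behavior(reactive = TRUE,
                                       baseline_heading = 200),
                    start = list(lon = 10, lat = 48, time = T0),
                    exposure_oracle = silent, n_steps = 12)
  tr_n <- gen_track(sp, agent_behavior(reactive = FALSE,
                                       baseline_heading = 200),
                    start = list(lon = 10, lat = 48, time = T0),
                    n_steps = 12)
  expect_equal(tr_r$lon, tr_n$lon)
  expect_equal(tr_r$lat, tr_n$lat)
})

test_that("a single oracle firing with full gain snaps the heading", {
  sp <- base_spec(amplitude = 0)
  fired <- FALSE
  once <- function(lon, lat, time) {
    if (!fired && as.numeric(time - T0, units = "hours") >= 3) {
      fired <<- TRUE
      return(list(fraction = 1, bearing = 90))
    }
    list(fraction = 0, bearing = NA_real_)
  }
  tr <- gen_track(sp, agent_behavior(reactive = TRUE, turn_gain = 1,
                                     baseline_heading = 180),
                  start = list(lon = 8, lat = 45, time = T0),
                  exposure_oracle = once, n_steps = 8)
  i <- which(tr$exposed)[1]
  seg <- gc_bearing(c(tr$lon[i], tr$lat[i]), c(tr$lon[i + 1], tr$lat[i + 1]))
  expect_lt(abs(wrap180(seg - 90)), 0.5)
})

test_that("agents leaving the domain terminate with a flag", {
  sp <- base_spec(amplitude = 0)
  tr <- gen_track(sp, agent_behavior(baseline_heading = 270,
                                     cruise_speed = 30, reactive = FALSE),
                  start = list(lon = 1, lat = 40, time = T0), n_steps = 40)
  expect_true(attr(tr, "left_domain"))
  expect_lt(nrow(tr), 41)
})

test_that("gen_scenario produces the requested groups deterministically", {
  sp <- base_spec(n_r = 3, n_n = 2, amplitude = 1)
  sc1 <- gen_scenario(sp, track_hours = 6)
  sc2 <- gen_scenario(sp, track_hours = 6)
  expect_equal(sort(unique(sc1$tracks$bird_id)),
               c("ION01", "ION02", "ION03", "ONS01", "ONS02"))
  expect_equal(sc1$groups$group, c("ION", "ION", "ION", "ONS", "ONS"))
  expect_identical(sc1$tracks, sc2$tracks)
  expect_identical(sc1$manifest, sc2$manifest)
})

test_that("reactive agents end nearer the corridor than non-reactive ones", {
  # displacement west of an eastern corridor, wind from the east carrying
  # corridor air to the agents; non-reactive agents hold a south-westerly
  # course away from the route
  sp <- scenario_spec(
    domain_bounds = list(lon = c(0, 20), lat = c(28, 50)),
    time_span = c(T0, T0 + 36 * 3600),
    wind_params = list(mean_u = -8, mean_v = 0, amplitude = 0.5,
                       wavelength = 6, period = 30, rotation = 0),
    corridor = rect_polygon(c(14, 16), c(30, 45)),
    goal = rect_polygon(c(14.5, 15.5), c(30, 32)),
    n_birds_reactive = 3, n_birds_nonreactive = 3, seed = 2)
  # tracks start once the wind record covers the oracle's look-back horizon
  starts <- tibble::tibble(lon = rep(c(11.5, 12, 12.5), 2),
                           lat = rep(c(42, 43, 44), 2),
                           heading = 225, time = T0 + 10 * 3600)
  sc <- gen_scenario(sp, starts = starts, track_hours = 24,
                     behavior_reactive = agent_behavior(reactive = TRUE,
                                                        turn_gain = 0.8,
                                                        baseline_heading = 225),
                     behavior_nonreactive = agent_behavior(reactive = FALSE,
                                                           baseline_heading = 225))
  ctr <- c(15, 37.5)
  moved_closer <- sc$tracks |>
    dplyr::group_by(bird_id, group) |>
    dplyr::summarise(
      closer = gc_distance(c(dplyr::last(lon), dplyr::last(lat)), ctr) <
        gc_distance(c(dplyr::first(lon), dplyr::first(lat)), ctr),
      .groups = "drop")
  expect_true(all(moved_closer$closer[moved_closer$group == "ION"]))
  expect_false(any(moved_closer$closer[moved_closer$group == "ONS"]))
})

test_that("scenario bundles round-trip through disk", {
  sp <- base_spec(n_r = 1, n_n = 1, amplitude = 1)
  dir <- withr::local_tempdir()
  sc <- gen_scenario(sp, track_hours = 4, dir = dir)
  expect_true(file.exists(file.path(dir, "wind_field.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  tr <- read_track(file.path(dir, "tracks", "ION01.csv"))
  orig <- dplyr::filter(sc$tracks, bird_id == "ION01")
  expect_equal(tr$lon, orig$lon, tolerance = 1e-9)
  expect_equal(tr$group, orig$group)
  poly <- read_geojson_polygon(file.path(dir, "corridor.geojson"))
  expect_equal(poly, sp$corridor)
})
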