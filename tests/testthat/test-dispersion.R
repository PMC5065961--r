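test_that("pure advection matches the closed-form displacement", {
  wf <- const_wind(u = 10, v = 0)
  cfg <- dispersion_config(n_particles = 50, max_age_h = 1, dt_s = 600,
                           kh = 0, kz = 0, reception_window_s = 1e-6,
                           seed = 7)
  ens <- advect_backward(receptor(0, 0, T0 + 8 * 3600), wf, cfg)
  # 36 km upwind = 36000 / 111195 degrees west at the equator
  expect_true(all(abs(ens$lon * M_PER_DEG + 36000) < 1))
  expect_true(all(abs(ens$lat) * M_PER_DEG < 1))
})

test_that("zero wind and zero diffusion leave particles at the receptor", {
  wf <- const_wind(u = 0, v = 0)
  cfg <- dispersion_config(n_particles = 20, max_age_h = 2, dt_s = 600,
                           kh = 0, kz = 0, seed = 1)
  ens <- advect_backward(receptor(0.5, 0.5, T0 + 8 * 3600), wf, cfg)
  expect_true(all(ens$lon == 0.5 & ens$lat == 0.5))
  sr <- source_contribution(ens)
  expect_equal(sum(sr$values > 0), 1)  # single occupied cell
})

test_that("random-walk variance matches 2*K*tau", {
  wf <- const_wind(u = 0, v = 0)
  cfg <- dispersion_config(n_particles = 10000, max_age_h = 1, dt_s = 600,
                           kh = 1000, kz = 0, reception_window_s = 1e-6,
                           seed = 3)
  ens <- advect_backward(receptor(0, 0, T0 + 8 * 3600), wf, cfg)
  target <- 2 * 1000 * 3600
  expect_lt(abs(var(ens$lon * M_PER_DEG) / target - 1), 0.05)
  expect_lt(abs(var(ens$lat * M_PER_DEG) / target - 1), 0.05)
})

test_that("raster mass equals emission rate times total residence time", {
  wf <- const_wind(u = 3, v = 2)
  cfg <- dispersion_config(n_particles = 500, max_age_h = 3, dt_s = 600,
                           kh = 2000, kz = 10, emission_rate = 2.5, seed = 9)
  ens <- advect_backward(receptor(0, 0, T0 + 8 * 3600), wf, cfg)
  sr <- source_contribution(ens)
  expected <- 2.5 * sum(ens$residence_steps) * 600
  expect_lt(abs(sum(sr$values) - expected) / expected, 1e-9)
  # nobody exits this large domain: residence = n * max_age exactly
  expect_equal(sum(ens$residence_steps), 500 * 18)
})

test_that("uniform wind with no diffusion paints a contiguous upwind line", {
  wf <- const_wind(u = 10, v = 0)
  cfg <- dispersion_config(n_particles = 100, max_age_h = 6, dt_s = 600,
                           kh = 0, kz = 0, out_res = 0.2,
                           reception_window_s = 1e-6, seed = 2)
  ens <- advect_backward(receptor(0.1, 0.1, T0 + 8 * 3600), wf, cfg)
  sr <- source_contribution(ens)
  occ <- which(sr$values > 0, arr.ind = TRUE)
  expect_equal(length(unique(occ[, 2])), 1)        # one latitude row
  cols <- sort(unique(occ[, 1]))
  expect_equal(cols, seq(min(cols), max(cols)))    # contiguous in lon
  expect_true(max(sr$lon[cols]) <= 0.2)            # strictly upwind (west)
})

test_that("shifting receptor and grid together shifts the raster", {
  mk <- function(lon0) {
    wf <- const_wind(u = 7, v = 4, lon = seq(-5, 5, 0.5) + lon0)
    cfg <- dispersion_config(n_particles = 64, max_age_h = 4, dt_s = 600,
                             kh = 0, kz = 0, out_res = 0.2,
                             reception_window_s = 1e-6, seed = 5)
    source_contribution(advect_backward(receptor(lon0 + 0.3, 0.3,
                                                 T0 + 8 * 3600), wf, cfg))
  }
  a <- mk(0); b <- mk(0.2)
  expect_equal(a$values, b$values)
  expect_equal(b$lon, a$lon + 0.2)
})

test_that("crosswind spread converges to the Gaussian plume profile", {
  wf <- const_wind(u = 10, v = 0)
  cfg <- dispersion_config(n_particles = 10000, max_age_h = 1, dt_s = 600,
                           kh = 1000, kz = 0, reception_window_s = 1e-6,
                           seed = 11)
  ens <- advect_backward(receptor(0, 0, T0 + 8 * 3600), wf, cfg)
  ks <- suppressWarnings(
    stats::ks.test(ens$lat * M_PER_DEG, "pnorm", 0, sqrt(2 * 1000 * 3600)))
  expect_gt(ks$p.value, 0.01)
})

test_that("backward transport under reversed winds mirrors forward advection", {
  wf_rev <- const_wind(u = -10, v = -4)
  cfg <- dispersion_config(n_particles = 20, max_age_h = 2, dt_s = 600,
                           kh = 0, kz = 0, reception_window_s = 1e-6,
                           seed = 4)
  ens <- advect_backward(receptor(0, 0, T0 + 8 * 3600), wf_rev, cfg)
  # reversed-wind backward = original-wind forward displacement
  expect_true(all(abs(ens$lat * M_PER_DEG - 4 * 7200) < 1))
  expect_gt(min(ens$lon), 0)
})

test_that("receptors beyond the wind data error; early track rows are skipped", {
  wf <- const_wind(hours = 12)
  cfg <- dispersion_config(n_particles = 10, max_age_h = 6, dt_s = 600,
                           seed = 1)
  expect_error(advect_backward(receptor(0, 0, T0 + 3600), wf, cfg),
               "earlier than the wind data")
  tr <- straight_track(n = 10, lon0 = 0, lat0 = 2, t0 = T0 + 3 * 3600)
  expect_warning(out <- run_receptor_series(tr, wf,
                                            dispersion_config(n_particles = 10,
                                                              max_age_h = 6,
                                                              dt_s = 1200,
                                                              seed = 1)),
                 "skipping")
  expect_lt(length(out), 10)
  expect_equal(length(out), length(attr(out, "track_index")))
})

test_that("receptor series are ordered, complete and seed-reproducible", {
  wf <- const_wind(u = 5, v = 0, hours = 20)
  cfg <- dispersion_config(n_particles = 40, max_age_h = 2, dt_s = 900,
                           kh = 1000, seed = 6)
  tr <- straight_track(n = 6, lon0 = 0, lat0 = 2, t0 = T0 + 8 * 3600)
  r1 <- run_receptor_series(tr, wf, cfg)
  r2 <- run_receptor_series(tr, wf, cfg)
  expect_equal(length(r1), 6)
  expect_equal(purrr::map_dbl(r1, ~ as.numeric(.x$receptor$time)),
               as.numeric(tr$time))
  expect_identical(purrr::map(r1, "values"), purrr::map(r2, "values"))
  expect_error(run_receptor_series(tr[0, ], wf, cfg), "empty")
})

test_that("raster sampling is exact at cell centres and bilinear between", {
  r <- make_raster(matrix(c(1, 2, 3, 4), 2, 2), res = 1, lon0 = 0, lat0 = 0)
  expect_equal(sample_raster(r, 0.5, 0.5), 1)
  expect_equal(sample_raster(r, 1.5, 1.5), 4)
  expect_equal(sample_raster(r, 1.0, 1.0), mean(c(1, 2, 3, 4)))
  expect_equal(sample_raster(r, 0.5, 0.5, method = "nearest"), 1)
  expect_equal(sample_raster(r, 10, 10), 0)
})
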