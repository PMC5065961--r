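test_that("corridor exposure computes mass fractions over cell centres", {
  inside_all <- make_raster(matrix(c(0, 0, 5, 3), 2, 2), res = 1)
  big <- rect_polygon(c(-1, 3), c(-1, 3))
  expect_equal(corridor_exposure(inside_all, big)$corridor_fraction, 1)
  far <- rect_polygon(c(10, 12), c(10, 12))
  out <- corridor_exposure(inside_all, far)
  expect_equal(out$corridor_fraction, 0)
  expect_false(out$exposed)
  # half the mass in one of two occupied cells
  two <- make_raster(matrix(c(4, 0, 0, 4), 2, 2), res = 1)
  west <- rect_polygon(c(0, 1), c(0, 1))   # contains centre (0.5, 0.5) only
  expect_equal(corridor_exposure(two, west)$corridor_fraction, 0.5)
  # invariance under rescaling of raster values
  two10 <- make_raster(10 * matrix(c(4, 0, 0, 4), 2, 2), res = 1)
  expect_equal(corridor_exposure(two10, west)$corridor_fraction, 0.5)
  # zero-mass raster
  expect_equal(corridor_exposure(make_raster(matrix(0, 2, 2)),
                                 big)$corridor_fraction, 0)
  expect_error(corridor_exposure(two, matrix(1, 1, 2)), "polygon")
})

test_that("plume bearings recover the upwind direction", {
  cfg <- dispersion_config(n_particles = 400, max_age_h = 3, dt_s = 600,
                           kh = 0, kz = 0, reception_window_s = 1e-6,
                           seed = 8)
  # air arriving from the east (u = -10)
  ens_e <- advect_backward(receptor(0, 0, T0 + 8 * 3600),
                           const_wind(u = -10, v = 0), cfg,
                           store_trajectory = TRUE)
  pb_e <- plume_bearing(ens_e)
  expect_lt(abs(wrap180(pb_e$bearing - 90)), 1)
  # air arriving from the north (v = -10)
  ens_n <- advect_backward(receptor(0, 0, T0 + 8 * 3600),
                           const_wind(u = 0, v = -10), cfg,
                           store_trajectory = TRUE)
  pb_n <- plume_bearing(ens_n)
  expect_lt(min(abs(wrap180(pb_n$bearing - 0))), 1)
  # pure diffusion: no preferred direction, low resultant length
  cfg_d <- dispersion_config(n_particles = 600, max_age_h = 3, dt_s = 600,
                             kh = 20000, kz = 0, seed = 8)
  ens_d <- advect_backward(receptor(0, 0, T0 + 8 * 3600),
                           const_wind(u = 0, v = 0), cfg_d,
                           store_trajectory = TRUE)
  expect_lt(plume_bearing(ens_d)$r, 0.15)
  # stationary air never reaches the trail distance
  cfg_0 <- dispersion_config(n_particles = 10, max_age_h = 1, dt_s = 600,
                             kh = 0, kz = 0, seed = 1)
  ens_0 <- advect_backward(receptor(0, 0, T0 + 8 * 3600),
                           const_wind(u = 0, v = 0), cfg_0,
                           store_trajectory = TRUE)
  expect_true(is.na(plume_bearing(ens_0)$bearing))
})

test_that("turn analysis wraps signed deltas through north", {
  expect_equal(plumetrack:::wrap180(150 - 180), -30)
  tr <- straight_track(n = 20, dlat = -0.3)
  out <- turn_analysis(tr, list(time = tr$time[10], plume_bearing = 170),
                       before_m = 150000, after_m = 150000)
  expect_lt(abs(out$delta), 0.5)                 # straight south: no turn
  expect_equal(out$plume_relative_angle, 170 - out$bearing_before,
               tolerance = 0.1)
  # wrap formula checks
  expect_equal(plumetrack:::ang_diff(150, 180), -30)
  expect_equal(plumetrack:::ang_diff(10, 350), 20)
  expect_error(turn_analysis(tr, list(time = tr$time[1],
                                      plume_bearing = 90)),
               "endpoint")
  expect_error(turn_analysis(tr, list(time = T0 + 1, plume_bearing = 90)),
               "not found")
})

test_that("reorientation classification needs exposure plus improvement", {
  turns <- tibble::tibble(
    bird_id = c("a", "b", "c"),
    bearing_before = c(150, 150, 150),
    bearing_after = c(178, 150, 178),
    delta = c(28, 0, 28),
    plume_bearing = 180,
    plume_relative_angle = c(30, 30, 30),
    exposed = c(TRUE, TRUE, FALSE))
  out <- classify_reorientation(turns, min_improvement = 8)
  expect_equal(out$reoriented, c(TRUE, FALSE, FALSE))
  expect_equal(out$improvement[1], 28, tolerance = 1e-9)
})

test_that("the V test matches its closed form", {
  vt <- v_test(rep(123, 8), 123)
  expect_equal(vt$r, 1)
  expect_equal(unname(vt$statistic["V"]), 8)
  expect_equal(unname(vt$statistic["u"]), 4)
  expect_equal(vt$p_value, pnorm(4, lower.tail = FALSE))
  expect_equal(vt$p_value, 3.167e-05, tolerance = 1e-3)
  # perfect uniformity: r = 0, V = 0, p = 0.5
  vt2 <- v_test(c(0, 90, 180, 270), 0)
  expect_equal(unname(vt2$statistic["V"]), 0, tolerance = 1e-12)
  expect_equal(vt2$p_value, 0.5, tolerance = 1e-9)
  # concentrated orthogonally to mu0: V = 0 despite r = 1
  vt3 <- v_test(rep(90, 6), 0)
  expect_equal(vt3$r, 1)
  expect_equal(unname(vt3$statistic["V"]), 0, tolerance = 1e-9)
  expect_error(v_test(1, 0), "n >= 2")
})

test_that("the paired Hotelling test is degenerate-safe and has power", {
  a <- c(10, 50, 170, 220, 300)
  expect_equal(hotelling_paired(a, a)$p_value, 1)
  expect_error(hotelling_paired(1:2, 1:2), "n >= 3")
  # concentrated before-bearings shifted by 90 degrees: overwhelming
  # rejection (a rotation of *uniform* angles leaves the mean difference
  # vector at zero and is invisible to a paired mean-vector test)
  set.seed(77)
  ps <- replicate(200, {
    b <- rnorm(20, 180, 15)
    hotelling_paired(b, b + 90)$p_value
  })
  expect_gte(mean(ps < 0.001), 0.99)
})

test_that("the contingency test reproduces hand-computed Pearson X^2", {
  out <- chi_square_contingency(matrix(c(10, 0, 0, 10), 2))
  expect_equal(out$statistic, 20)
  expect_equal(out$df, 1)
  out2 <- chi_square_contingency(matrix(c(5, 5, 5, 5), 2))
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)
  # the 2x3 reorientation-by-ability table assembled from group counts
  tab <- matrix(c(8, 1, 0, 5, 3, 0), nrow = 2)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - exp_counts)^2 / exp_counts)
  out3 <- chi_square_contingency(tab)
  expect_equal(out3$statistic, x2_hand)
  expect_equal(out3$df, 2)
  expect_error(chi_square_contingency(matrix(c(1, 2, 0, 0), 2)),
               "zero row or column")
  expect_error(chi_square_contingency(matrix(c(1.5, 2, 3, 4), 2)),
               "integer")
})

test_that("turn-angle regression recovers identity and degenerate cases", {
  rec <- tibble::tibble(delta = c(-30, -10, 5, 20, 40),
                        plume_relative_angle = c(-30, -10, 5, 20, 40))
  fit <- angle_turn_relation(rec)
  expect_equal(fit$slope, 1)
  expect_equal(fit$correlation, 1)
  rec2 <- tibble::tibble(delta = 7, plume_relative_angle = c(-30, 0, 30))
  fit2 <- angle_turn_relation(rec2)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$correlation, 0)
  rec3 <- tibble::tibble(delta = c(1, 2, 3), plume_relative_angle = 10)
  expect_error(angle_turn_relation(rec3), "zero variance")
})
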