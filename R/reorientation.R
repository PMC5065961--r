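#' Corridor plume exposure of one raster
#'
#' Fraction of the raster's total mass falling in cells whose centres lie
#' inside the corridor polygon; the receptor is "exposed" when the fraction
#' reaches the threshold. A zero-mass raster yields fraction 0.
#'
#' @param raster A `source_raster`.
#' @param corridor Polygon matrix (lon, lat).
#' @param threshold Mass fraction triggering exposure.
#' @param mask Optional precomputed logical cell-centre mask (internal
#'   fast path for raster series sharing one grid).
#' @return List with `corridor_fraction` and `exposed`.
#' @export
corridor_exposure <- function(raster, corridor, threshold = 0.05,
                              mask = NULL) {
  if (is.null(mask)) mask <- corridor_mask(raster, corridor)
  total <- sum(raster$values)
  frac <- if (total > 0) sum(raster$values[mask]) / total else 0
  list(corridor_fraction = frac, exposed = frac >= threshold)
}

#' @rdname corridor_exposure
#' @export
corridor_mask <- function(raster, corridor) {
  corridor <- as_polygon(corridor)
  lon <- rep(raster$lon, times = length(raster$lat))
  lat <- rep(raster$lat, each = length(raster$lon))
  matrix(poly_contains(corridor, lon, lat),
         nrow = length(raster$lon), ncol = length(raster$lat))
}

#' Plume-arrival bearing from backward trajectories
#'
#' For each particle, takes its position when it was last at least
#' `trail_m` from the receptor along its approach path (the first backward
#' step at which the particle's distance from the receptor reaches
#' `trail_m`) and returns the circular mean of the bearings from the
#' receptor toward those positions: the direction FROM which the arriving
#' air travelled its final approach.
#'
#' @param ensemble A `particle_ensemble` built with
#'   `store_trajectory = TRUE`.
#' @param trail_m Approach trail length in metres (30 km by default).
#' @return List with `bearing` (degrees in \[0, 360), `NA` if no particle
#'   ever reaches `trail_m`), the mean resultant length `r` of the
#'   per-particle bearings, and `n_used`.
#' @export
plume_bearing <- function(ensemble, trail_m = 30000) {
  if (is.null(ensemble$traj_lon)) {
    stopf("plume_bearing needs an ensemble built with store_trajectory = TRUE")
  }
  rec <- ensemble$receptor
  n <- nrow(ensemble$traj_lon)
  n_pos <- ncol(ensemble$traj_lon)
  crossing_lon <- crossing_lat <- rep(NA_real_, n)
  found <- rep(FALSE, n)
  for (k in 2:n_pos) {
    lon_k <- ensemble$traj_lon[, k]
    lat_k <- ensemble$traj_lat[, k]
    cand <- which(!found & !is.na(lon_k))
    if (!length(cand)) next
    d <- gc_distance(cbind(lon_k[cand], lat_k[cand]), c(rec$lon, rec$lat))
    hit <- d >= trail_m
    if (any(hit)) {
      idx <- cand[hit]
      crossing_lon[idx] <- lon_k[idx]
      crossing_lat[idx] <- lat_k[idx]
      found[idx] <- TRUE
    }
    if (all(found)) break
  }
  if (!any(found)) {
    return(list(bearing = NA_real_, r = NA_real_, n_used = 0L))
  }
  brg <- gc_bearing(matrix(c(rec$lon, rec$lat), sum(found), 2, byrow = TRUE),
                    cbind(crossing_lon[found], crossing_lat[found]))
  list(bearing = circ_mean_deg(brg), r = circ_r(brg), n_used = sum(found))
}

#' Before/after turn analysis around an exposure event
#'
#' Computes the flight bearing over the `before_m` window ending at the
#' event (bearing from the window start to the event position), the
#' bearing over the `after_m` window starting there, the signed turn
#' `delta` (positive clockwise, wrapped to (-180, 180\]), and the signed
#' angle between the plume-arrival bearing and the before-bearing.
#'
#' @param track The bird's hourly track tibble.
#' @param event List with at least `time` (the exposure instant, matching
#'   a track row) and `plume_bearing` (degrees).
#' @param before_m,after_m Along-path window lengths in metres.
#' @return One-row tibble: bearings, `delta`, `plume_relative_angle`, and
#'   window-completeness flags.
#' @export
turn_analysis <- function(track, event, before_m = 500000, after_m = 200000) {
  anchor <- which(as.numeric(track$time) == as.numeric(event$time))
  if (!length(anchor)) stopf("event time not found on the track")
  anchor <- anchor[1]
  win_b <- path_window(track, anchor, before_m, "before")
  win_a <- path_window(track, anchor, after_m, "after")
  if (nrow(win_b) < 2 || nrow(win_a) < 2) {
    stopf("event lies at a track endpoint; turn windows are empty")
  }
  p_evt <- c(track$lon[anchor], track$lat[anchor])
  bearing_before <- gc_bearing(c(win_b$lon[1], win_b$lat[1]), p_evt)
  bearing_after <- gc_bearing(p_evt, c(win_a$lon[nrow(win_a)],
                                       win_a$lat[nrow(win_a)]))
  pb <- event$plume_bearing %||% NA_real_
  tibble::tibble(
    bird_id = track$bird_id[1] %||% NA_character_,
    bearing_before = bearing_before,
    bearing_after = bearing_after,
    delta = ang_diff(bearing_after, bearing_before),
    plume_bearing = pb,
    plume_relative_angle = if (is.na(pb)) NA_real_ else
      ang_diff(pb, bearing_before),
    before_complete = attr(win_b, "complete"),
    after_complete = attr(win_a, "complete")
  )
}

#' Classify reorientation from turn records
#'
#' A bird counts as reoriented when it was exposed and its after-bearing is
#' closer to the plume-arrival bearing than its before-bearing was, by at
#' least `min_improvement` degrees — the operational reading of "changed
#' its flight direction towards the corridor".
#'
#' @param turns Tibble of turn records ([turn_analysis()] rows) with an
#'   `exposed` column.
#' @param min_improvement Required angular improvement toward the plume
#'   bearing, degrees.
#' @return `turns` with `improvement` and `reoriented` columns added.
#' @export
classify_reorientation <- function(turns, min_improvement = 8) {
  dplyr::mutate(
    turns,
    improvement = abs(.data$plume_relative_angle) -
      abs(ang_diff(.data$bearing_after, .data$plume_bearing)),
    reoriented = .data$exposed & !is.na(.data$improvement) &
      .data$improvement >= min_improvement
  )
}

#' V test for a prespecified direction
#'
#' Circular test of concentration around a known direction `mu0`:
#' `V = n * r * cos(mean - mu0)`, `u = V * sqrt(2 / n)`, with a one-sided
#' p-value from the standard normal upper tail of `u`.
#'
#' @param angles Angles in degrees (n >= 2).
#' @param mu0 Hypothesised direction, degrees.
#' @return An object of class `circ_test`.
#' @export
v_test <- function(angles, mu0) {
  n <- length(angles)
  if (n < 2) stopf("v_test needs n >= 2 angles")
  r <- circ_r(angles)
  mean_dir <- circ_mean_deg(angles)
  v <- n * r * (if (is.na(mean_dir)) 0 else cos(deg2rad(mean_dir - mu0)))
  u <- v * sqrt(2 / n)
  structure(
    list(method = "V test", n = n,
         mean_direction = mean_dir, r = r,
         statistic = c(V = v, u = u),
         p_value = stats::pnorm(u, lower.tail = FALSE),
         mu0 = mu0),
    class = "circ_test"
  )
}

#' Paired Hotelling test on circular data
#'
#' Two-dimensional paired test on the unit-vector differences of before /
#' after directions: with `d_i = (cos a_i - cos b_i, sin a_i - sin b_i)`,
#' `T2 = n * t(dbar) %*% solve(S) %*% dbar` (S the sample covariance of
#' the d_i) and `F = (n - 2) / (2 * (n - 1)) * T2` referred to an F
#' distribution with (2, n - 2) degrees of freedom. When every pair is
#' identical (all differences zero) the result is reported as no change
#' with p = 1 by convention; any other singular covariance is an error.
#'
#' @param before,after Equal-length angle vectors in degrees, n >= 3.
#' @return An object of class `circ_test`.
#' @export
hotelling_paired <- function(before, after) {
  n <- length(before)
  if (length(after) != n) stopf("before and after must have equal length")
  if (n < 3) stopf("hotelling_paired needs n >= 3 pairs")
  a <- deg2rad(after); b <- deg2rad(before)
  d <- cbind(cos(a) - cos(b), sin(a) - sin(b))
  if (max(abs(d)) < 1e-12) {
    return(structure(
      list(method = "Paired Hotelling test (circular)", n = n,
           mean_direction = NA_real_, r = NA_real_,
           statistic = c(T2 = 0, F = 0), p_value = 1,
           note = "all paired differences are zero"),
      class = "circ_test"))
  }
  S <- stats::cov(d)
  if (rcond(S) < 1e-12) {
    stopf("singular covariance of the paired difference vectors")
  }
  dbar <- colMeans(d)
  t2 <- n * drop(t(dbar) %*% solve(S, dbar))
  f <- (n - 2) / (2 * (n - 1)) * t2
  structure(
    list(method = "Paired Hotelling test (circular)", n = n,
         mean_direction = circ_mean_deg(after), r = circ_r(after),
         statistic = c(T2 = t2, F = f),
         p_value = stats::pf(f, 2, n - 2, lower.tail = FALSE)),
    class = "circ_test"
  )
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("<circ_test> %s: n = %d, %s, p = %.4g\n", x$method, x$n,
              paste(names(x$statistic), signif(x$statistic, 4),
                    sep = " = ", collapse = ", "),
              x$p_value))
  invisible(x)
}

#' @export
tidy.circ_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n,
    statistic = unname(x$statistic[1]),
    derived_statistic = unname(x$statistic[2]),
    mean_direction = x$mean_direction, r = x$r,
    p_value = x$p_value
  )
}

#' @export
glance.circ_test <- function(x, ...) tidy(x)

#' Pearson chi-square test on a contingency table
#'
#' Standard Pearson X^2 with expected counts from the row/column margins,
#' `df = (rows - 1) * (cols - 1)`, upper-tail chi-square p-value, no
#' continuity correction by default. A zero row or column margin is an
#' error.
#'
#' @param table Nonnegative integer counts, at least 2 x 2.
#' @param correct Apply the Yates continuity correction (2 x 2 only)?
#' @return An object of class `contingency_test`: `statistic`, `df`,
#'   `p_value`, `expected`, `observed`.
#' @export
chi_square_contingency <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stopf("contingency table must hold nonnegative integer counts")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("zero row or column margin; the test is undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, expected = ht$expected, observed = tab),
    class = "contingency_test"
  )
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("<contingency_test> X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.contingency_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Turn angle vs plume-arrival angle regression
#'
#' Ordinary least squares of the signed turn `delta` on the signed
#' plume-relative arrival angle (both wrapped to (-180, 180\]), with the
#' Pearson correlation and its t-test p-value — the synthetic counterpart
#' of relating reorientation magnitude to how the aerial information
#' arrived relative to the flight direction.
#'
#' @param records Tibble of turn records with `delta` and
#'   `plume_relative_angle` (n >= 3).
#' @return An object of class `turn_relation`: `slope`, `intercept`,
#'   `correlation`, `p_value`, `n` and the `lm` fit.
#' @export
angle_turn_relation <- function(records) {
  rec <- dplyr::filter(records, is.finite(.data$delta),
                       is.finite(.data$plume_relative_angle))
  if (nrow(rec) < 3) stopf("angle_turn_relation needs n >= 3 records")
  x <- wrap180(rec$plume_relative_angle)
  y <- wrap180(rec$delta)
  if (stats::sd(x) == 0) stopf("zero variance in the plume-relative angle")
  fit <- stats::lm(y ~ x)
  if (stats::sd(y) == 0) {
    ct <- list(estimate = c(cor = 0), p.value = 1)
  } else {
    ct <- stats::cor.test(x, y)
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         correlation = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(rec), fit = fit),
    class = "turn_relation"
  )
}

#' @export
print.turn_relation <- function(x, ...) {
  cat(sprintf("<turn_relation> slope = %.3f, r = %.3f, p = %.4g, n = %d\n",
              x$slope, x$correlation, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.turn_relation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 correlation = x$correlation, p_value = x$p_value, n = x$n)
}
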