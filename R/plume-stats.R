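#' Pearson correlation between two source rasters
#'
#' Flattens both rasters (which must share a grid) and returns the Pearson
#' correlation over all cells. Returns `NA` (the undefined marker) when
#' either raster has zero variance.
#'
#' @param r1,r2 `source_raster` objects on identical grids.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
raster_correlation <- function(r1, r2) {
  if (!isTRUE(all.equal(r1$lon, r2$lon)) ||
      !isTRUE(all.equal(r1$lat, r2$lat))) {
    stopf("raster grids do not match")
  }
  v1 <- as.vector(r1$values); v2 <- as.vector(r2$values)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Time-lag correlogram of dispersion rasters
#'
#' For each bird and each lag from 1 to `max_lag` hours, samples up to
#' `pairs_per_lag` random ordered raster pairs separated by exactly that
#' lag (without replacement), averages their Pearson correlation, and
#' summarises the per-bird means into a grand mean and standard deviation
#' across birds. Pairs involving a zero-variance raster are skipped. Lags
#' with no available pairs are omitted. Deterministic given `seed`.
#'
#' @param raster_series Named list (one element per bird) of lists of
#'   `source_raster` objects with hourly receptor timestamps.
#' @param max_lag Maximum lag in hours.
#' @param pairs_per_lag Pairs sampled per bird and lag.
#' @param seed Integer seed for the pair sampling.
#'
#' @return An object of class `plume_correlogram`: tibbles `by_bird`
#'   (`bird_id`, `lag`, `mean_r`, `n_pairs`) and `summary` (`lag`,
#'   `grand_mean`, `grand_sd`, `n_birds`).
#' @export
correlogram <- function(raster_series, max_lag = 48, pairs_per_lag = 50,
                        seed = 1L) {
  if (!length(raster_series)) stopf("empty raster series")
  if (is.null(names(raster_series))) {
    names(raster_series) <- sprintf("bird%02d", seq_along(raster_series))
  }
  by_bird <- purrr::imap_dfr(raster_series, function(rasters, id) {
    if (length(rasters) < 2) stopf("need >= 2 rasters per bird ('%s')", id)
    th <- round(purrr::map_dbl(rasters, ~ as.numeric(.x$receptor$time)) / 3600)
    rows <- withr::with_seed(derive_seed(seed, match(id, names(raster_series))), {
      purrr::map_dfr(seq_len(max_lag), function(lag) {
        i <- which((th + lag) %in% th)
        if (!length(i)) return(NULL)
        j <- match(th[i] + lag, th)
        take <- sample.int(length(i), min(pairs_per_lag, length(i)))
        rs <- purrr::map_dbl(take, function(k)
          raster_correlation(rasters[[i[k]]], rasters[[j[k]]]))
        rs <- rs[!is.na(rs)]
        if (!length(rs)) return(NULL)
        tibble::tibble(lag = lag, mean_r = mean(rs), n_pairs = length(rs))
      })
    })
    dplyr::mutate(rows, bird_id = id, .before = 1)
  })
  summary <- by_bird |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(grand_mean = mean(.data$mean_r),
                     grand_sd = stats::sd(.data$mean_r),
                     n_birds = dplyr::n(), .groups = "drop")
  structure(list(by_bird = by_bird, summary = summary,
                 pairs_per_lag = pairs_per_lag),
            class = "plume_correlogram")
}

#' @export
print.plume_correlogram <- function(x, ...) {
  cat(sprintf("<plume_correlogram> %d birds, lags %d..%d h\n",
              length(unique(x$by_bird$bird_id)), min(x$summary$lag),
              max(x$summary$lag)))
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' @export
tidy.plume_correlogram <- function(x, ...) x$by_bird

#' @export
glance.plume_correlogram <- function(x, ...) {
  tibble::tibble(
    n_birds = length(unique(x$by_bird$bird_id)),
    n_lags = nrow(x$summary),
    mean_r_lag1 = x$summary$grand_mean[x$summary$lag == min(x$summary$lag)],
    mean_r_max_lag = x$summary$grand_mean[x$summary$lag == max(x$summary$lag)]
  )
}

#' Accumulated-particle score of one bird
#'
#' For each hourly raster at time t, samples the raster at the bird's
#' positions later than t that pass the activity filter (ground speed of at
#' least `v_min` to the next fix), sums those samples over all rasters, and
#' divides by the number of track locations. This is the per-bird measure
#' of how much modelled plume material the bird's (future, actively moving)
#' path intersects.
#'
#' @param raster_series List of `source_raster` objects for the bird, with
#'   receptor timestamps matching track rows.
#' @param track The bird's hourly track tibble.
#' @param v_min Activity threshold, m/s.
#' @param positions Sample at positions strictly later than each raster
#'   (`"future"`, default) or only at the concurrent position
#'   (`"current"`).
#' @param denominator Normalise by all track locations (`"all"`, default)
#'   or active ones only.
#' @param method Raster sampling, `"bilinear"` or `"nearest"`.
#'
#' @return One-row tibble: `bird_id`, `group`, `total`, `n_locations`,
#'   `score`.
#' @export
accumulation_score <- function(raster_series, track, v_min = 2,
                               positions = c("future", "current"),
                               denominator = c("all", "active"),
                               method = "bilinear") {
  positions <- match.arg(positions)
  denominator <- match.arg(denominator)
  active <- active_mask(track, v_min)
  n_loc <- if (denominator == "all") nrow(track) else sum(active)
  if (n_loc == 0) {
    warnf("no locations pass the activity filter; score is 0")
    n_loc <- nrow(track)
  }
  th <- as.numeric(track$time)
  total <- 0
  for (r in raster_series) {
    t0 <- as.numeric(r$receptor$time)
    idx <- if (positions == "future") which(th > t0 & active) else
      which(th == t0 & active)
    if (length(idx)) {
      total <- total + sum(sample_raster(r, track$lon[idx], track$lat[idx],
                                         method = method))
    }
  }
  tibble::tibble(
    bird_id = track$bird_id[1] %||% NA_character_,
    group = track$group[1] %||% NA_character_,
    total = total, n_locations = n_loc, score = total / n_loc
  )
}

#' Compare accumulation scores between treatment groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the per-bird scores
#' by group: exact null distribution when the combined sample size is at
#' most 20 and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param scores Tibble with columns `score` and `group` (exactly two
#'   groups, both non-empty).
#' @return An object of class `group_comparison`: `statistic` (W),
#'   `p_value`, `medians`, `method`.
#' @export
compare_groups <- function(scores) {
  groups <- unique(scores$group)
  if (length(groups) != 2 || any(table(scores$group) < 1)) {
    stopf("compare_groups needs exactly two non-empty groups")
  }
  x <- scores$score[scores$group == groups[1]]
  y <- scores$score[scores$group == groups[2]]
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         medians = tibble::tibble(group = groups,
                                  median = c(stats::median(x),
                                             stats::median(y)),
                                  n = c(length(x), length(y))),
         method = ht$method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> W = %g, p = %.4g\n", x$statistic, x$p_value))
  print(x$medians)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method)
}
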