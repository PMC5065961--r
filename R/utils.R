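# Internal helpers shared across modules.

# Metres per degree of latitude on the 6371 km sphere; longitude scales by
# cos(latitude). Small-displacement geodesy used by the particle stepper.
M_PER_DEG <- 111195

EARTH_RADIUS_M <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
wrap360 <- function(x) x %% 360

# Signed wrap to (-180, 180], positive clockwise.
#' @keywords internal
wrap180 <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

# Signed angular difference a - b wrapped to (-180, 180].
ang_diff <- function(a, b) wrap180(a - b)

# Circular mean of bearings in degrees; NA when the resultant vanishes.
circ_mean_deg <- function(x) {
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < .Machine$double.eps^0.5) return(NA_real_)
  wrap360(rad2deg(atan2(s, c)))
}

# Mean resultant length of angles in degrees.
circ_r <- function(x) {
  sqrt(mean(sin(deg2rad(x)))^2 + mean(cos(deg2rad(x)))^2)
}

# Deterministic derived seed, kept within 32-bit integer range so that
# per-receptor and per-agent streams are reproducible independent of
# execution order.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(index) * 7919 + 1) %%
               2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
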