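# Polygon helpers and GeoJSON / CSV interfaces.

#' Coerce to a polygon matrix
#'
#' Polygons are plain two-column numeric matrices (lon, lat, WGS84 degrees);
#' an unclosed ring is accepted and treated as closed.
#'
#' @param x A two-column matrix/data frame, or a list with `lon` and `lat`.
#' @return A two-column numeric matrix with columns `lon`, `lat`.
#' @export
as_polygon <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$lon)) {
    x <- cbind(x$lon, x$lat)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2 || nrow(x) < 3 || !all(is.finite(x))) {
    stopf("a polygon needs >= 3 finite (lon, lat) vertices")
  }
  storage.mode(x) <- "double"
  colnames(x) <- c("lon", "lat")
  x
}

#' Rectangle polygon from bounds
#'
#' @param lon,lat Length-2 numeric ranges in degrees.
#' @return A polygon matrix (counter-clockwise rectangle).
#' @export
rect_polygon <- function(lon, lat) {
  as_polygon(cbind(c(lon[1], lon[2], lon[2], lon[1]),
                   c(lat[1], lat[1], lat[2], lat[2])))
}

# Point-in-polygon test on cell centres / track points.
poly_contains <- function(poly, lon, lat) {
  poly <- as_polygon(poly)
  as.logical(pracma::inpolygon(lon, lat, poly[, 1], poly[, 2],
                               boundary = TRUE))
}

# Area centroid (shoelace); falls back to the vertex mean for degenerate
# rings.
poly_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x, x[1]); ys <- c(y, y[1])
  cr <- xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(lon = mean(x), lat = mean(y)))
  c(lon = sum((xs[-length(xs)] + xs[-1]) * cr) / (6 * a),
    lat = sum((ys[-length(ys)] + ys[-1]) * cr) / (6 * a))
}

#' Read / write GeoJSON polygons
#'
#' Minimal GeoJSON (RFC 7946) Polygon/MultiPolygon interface; MultiPolygons
#' are read as a list of rings, of which the first is returned with a
#' warning.
#'
#' @param poly Polygon matrix (lon, lat).
#' @param path File path.
#' @return The polygon matrix (reader); `path`, invisibly (writer).
#' @export
write_geojson_polygon <- function(poly, path) {
  poly <- as_polygon(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])  # closed ring per RFC 7946
  gj <- list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                      c(ring[i, 1], ring[i, 2])))),
    properties = list()
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_polygon
#' @export
read_geojson_polygon <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- if (!is.null(gj$geometry)) gj$geometry else gj
  coords <- geom$coordinates
  if (identical(geom$type, "MultiPolygon")) {
    if (length(coords) > 1) warnf("MultiPolygon in '%s': using first part", path)
    coords <- coords[[1]]
  } else if (!identical(geom$type, "Polygon")) {
    stopf("'%s' does not contain a Polygon geometry", path)
  }
  ring <- do.call(rbind, lapply(coords[[1]], function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  # drop the closing vertex
  if (nrow(ring) > 3 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  as_polygon(ring)
}
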