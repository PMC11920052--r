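#' Construct a reservoir polygon table
#'
#' Reservoir footprints are simple closed polygons (one outer ring, no holes)
#' in the same planar y-down frame as [pop_grid()]. They are carried as a
#' tibble with one row per polygon: an `id`, the ring as a two-column
#' `(x, y)` matrix in a list-column, and the shoelace area in km².
#'
#' @param id Character vector of unique polygon ids.
#' @param ring A single two-column matrix, or a list of them (one per id).
#'   Rings must have at least 3 vertices, be non-self-intersecting, and
#'   enclose a positive area; the closing vertex must not be repeated.
#' @return A tibble with columns `id`, `ring` (list of matrices), `area_km2`.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' reservoir_polygons(id = "r1", ring = sq)
#' @export
reservoir_polygons <- function(id, ring) {
  if (is.matrix(ring)) ring <- list(ring)
  id <- as.character(id)
  if (length(id) != length(ring)) {
    stop("`id` and `ring` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate polygon id(s): %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")), call. = FALSE)
  }
  ring <- purrr::map2(ring, id, validate_ring)
  tibble::tibble(
    id = id,
    ring = ring,
    area_km2 = purrr::map_dbl(ring, polygon_area_km2)
  )
}

validate_ring <- function(ring, id = "?") {
  if (!is.matrix(ring) || ncol(ring) != 2 || !is.numeric(ring)) {
    stop(sprintf("polygon '%s': ring must be a numeric matrix with 2 columns", id),
         call. = FALSE)
  }
  storage.mode(ring) <- "double"
  # drop an explicitly repeated closing vertex
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) {
    stop(sprintf("polygon '%s': a ring needs at least 3 distinct vertices", id),
         call. = FALSE)
  }
  if (anyNA(ring) || any(!is.finite(ring))) {
    stop(sprintf("polygon '%s': non-finite vertex coordinates", id), call. = FALSE)
  }
  if (ring_self_intersects(ring)) {
    stop(sprintf("polygon '%s': ring is self-intersecting", id), call. = FALSE)
  }
  if (polygon_area_km2(ring) <= 0) {
    stop(sprintf("polygon '%s': zero enclosed area", id), call. = FALSE)
  }
  colnames(ring) <- c("x", "y")
  ring
}

# Check whether any two non-adjacent edges of the ring properly intersect.
# O(V^2); rings here have tens of vertices at most.
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # skip edges sharing a vertex with edge i
    if (!length(js)) next
    if (any(segments_cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2],
                           a[js, 1], a[js, 2], b[js, 1], b[js, 2]))) {
      return(TRUE)
    }
  }
  FALSE
}

# Proper crossing of segment (x1,y1)-(x2,y2) with segments (x3,y3)-(x4,y4);
# vectorised over the second set.
segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
  d2 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
  d3 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d4 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Shoelace area of a polygon ring, in square kilometres
#'
#' Orientation-independent: clockwise and counter-clockwise rings give the
#' same (positive) area.
#'
#' @param ring Two-column `(x, y)` vertex matrix in metres (closing vertex
#'   optional).
#' @return Enclosed area in km².
#' @examples
#' polygon_area_km2(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
#' @export
polygon_area_km2 <- function(ring) {
  stopifnot(is.matrix(ring), ncol(ring) == 2)
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  x <- ring[, 1]
  y <- ring[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 / 1e6
}

polygon_centroid <- function(ring) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Shrink a polygon toward its centroid by a target area fraction
#'
#' Scales every vertex toward the area centroid by `sqrt(1 - s)`, so the new
#' area is exactly `(1 - s)` times the old one while the centroid stays put.
#' This is how the synthetic world reproduces the systematic
#' under-representation of reservoir extents by satellite-derived polygons.
#'
#' @param ring Two-column vertex matrix (metres).
#' @param s Area fraction to remove, in `[0, 1)`; `s = 0.188` shrinks a
#'   polygon to 81.2% of its area.
#' @return The shrunken ring matrix.
#' @export
shrink_polygon <- function(ring, s) {
  stopifnot(is.numeric(s), length(s) == 1, s >= 0, s < 1)
  ring <- validate_ring(ring)
  if (s == 0) return(ring)
  ctr <- polygon_centroid(ring)
  k <- sqrt(1 - s)
  out <- sweep(sweep(ring, 2, ctr) * k, 2, ctr, "+")
  colnames(out) <- c("x", "y")
  out
}

#' Point-in-polygon test (centroid membership rule)
#'
#' Even-odd (crossing-number) membership, vectorised over points. Points that
#' lie exactly on the boundary count as inside — a consistent, measure-zero
#' choice that makes the centroid zonal rule deterministic.
#'
#' @param px,py Numeric vectors of point coordinates (metres).
#' @param ring Two-column vertex matrix.
#' @return Logical vector, `TRUE` where the point is inside or on the ring.
#' @export
point_in_polygon <- function(px, py, ring) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, length(px) == length(py))
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  scale <- max(abs(ring)) + 1
  tol <- 1e-9 * scale
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (i in seq_len(n)) {
    xi <- x1[i]; yi <- y1[i]; xj <- x2[i]; yj <- y2[i]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # boundary: distance from point to segment i within tol
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    ex <- px - (xi + t * dx); ey <- py - (yi + t * dy)
    on_edge <- on_edge | (ex * ex + ey * ey <= tol * tol)
  }
  inside | on_edge
}

#' Read and write reservoir polygons as GeoJSON
#'
#' The on-disk format is a GeoJSON `FeatureCollection` with one `Polygon` per
#' feature and the polygon id in the `id` property. Only single outer rings
#' are supported (no holes, no multipolygons), matching the planar geometry
#' model of the package. Coordinates are planar metres in the package's
#' y-down frame, not longitude/latitude.
#'
#' @param path Path to a `.geojson` file.
#' @return `read_reservoir_polygons()` returns the tibble described in
#'   [reservoir_polygons()]; `write_reservoir_polygons()` returns `path`
#'   invisibly.
#' @name polygon_io
NULL

#' @rdname polygon_io
#' @export
read_reservoir_polygons <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("polygon file not found: %s", path), call. = FALSE)
  }
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop(sprintf("%s: expected a GeoJSON FeatureCollection", path), call. = FALSE)
  }
  feats <- gj$features
  ids <- character(length(feats))
  rings <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    if (is.null(f$properties$id)) {
      stop(sprintf("%s: feature %d has no 'id' property", path, k), call. = FALSE)
    }
    ids[k] <- as.character(f$properties$id)
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon") {
      stop(sprintf("polygon '%s': unsupported geometry type '%s'",
                   ids[k], geom$type %||% "NULL"), call. = FALSE)
    }
    if (length(geom$coordinates) != 1) {
      stop(sprintf("polygon '%s': holes are not supported", ids[k]), call. = FALSE)
    }
    coords <- geom$coordinates[[1]]
    mat <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    rings[[k]] <- mat
  }
  reservoir_polygons(ids, rings)
}

#' @rdname polygon_io
#' @param polygons Tibble from [reservoir_polygons()].
#' @export
write_reservoir_polygons <- function(polygons, path) {
  stopifnot(all(c("id", "ring") %in% names(polygons)))
  features <- purrr::map2(polygons$id, polygons$ring, function(id, ring) {
    closed <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
    list(
      type = "Feature",
      properties = list(id = id),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
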