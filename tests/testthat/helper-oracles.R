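# Independent oracles, deliberately written as slow scalar loops so they share
# no code path with the vectorised implementations they check.

# Scalar crossing-number point-in-polygon with boundary counted as inside.
oracle_pip <- function(x, y, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    # on-segment check
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((x - xi) * dx + (y - yi) * dy) / len2
      t <- min(1, max(0, t))
      if ((x - (xi + t * dx))^2 + (y - (yi + t * dy))^2 < 1e-12) return(TRUE)
    }
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive refined-centroid enumeration: tests every refined centroid of the
# whole grid independently, one scalar point-in-polygon call each.
oracle_zonal <- function(grid, ring, r) {
  cs <- grid$cell_size / r
  total <- 0
  for (i in seq_len(nrow(grid$counts) * r)) {
    for (j in seq_len(ncol(grid$counts) * r)) {
      cx <- grid$origin_x + (j - 0.5) * cs
      cy <- grid$origin_y + (i - 0.5) * cs
      if (oracle_pip(cx, cy, ring)) {
        total <- total + grid$counts[ceiling(i / r), ceiling(j / r)] / r^2
      }
    }
  }
  total
}

# Random convex ring (convex hull of uniform points), coordinates in metres.
random_test_ring <- function(cx, cy, radius, n_points = 10L) {
  repeat {
    pts <- cbind(runif(n_points, -radius, radius), runif(n_points, -radius, radius))
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3) break
  }
  sweep(pts[hull, , drop = FALSE], 2, c(cx, cy), "+")
}

# A tiny but complete record tibble with sensible defaults.
make_record <- function(id, area = 4, year = 1990L, resettled = 400,
                        country = "BRA", income = "low",
                        transboundary = FALSE, preexisting = FALSE) {
  tibble::tibble(
    id = id, country = country, income_level = income,
    completion_year = as.integer(year), reported_area_km2 = area,
    resettled_persons = resettled,
    excluded_transboundary = transboundary,
    excluded_preexisting = preexisting
  )
}

# Small-world config used by pipeline-level tests.
small_world_config <- function(seed = 11, ...) {
  synthetic_world_config(
    seed = seed,
    extent_m = 20000, true_cell_size_m = 100,
    n_clusters = 4, cluster_intensity = 5000, cluster_spread_m = 800,
    background_density_per_km2 = 20,
    n_reservoirs = 12, area_range_km2 = c(1, 8),
    dataset_specs = tibble::tibble(
      dataset = c("fine", "coarse"),
      beta = c(1, 0.5),
      realloc_fraction = c(0, 0.2),
      realloc_radius_m = c(0, 300),
      out_cell_size_m = c(100, 1000),
      year_min = c(1975L, 1975L), year_max = c(2010L, 2010L)
    ),
    ...
  )
}
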