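#' Construct a population grid
#'
#' A `pop_grid` is a planar raster of person counts: a numeric matrix plus the
#' georeferencing needed to place every cell in a Cartesian plane measured in
#' metres. The coordinate convention follows raster order: the origin is the
#' grid's upper-left corner and y increases downward, so the centroid of cell
#' `(r, c)` (1-based) sits at
#' `(origin_x + (c - 0.5) * cell_size, origin_y + (r - 0.5) * cell_size)`.
#'
#' Counts are real-valued, not integers: gridded population products store
#' fractional persons after dasymetric disaggregation.
#'
#' @param counts Numeric matrix of persons per cell; all values finite and
#'   non-negative.
#' @param cell_size Cell edge length in metres (> 0); cells are square.
#' @param origin_x,origin_y Planar coordinates (metres) of the upper-left
#'   corner of the grid.
#' @param reference_year Integer year the grid represents, or `NA` if unknown.
#' @param dataset_name Label for the dataset the grid belongs to, or `NA`.
#'
#' @return An object of class `pop_grid`.
#' @examples
#' g <- pop_grid(matrix(1:4, 2, 2), cell_size = 100)
#' grid_total(g)
#' @export
pop_grid <- function(counts, cell_size, origin_x = 0, origin_y = 0,
                     reference_year = NA_integer_, dataset_name = NA_character_) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("grid counts must all be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("grid counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      cell_size = as.numeric(cell_size),
      origin_x = as.numeric(origin_x),
      origin_y = as.numeric(origin_y),
      reference_year = as.integer(reference_year),
      dataset_name = as.character(dataset_name)
    ),
    class = "pop_grid"
  )
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf(
    "<pop_grid> %d x %d cells of %g m  |  dataset: %s  year: %s\n",
    nrow(x$counts), ncol(x$counts), x$cell_size,
    ifelse(is.na(x$dataset_name), "?", x$dataset_name),
    ifelse(is.na(x$reference_year), "?", x$reference_year)
  ))
  cat(sprintf(
    "  origin (%g, %g) m, extent %g x %g km, total population %.2f\n",
    x$origin_x, x$origin_y,
    ncol(x$counts) * x$cell_size / 1000, nrow(x$counts) * x$cell_size / 1000,
    grid_total(x)
  ))
  invisible(x)
}

#' Total population of a grid
#'
#' @param grid A [pop_grid()].
#' @return Sum of all cell counts.
#' @export
grid_total <- function(grid) {
  stopifnot(inherits(grid, "pop_grid"))
  sum(grid$counts)
}

#' Refine a grid to a finer resolution, conserving mass
#'
#' Each coarse cell of size `s` is split into `factor^2` children of size
#' `s / factor`, and the coarse count is distributed evenly among them. This
#' mirrors the mass-preserving refinement used before centroid-based zonal
#' extraction: totals at the native resolution are kept, only re-expressed on
#' a finer lattice.
#'
#' @param grid A [pop_grid()].
#' @param factor Positive integer refinement factor; `factor = 1` returns the
#'   grid unchanged.
#' @return A `pop_grid` with `factor`-times smaller cells and identical total
#'   population.
#' @seealso [aggregate_grid()] for the exact inverse.
#' @examples
#' refine_grid(pop_grid(matrix(3), cell_size = 300), factor = 3)$counts
#' @export
refine_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "pop_grid"))
  factor <- check_factor(factor)
  if (factor == 1L) return(grid)
  m <- grid$counts / factor^2
  fine <- m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor),
            drop = FALSE]
  pop_grid(fine, grid$cell_size / factor, grid$origin_x, grid$origin_y,
           grid$reference_year, grid$dataset_name)
}

#' Aggregate a grid to a coarser resolution, conserving mass
#'
#' Each block of `factor x factor` cells is summed into one coarse cell.
#' `aggregate_grid(refine_grid(g, k), k)` recovers `g` exactly.
#'
#' @param grid A [pop_grid()] whose row and column counts are divisible by
#'   `factor`.
#' @param factor Positive integer aggregation factor.
#' @return A `pop_grid` with `factor`-times larger cells and identical total
#'   population.
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "pop_grid"))
  factor <- check_factor(factor)
  if (factor == 1L) return(grid)
  m <- grid$counts
  if (nrow(m) %% factor != 0 || ncol(m) %% factor != 0) {
    stop(sprintf("grid dimensions %d x %d are not divisible by factor %d",
                 nrow(m), ncol(m), factor), call. = FALSE)
  }
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  # sum factor x factor blocks: collapse rows, then columns
  row_grp <- rep(seq_len(nr), each = factor)
  col_grp <- rep(seq_len(nc), each = factor)
  m2 <- rowsum(m, row_grp, reorder = TRUE)
  m2 <- t(rowsum(t(m2), col_grp, reorder = TRUE))
  dimnames(m2) <- NULL
  pop_grid(m2, grid$cell_size * factor, grid$origin_x, grid$origin_y,
           grid$reference_year, grid$dataset_name)
}

check_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer >= 1", call. = FALSE)
  }
  as.integer(factor)
}
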