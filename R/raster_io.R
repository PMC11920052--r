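#' Read and write population rasters
#'
#' Rasters are stored as ESRI ASCII grids (`.asc`), a plain-text raster format
#' with a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of cell values, top row first.
#' Because the package works in a planar, y-down raster frame (see
#' [pop_grid()]), `xllcorner`/`yllcorner` record the grid origin — the corner
#' of the first cell of the first row — rather than a map-display corner; a
#' file written and read by this package round-trips exactly.
#'
#' Dataset metadata (`reference_year`, `dataset_name`) does not fit the ASCII
#' grid header, so it rides in a JSON sidecar at `<path>.meta.json`. If the
#' sidecar is missing the caller must supply both values; they are never
#' guessed.
#'
#' Nodata cells are treated as zero population on read; the number of such
#' cells is reported in a message and recorded in the `nodata_cells` attribute
#' of the returned grid.
#'
#' @param path Path to the `.asc` file.
#' @param reference_year,dataset_name Metadata used when the sidecar file is
#'   absent. Ignored (with a warning on conflict) when the sidecar is present.
#' @return `read_population_raster()` returns a [pop_grid()];
#'   `write_population_raster()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' g <- pop_grid(matrix(c(1, 2, 3, 4), 2, 2), cell_size = 100,
#'               reference_year = 2000, dataset_name = "demo")
#' write_population_raster(g, f)
#' grid_total(read_population_raster(f))
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
read_population_raster <- function(path, reference_year = NULL, dataset_name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, n = 6L)
  is_hdr <- grepl("^\\s*[A-Za-z]", lines)
  hdr <- list()
  for (ln in lines[is_hdr]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) {
    stop(sprintf("malformed ASCII grid header in %s", path), call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- sum(is_hdr)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d cell values in %s, found %d",
                 nr * nc, path, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  is_nodata <- m == nodata
  n_nodata <- sum(is_nodata)
  if (n_nodata > 0) {
    m[is_nodata] <- 0
    message(sprintf("read_population_raster: %d nodata cell(s) in %s treated as 0",
                    n_nodata, basename(path)))
  }
  if (any(m < 0)) {
    stop(sprintf("raster %s contains negative counts", path), call. = FALSE)
  }

  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(reference_year) && !identical(as.integer(reference_year),
                                               as.integer(meta$reference_year))) {
      warning("supplied reference_year differs from sidecar metadata; using sidecar",
              call. = FALSE)
    }
    reference_year <- meta$reference_year
    dataset_name <- meta$dataset_name
  } else if (is.null(reference_year) || is.null(dataset_name)) {
    stop(sprintf(paste0("no metadata sidecar at %s: supply `reference_year` and ",
                        "`dataset_name` explicitly"), meta_path), call. = FALSE)
  }

  g <- pop_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                reference_year, dataset_name)
  attr(g, "nodata_cells") <- n_nodata
  g
}

#' @rdname raster_io
#' @param grid A [pop_grid()] to write.
#' @export
write_population_raster <- function(grid, path) {
  stopifnot(inherits(grid, "pop_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  }
  m <- grid$counts
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999"
  )
  body <- vapply(seq_len(nrow(m)),
                 function(r) paste(sprintf("%.15g", m[r, ]), collapse = " "),
                 character(1))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(
    list(reference_year = grid$reference_year, dataset_name = grid$dataset_name),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, null = "null", na = "null"
  )
  invisible(path)
}
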