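#' Define the analysis lattice
#'
#' Every raster, occurrence assignment and cell index in the package refers to
#' one `grid_spec`: a regular lattice in decimal degrees anchored at its
#' north-west corner. Cell `(row, col)` (0-based, row 0 northernmost) covers
#' the half-open box `[lon_min + col*res, lon_min + (col+1)*res)` in longitude
#' and `(lat_max - (row+1)*res, lat_max - row*res]` in latitude, so every
#' in-grid point belongs to exactly one cell. Cell ids are row-major:
#' `cell_id = row * ncols + col`.
#'
#' @param lon_min Western edge of the grid (decimal degrees).
#' @param lat_max Northern edge of the grid (decimal degrees).
#' @param resolution Cell side in decimal degrees. Default 0.083, roughly a
#'   9-km cell at the equator.
#' @param nrows,ncols Grid dimensions (rows count southwards).
#' @param cell_area_km2 Nominal area of one cell, used only for reporting
#'   range sizes in km2. Default 85 (a 0.083-degree cell near the equator).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min = -74, lat_max = 5, resolution = 0.083,
                      nrows = 40, ncols = 40, cell_area_km2 = 85) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    stop("`resolution` must be a single positive number.", call. = FALSE)
  }
  for (nm in c("nrows", "ncols")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop("`", nm, "` must be a positive whole number.", call. = FALSE)
    }
  }
  if (!is.numeric(cell_area_km2) || cell_area_km2 <= 0) {
    stop("`cell_area_km2` must be positive.", call. = FALSE)
  }
  structure(
    list(lon_min = lon_min, lat_max = lat_max, resolution = resolution,
         nrows = as.integer(nrows), ncols = as.integer(ncols),
         cell_area_km2 = cell_area_km2),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells at %g deg, NW corner (%g, %g), %g km2/cell\n",
    x$nrows, x$ncols, x$resolution, x$lon_min, x$lat_max, x$cell_area_km2))
  invisible(x)
}

n_cells <- function(grid) grid$nrows * grid$ncols

#' Enumerate grid cells as a tibble
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `cell_id` (0-based, row-major),
#'   `row`, `col` (0-based), and the cell-centre coordinates `lon`, `lat`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$nrows) - 1L, each = grid$ncols)
  col <- rep(seq_len(grid$ncols) - 1L, times = grid$nrows)
  tibble::tibble(
    cell_id = row * grid$ncols + col,
    row = row, col = col,
    lon = grid$lon_min + (col + 0.5) * grid$resolution,
    lat = grid$lat_max - (row + 0.5) * grid$resolution
  )
}

# row/col of points; returns NA outside the grid (half-open convention)
point_to_rowcol <- function(lon, lat, grid) {
  col <- floor((lon - grid$lon_min) / grid$resolution)
  row <- floor((grid$lat_max - lat) / grid$resolution)
  # northern edge of the grid is closed: lat == lat_max belongs to row 0
  row[lat == grid$lat_max] <- 0
  bad <- col < 0 | col >= grid$ncols | row < 0 | row >= grid$nrows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

grid_attr <- function(x) {
  g <- attr(x, "grid", exact = TRUE)
  if (is.null(g)) stop("input carries no `grid` attribute.", call. = FALSE)
  g
}

#' Write a per-cell value vector as an ESRI ASCII grid
#'
#' Values are ordered by `cell_id` (row-major from the north-west corner),
#' matching [grid_cells()]. `NA` is written as the NODATA value.
#'
#' @param values Numeric vector of length `nrows * ncols`.
#' @param grid A [grid_spec()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) != n_cells(grid)) {
    stop("`values` must have one entry per grid cell.", call. = FALSE)
  }
  v <- as.numeric(values)
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$lon_min),
    sprintf("yllcorner %.10g", grid$lat_max - grid$nrows * grid$resolution),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %g", nodata)
  )
  m <- matrix(v, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 12),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_esri_ascii()]
#'
#' @param path File path.
#' @return A list with `values` (row-major numeric vector, NODATA as `NA`)
#'   and `grid` (a [grid_spec()] with default cell area).
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  cellsize <- val("cellsize"); nodata <- val("NODATA_value")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  body <- paste(lines[-(1:6)], collapse = " ")
  v <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  v[v == nodata] <- NA_real_
  list(
    values = v,
    grid = grid_spec(lon_min = xll, lat_max = yll + nrows * cellsize,
                     resolution = cellsize, nrows = nrows, ncols = ncols)
  )
}
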