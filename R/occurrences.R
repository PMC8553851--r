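#' Load occurrence records from CSV
#'
#' Reads a CSV of georeferenced records, validates coordinates and drops rows
#' that cannot enter the analysis: unparseable or out-of-range longitude or
#' latitude (outside `[-180, 180]` or `[-90, 90]`) or an empty species field.
#' Nothing is silently lost: a drop report travels with the result.
#'
#' @param path CSV path. Must contain the three mandatory columns.
#' @param species_col,lon_col,lat_col Column names in the file.
#' @return A tibble `species, lon, lat` (plus `source` if present) of valid
#'   records, with attribute `report` (see [drop_report()]) counting rows
#'   read, kept, and dropped by reason.
#' @export
load_occurrences <- function(path, species_col = "species", lon_col = "lon",
                             lat_col = "lat") {
  if (!file.exists(path)) stop("occurrence file not found: ", path,
                               call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (col in c(species_col, lon_col, lat_col)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' missing from ", path, call. = FALSE)
    }
  }
  rec <- tibble::tibble(
    species = trimws(raw[[species_col]]),
    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
    lat = suppressWarnings(as.numeric(raw[[lat_col]]))
  )
  if ("source" %in% names(raw)) rec$source <- raw$source
  bad_species <- is.na(rec$species) | rec$species == ""
  bad_coord <- !bad_species &
    (is.na(rec$lon) | is.na(rec$lat) |
       rec$lon < -180 | rec$lon > 180 | rec$lat < -90 | rec$lat > 90)
  out <- rec[!bad_species & !bad_coord, ]
  attr(out, "report") <- tibble::tibble(
    n_read = nrow(rec), n_kept = nrow(out),
    n_invalid_coordinate = sum(bad_coord),
    n_missing_species = sum(bad_species)
  )
  out
}

#' Retrieve the drop report attached to a cleaning step
#'
#' @param x A tibble returned by [load_occurrences()],
#'   [filter_municipality_proximity()], [filter_min_records()] or
#'   [assign_to_cells()].
#' @return The step's report (a tibble or vector, depending on the step).
#' @export
drop_report <- function(x) {
  r <- attr(x, "report", exact = TRUE)
  if (is.null(r)) stop("no `report` attribute found.", call. = FALSE)
  r
}

#' Drop records too close to a municipality seat
#'
#' Museum records georeferenced only to the municipality are typically placed
#' at its seat; such coordinates are too imprecise for gridded modelling. A
#' record is dropped when its great-circle (haversine) distance to the
#' *nearest* seat is below `min_km`. Survivor order is preserved.
#'
#' @param records Tibble with `lon`, `lat` columns.
#' @param seats Tibble (or data frame) of seat coordinates with `lon`, `lat`.
#' @param min_km Exclusion radius in kilometres (default 2).
#' @return The kept records, with attribute `report`:
#'   `tibble(n_in, n_kept, n_dropped_near_seat)`.
#' @export
filter_municipality_proximity <- function(records, seats, min_km = 2) {
  if (is.null(seats) || nrow(seats) == 0) {
    stop("`seats` is empty: the proximity filter needs seat coordinates.",
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    attr(records, "report") <- tibble::tibble(
      n_in = 0L, n_kept = 0L, n_dropped_near_seat = 0L)
    return(records)
  }
  d <- geosphere::distm(cbind(records$lon, records$lat),
                        cbind(seats$lon, seats$lat),
                        fun = geosphere::distHaversine)
  nearest_m <- apply(d, 1, min)
  keep <- nearest_m >= min_km * 1000
  out <- records[keep, ]
  attr(out, "report") <- tibble::tibble(
    n_in = nrow(records), n_kept = sum(keep),
    n_dropped_near_seat = sum(!keep))
  out
}

#' Exclude species with too few records
#'
#' Distribution models need a minimum number of occurrences; species below
#' the floor (three, by default) are excluded and listed.
#'
#' @param records Tibble with a `species` column.
#' @param min_n Minimum records per species (default 3).
#' @return Records of the surviving species, with attribute `report`: a
#'   tibble `species, n_records, kept` covering every input species (the
#'   excluded species are the rows with `kept == FALSE`).
#' @export
filter_min_records <- function(records, min_n = 3) {
  min_n <- check_count(min_n, "min_n", 0)
  counts <- dplyr::count(records, .data$species, name = "n_records")
  counts$kept <- counts$n_records >= min_n
  out <- records[records$species %in% counts$species[counts$kept], ]
  attr(out, "report") <- counts
  out
}

#' Assign occurrence records to grid cells
#'
#' Each record maps to exactly one cell by the grid's half-open box rule;
#' duplicate records of a species within a cell collapse to one presence.
#'
#' @param records Tibble with `species`, `lon`, `lat`.
#' @param grid A [grid_spec()].
#' @param out_of_grid `"drop"` (default; dropped records are counted in the
#'   report) or `"error"`.
#' @return A tibble `species, cell_id, row, col` of distinct presences, with
#'   attributes `grid` and `report` (`tibble(n_records, n_out_of_grid,
#'   n_presences)`).
#' @export
assign_to_cells <- function(records, grid, out_of_grid = c("drop", "error")) {
  out_of_grid <- match.arg(out_of_grid)
  rc <- point_to_rowcol(records$lon, records$lat, grid)
  outside <- is.na(rc$row)
  if (any(outside) && out_of_grid == "error") {
    stop(sum(outside), " record(s) fall outside the grid.", call. = FALSE)
  }
  out <- tibble::tibble(
    species = records$species[!outside],
    row = rc$row[!outside], col = rc$col[!outside]
  )
  out$cell_id <- out$row * grid$ncols + out$col
  out <- dplyr::distinct(out[, c("species", "cell_id", "row", "col")])
  out <- dplyr::arrange(out, .data$species, .data$cell_id)
  attr(out, "grid") <- grid
  attr(out, "report") <- tibble::tibble(
    n_records = nrow(records), n_out_of_grid = sum(outside),
    n_presences = nrow(out))
  out
}
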