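#' Generate a synthetic environmental landscape
#'
#' Builds a stack of spatially autocorrelated, mutually correlated
#' environmental layers on a regular grid, emulating the key property of
#' bioclimatic variable sets: high collinearity. Layers are linear mixtures of
#' a small number of latent Gaussian random fields (smoothed white noise with
#' characteristic scale `autocorr_scale`) plus a little independent noise, so
#' a principal component analysis can compress the stack back to about the
#' latent dimension. The whole landscape, including the fixed set of synthetic
#' municipality-seat points used by the coordinate-precision filter, is a pure
#' function of `seed`.
#'
#' @param seed Integer seed; fully determines the output.
#' @param nrows,ncols Grid dimensions (each at least 8).
#' @param n_layers Number of environmental layers (at least 3).
#' @param autocorr_scale Smoothing scale of the latent fields, in cells.
#' @param n_latent Number of latent fields the layers mix; default
#'   `ceiling(n_layers / 3)`.
#' @param noise_sd Standard deviation of the independent per-layer noise,
#'   relative to the unit-variance latent mixture. Default 0.05.
#' @param grid Optional [grid_spec()]; defaults to a grid of the requested
#'   shape at 0.083 degrees anchored near the equator.
#' @param seats_per_cells One municipality seat is expected per this many
#'   cells (Poisson-sampled count, at least 1 seat). Default 100.
#' @return A tibble with one row per cell (`cell_id`, `row`, `col`, `lon`,
#'   `lat`) and columns `env_01 ... env_NN`; attributes `grid` (the
#'   [grid_spec()]), `latent` (cells x n_latent matrix of latent fields),
#'   `seats` (tibble of seat coordinates), `mixing` (layer loading matrix) and
#'   `seed`. Retrieve the ground truth with [synthetic_truth()].
#' @examples
#' land <- make_landscape(seed = 1, nrows = 12, ncols = 12, n_layers = 6)
#' @export
make_landscape <- function(seed, nrows = 40, ncols = 40, n_layers = 19,
                           autocorr_scale = 5,
                           n_latent = ceiling(n_layers / 3),
                           noise_sd = 0.05, grid = NULL,
                           seats_per_cells = 100) {
  nrows <- check_count(nrows, "nrows", 8)
  ncols <- check_count(ncols, "ncols", 8)
  n_layers <- check_count(n_layers, "n_layers", 3)
  n_latent <- check_count(n_latent, "n_latent", 1)
  if (autocorr_scale < 0) stop("`autocorr_scale` must be >= 0.", call. = FALSE)
  if (is.null(grid)) {
    grid <- grid_spec(nrows = nrows, ncols = ncols)
  }
  stopifnot(grid$nrows == nrows, grid$ncols == ncols)
  local_seed(seed)

  nc <- nrows * ncols
  latent <- vapply(seq_len(n_latent), function(i) {
    f <- gaussian_smooth(matrix(rnorm(nc), nrows, ncols), autocorr_scale)
    f <- as.vector(t(f))            # row-major, matching cell_id order
    (f - mean(f)) / sd(f)
  }, numeric(nc))

  mixing <- matrix(runif(n_layers * n_latent, -1, 1), n_layers, n_latent)
  raw <- latent %*% t(mixing)
  if (noise_sd > 0) raw <- raw + noise_sd * matrix(rnorm(nc * n_layers), nc)
  # arbitrary per-layer units, as bioclim layers have
  gains <- runif(n_layers, 0.5, 3)
  offsets <- runif(n_layers, -10, 30)
  layers <- sweep(sweep(raw, 2, gains, `*`), 2, offsets, `+`)
  colnames(layers) <- sprintf("env_%02d", seq_len(n_layers))

  n_seats <- max(1L, rpois(1, nc / seats_per_cells))
  seats <- tibble::tibble(
    name = sprintf("seat_%02d", seq_len(n_seats)),
    lon = grid$lon_min + runif(n_seats, 0, ncols * grid$resolution),
    lat = grid$lat_max - runif(n_seats, 0, nrows * grid$resolution)
  )

  out <- dplyr::bind_cols(grid_cells(grid), tibble::as_tibble(layers))
  attr(out, "grid") <- grid
  attr(out, "latent") <- latent
  attr(out, "seats") <- seats
  attr(out, "mixing") <- mixing
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic species with known ranges and occurrence records
#'
#' Each species gets a logistic suitability surface over the landscape's
#' latent environmental axes. Its presence threshold is set so the true range
#' (the cells where suitability meets the threshold) has exactly the size
#' implied by its entry in `range_quantiles` (a fraction of the landscape,
#' floored at one cell). Occurrence records are drawn uniformly over the true
#' range and jittered within the cell; a fixed fraction of records is then
#' snapped exactly onto the nearest municipality seat, emulating imprecise
#' museum records that a coordinate-precision filter must remove. Jittered
#' (non-snapped) points are rejection-sampled away from seats so the snapped
#' count is exactly the records within the filter radius.
#'
#' @param seed Integer seed.
#' @param landscape A landscape from [make_landscape()].
#' @param n_species Number of species to generate.
#' @param range_quantiles Fractions of the landscape assigned cyclically as
#'   true range sizes. Defaults span roughly 0.1% to 20% of cells, so on the
#'   default landscape ranges run from a couple of cells to hundreds.
#' @param n_occurrences Records per species; a scalar, or a vector recycled
#'   across species to emulate assemblages whose species differ in sampling
#'   effort.
#' @param snap_fraction Fraction (in `[0, 1)`) of all records snapped to
#'   municipality seats.
#' @param min_km Seat exclusion radius (km) used when jittering clean records.
#' @return A tibble of occurrence records (`species`, `lon`, `lat`,
#'   `snapped`), with attribute `truth` (class `synthetic_truth`) holding the
#'   per-species coefficients, thresholds and true range cell sets, plus the
#'   landscape's grid and seats. Retrieve it with [synthetic_truth()].
#' @export
make_species <- function(seed, landscape, n_species = 25,
                         range_quantiles = c(0.00125, 0.0025, 0.00625, 0.0125,
                                             0.025, 0.05, 0.1, 0.2),
                         n_occurrences = 20, snap_fraction = 0.1,
                         min_km = 2) {
  n_species <- check_count(n_species, "n_species", 1)
  if (!is.numeric(n_occurrences) || any(n_occurrences < 1) ||
      any(n_occurrences != round(n_occurrences))) {
    stop("`n_occurrences` must be positive whole number(s).", call. = FALSE)
  }
  n_occ_sp <- rep_len(as.integer(n_occurrences), n_species)
  check_fraction(snap_fraction, "snap_fraction", 0, 1, open_hi = TRUE)
  grid <- grid_attr(landscape)
  latent <- attr(landscape, "latent", exact = TRUE)
  seats <- attr(landscape, "seats", exact = TRUE)
  if (is.null(latent) || is.null(seats)) {
    stop("`landscape` must come from make_landscape().", call. = FALSE)
  }
  local_seed(seed)

  nc <- nrow(latent)
  ids <- sprintf("sp%03d", seq_len(n_species))
  q <- rep_len(range_quantiles, n_species)
  target <- pmax(1L, as.integer(round(q * nc)))

  species <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    repeat {
      beta <- rnorm(ncol(latent))
      eta <- drop(latent %*% beta)
      ord <- order(eta, decreasing = TRUE)
      range_cells <- sort(ord[seq_len(target[i])])
      if (length(range_cells) > 0) break   # regeneration guard (cannot be 0
      warning("empty range for species ", ids[i], "; regenerating")
    }
    thr <- eta[ord[target[i]]]
    species[[i]] <- list(id = ids[i], coef = beta, threshold = thr,
                         range = landscape$cell_id[range_cells],
                         range_rows = range_cells)
  }

  res <- grid$resolution
  jitter_point <- function(cell_row) {
    r <- landscape$row[cell_row]; cc <- landscape$col[cell_row]
    for (try in 1:200) {
      lon <- grid$lon_min + (cc + runif(1)) * res
      lat <- grid$lat_max - (r + runif(1)) * res
      d <- min(geosphere::distHaversine(cbind(lon, lat),
                                        cbind(seats$lon, seats$lat)))
      if (d >= min_km * 1000) return(c(lon, lat))
    }
    c(lon, lat)  # pathological seat density; accept the last draw
  }

  occ <- purrr::map2_dfr(species, n_occ_sp, function(sp, n_occ) {
    rows <- sp$range_rows[sample.int(length(sp$range_rows), n_occ,
                                     replace = TRUE)]
    pts <- t(vapply(rows, jitter_point, numeric(2)))
    tibble::tibble(species = sp$id, lon = pts[, 1], lat = pts[, 2])
  })

  n_snap <- round(snap_fraction * nrow(occ))
  occ$snapped <- FALSE
  if (n_snap > 0) {
    idx <- sample(nrow(occ), n_snap)
    near <- apply(geosphere::distm(cbind(occ$lon[idx], occ$lat[idx]),
                                   cbind(seats$lon, seats$lat)), 1, which.min)
    occ$lon[idx] <- seats$lon[near]
    occ$lat[idx] <- seats$lat[near]
    occ$snapped[idx] <- TRUE
  }

  truth <- structure(
    list(grid = grid, seats = seats,
         species = stats::setNames(species, ids),
         latent = latent, seed = seed,
         n_occurrences = n_occurrences, snap_fraction = snap_fraction),
    class = "synthetic_truth"
  )
  attr(occ, "truth") <- truth
  attr(occ, "grid") <- grid
  occ
}

#' Extract the stored ground truth from a synthetic object
#'
#' @param x Output of [make_species()] (or any object carrying a `truth`
#'   attribute).
#' @return The `synthetic_truth` object.
#' @export
synthetic_truth <- function(x) {
  t <- attr(x, "truth", exact = TRUE)
  if (is.null(t)) stop("no `truth` attribute found.", call. = FALSE)
  t
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d species on %d x %d grid, seed %s\n",
              length(x$species), x$grid$nrows, x$grid$ncols,
              format(x$seed)))
  invisible(x)
}

#' Generate biome and protected-area masks
#'
#' Biomes are contiguous nearest-seed (Voronoi-like) partitions of the grid.
#' Protection is a per-cell coverage fraction in `[0, 1]`: cells counted as
#' protected (fraction at least 0.5) total `round(cu_coverage * n_cells)`.
#' Placement is uniform at random, concentrated on the highest-importance
#' cells (`importance_top`), or random but requiring an importance map purely
#' as a provenance statement (`importance_independent`). A configurable band
#' of cells receives fractional coverage on either side of the 50% rule so
#' the protected/unprotected classification has real work to do.
#'
#' @param seed Integer seed.
#' @param grid A [grid_spec()].
#' @param n_biomes Number of biome labels (must not exceed the cell count).
#' @param cu_coverage Fraction of cells protected, in (0, 1). Default 0.13.
#' @param placement One of `"random"`, `"importance_top"`,
#'   `"importance_independent"`.
#' @param importance Per-cell importance values (cell_id order); required for
#'   the importance-aware placements.
#' @param partial_band Fraction of the protected count that gets a coverage
#'   fraction in `[0.5, 1)` rather than 1, with an equal number of unprotected
#'   cells given fractions in `(0, 0.5)`. Default 0.1.
#' @return A tibble `cell_id, row, col, biome, protection` with attribute
#'   `grid`.
#' @export
make_masks <- function(seed, grid, n_biomes = 6, cu_coverage = 0.13,
                       placement = c("random", "importance_top",
                                     "importance_independent"),
                       importance = NULL, partial_band = 0.1) {
  placement <- match.arg(placement)
  n_biomes <- check_count(n_biomes, "n_biomes", 1)
  check_fraction(cu_coverage, "cu_coverage", 0, 1, open_lo = TRUE,
                 open_hi = TRUE)
  nc <- n_cells(grid)
  if (n_biomes > nc) {
    stop("`n_biomes` exceeds the number of grid cells.", call. = FALSE)
  }
  if (placement != "random" && is.null(importance)) {
    stop("placement '", placement, "' requires an `importance` map.",
         call. = FALSE)
  }
  if (!is.null(importance) && length(importance) != nc) {
    stop("`importance` must have one value per cell.", call. = FALSE)
  }
  local_seed(seed)

  cells <- grid_cells(grid)
  seeds <- sample.int(nc, n_biomes)
  d2 <- outer(cells$row, cells$row[seeds], `-`)^2 +
    outer(cells$col, cells$col[seeds], `-`)^2
  biome <- max.col(-d2, ties.method = "first")

  n_prot <- round(cu_coverage * nc)
  prot_cells <- switch(placement,
    random = sample.int(nc, n_prot),
    importance_independent = sample.int(nc, n_prot),
    importance_top = order(-importance, cells$cell_id)[seq_len(n_prot)]
  )
  protection <- numeric(nc)
  protection[prot_cells] <- 1
  n_band <- min(round(partial_band * n_prot), n_prot,
                nc - n_prot)
  if (n_band > 0) {
    soft_hi <- sample(prot_cells, n_band)
    protection[soft_hi] <- runif(n_band, 0.5, 1)
    soft_lo <- sample(setdiff(seq_len(nc), prot_cells), n_band)
    protection[soft_lo] <- runif(n_band, 0.01, 0.49)
  }

  out <- dplyr::mutate(cells[c("cell_id", "row", "col")],
                       biome = sprintf("biome_%d", biome),
                       protection = protection)
  attr(out, "grid") <- grid
  attr(out, "placement") <- placement
  attr(out, "seed") <- seed
  out
}
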