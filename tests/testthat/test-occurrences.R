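write_occ_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("well-formed occurrence files load completely", {
  path <- write_occ_csv(c("species,lon,lat", "a,-50.1,-10.2",
                          "b,-51,2", "a,-49.9,0"))
  occ <- load_occurrences(path)
  expect_equal(nrow(occ), 3)
  rep <- drop_report(occ)
  expect_equal(rep$n_read, 3)
  expect_equal(rep$n_invalid_coordinate, 0)
})

test_that("out-of-range and malformed coordinates are dropped and counted", {
  path <- write_occ_csv(c("species,lon,lat", "a,-50,95", "b,-51,2",
                          "c,not_a_number,1", ",0,0"))
  occ <- load_occurrences(path)
  expect_equal(nrow(occ), 1)
  rep <- drop_report(occ)
  expect_equal(rep$n_invalid_coordinate, 2)
  expect_equal(rep$n_missing_species, 1)
})

test_that("a missing mandatory column is a hard error naming it", {
  path <- write_occ_csv(c("taxon,lon,lat", "a,-50,0"))
  expect_error(load_occurrences(path), "species")
  expect_error(load_occurrences("no/such/file.csv"), "no/such/file")
})

test_that("municipality filter drops by nearest-seat great-circle distance", {
  seats <- tibble::tibble(name = "s1", lon = -50, lat = -10)
  at_seat <- tibble::tibble(species = "a", lon = -50, lat = -10)
  far <- tibble::tibble(species = "a", lon = -49, lat = -9)  # > 100 km
  p19 <- offset_north_km(-50, -10, 1.9)
  p21 <- offset_north_km(-50, -10, 2.1)
  recs <- dplyr::bind_rows(
    at_seat, far,
    tibble::tibble(species = "b", lon = p19[1], lat = p19[2]),
    tibble::tibble(species = "c", lon = p21[1], lat = p21[2]))
  kept <- filter_municipality_proximity(recs, seats, min_km = 2)
  expect_equal(kept$species, c("a", "c"))
  expect_equal(kept$lat[1], -9)
  expect_equal(drop_report(kept)$n_dropped_near_seat, 2)
})

test_that("the filter agrees with an independent haversine implementation", {
  set.seed(21)
  seats <- tibble::tibble(lon = runif(5, -55, -45), lat = runif(5, -15, -5))
  recs <- tibble::tibble(species = "x", lon = runif(200, -55, -45),
                         lat = runif(200, -15, -5))
  kept <- filter_municipality_proximity(recs, seats, min_km = 25)
  nearest <- vapply(seq_len(nrow(recs)), function(i) {
    min(haversine_m(recs$lon[i], recs$lat[i], seats$lon, seats$lat))
  }, numeric(1))
  expect_equal(kept$lon, recs$lon[nearest >= 25000])
  expect_error(filter_municipality_proximity(recs, seats[0, ]), "empty")
})

test_that("the minimum-record floor excludes and lists sparse species", {
  recs <- tibble::tibble(
    species = rep(c("two", "three", "many"), c(2, 3, 7)),
    lon = 0, lat = 0)
  kept <- filter_min_records(recs, min_n = 3)
  expect_setequal(unique(kept$species), c("three", "many"))
  rep <- drop_report(kept)
  expect_false(rep$kept[rep$species == "two"])
})

test_that("a 208-species pool with 111 modellable species splits correctly", {
  set.seed(3)
  n_per <- c(rep(2, 97), sample(3:40, 111, replace = TRUE))
  recs <- tibble::tibble(
    species = rep(sprintf("sp%03d", 1:208), n_per), lon = 0, lat = 0)
  kept <- filter_min_records(recs, min_n = 3)
  expect_equal(dplyr::n_distinct(kept$species), 111)
  expect_equal(sum(!drop_report(kept)$kept), 97)
})

test_that("cell assignment collapses duplicates and reports off-grid drops", {
  g <- grid_spec(lon_min = 0, lat_max = 10, resolution = 1, nrows = 5,
                 ncols = 5)
  recs <- tibble::tibble(
    species = c("a", "a", "a", "b"),
    lon = c(0.2, 0.7, 2.5, 99),
    lat = c(9.5, 9.5, 7.5, 0))
  pres <- assign_to_cells(recs, g)
  expect_equal(nrow(pres), 2)   # two a-records share cell (0,0)
  expect_equal(pres$cell_id, c(0, 12))
  expect_equal(drop_report(pres)$n_out_of_grid, 1)
  expect_error(assign_to_cells(recs, g, out_of_grid = "error"), "outside")
})

test_that("filters are order-independent as sets", {
  set.seed(4)
  recs <- tibble::tibble(
    species = sample(letters[1:5], 60, replace = TRUE),
    lon = runif(60, -51, -49), lat = runif(60, -11, -9))
  seats <- tibble::tibble(lon = -50.5, lat = -10.5)
  perm <- sample(nrow(recs))
  a <- filter_municipality_proximity(recs, seats, min_km = 10)
  b <- filter_municipality_proximity(recs[perm, ], seats, min_km = 10)
  expect_setequal(paste(a$species, a$lon, a$lat),
                  paste(b$species, b$lon, b$lat))
  g <- grid_spec(lon_min = -51, lat_max = -9, resolution = 0.1, nrows = 20,
                 ncols = 20)
  expect_identical(assign_to_cells(recs, g), assign_to_cells(recs[perm, ], g))
})

test_that("gridded synthetic records recover cells inside the stored truth", {
  land <- make_landscape(8, nrows = 15, ncols = 15, n_layers = 5)
  occ <- make_species(9, land, n_species = 6, n_occurrences = 15,
                      snap_fraction = 0, range_quantiles = c(0.05, 0.15))
  truth <- synthetic_truth(occ)
  pres <- assign_to_cells(occ, truth$grid)
  ok <- vapply(seq_len(nrow(pres)), function(i) {
    pres$cell_id[i] %in% truth$species[[pres$species[i]]]$range
  }, logical(1))
  expect_true(all(ok))
  expect_equal(drop_report(pres)$n_out_of_grid, 0)
})
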