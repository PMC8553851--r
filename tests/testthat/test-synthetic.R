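test_that("landscapes are bit-identical under the same seed", {
  a <- make_landscape(11, nrows = 10, ncols = 12, n_layers = 5)
  b <- make_landscape(11, nrows = 10, ncols = 12, n_layers = 5)
  expect_identical(a, b)
  c <- make_landscape(12, nrows = 10, ncols = 12, n_layers = 5)
  expect_false(identical(a$env_01, c$env_01))
})

test_that("a rank-1 noise-free mixture gives perfectly correlated layers", {
  land <- make_landscape(3, nrows = 10, ncols = 10, n_layers = 3,
                         n_latent = 1, noise_sd = 0)
  env <- as.matrix(land[grep("^env_", names(land))])
  cors <- cor(env)
  expect_equal(abs(cors), matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("the default 19-layer stack is PCA-compressible as designed", {
  land <- make_landscape(1, nrows = 40, ncols = 40, n_layers = 19,
                         autocorr_scale = 5)
  pca <- pca_reduce(standardize_stack(land), target_cumvar = 0.95)
  # 19 layers mix ceiling(19/3) = 7 latent fields; 95% of the variance must
  # be reachable within latent dimension + 1 axes
  expect_lte(pca$n_retained, 8)
  expect_gte(sum(pca$explained[seq_len(pca$n_retained)]), 0.95)
})

test_that("landscape dimension errors name the offending parameter", {
  expect_error(make_landscape(1, nrows = 4), "nrows")
  expect_error(make_landscape(1, ncols = 0), "ncols")
  expect_error(make_landscape(1, n_layers = 2), "n_layers")
})

test_that("species records respect count, snapping and range membership", {
  land <- make_landscape(5, nrows = 20, ncols = 20, n_layers = 6)
  occ <- make_species(6, land, n_species = 25, n_occurrences = 20,
                      snap_fraction = 0.1,
                      range_quantiles = c(0.02, 0.05, 0.1))
  expect_equal(nrow(occ), 500)
  expect_equal(sum(occ$snapped), 50)

  # exactly the snapped records lie within 2 km of a seat
  seats <- synthetic_truth(occ)$seats
  d <- geosphere::distm(cbind(occ$lon, occ$lat), cbind(seats$lon, seats$lat))
  near <- apply(d, 1, min) < 2000
  expect_equal(sum(near), 50)
  expect_equal(which(near), which(occ$snapped))

  # every non-snapped record falls inside its species' true range cells
  truth <- synthetic_truth(occ)
  clean <- occ[!occ$snapped, ]
  assigned <- aquagap:::point_to_rowcol(clean$lon, clean$lat, truth$grid)
  cell <- assigned$row * truth$grid$ncols + assigned$col
  in_range <- vapply(seq_len(nrow(clean)), function(i) {
    cell[i] %in% truth$species[[clean$species[i]]]$range
  }, logical(1))
  expect_true(all(in_range))
})

test_that("a quantile of one cell yields a single-cell true range", {
  land <- make_landscape(5, nrows = 20, ncols = 20, n_layers = 6)
  occ <- make_species(7, land, n_species = 2, n_occurrences = 5,
                      snap_fraction = 0, range_quantiles = 1 / 400)
  truth <- synthetic_truth(occ)
  expect_equal(lengths(lapply(truth$species, `[[`, "range")),
               c(sp001 = 1L, sp002 = 1L))
})

test_that("biome masks partition the grid into contiguous labelled regions", {
  g <- grid_spec(nrows = 40, ncols = 40)
  masks <- make_masks(9, g, n_biomes = 6, cu_coverage = 0.1)
  expect_equal(nrow(masks), 1600)
  expect_setequal(unique(masks$biome), sprintf("biome_%d", 1:6))

  # queen-adjacency flood fill per biome: one connected component each
  lab <- matrix(masks$biome[order(masks$cell_id)], 40, 40, byrow = TRUE)
  for (b in unique(masks$biome)) {
    cells <- which(lab == b, arr.ind = TRUE)
    comp <- rep(NA_integer_, nrow(cells))
    key <- paste(cells[, 1], cells[, 2])
    comp[1] <- 1L
    frontier <- 1L
    while (length(frontier) > 0) {
      nxt <- integer()
      for (i in frontier) {
        nb <- cbind(rep(cells[i, 1] + (-1:1), 3),
                    rep(cells[i, 2] + (-1:1), each = 3))
        hits <- match(paste(nb[, 1], nb[, 2]), key)
        hits <- hits[!is.na(hits)]
        new <- hits[is.na(comp[hits])]
        comp[new] <- 1L
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    expect_true(all(comp == 1L), label = paste("biome", b, "contiguous"))
  }
})

test_that("protected coverage matches the requested fraction", {
  g <- grid_spec(nrows = 40, ncols = 40)
  masks <- make_masks(10, g, n_biomes = 4, cu_coverage = 0.1,
                      placement = "random")
  expect_lte(abs(sum(masks$protection >= 0.5) - 160), 1)
  expect_true(all(masks$protection >= 0 & masks$protection <= 1))
})

test_that("importance_top placement concentrates protection on importance", {
  g <- grid_spec(nrows = 20, ncols = 20)
  set.seed(2)
  imp <- runif(400)
  masks <- make_masks(11, g, n_biomes = 3, cu_coverage = 0.15,
                      placement = "importance_top", importance = imp)
  prot <- masks$protection[order(masks$cell_id)] >= 0.5
  expect_gt(mean(imp[prot]), mean(imp[!prot]))
})

test_that("mask preconditions are enforced", {
  g <- grid_spec(nrows = 8, ncols = 8)
  expect_error(make_masks(1, g, n_biomes = 100), "n_biomes")
  expect_error(make_masks(1, g, cu_coverage = 0), "cu_coverage")
  expect_error(make_masks(1, g, placement = "importance_top"), "importance")
})
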