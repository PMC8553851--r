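# Shared fixtures and independent oracles used across the suite.

# haversine distance in metres, written independently of geosphere
# (same sphere radius so the two must agree)
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# move a point due north by `km` on the haversine sphere
offset_north_km <- function(lon, lat, km, r = 6378137) {
  c(lon, lat + km * 1000 / (r * pi / 180))
}

# Baselga pairwise partition from explicit species sets
beta_pair_oracle <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  cc <- length(setdiff(s2, s1))
  if (a + b + cc == 0) return(c(total = 0, turnover = 0, nestedness = 0))
  if (length(s1) == 0 || length(s2) == 0) {
    return(c(total = 1, turnover = 1, nestedness = 0))
  }
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- min(b, cc) / (a + min(b, cc))
  c(total = sor, turnover = sim, nestedness = sor - sim)
}

# trapezoidal integration of the empirical ROC curve
auc_trapezoid_oracle <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# exhaustive pairwise-comparison AUC
auc_pairwise_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# brute-force max-TSS scan over the same candidate family
max_tss_oracle <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  for (t in cand) {
    tss <- mean(pos >= t) + mean(neg < t) - 1
    if (tss > best) best <- tss
  }
  best
}

# build a community matrix tibble from a plain 0/1 matrix (cells x species)
cm_from_matrix <- function(M, ncols = NULL) {
  n <- nrow(M)
  ncols <- ncols %||% ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  grid <- grid_spec(nrows = nrows, ncols = ncols)
  cells <- grid_cells(grid)[seq_len(n), c("cell_id", "row", "col")]
  colnames(M) <- colnames(M) %||% sprintf("sp%02d", seq_len(ncol(M)))
  preds <- tidyr::pivot_longer(
    dplyr::bind_cols(cells["cell_id"], tibble::as_tibble(M)),
    -cell_id, names_to = "species", values_to = "presence")
  # restrict to the first n cells of the grid
  out <- suppressWarnings(community_matrix(preds, grid))
  out[out$cell_id %in% cells$cell_id, ]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a small landscape + species set shared by SDM-level tests
small_synthetic <- function(seed = 42, nrows = 20, ncols = 20,
                            n_layers = 9, n_species = 8,
                            range_quantiles = c(0.05, 0.1, 0.2),
                            n_occurrences = 20) {
  land <- make_landscape(seed, nrows = nrows, ncols = ncols,
                         n_layers = n_layers, autocorr_scale = 3)
  occ <- make_species(seed + 1, land, n_species = n_species,
                      range_quantiles = range_quantiles,
                      n_occurrences = n_occurrences, snap_fraction = 0)
  std <- standardize_stack(land)
  pca <- pca_reduce(std)
  list(land = land, occ = occ, truth = synthetic_truth(occ), pca = pca,
       grid = attr(land, "grid"))
}
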