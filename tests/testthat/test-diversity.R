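test_that("community matrix stacks predictions and excludes NA cells", {
  g <- grid_spec(nrows = 3, ncols = 3)
  preds <- tidyr::expand_grid(species = c("a", "b"), cell_id = 0:8)
  preds$presence <- as.numeric(preds$cell_id %% 2 == 0)
  preds$presence[preds$species == "b"] <- 1
  preds$presence[preds$species == "a" & preds$cell_id == 4] <- NA
  cm <- community_matrix(preds, g)
  expect_equal(nrow(cm), 8)
  expect_equal(attr(cm, "excluded_cells"), 4)
  expect_equal(cm$b, rep(1, 8))
  expect_error(community_matrix(preds[preds$species == "x", ], g))
})

test_that("richness equals brute-force row counting", {
  set.seed(12)
  M <- matrix(rbinom(200, 1, 0.4), 20, 10)
  cm <- cm_from_matrix(M)
  r <- richness(cm)
  loop <- vapply(seq_len(20), function(i) sum(M[i, ]), numeric(1))
  expect_equal(r$richness, loop)
  expect_equal(richness(cm_from_matrix(matrix(0, 4, 3)))$richness, rep(0, 4))
  expect_equal(richness(cm_from_matrix(matrix(1, 10, 5)))$richness,
               rep(5, 10))
})

test_that("beta partition reproduces the defining worked examples", {
  M <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0),  # identical compositions
             c(0, 0, 1, 1))
  # identical cells
  parts <- pairwise_beta(cm_from_matrix(rbind(c(1, 1, 1), c(1, 1, 1))))
  expect_equal(parts$total[1, 2], 0)
  expect_equal(parts$turnover[1, 2], 0)
  expect_equal(parts$nestedness[1, 2], 0)
  # complete turnover: {1,2} vs {3,4}
  parts <- pairwise_beta(cm_from_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))))
  expect_equal(parts$total[1, 2], 1)
  expect_equal(parts$turnover[1, 2], 1)
  expect_equal(parts$nestedness[1, 2], 0)
  # pure nestedness: {1,2,3,4} vs {1,2}
  parts <- pairwise_beta(cm_from_matrix(rbind(c(1, 1, 1, 1), c(1, 1, 0, 0))))
  expect_equal(parts$turnover[1, 2], 0)
  expect_equal(parts$total[1, 2], 1 / 3)
  expect_equal(parts$nestedness[1, 2], 1 / 3)
})

test_that("beta partition obeys its identity and degenerate conventions", {
  set.seed(13)
  M <- matrix(rbinom(300, 1, 0.35), 30, 10)
  M[1:2, ] <- 0    # two empty cells
  parts <- pairwise_beta(cm_from_matrix(M))
  expect_lt(max(abs(parts$total - (parts$turnover + parts$nestedness))),
            1e-12)
  expect_true(isSymmetric(parts$total))
  expect_true(all(diag(parts$total) == 0))
  expect_true(all(parts$total >= 0 & parts$total <= 1))
  # empty vs empty -> 0; empty vs non-empty -> 1, attributed to turnover
  expect_equal(parts$total[1, 2], 0)
  expect_equal(parts$total[1, 3], 1)
  expect_equal(parts$turnover[1, 3], 1)
  expect_equal(parts$nestedness[1, 3], 0)
})

test_that("beta partition agrees with a set-arithmetic oracle", {
  set.seed(14)
  M <- matrix(rbinom(200, 1, 0.5), 20, 10)
  parts <- pairwise_beta(cm_from_matrix(M))
  for (i in 1:19) for (j in (i + 1):20) {
    o <- beta_pair_oracle(which(M[i, ] == 1), which(M[j, ] == 1))
    expect_equal(parts$total[i, j], o[["total"]], tolerance = 1e-12)
    expect_equal(parts$turnover[i, j], o[["turnover"]], tolerance = 1e-12)
    expect_equal(parts$nestedness[i, j], o[["nestedness"]],
                 tolerance = 1e-12)
  }
})

test_that("equal-richness pairs have zero nestedness component", {
  set.seed(15)
  for (i in 1:20) {
    s1 <- sample(10, 4)
    s2 <- sample(10, 4)
    M <- matrix(0, 2, 10)
    M[1, s1] <- 1; M[2, s2] <- 1
    parts <- pairwise_beta(cm_from_matrix(M))
    expect_equal(parts$nestedness[1, 2], 0, tolerance = 1e-12)
  }
})

test_that("PCoA axis 1 recovers collinear coordinates exactly", {
  x <- c(0, 1, 2.5, 4, 7, 11)
  D <- as.matrix(dist(x))
  scores <- pcoa_first_axis(D)
  expect_equal(abs(cor(scores, x)), 1, tolerance = 1e-8)
  # pairwise score distances never exceed the original distances
  expect_true(all(as.matrix(dist(scores)) <= D + 1e-8))
  # cross-check against classical MDS
  ref <- cmdscale(D, k = 1)[, 1]
  expect_equal(abs(cor(scores, ref)), 1, tolerance = 1e-10)
  expect_equal(sd(scores), sd(ref), tolerance = 1e-8)
})

test_that("PCoA handles degenerate and invalid input", {
  expect_equal(pcoa_first_axis(matrix(0, 4, 4)), rep(0, 4))
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_first_axis(bad), "symmetric")
})

test_that("diversity maps bundle richness with spatialized beta scores", {
  set.seed(16)
  M <- matrix(rbinom(120, 1, 0.4), 12, 10)
  cm <- cm_from_matrix(M)
  dm <- diversity_maps(cm)
  expect_equal(dm$richness, richness(cm)$richness)
  expect_equal(nrow(dm), 12)
  # two-cell landscape: scores are +/- the same magnitude
  dm2 <- diversity_maps(cm_from_matrix(rbind(c(1, 1, 0), c(0, 1, 1))))
  expect_equal(dm2$beta_total[1], -dm2$beta_total[2], tolerance = 1e-10)
})

test_that("diversity maps are equivariant under cell permutation", {
  set.seed(17)
  M <- matrix(rbinom(150, 1, 0.4), 15, 10)
  cm <- cm_from_matrix(M)
  dm <- diversity_maps(cm)
  perm <- sample(15)
  cmp <- cm[perm, ]
  attr(cmp, "grid") <- attr(cm, "grid")
  dmp <- diversity_maps(cmp)
  ord <- match(dm$cell_id, dmp$cell_id)
  expect_equal(dmp$richness[ord], dm$richness)
  expect_equal(abs(dmp$beta_total[ord]), abs(dm$beta_total),
               tolerance = 1e-8)
})

test_that("oversized landscapes trigger the dense-PCoA cap", {
  M <- matrix(1, 10, 2)
  expect_error(pairwise_beta(cm_from_matrix(M), max_cells = 5), "capped")
})
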