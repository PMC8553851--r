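test_that("Monte Carlo p-values follow the add-one convention", {
  r <- rep(0.5, 10000)
  top <- mc_pvalue(0.9, r)
  expect_equal(top$p, 0)
  expect_match(top$p_label, "^< ")
  expect_equal(mc_pvalue(0.1, r)$p, 10000 / 10001)
  expect_equal(mc_pvalue(0.5, r)$p, 10000 / 10001)  # >= counts ties

  set.seed(20)
  mid <- mc_pvalue(0, rnorm(999))
  expect_lt(abs(mid$p - 0.5), 0.05)

  # antitone in the observed value
  randoms <- rnorm(200)
  obs <- seq(-2, 2, length.out = 11)
  ps <- vapply(obs, function(o) mc_pvalue(o, randoms)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("a biome covering every cell is its own null", {
  set.seed(21)
  data <- tibble::tibble(v = rnorm(100), biome = "all")
  out <- biome_randomization(data, v, biome, n_rand = 199, seed = 1)
  expect_equal(out$random_sd, 0)
  expect_equal(out$observed_mean, out$random_mean)
  expect_gte(out$p, 199 / 200)
})

test_that("biome test is reproducible and order-independent", {
  set.seed(22)
  data <- tibble::tibble(v = rnorm(200),
                         biome = sample(c("a", "b"), 200, replace = TRUE))
  r1 <- biome_randomization(data, v, biome, n_rand = 99, seed = 7)
  r2 <- biome_randomization(data, v, biome, n_rand = 99, seed = 7)
  expect_identical(r1, r2)
  r3 <- biome_randomization(data[sample(200), ], v, biome, n_rand = 99,
                            seed = 7)
  expect_equal(r3$observed_mean, r1$observed_mean)
  expect_equal(r3$n_cells, r1$n_cells)
})

test_that("a planted top-decile biome is detected", {
  set.seed(23)
  v <- rnorm(400)
  biome <- ifelse(rank(-v) <= 40, "hot", "rest")
  out <- biome_randomization(tibble::tibble(v = v, biome = biome), v, biome,
                             n_rand = 999, seed = 3)
  expect_lt(out$p[out$biome == "hot"], 0.01)
})

test_that("the AUC-class test is flat when AUC is constant", {
  data <- tibble::tibble(auc = rep(0.9, 50),
                         n_occ = rep(c(10, 20, 40, 55, 70), 10))
  out <- auc_class_test(data, auc, n_occ, n_rand = 199, seed = 1)
  expect_equal(out$class[1], "4 to 15")
  expect_true(is.na(out$p[1]))              # control row carries no p
  expect_equal(out$p[-1], rep(1, nrow(out) - 1))
})

test_that("inflated low-occurrence AUC is flagged by every other class", {
  # the artifact the test exists for: sparse species score spuriously high,
  # so the control class's observed mean towers over random species sets
  set.seed(24)
  n_occ <- sample(4:75, 60, replace = TRUE)
  a <- 0.95 - 0.25 * (n_occ / 75) + rnorm(60, 0, 0.01)
  out <- auc_class_test(tibble::tibble(auc = a, n_occ = n_occ), auc, n_occ,
                        n_rand = 999, seed = 2)
  expect_true(all(out$p[-1] < 0.05, na.rm = TRUE))

  # the own-class reference variant flags classes whose own mean is high
  a2 <- 0.5 + 0.4 * (n_occ / 75) + rnorm(60, 0, 0.01)
  out2 <- auc_class_test(tibble::tibble(auc = a2, n_occ = n_occ), auc,
                         n_occ, n_rand = 999, seed = 3,
                         reference = "own_class")
  expect_lt(out2$p[out2$class == "61 to 75"], 0.05)
})

test_that("AUC-class nulls are rarely significant when AUC is unrelated", {
  # the control-reference design is only near-calibrated when the control
  # class mean is stable, i.e. when most species are sparse (as in real
  # assemblages, where the lowest occurrence class dominates)
  set.seed(25)
  n_tests <- 0; n_sig <- 0
  for (i in 1:100) {
    n_occ <- c(sample(4:15, 28, replace = TRUE),
               sample(16:75, 12, replace = TRUE))
    a <- runif(40, 0.7, 0.95)
    out <- auc_class_test(tibble::tibble(auc = a, n_occ = n_occ), auc,
                          n_occ, n_rand = 199, seed = i)
    n_tests <- n_tests + sum(!is.na(out$p))
    n_sig <- n_sig + sum(out$p < 0.05, na.rm = TRUE)
  }
  expect_lte(n_sig / n_tests, 0.1)
})

test_that("class binning matches the declared boundaries", {
  data <- tibble::tibble(auc = runif(6, 0.8, 0.9),
                         n_occ = c(4, 15, 16, 30, 31, 46))
  out <- auc_class_test(data, auc, n_occ, n_rand = 9, seed = 1)
  expect_equal(out$n_species[out$class == "4 to 15"], 2)
  expect_equal(out$n_species[out$class == "16 to 30"], 2)
  expect_equal(out$n_species[out$class == "31 to 45"], 1)
  expect_equal(out$n_species[out$class == "46 to 60"], 1)
  expect_error(auc_class_test(tibble::tibble(auc = 0.9, n_occ = 3), auc,
                              n_occ), "at least 4")
})

test_that("protection placed on top-importance cells is detected", {
  set.seed(26)
  imp <- runif(300)
  prot <- as.numeric(rank(-imp) <= 30)
  out <- protection_randomization(
    tibble::tibble(importance = imp, protection = prot), importance,
    protection, n_rand = 999, seed = 4)
  expect_lt(out$p, 0.01)
})

test_that("a single protected cell holding the maximum gives the boundary p", {
  imp <- c(1, runif(99, 0, 0.9))
  prot <- c(1, rep(0, 99))
  out <- protection_randomization(
    tibble::tibble(importance = imp, protection = prot), importance,
    protection, n_rand = 199, seed = 5)
  expect_equal(out$p, 0)
  expect_match(out$p_label, "^< ")
  expect_lt(1 / 200 - out$p, 1 / 199)
})

test_that("per-biome protection runs cover every biome and flag empties", {
  set.seed(27)
  data <- tibble::tibble(
    importance = runif(200),
    protection = rbinom(200, 1, 0.2),
    biome = rep(c("a", "b"), each = 100))
  data$protection[data$biome == "b"] <- 0    # no protected cells in b
  out <- protection_randomization(data, importance, protection,
                                  biome = biome, n_rand = 99, seed = 6,
                                  scope = "per_biome")
  expect_equal(out$scope, c("total", "a", "b"))
  expect_true(is.na(out$p[out$scope == "b"]))
  expect_match(out$p_label[out$scope == "b"], "undefined")
})
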