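#' Monte Carlo p-value
#'
#' Upper-tail p-value of an observed statistic against its randomization
#' distribution: the count of random values greater than or equal to the
#' observed one, divided by `n_randomizations + 1` (the add-one convention).
#' The lower-tail companion is returned so the direction of a deviation can
#' be reported alongside significance. When no random value reaches the
#' observed one the numeric p is 0 and the label reports the resolution
#' bound `< 1/(n+1)`.
#'
#' @param observed Observed scalar statistic.
#' @param randoms Non-empty vector of randomized statistics.
#' @return One-row tibble: `p` (upper tail), `p_lower`, `n_randomizations`,
#'   `p_label`.
#' @export
mc_pvalue <- function(observed, randoms) {
  n <- length(randoms)
  if (n == 0) stop("`randoms` must be non-empty.", call. = FALSE)
  hits <- sum(randoms >= observed)
  p <- hits / (n + 1)
  tibble::tibble(
    p = p,
    p_lower = sum(randoms <= observed) / (n + 1),
    n_randomizations = n,
    p_label = if (hits == 0) sprintf("< %.4g", 1 / (n + 1)) else
      sprintf("%.4g", p)
  )
}

#' Biome randomization test of a diversity metric
#'
#' For each biome: the observed mean and SD of the per-cell metric over the
#' biome's N cells are compared with the means of `n_rand` draws of N cells
#' sampled uniformly without replacement from *all* cells. The Monte Carlo
#' p-value is upper-tail via [mc_pvalue()] (add-one denominator); its
#' lower-tail companion flags biomes sitting below the null.
#'
#' @param data Tibble with one row per cell.
#' @param value Column holding the per-cell metric (richness or a beta
#'   score); tidy-eval.
#' @param biome Column of biome labels; tidy-eval.
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Integer seed.
#' @return A tibble with one row per biome: `biome, n_cells, observed_mean,
#'   observed_sd, random_mean, random_sd, p, p_lower, p_label`.
#' @export
biome_randomization <- function(data, value, biome, n_rand = 10000,
                                seed = NULL) {
  n_rand <- check_count(n_rand, "n_rand", 1)
  v <- pull_col(data, {{ value }})
  g <- pull_col(data, {{ biome }})
  if (length(v) != length(g)) stop("column length mismatch.", call. = FALSE)
  local_seed(seed)
  groups <- sort(unique(as.character(g)))
  purrr::map_dfr(groups, function(b) {
    idx <- which(g == b)
    if (length(idx) == 0) {
      warning("biome '", b, "' has no cells; skipped.")
      return(NULL)
    }
    obs <- mean(v[idx])
    rand_means <- vapply(seq_len(n_rand), function(i) {
      mean(v[sample.int(length(v), length(idx))])
    }, numeric(1))
    pv <- mc_pvalue(obs, rand_means)
    tibble::tibble(
      biome = b, n_cells = length(idx),
      observed_mean = obs, observed_sd = sd(v[idx]),
      random_mean = mean(rand_means), random_sd = sd(rand_means),
      p = pv$p, p_lower = pv$p_lower, p_label = pv$p_label
    )
  })
}

#' Monte Carlo test of AUC dependence on occurrence count
#'
#' Species are binned into occurrence-count classes (`[4,15]`, `[16,30]`,
#' `[31,45]`, ... by default). The first class is the control: its observed
#' mean AUC is the critical value. For every other class of k species, the
#' test draws k species uniformly without replacement from all modelled
#' species `n_rand` times; the class p-value is the fraction of random mean
#' AUCs greater than or equal to the *control class's* observed mean, with
#' the plain `n_rand` divisor. A large p means the class's models are not
#' systematically better than a random species set — i.e. AUC does not
#' simply track occurrence count. A per-class-reference variant (each class
#' compared with its own observed mean) is available but off by default.
#'
#' @param data Tibble with one row per modelled species.
#' @param auc Column of per-species AUC values; tidy-eval.
#' @param n_occurrences Column of occurrence counts; tidy-eval.
#' @param class_width Width of the occurrence classes after the first
#'   (default 15).
#' @param first_class Two-element vector, the control class bounds (default
#'   `c(4, 15)`).
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Integer seed.
#' @param reference `"control"` (as described) or `"own_class"` (variant).
#' @return A tibble: `class, n_species, mean_auc, p, p_label` — the control
#'   row and empty classes carry `NA` p.
#' @export
auc_class_test <- function(data, auc, n_occurrences, class_width = 15,
                           first_class = c(4, 15), n_rand = 10000,
                           seed = NULL,
                           reference = c("control", "own_class")) {
  reference <- match.arg(reference)
  n_rand <- check_count(n_rand, "n_rand", 1)
  a <- pull_col(data, {{ auc }})
  n_occ <- pull_col(data, {{ n_occurrences }})
  if (any(n_occ < first_class[1])) {
    stop("every species needs at least ", first_class[1], " occurrences.",
         call. = FALSE)
  }
  lo <- first_class[1]; hi <- first_class[2]
  breaks <- c(lo, hi)
  while (max(n_occ) > breaks[length(breaks)]) {
    breaks <- c(breaks, breaks[length(breaks)] + class_width)
  }
  n_classes <- length(breaks) - 1
  labels <- vapply(seq_len(n_classes), function(i) {
    sprintf("%d to %d", if (i == 1) breaks[1] else breaks[i] + 1,
            breaks[i + 1])
  }, character(1))
  cls <- findInterval(n_occ, c(breaks[1], breaks[-1] + 1),
                      rightmost.closed = FALSE)

  local_seed(seed)
  control_mean <- mean(a[cls == 1])
  purrr::map_dfr(seq_len(n_classes), function(i) {
    idx <- which(cls == i)
    k <- length(idx)
    row <- tibble::tibble(class = labels[i], n_species = k,
                          mean_auc = if (k > 0) mean(a[idx]) else NA_real_,
                          p = NA_real_, p_label = NA_character_)
    if (i == 1 || k == 0) return(row)
    crit <- if (reference == "control") control_mean else mean(a[idx])
    rand_means <- vapply(seq_len(n_rand), function(r) {
      mean(a[sample.int(length(a), k)])
    }, numeric(1))
    hits <- sum(rand_means >= crit)
    row$p <- hits / n_rand          # plain divisor, as this test defines it
    row$p_label <- if (hits == 0) sprintf("< %.4g", 1 / n_rand) else
      sprintf("%.4g", row$p)
    row
  })
}

#' Randomization test of protected-cell importance
#'
#' Classifies cells as protected (coverage fraction at least `cutoff`) or
#' unprotected, takes the observed mean conservation importance over the
#' protected cells, and compares it with the means of equally sized random
#' draws from the *unprotected* cells (without replacement). Run for the
#' whole region and, optionally, within each biome. An upper-tail p near 1
#' means reserves sit on cells no more important than a random complement —
#' the signature of a reserve network blind to the taxon.
#'
#' @param data Tibble with one row per cell.
#' @param importance Column of per-cell importance; tidy-eval.
#' @param protection Column of protected coverage fractions in `[0,1]`;
#'   tidy-eval.
#' @param biome Optional biome-label column for per-biome runs; tidy-eval.
#' @param cutoff Protected-classification cutoff (default 0.5).
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Integer seed.
#' @param scope `"whole"` (default) or `"per_biome"` (whole-region row plus
#'   one row per biome; requires `biome`).
#' @return A tibble with one row per scope: `scope, n_cells, n_protected,
#'   observed_mean, observed_sd, random_mean, random_sd, p, p_lower,
#'   p_label`. A scope with no protected (or no unprotected) cells yields
#'   `NA` statistics and is flagged in `p_label`.
#' @export
protection_randomization <- function(data, importance, protection,
                                     biome = NULL, cutoff = 0.5,
                                     n_rand = 10000, seed = NULL,
                                     scope = c("whole", "per_biome")) {
  scope <- match.arg(scope)
  n_rand <- check_count(n_rand, "n_rand", 1)
  imp <- pull_col(data, {{ importance }})
  prot <- pull_col(data, {{ protection }})
  biome_quo <- rlang::enquo(biome)
  b <- if (!rlang::quo_is_null(biome_quo)) {
    as.character(pull_col(data, !!biome_quo))
  }
  if (scope == "per_biome" && is.null(b)) {
    stop("per-biome scope needs a `biome` column.", call. = FALSE)
  }
  local_seed(seed)

  one_scope <- function(label, idx) {
    is_prot <- prot[idx] >= cutoff
    n_p <- sum(is_prot); n_u <- sum(!is_prot)
    if (n_p == 0 || n_u == 0) {
      return(tibble::tibble(
        scope = label, n_cells = length(idx), n_protected = n_p,
        observed_mean = NA_real_, observed_sd = NA_real_,
        random_mean = NA_real_, random_sd = NA_real_,
        p = NA_real_, p_lower = NA_real_,
        p_label = "undefined (no protected or no unprotected cells)"))
    }
    obs <- mean(imp[idx][is_prot])
    pool <- imp[idx][!is_prot]
    draw_n <- min(n_p, n_u)
    rand_means <- vapply(seq_len(n_rand), function(i) {
      mean(pool[sample.int(n_u, draw_n)])
    }, numeric(1))
    pv <- mc_pvalue(obs, rand_means)
    tibble::tibble(
      scope = label, n_cells = length(idx), n_protected = n_p,
      observed_mean = obs,
      observed_sd = if (n_p > 1) sd(imp[idx][is_prot]) else NA_real_,
      random_mean = mean(rand_means), random_sd = sd(rand_means),
      p = pv$p, p_lower = pv$p_lower, p_label = pv$p_label
    )
  }

  out <- one_scope("total", seq_along(imp))
  if (scope == "per_biome") {
    per <- purrr::map_dfr(sort(unique(b)),
                          function(bb) one_scope(bb, which(b == bb)))
    out <- dplyr::bind_rows(out, per)
  }
  out
}
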