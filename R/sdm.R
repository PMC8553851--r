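#' Sample background cells
#'
#' Uniform sample without replacement over the valid cells of the grid, used
#' as the pseudo-absence set of the presence-background models.
#'
#' @param grid A [grid_spec()], or an integer count of valid cells.
#' @param n Sample size.
#' @param seed Integer seed (`NULL` leaves the RNG stream alone).
#' @param valid_cells Optional vector of valid cell ids to sample from;
#'   default: every cell of the grid.
#' @return Sorted integer vector of sampled cell ids.
#' @export
sample_background <- function(grid, n, seed = NULL, valid_cells = NULL) {
  if (is.null(valid_cells)) {
    nc <- if (inherits(grid, "grid_spec")) n_cells(grid) else
      check_count(grid, "grid", 1)
    valid_cells <- seq_len(nc) - 1L
  }
  n <- check_count(n, "n", 1)
  if (n > length(valid_cells)) {
    stop("`n` (", n, ") exceeds the number of valid cells (",
         length(valid_cells), ").", call. = FALSE)
  }
  local_seed(seed)
  sort(sample(valid_cells, n))
}

# linear + quadratic feature expansion of the retained axes at given rows
sdm_features <- function(axes, rows) {
  axis_cols <- grep("^axis_", names(axes), value = TRUE)
  if (length(axis_cols) == 0) stop("no axis_* columns in `axes`.",
                                   call. = FALSE)
  X <- as.matrix(axes[rows, axis_cols, drop = FALSE])
  out <- cbind(X, X^2)
  colnames(out) <- c(axis_cols, paste0(axis_cols, "_sq"))
  out
}

#' Fit a presence-background distribution model
#'
#' A ridge-penalized logistic regression of presence cells against background
#' cells on linear and quadratic terms of the environmental PCA axes — an
#' explicit, reproducible presence-background model in the maximum-entropy
#' tradition. Features are standardized internally; the intercept is never
#' penalized. If an unpenalized fit fails to converge (the signature of
#' complete separation), the model is refitted at the default regularization
#' and flagged.
#'
#' @param axes Axis-score tibble from [pca_reduce()] (`$axes`).
#' @param presence_cells Cell ids holding presences (at least 3 — the
#'   modelling floor for occurrence data).
#' @param background_cells Cell ids of the background sample. Presence cells
#'   appearing in the background are kept, as usual in presence-background
#'   designs.
#' @param regularization Ridge penalty (lambda) on the standardized features.
#'   Default 1.
#' @param species Optional species id carried through to outputs.
#' @return An object of class `sdm_model`.
#' @export
fit_sdm <- function(axes, presence_cells, background_cells,
                    regularization = 1, species = NULL) {
  if (length(presence_cells) < 3) {
    stop("need at least 3 presence cells to fit a model.", call. = FALSE)
  }
  fit_sdm_impl(axes, presence_cells, background_cells, regularization,
               species)
}

# the fit without the 3-presence modelling floor; cross-validation folds of a
# floor-sized species legitimately train on fewer presences
fit_sdm_impl <- function(axes, presence_cells, background_cells,
                         regularization = 1, species = NULL) {
  if (regularization < 0) stop("`regularization` must be >= 0.", call. = FALSE)
  rows_p <- match(presence_cells, axes$cell_id)
  rows_b <- match(background_cells, axes$cell_id)
  if (anyNA(rows_p) || anyNA(rows_b)) {
    stop("some cells are missing from `axes`.", call. = FALSE)
  }
  F <- sdm_features(axes, c(rows_p, rows_b))
  if (anyNA(F)) stop("features are not finite at all used cells.",
                     call. = FALSE)
  y <- c(rep(1, length(rows_p)), rep(0, length(rows_b)))
  centers <- colMeans(F)
  scales <- apply(F, 2, sd)
  scales[scales < 1e-12] <- 1
  Fs <- sweep(sweep(F, 2, centers), 2, scales, `/`)
  X <- cbind(`(intercept)` = 1, Fs)

  fit <- ridge_logistic(X, y, lambda = regularization)
  separation_refit <- FALSE
  if (!fit$converged && regularization == 0) {
    fit <- ridge_logistic(X, y, lambda = 1)
    separation_refit <- TRUE
    regularization <- 1
  }
  if (!fit$converged) {
    stop("SDM fit did not converge (gradient norm ",
         format(fit$grad_norm), ").", call. = FALSE)
  }
  structure(
    list(species = species, coef = fit$coef,
         feature_names = colnames(F), centers = centers, scales = scales,
         regularization = regularization,
         separation_refit = separation_refit,
         n_presence = length(presence_cells),
         n_background = length(background_cells),
         n_axes = sum(!grepl("_sq$", colnames(F)))),
    class = "sdm_model"
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf(
    "<sdm_model>%s %d presences vs %d background, %d axes (lambda = %g)%s\n",
    if (is.null(x$species)) "" else paste0(" ", x$species),
    x$n_presence, x$n_background, x$n_axes, x$regularization,
    if (x$separation_refit) " [refit: separation]" else ""))
  invisible(x)
}

#' Predict per-cell suitability
#'
#' Logistic transform of the fitted linear predictor, so suitability lies in
#' `[0, 1]` and preserves the predictor's ordering. Cells with missing axis
#' scores propagate `NA`.
#'
#' @param model An [fit_sdm()] model.
#' @param axes Axis-score tibble on the training grid.
#' @return A tibble `cell_id, row, col, suitability`.
#' @export
predict_suitability <- function(model, axes) {
  axis_cols <- grep("^axis_", names(axes), value = TRUE)
  expected <- model$feature_names[!grepl("_sq$", model$feature_names)]
  if (!identical(sort(axis_cols), sort(expected))) {
    stop("axis columns do not match the model's training grid.",
         call. = FALSE)
  }
  F <- sdm_features(axes, seq_len(nrow(axes)))
  F <- F[, model$feature_names, drop = FALSE]
  Fs <- sweep(sweep(F, 2, model$centers), 2, model$scales, `/`)
  eta <- model$coef[1] + drop(Fs %*% model$coef[-1])
  out <- axes[intersect(c("cell_id", "row", "col"), names(axes))]
  out$suitability <- plogis(eta)
  attr(out, "grid") <- attr(axes, "grid", exact = TRUE)
  out
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a randomly chosen
#' presence score exceeds a randomly chosen background score, ties counting
#' one half.
#'
#' @param scores_presence,scores_background Non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) {
    stop("both score sets must be non-empty.", call. = FALSE)
  }
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Max-TSS threshold
#'
#' Scans every threshold that yields a distinct classification — midpoints
#' between consecutive distinct pooled scores, plus `-Inf`/`+Inf` sentinels —
#' and returns the one maximizing the true skill statistic
#' (sensitivity + specificity − 1), with ties broken toward the *higher*
#' threshold (the more range-restricted binarization). A cell is classified
#' present when its score is greater than or equal to the threshold.
#'
#' @inheritParams auc
#' @return One-row tibble: `threshold, sensitivity, specificity, tss`.
#' @export
max_tss_threshold <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) {
    stop("both score sets must be non-empty.", call. = FALSE)
  }
  u <- sort(unique(c(scores_presence, scores_background)))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(scores_presence >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores_background < t), numeric(1))
  tss <- sens + spec - 1
  best <- max(tss)
  pick <- max(which(tss >= best - 1e-12))   # ties -> higher threshold
  tibble::tibble(threshold = cand[pick], sensitivity = sens[pick],
                 specificity = spec[pick], tss = tss[pick])
}

#' Binarize a suitability map at a threshold
#'
#' @param suitability Tibble with a `suitability` column (from
#'   [predict_suitability()]) or a bare numeric vector.
#' @param threshold Finite cutoff (or `-Inf`/`Inf` sentinels); a cell is
#'   present iff suitability >= threshold. `NA` stays `NA`.
#' @return Same shape as the input with `presence` (0/1) replacing or joining
#'   `suitability`.
#' @export
binarize <- function(suitability, threshold) {
  if (is.data.frame(suitability)) {
    out <- suitability
    out$presence <- as.numeric(out$suitability >= threshold)
    out$suitability <- NULL
    attr(out, "grid") <- attr(suitability, "grid", exact = TRUE)
    return(out)
  }
  as.numeric(suitability >= threshold)
}

#' Evaluate a distribution model by cross-validation
#'
#' Presence cells are partitioned into `k_folds` folds; for each fold the
#' model is refitted on the remaining presences (the background is reused)
#' and scored on the held-out presences against the background, yielding
#' fold-wise AUC and max-TSS values whose means are the reported
#' cross-validated `auc` and `cv_tss`. The reported `threshold`,
#' `sensitivity`, `specificity` and `tss` come from the full-data fit at its
#' max-TSS threshold, so `tss = sensitivity + specificity - 1` holds exactly
#' for the binarization actually used downstream.
#'
#' @inheritParams fit_sdm
#' @param k_folds Number of folds (default 5); reduced with a warning when a
#'   species has fewer presences than folds.
#' @param seed Integer seed for the fold assignment.
#' @return One-row tibble: `species, n_presence, auc, cv_tss, tss, threshold,
#'   sensitivity, specificity, k_folds`. The full-data model is attached as
#'   attribute `model`, its predictions as attribute `suitability`.
#' @export
evaluate_sdm <- function(axes, presence_cells, background_cells,
                         k_folds = 5, seed = NULL, regularization = 1,
                         species = NULL) {
  k_folds <- check_count(k_folds, "k_folds", 2)
  np <- length(presence_cells)
  if (np < k_folds) {
    warning("only ", np, " presences; reducing folds from ", k_folds,
            " to ", np, ".")
    k_folds <- np
  }
  local_seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), np))

  fold_stats <- purrr::map_dfr(seq_len(k_folds), function(k) {
    train <- presence_cells[fold != k]
    test <- presence_cells[fold == k]
    m <- fit_sdm_impl(axes, train, background_cells,
                      regularization = regularization, species = species)
    pred <- predict_suitability(m, axes)
    s_test <- pred$suitability[match(test, pred$cell_id)]
    s_bg <- pred$suitability[match(background_cells, pred$cell_id)]
    tss_k <- max_tss_threshold(s_test, s_bg)$tss
    tibble::tibble(auc = auc(s_test, s_bg), tss = tss_k)
  })

  full <- fit_sdm(axes, presence_cells, background_cells,
                  regularization = regularization, species = species)
  pred <- predict_suitability(full, axes)
  s_p <- pred$suitability[match(presence_cells, pred$cell_id)]
  s_b <- pred$suitability[match(background_cells, pred$cell_id)]
  thr <- max_tss_threshold(s_p, s_b)

  out <- tibble::tibble(
    species = species %||% NA_character_,
    n_presence = np,
    auc = mean(fold_stats$auc),
    cv_tss = mean(fold_stats$tss),
    tss = thr$tss,
    threshold = thr$threshold,
    sensitivity = thr$sensitivity,
    specificity = thr$specificity,
    k_folds = k_folds
  )
  attr(out, "model") <- full
  attr(out, "suitability") <- pred
  out
}
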