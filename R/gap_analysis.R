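#' Classify cells as protected
#'
#' A cell counts as protected when at least `cutoff` (default 50%) of it lies
#' within a conservation unit.
#'
#' @param protection Per-cell coverage fractions in `[0, 1]` (vector), or a
#'   tibble with a `protection` column.
#' @param cutoff Classification cutoff (default 0.5; the rule is `>=`).
#' @return Logical vector, or the tibble with a logical `protected` column
#'   appended.
#' @export
protected_cells <- function(protection, cutoff = 0.5) {
  if (is.data.frame(protection)) {
    out <- protection
    out$protected <- out$protection >= cutoff
    return(out)
  }
  protection >= cutoff
}

#' Per-species protection status
#'
#' A species is protected (status 1) when at least one of its occupied cells
#' is protected. Species occupying no cells at all cannot be classified and
#' are reported separately.
#'
#' @param cm A community matrix.
#' @param protected Logical vector over the community matrix's cells (e.g.
#'   from [protected_cells()]).
#' @return A tibble `species, range_cells, protected` (0/1) for species with
#'   non-empty ranges, with attribute `report` listing range-zero species.
#' @export
species_protection_status <- function(cm, protected) {
  M <- cm_as_matrix(cm)
  if (length(protected) != nrow(M)) {
    stop("`protected` must have one entry per community-matrix cell.",
         call. = FALSE)
  }
  rng <- colSums(M)
  status <- as.integer(colSums(M * protected) > 0)
  out <- tibble::tibble(species = colnames(M), range_cells = unname(rng),
                        protected = status)
  empty <- out$species[out$range_cells == 0]
  out <- out[out$range_cells > 0, ]
  attr(out, "report") <- empty
  out
}

#' Per-species range size
#'
#' Range size is the number of cells a species occupies in the community
#' matrix (column sums).
#'
#' @param cm A community matrix.
#' @return A tibble `species, range_cells`.
#' @export
range_size <- function(cm) {
  M <- cm_as_matrix(cm)
  tibble::tibble(species = colnames(M), range_cells = unname(colSums(M)))
}

#' Logistic regression of protection status on range size
#'
#' Maximum-likelihood logistic fit of the per-species protected/unprotected
#' status (0/1) on range size in cells, the model behind the
#' minimum-range-size-for-protection estimate. The reported chi-square is the
#' likelihood-ratio statistic against the intercept-only model (1 df).
#' Complete separation is detected (non-convergence or unbounded linear
#' predictor) and handled by a ridge-penalized refit, flagged in the result.
#'
#' @param data Tibble with one row per species.
#' @param range_cells Column of range sizes in cells; tidy-eval.
#' @param protected Column of 0/1 protection statuses; tidy-eval.
#' @return An object of class `protection_fit` with elements `intercept`,
#'   `slope`, `chi_square`, `df`, `p_value`, `separation`, `n`,
#'   `range_span`, and the underlying `glm` (when used). Methods: `tidy()`,
#'   `glance()`, [protection_threshold()], `autoplot()`.
#' @export
fit_protection_logistic <- function(data, range_cells, protected) {
  x <- pull_col(data, {{ range_cells }})
  y <- pull_col(data, {{ protected }})
  if (!all(y %in% c(0, 1))) stop("`protected` must be 0/1.", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("all species share one protection status; the regression is ",
         "undefined.", call. = FALSE)
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  separation <- !fit$converged || max(abs(predict(fit))) > 30
  if (separation) {
    # penalized-likelihood fallback keeps the estimate finite
    xs <- (x - mean(x)) / sd(x)
    rf <- ridge_logistic(cbind(1, xs), y, lambda = 0.5)
    slope <- rf$coef[2] / sd(x)
    intercept <- rf$coef[1] - slope * mean(x)
    eta <- intercept + slope * x
    ll_full <- sum(y * eta - log1p(exp(eta)))
  } else {
    intercept <- unname(coef(fit)[1])
    slope <- unname(coef(fit)[2])
    ll_full <- as.numeric(stats::logLik(fit))
  }
  p0 <- mean(y)
  ll_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  chi_square <- max(0, 2 * (ll_full - ll_null))
  structure(
    list(intercept = intercept, slope = slope,
         chi_square = chi_square, df = 1L,
         p_value = pchisq(chi_square, df = 1, lower.tail = FALSE),
         separation = separation, n = length(y),
         range_span = range(x),
         data = tibble::tibble(range_cells = x, protected = y),
         glm = if (!separation) fit),
    class = "protection_fit"
  )
}

#' @export
print.protection_fit <- function(x, ...) {
  cat(sprintf(
    "<protection_fit> n = %d, logit(p) = %.3f + %.3f * cells, X2(1) = %.3f, p = %.3g%s\n",
    x$n, x$intercept, x$slope, x$chi_square, x$p_value,
    if (x$separation) " [separation: penalized refit]" else ""))
  invisible(x)
}

#' @rdname fit_protection_logistic
#' @param x A `protection_fit`.
#' @param ... Unused.
#' @method tidy protection_fit
#' @export
tidy.protection_fit <- function(x, ...) {
  if (!is.null(x$glm)) {
    s <- summary(x$glm)$coefficients
    return(tibble::tibble(
      term = c("(Intercept)", "range_cells"),
      estimate = unname(s[, 1]), std.error = unname(s[, 2]),
      statistic = unname(s[, 3]), p.value = unname(s[, 4])))
  }
  tibble::tibble(term = c("(Intercept)", "range_cells"),
                 estimate = c(x$intercept, x$slope),
                 std.error = NA_real_, statistic = NA_real_,
                 p.value = NA_real_)
}

#' @rdname fit_protection_logistic
#' @method glance protection_fit
#' @export
glance.protection_fit <- function(x, ...) {
  tibble::tibble(n = x$n, chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value, separation = x$separation)
}

#' Minimum range size for protection
#'
#' The smallest integer range size (in cells) whose fitted protection
#' probability reaches `prob`, and its area equivalent. Undefined (flagged,
#' `NA` threshold) when the slope is not positive or the crossing lies
#' outside the observed range-size span.
#'
#' @param fit A [fit_protection_logistic()] result.
#' @param prob Target probability (default 0.5).
#' @param cell_area_km2 Nominal cell area for the km2 report (default 85).
#' @return One-row tibble: `threshold_cells, threshold_km2, prob, defined`.
#' @export
protection_threshold <- function(fit, prob = 0.5, cell_area_km2 = 85) {
  check_fraction(prob, "prob", 0, 1)
  if (prob == 0) {
    return(tibble::tibble(threshold_cells = 1, threshold_km2 = cell_area_km2,
                          prob = prob, defined = TRUE))
  }
  if (fit$slope <= 0) {
    return(tibble::tibble(threshold_cells = NA_real_,
                          threshold_km2 = NA_real_, prob = prob,
                          defined = FALSE))
  }
  crossing <- (qlogis(prob) - fit$intercept) / fit$slope
  cells <- max(1, ceiling(crossing - 1e-9))
  defined <- crossing <= fit$range_span[2] + 1e-9
  tibble::tibble(
    threshold_cells = if (defined) cells else NA_real_,
    threshold_km2 = if (defined) cells * cell_area_km2 else NA_real_,
    prob = prob, defined = defined
  )
}
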