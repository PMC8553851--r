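#' Standardize an environmental stack
#'
#' Centres and scales each layer to mean 0, SD 1 over its valid (non-missing)
#' cells, the usual preparation for a correlation-matrix PCA of layers in
#' incommensurable units. Constant layers (SD numerically 0) cannot be
#' standardized and are dropped with a warning.
#'
#' @param stack Tibble with cell columns (`cell_id`, `row`, `col`, optionally
#'   `lon`, `lat`) and one numeric column per layer.
#' @param layer_cols Character vector of layer column names; by default every
#'   column not in the cell-identification set.
#' @return The stack with layers standardized, carrying attributes `centers`,
#'   `scales` (named numeric vectors) and `dropped_layers`.
#' @export
standardize_stack <- function(stack, layer_cols = NULL) {
  layer_cols <- layer_cols %||% setdiff(names(stack),
                                        c("cell_id", "row", "col", "lon", "lat"))
  if (length(layer_cols) == 0) stop("no layer columns found.", call. = FALSE)
  centers <- scales <- stats::setNames(numeric(length(layer_cols)), layer_cols)
  dropped <- character()
  out <- stack
  for (col in layer_cols) {
    v <- out[[col]]
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12) {
      warning("layer '", col, "' is constant; dropped from the stack.")
      dropped <- c(dropped, col)
      out[[col]] <- NULL
      next
    }
    centers[col] <- m
    scales[col] <- s
    out[[col]] <- (v - m) / s
  }
  keep <- setdiff(layer_cols, dropped)
  attr(out, "centers") <- centers[keep]
  attr(out, "scales") <- scales[keep]
  attr(out, "dropped_layers") <- dropped
  attr(out, "grid") <- attr(stack, "grid", exact = TRUE)
  out
}

#' Undo [standardize_stack()]
#'
#' @param stack A standardized stack carrying `centers`/`scales` attributes.
#' @return The stack on its original scale.
#' @export
unstandardize_stack <- function(stack) {
  centers <- attr(stack, "centers", exact = TRUE)
  scales <- attr(stack, "scales", exact = TRUE)
  if (is.null(centers)) stop("not a standardized stack.", call. = FALSE)
  out <- stack
  for (col in names(centers)) {
    out[[col]] <- out[[col]] * scales[col] + centers[col]
  }
  attr(out, "centers") <- NULL
  attr(out, "scales") <- NULL
  out
}

#' Compress a collinear stack with PCA
#'
#' Principal component analysis of the standardized layer stack (equivalently,
#' of the layer correlation matrix). The number of retained axes is the
#' smallest `k` whose cumulative explained-variance fraction reaches
#' `target_cumvar`. Axis signs are fixed by forcing each axis's
#' largest-magnitude loading positive, so results are reproducible across
#' platforms. The retained axes' per-cell scores become the orthogonal
#' predictors for the distribution models.
#'
#' @param stack A standardized stack from [standardize_stack()].
#' @param target_cumvar Cumulative variance target in (0, 1]; default 0.95.
#' @param layer_cols Layer columns; default: all non-cell columns.
#' @return An object of class `env_pca`: a list with `loadings` (layers x
#'   axes), `explained` (per-axis variance fractions), `n_retained`,
#'   `centers`, `scales`, and `axes` — a tibble `cell_id, row, col,
#'   axis_1 ... axis_k` of retained scores (missing cells propagate as `NA`).
#'   `tidy()` returns the variance table, `glance()` a one-row summary.
#' @export
pca_reduce <- function(stack, target_cumvar = 0.95, layer_cols = NULL) {
  check_fraction(target_cumvar, "target_cumvar", 0, 1, open_lo = TRUE)
  layer_cols <- layer_cols %||% setdiff(names(stack),
                                        c("cell_id", "row", "col", "lon", "lat"))
  X <- as.matrix(stack[layer_cols])
  valid <- stats::complete.cases(X)
  if (sum(valid) <= length(layer_cols)) {
    stop("need more valid cells than layers for PCA.", call. = FALSE)
  }
  fit <- prcomp(X[valid, , drop = FALSE], center = TRUE, scale. = FALSE)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  n_retained <- which(cumsum(var_frac) >= target_cumvar - 1e-10)[1]

  rot <- fit$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)

  scores <- matrix(NA_real_, nrow(X), n_retained)
  scores[valid, ] <- sweep(X[valid, , drop = FALSE], 2, fit$center) %*%
    rot[, seq_len(n_retained), drop = FALSE]
  colnames(scores) <- paste0("axis_", seq_len(n_retained))

  axes <- dplyr::bind_cols(stack[intersect(c("cell_id", "row", "col"),
                                           names(stack))],
                           tibble::as_tibble(scores))
  attr(axes, "grid") <- attr(stack, "grid", exact = TRUE)

  structure(
    list(loadings = rot, explained = var_frac, n_retained = n_retained,
         centers = attr(stack, "centers", exact = TRUE),
         scales = attr(stack, "scales", exact = TRUE),
         target_cumvar = target_cumvar, axes = axes),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf(
    "<env_pca> %d of %d axes retained (%.1f%% variance, target %.0f%%)\n",
    x$n_retained, length(x$explained),
    100 * sum(x$explained[seq_len(x$n_retained)]), 100 * x$target_cumvar))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname pca_reduce
#' @param x An `env_pca` object.
#' @param ... Unused.
#' @method tidy env_pca
#' @export
tidy.env_pca <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$explained),
    explained_variance = x$explained,
    cumulative_variance = cumsum(x$explained),
    retained = seq_along(x$explained) <= x$n_retained
  )
}

#' @rdname pca_reduce
#' @method glance env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$explained),
    n_retained = x$n_retained,
    cumulative_variance = sum(x$explained[seq_len(x$n_retained)]),
    target_cumvar = x$target_cumvar
  )
}
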