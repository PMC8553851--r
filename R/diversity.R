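#' Build the cells-by-species community matrix
#'
#' Stacks the binarized per-species distribution maps into one wide table:
#' one row per grid cell, one 0/1 column per species — the hub every
#' downstream diversity, prioritization and gap computation reads from.
#' Cells with a missing prediction for *any* species are excluded and
#' reported.
#'
#' @param predictions Long tibble `species, cell_id, presence` covering the
#'   grid (e.g. row-bound [binarize()] outputs), or a named list of per-cell
#'   0/1 vectors in cell-id order.
#' @param grid A [grid_spec()].
#' @return A tibble `cell_id, row, col, <species...>` with attributes `grid`
#'   and `excluded_cells` (cell ids dropped for missingness).
#' @export
community_matrix <- function(predictions, grid) {
  cells <- grid_cells(grid)[c("cell_id", "row", "col")]
  if (is.list(predictions) && !is.data.frame(predictions)) {
    if (is.null(names(predictions))) {
      stop("a list of predictions must be named by species.", call. = FALSE)
    }
    wide <- dplyr::bind_cols(
      cells, tibble::as_tibble(lapply(predictions, as.numeric)))
  } else {
    need <- c("species", "cell_id", "presence")
    if (!all(need %in% names(predictions))) {
      stop("`predictions` must have columns species, cell_id, presence.",
           call. = FALSE)
    }
    wide <- tidyr::pivot_wider(predictions[need], names_from = "species",
                               values_from = "presence")
    wide <- dplyr::left_join(cells, wide, by = "cell_id")
  }
  if (ncol(wide) <= 3) stop("at least one species is required.",
                            call. = FALSE)
  sp_cols <- setdiff(names(wide), c("cell_id", "row", "col"))
  bad <- !stats::complete.cases(wide[sp_cols])
  excluded <- wide$cell_id[bad]
  out <- wide[!bad, ]
  vals <- as.matrix(out[sp_cols])
  if (!all(vals %in% c(0, 1))) {
    stop("community matrix entries must be 0 or 1.", call. = FALSE)
  }
  attr(out, "grid") <- grid
  attr(out, "excluded_cells") <- excluded
  class(out) <- c("comm_matrix", class(out))
  out
}

# species columns / numeric matrix of a community matrix tibble
cm_species <- function(cm) setdiff(names(cm), c("cell_id", "row", "col"))
cm_as_matrix <- function(cm) {
  m <- as.matrix(cm[cm_species(cm)])
  rownames(m) <- cm$cell_id
  m
}

#' Per-cell species richness
#'
#' @param cm A community matrix from [community_matrix()].
#' @return A tibble `cell_id, row, col, richness` (row sums).
#' @export
richness <- function(cm) {
  out <- tibble::as_tibble(cm[c("cell_id", "row", "col")])
  out$richness <- unname(rowSums(cm_as_matrix(cm)))
  attr(out, "grid") <- attr(cm, "grid", exact = TRUE)
  out
}

#' Pairwise beta-diversity partition (Sorensen family)
#'
#' For every pair of cells with `a` shared species and `b`, `c` species
#' unique to either cell, total dissimilarity is partitioned into a turnover
#' (species-replacement) and a nestedness (richness-difference) component:
#' \deqn{\beta_{sor} = (b+c)/(2a+b+c), \quad
#'       \beta_{sim} = \min(b,c)/(a+\min(b,c)), \quad
#'       \beta_{sne} = \beta_{sor} - \beta_{sim}.}
#' Declared conventions for degenerate pairs: two empty cells are identical
#' (all three components 0); an empty against a non-empty cell is complete
#' dissimilarity attributed to turnover (`beta_sor = beta_sim = 1`,
#' `beta_sne = 0`).
#'
#' @param cm A community matrix (at least 2 cells).
#' @param max_cells Dense pairwise matrices need `n^2` memory; above this cap
#'   (default 4000 cells) the call errors and asks for subsampling rather
#'   than silently approximating.
#' @return A list of class `beta_parts` with symmetric zero-diagonal matrices
#'   `total`, `turnover`, `nestedness` (dimnames = cell ids).
#' @export
pairwise_beta <- function(cm, max_cells = 4000) {
  M <- cm_as_matrix(cm)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 cells.", call. = FALSE)
  if (n > max_cells) {
    stop("community matrix has ", n, " cells; dense pairwise matrices are ",
         "capped at ", max_cells, ". Subsample cells or raise `max_cells`.",
         call. = FALSE)
  }
  a <- tcrossprod(M)
  rich <- rowSums(M)
  b <- matrix(rich, n, n) - a          # unique to the row cell
  cc <- t(b)                           # unique to the column cell
  minbc <- pmin(b, cc)
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- minbc / (a + minbc)
  # degenerate pairs: 0/0 -> declared conventions
  both_empty <- outer(rich == 0, rich == 0, `&`)
  one_empty <- outer(rich == 0, rich == 0, `|`) & !both_empty
  sor[both_empty] <- 0
  sim[both_empty] <- 0
  sor[one_empty] <- 1
  sim[one_empty] <- 1
  sne <- sor - sim
  dimnames(sor) <- dimnames(sim) <- dimnames(sne) <-
    list(cm$cell_id, cm$cell_id)
  diag(sor) <- diag(sim) <- diag(sne) <- 0
  structure(list(total = sor, turnover = sim, nestedness = sne),
            class = "beta_parts",
            cell_id = cm$cell_id)
}

#' First principal-coordinate axis of a dissimilarity matrix
#'
#' Classical PCoA: Gower double-centering of \eqn{-\frac{1}{2} D \circ D},
#' leading eigenpair, scores scaled by the square root of the leading
#' eigenvalue. The axis sign (arbitrary in PCoA) is oriented so scores
#' correlate non-negatively with each cell's mean dissimilarity. A
#' non-positive leading eigenvalue yields all-zero scores with a warning.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return Numeric score vector (one per row of `D`).
#' @export
pcoa_first_axis <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("`D` must be a symmetric matrix.", call. = FALSE)
  }
  if (any(diag(D) != 0) || any(D < 0)) {
    stop("`D` must have zero diagonal and non-negative entries.",
         call. = FALSE)
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n,
                                              byrow = TRUE) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda1 <- e$values[1]
  if (lambda1 <= 1e-12) {
    if (any(D > 0)) warning("leading PCoA eigenvalue is not positive; ",
                            "returning zero scores.")
    return(numeric(n))
  }
  scores <- e$vectors[, 1] * sqrt(lambda1)
  r <- suppressWarnings(cor(scores, rowMeans(D)))
  if (!is.na(r) && r < 0) scores <- -scores
  scores
}

#' Per-cell diversity maps
#'
#' Bundles richness with the first-PCoA-axis spatialization of total beta
#' diversity and its turnover and nestedness components: each cell's score on
#' the leading axis of the corresponding pairwise dissimilarity matrix
#' summarizes its compositional position. Negative scores are legitimate axis
#' values; no shifting is applied.
#'
#' @param cm A community matrix (at least 2 cells).
#' @param max_cells Passed to [pairwise_beta()].
#' @return A tibble `cell_id, row, col, richness, beta_total, beta_turnover,
#'   beta_nestedness` with attribute `grid`.
#' @export
diversity_maps <- function(cm, max_cells = 4000) {
  parts <- pairwise_beta(cm, max_cells = max_cells)
  out <- richness(cm)
  out$beta_total <- pcoa_first_axis(parts$total)
  out$beta_turnover <- pcoa_first_axis(parts$turnover)
  out$beta_nestedness <- pcoa_first_axis(parts$nestedness)
  attr(out, "grid") <- attr(cm, "grid", exact = TRUE)
  out
}
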