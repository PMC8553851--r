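#' @importFrom rlang %||% .data enquo as_name
#' @importFrom stats plogis qlogis prcomp rnorm runif rpois pchisq glm binomial
#'   coef predict cor sd quantile dnorm
#' @importFrom utils head
NULL

# set the RNG for the calling frame and restore it on exit; NULL = leave alone
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) ||
      x < min) {
    stop("`", name, "` must be a whole number >= ", min, ".", call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                           open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop("`", name, "` must lie in ", if (open_lo) "(" else "[", lo, ", ", hi,
         if (open_hi) ")" else "]", ".", call. = FALSE)
  }
  x
}

# Ridge-penalized logistic regression by Newton/IRLS.
# X includes the intercept column; `penalize` marks coefficients carrying the
# ridge penalty (the intercept never does). Maximizes
#   sum[y*eta - log(1+exp(eta))] - lambda/2 * sum(penalize * beta^2).
ridge_logistic <- function(X, y, lambda = 0, penalize = NULL,
                           tol = 1e-8, maxit = 100) {
  p <- ncol(X)
  if (is.null(penalize)) penalize <- c(FALSE, rep(TRUE, p - 1))
  pen <- lambda * as.numeric(penalize)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # halve the step until the penalized log-likelihood does not decrease
    ll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e))) - sum(pen * b^2) / 2
    }
    ll0 <- ll(beta)
    s <- 1
    repeat {
      cand <- beta + s * step
      if (ll(cand) >= ll0 - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  g <- drop(crossprod(X, y - mu)) - pen * beta
  list(coef = beta, converged = converged || max(abs(g)) < 1e-6,
       grad_norm = max(abs(g)), iterations = it)
}

# smooth a matrix with a separable Gaussian kernel; edges renormalized
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(i - j, sd = sigma))
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# extract one column through full tidyselect semantics (bare name, string,
# all_of(...)); pull() alone does not accept select helpers
pull_col <- function(data, col) {
  out <- dplyr::select(data, {{ col }})
  if (ncol(out) != 1) stop("expected exactly one column.", call. = FALSE)
  out[[1]]
}
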