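#' Embed generation-time series in m dimensions
#'
#' Builds one m-dimensional point per lineage from the first m entries of its
#' generation-time series (lineages shorter than m are dropped, with the
#' count recorded). Treating each surviving lineage as a segment of one long
#' hypothetical lineage (an ergodicity assumption), the embedded points
#' sample the attractor of whatever dynamical system drives the
#' generation-time transitions.
#'
#' @param series A list of numeric generation-time series, a list of
#'   `lineage_series`, or a cycle `data.frame`.
#' @param m Embedding dimension (`>= 1`).
#' @return A numeric matrix with one row per eligible lineage and `m`
#'   columns; attribute `n_dropped` counts lineages shorter than `m`.
#' @export
embed_lineages <- function(series, m) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1")
  tl <- as_tau_series(series)
  len <- vapply(tl, length, integer(1))
  keep <- tl[len >= m]
  if (!length(keep)) stop("no lineage holds at least m = ", m, " cycles")
  out <- t(vapply(keep, function(v) v[seq_len(m)], numeric(m)))
  if (m == 1L) out <- matrix(unlist(lapply(keep, `[`, 1L)), ncol = 1L)
  attr(out, "n_dropped") <- sum(len < m)
  out
}

pairwise_distances <- function(vectors, norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  if (norm == "euclidean") {
    as.numeric(stats::dist(vectors))
  } else {
    as.numeric(stats::dist(vectors, method = "maximum"))
  }
}

#' Correlation integral
#'
#' The fraction of ordered pairs of embedded points closer than r:
#' \deqn{C^m(r) = \frac{1}{N^2} \sum_{i \ne j} I(r - |T^m(i) - T^m(j)|),}
#' with the Heaviside step I equal to 1 at 0 (distances exactly r count).
#' The literal `1/N^2` normalization is used, so `C` is bounded by
#' `1 - 1/N`.
#'
#' @param vectors Numeric matrix of embedded points (rows) from
#'   [embed_lineages()], or a numeric vector (treated as 1-D points).
#' @param r Radius or vector of radii (hours).
#' @param norm Distance norm: `"euclidean"` (default) or `"max"`.
#' @return `C^m(r)`, same length as `r`.
#' @export
#' @examples
#' correlation_integral(c(0, 1, 3), 1.5)  # 2/9
correlation_integral <- function(vectors, r, norm = c("euclidean", "max")) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 1L)
  n <- nrow(vectors)
  if (n < 2L) stop("need at least 2 embedded points")
  if (any(r < 0)) stop("r must be >= 0")
  d <- sort(pairwise_distances(vectors, norm))
  counts <- findInterval(r + 1e-12, d)  # unordered pairs with distance <= r
  2 * counts / n^2
}

#' Correlation-dimension estimate from a correlation-integral curve
#'
#' Moving linear regression on the log-log correlation-integral curve: an
#' ordinary least-squares slope is computed in every sliding window of
#' `regression_window` consecutive points (over the points with `C > 0`),
#' and the maximum slope is reported as the dimension estimate.
#'
#' @param r_grid Radii (hours).
#' @param C_values Correlation integrals at `r_grid`.
#' @param regression_window Points per local fit (default 5).
#' @return The dimension estimate (maximum local slope).
#' @export
estimate_dimension <- function(r_grid, C_values, regression_window = 5L) {
  ok <- is.finite(r_grid) & r_grid > 0 & is.finite(C_values) & C_values > 0
  x <- log(r_grid[ok])
  y <- log(C_values[ok])
  w <- as.integer(regression_window)
  if (length(x) < w) {
    stop("need at least ", w, " points with C > 0; got ", length(x))
  }
  n_win <- length(x) - w + 1L
  slopes <- vapply(seq_len(n_win), function(i) {
    xi <- x[i:(i + w - 1L)]
    yi <- y[i:(i + w - 1L)]
    if (stats::var(xi) == 0) return(NA_real_)
    stats::cov(xi, yi) / stats::var(xi)
  }, numeric(1))
  max(slopes, na.rm = TRUE)
}

#' Grassberger-Procaccia analysis of generation-time series
#'
#' Runs the full correlation-dimension analysis over a range of embedding
#' dimensions: for each m, lineages with at least m complete cycles are
#' embedded via their first m generation times, the correlation integral is
#' evaluated on a logarithmic radius grid spanning the 1st to 99th percentile
#' of observed pairwise distances, and the dimension is estimated by the
#' maximum moving-regression slope of the log-log curve. For a stochastic
#' process the estimates grow with m (`C^m(r) ~ r^m`); for a deterministic
#' process they saturate at the attractor dimension (`C^m(r) ~ r^D` for
#' `m >= D`).
#'
#' With N embedded lineages, estimates above about `2 log10(N)` exceed what
#' the sample can support and are flagged (field `reliable_limit`), not
#' suppressed.
#'
#' @param series A list of generation-time series, `lineage_series` list, or
#'   cycle `data.frame`.
#' @param m_range Embedding dimensions (default `1:9`).
#' @param n_grid Radius grid size (default 300).
#' @param regression_window Points per local regression (default 5).
#' @param norm Distance norm (default `"euclidean"`).
#' @return An object of class `gp_result`: list with `per_m` (per dimension:
#'   `m`, `r`, `C`, `slopes`, `estimate`, `N`), `estimates` (named vector),
#'   `reliable_limit`, and `flagged` (dimensions whose estimate exceeds the
#'   limit).
#' @export
gp_analysis <- function(series, m_range = 1:9, n_grid = 300L,
                        regression_window = 5L,
                        norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  tl <- as_tau_series(series)
  per_m <- lapply(m_range, function(m) {
    vec <- embed_lineages(tl, m)
    N <- nrow(vec)
    d <- sort(pairwise_distances(vec, norm))
    d <- d[d > 0]
    if (length(d) < 10L) stop("too few distinct pairwise distances at m = ", m)
    qs <- stats::quantile(d, c(0.01, 0.99), names = FALSE)
    r <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_grid))
    C <- 2 * findInterval(r + 1e-12, d) / N^2
    est <- estimate_dimension(r, C, regression_window)
    list(m = m, r = r, C = C, estimate = est, N = N)
  })
  estimates <- vapply(per_m, `[[`, numeric(1), "estimate")
  names(estimates) <- paste0("m", m_range)
  N_min <- min(vapply(per_m, `[[`, numeric(1), "N"))
  limit <- 2 * log10(N_min)
  structure(list(per_m = per_m, estimates = estimates,
                 reliable_limit = limit,
                 flagged = m_range[estimates > limit]),
            class = "gp_result")
}

#' @export
print.gp_result <- function(x, ...) {
  cat("Grassberger-Procaccia correlation-dimension analysis\n")
  for (p in x$per_m) {
    cat(sprintf("  m = %d: N = %d lineages, dimension estimate %.3f%s\n",
                p$m, p$N, p$estimate,
                if (p$m %in% x$flagged) "  [beyond sample-size support]"
                else ""))
  }
  cat(sprintf("  finite-sample support limit ~ %.2f\n", x$reliable_limit))
  invisible(x)
}

#' Saturation check for a dimension-estimate profile
#'
#' Deterministic dynamics make the correlation-dimension estimate plateau
#' once the embedding dimension exceeds the attractor dimension; stochastic
#' dynamics keep it growing. This helper reports whether the estimates for
#' `m >= m_from` stay within `tol` of each other.
#'
#' @param result A `gp_result`.
#' @param m_from First embedding dimension of the would-be plateau (default
#'   5).
#' @param tol Maximum spread of estimates on the plateau (default 0.5).
#' @return `TRUE` if the profile has saturated.
#' @export
gp_saturated <- function(result, m_from = 5L, tol = 0.5) {
  ms <- vapply(result$per_m, `[[`, numeric(1), "m")
  est <- result$estimates[ms >= m_from]
  if (length(est) < 2L) stop("need at least two estimates at m >= ", m_from)
  (max(est) - min(est)) < tol
}
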