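#' Shared axis limits across a layer's series
#'
#' Distribution glyphs of one layer (one geom + side combination) share a
#' single x-axis domain across every reaction and every selected condition,
#' so the same variable can be compared between reactions at a glance. The
#' domain is the global minimum and maximum over all values; a degenerate
#' domain (all values equal) is expanded by 0.5 on each side.
#'
#' @param series_values A list of numeric vectors (one per series).
#' @return Numeric `c(lo, hi)`.
#' @export
shared_limits <- function(series_values) {
  values <- unlist(series_values, use.names = FALSE)
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop(pg_error("pg_empty_data", "no values from which to compute shared limits"))
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) c(lo - 0.5, hi + 0.5) else c(lo, hi)
}

# Freedman-Diaconis bin count on the data, clamped to [5, 50]; sqrt fallback
# when the IQR collapses.
fd_bins <- function(values) {
  n <- length(values)
  iqr <- stats::IQR(values)
  if (iqr == 0) return(ceiling(sqrt(n)))
  width <- 2 * iqr * n^(-1 / 3)
  span <- diff(range(values))
  if (span == 0 || width == 0) return(ceiling(sqrt(n)))
  min(max(ceiling(span / width), 5L), 50L)
}

#' Histogram glyph over a shared domain
#'
#' Bins partition `[lo, hi]` into `n_bins` equal half-open intervals
#' `[e_i, e_{i+1})`, the last bin closed; values outside the domain are
#' excluded from the counts and reported in `n_excluded`.
#'
#' @param values Numeric vector, at least 2 values.
#' @param domain `c(lo, hi)` shared x-limits, `lo < hi`.
#' @param n_bins Number of bins; default is the Freedman-Diaconis rule on the
#'   values clamped to \[5, 50\], with a ceiling-sqrt(n) fallback when the IQR
#'   is zero.
#' @return A `histogram_glyph`: `bin_edges` (n_bins + 1), `counts` (n_bins),
#'   `domain`, `n_excluded`.
#' @export
histogram <- function(values, domain, n_bins = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop(pg_error("pg_insufficient_data", "histogram needs at least 2 values"))
  }
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  if (is.null(n_bins)) n_bins <- fd_bins(values)
  stopifnot(n_bins >= 1)
  edges <- seq(domain[1], domain[2], length.out = n_bins + 1)
  inside <- values >= domain[1] & values <= domain[2]
  idx <- findInterval(values[inside], edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, domain = domain,
                 n_excluded = sum(!inside)),
            class = "histogram_glyph")
}

# Silverman's rule of thumb; falls back to sd when the IQR collapses.
silverman_bw <- function(values) {
  n <- length(values)
  s <- stats::sd(values)
  iqr <- stats::IQR(values)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density glyph
#'
#' Evaluates the Gaussian kernel density estimate
#' `f(x) = (1 / (n h)) * sum_i phi((x - x_i) / h)` on an equally spaced grid
#' that spans both the shared domain and the data plus three bandwidths, so
#' the curve integrates to ~1 regardless of where the shared limits fall.
#'
#' @param values Numeric vector, at least 2 values with nonzero variance.
#' @param domain `c(lo, hi)` shared x-limits.
#' @param bandwidth Kernel bandwidth `h`; default Silverman's rule
#'   `0.9 * min(sd, IQR/1.34) * n^(-1/5)`.
#' @param grid_size Number of grid points.
#' @return A `density_glyph`: `grid`, `density`, `bandwidth`, `domain`.
#' @export
kde <- function(values, domain, bandwidth = NULL, grid_size = 128) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop(pg_error("pg_insufficient_data", "kde needs at least 2 values"))
  }
  if (stats::var(values) == 0) {
    stop(pg_error("pg_degenerate_distribution",
                  "kde needs values with nonzero variance; use a histogram instead"))
  }
  stopifnot(length(domain) == 2)
  h <- if (is.null(bandwidth)) silverman_bw(values) else bandwidth
  stopifnot(h > 0)
  lo <- min(domain[1], min(values) - 3 * h)
  hi <- max(domain[2], max(values) + 3 * h)
  grid <- seq(lo, hi, length.out = grid_size)
  n <- length(values)
  # vectorized kernel sum: grid_size x n standardized distances
  z <- outer(grid, values, "-") / h
  dens <- rowSums(stats::dnorm(z)) / (n * h)
  structure(list(grid = grid, density = dens, bandwidth = h, domain = domain),
            class = "density_glyph")
}

# trapezoidal integral, used by tests and internal sanity checks
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
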