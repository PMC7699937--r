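#' Rayleigh probability density
#'
#' `f(x; sigma) = (x / sigma^2) * exp(-x^2 / (2 sigma^2))` for `x >= 0`.
#' This is the exact nearest-neighbour distance law of a homogeneous planar
#' Poisson point process (with `sigma = 1 / sqrt(2 pi lambda)`), which is
#' why stomatal spacing statistics are compared against it.
#'
#' @param x Non-negative quantiles.
#' @param sigma Positive scale parameter (pixels).
#' @return Density values.
#' @export
rayleigh_pdf <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  if (any(x < 0)) stop("x must be non-negative")
  (x / sigma^2) * exp(-x^2 / (2 * sigma^2))
}

## Rayleigh probability mass per histogram bin via CDF differences.
## edges: increasing bin edges; sigma may be a vector -> matrix
## (length(sigma) x nbins).
rayleigh_bin_mass <- function(edges, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  e2 <- edges^2
  surv <- exp(-outer(1 / (2 * sigma^2), e2))   # P(X > edge)
  nb <- length(edges) - 1L
  surv[, seq_len(nb), drop = FALSE] - surv[, seq_len(nb) + 1L, drop = FALSE]
}

#' Empirical occurrence probabilities of edge distances
#'
#' Bins the distance vector on `[0, max(d) + bin_width)` with fixed-width
#' bins and normalizes the counts to occurrence probabilities.
#'
#' @param d Non-empty vector of positive distances (pixels).
#' @param bin_width Positive bin width (pixels).
#' @return A `DistanceHistogram`: list with `bin_edges` (length `nbins + 1`)
#'   and `probs` (non-negative, summing to 1).
#' @export
distance_histogram <- function(d, bin_width = 1) {
  if (length(d) == 0L) stop("distance vector is empty")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  nb <- floor(max(d) / bin_width) + 1L
  edges <- (0:nb) * bin_width
  bin <- findInterval(d, edges)            # bins are [lo, hi)
  counts <- tabulate(bin, nbins = nb)
  structure(list(bin_edges = edges, probs = counts / sum(counts)),
            class = "DistanceHistogram")
}

#' RMSD between an empirical histogram and a binned Rayleigh
#'
#' Converts the Rayleigh density to probability mass per histogram bin (CDF
#' difference across the bin edges) so both operands are on the
#' probability-mass scale, then returns
#' `sqrt(sum((mass - probs)^2) / n_bins)`. Zero is attained exactly when the
#' histogram equals the binned Rayleigh mass.
#'
#' @param hist A `DistanceHistogram`.
#' @param sigma Positive Rayleigh scale.
#' @return Non-negative RMSD.
#' @export
rayleigh_rmsd <- function(hist, sigma) {
  check_histogram(hist)
  mass <- rayleigh_bin_mass(hist$bin_edges, sigma)[1L, ]
  sqrt(mean((mass - hist$probs)^2))
}

check_histogram <- function(hist) {
  if (!inherits(hist, "DistanceHistogram") ||
      !is.numeric(hist$probs) || !is.numeric(hist$bin_edges) ||
      length(hist$probs) != length(hist$bin_edges) - 1L) {
    stop("hist must be a DistanceHistogram")
  }
  if (abs(sum(hist$probs) - 1) > 1e-9 || any(hist$probs < 0)) {
    stop("histogram probabilities must be non-negative and sum to 1")
  }
  invisible(hist)
}

#' Grid search for the best-fitting Rayleigh scale
#'
#' Evaluates [rayleigh_rmsd()] on every sigma in the grid and returns the
#' minimizer; ties break toward the smaller sigma.
#'
#' @param hist A `DistanceHistogram`.
#' @param sigma_grid Increasing vector of positive scales.
#' @return List with `sigma` (best scale) and `rmsd` (its RMSD).
#' @export
fit_sigma <- function(hist, sigma_grid = seq(0.5, 100, by = 0.1)) {
  check_histogram(hist)
  if (length(sigma_grid) == 0L) stop("sigma_grid is empty")
  if (any(sigma_grid <= 0)) stop("sigma_grid must be positive")
  mass <- rayleigh_bin_mass(hist$bin_edges, sigma_grid)
  dev <- mass - matrix(hist$probs, nrow = nrow(mass),
                       ncol = length(hist$probs), byrow = TRUE)
  rmsd <- sqrt(rowMeans(dev^2))
  i <- which.min(rmsd)                      # first minimum = smallest sigma
  list(sigma = sigma_grid[i], rmsd = rmsd[i])
}
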