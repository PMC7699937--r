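#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbour scheme for the Perona-Malik heat equation with an
#' edge-stopping conductance: diffusion is strong in flat regions (noise is
#' smoothed away) and weak across strong gradients (stomatal outlines are
#' preserved). Boundaries are reflecting (Neumann), so each iteration
#' conserves total intensity; the final result is clipped to `[0, 1]` to
#' guard against floating-point overshoot.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param iterations Number of filter applications `t` (>= 1).
#' @param kappa Contrast parameter of the conductance, on `[0, 1]`
#'   intensities; gradients well below `kappa` diffuse freely, gradients
#'   above it are treated as edges.
#' @param step Integration step per iteration; must be `<= 0.25` for
#'   stability of the explicit 2-D scheme.
#' @param conductance `"exponential"` for `g(s) = exp(-(s/kappa)^2)` or
#'   `"rational"` for `g(s) = 1 / (1 + (s/kappa)^2)`.
#' @return Diffused matrix, same shape, values in `[0, 1]`.
#' @export
perona_malik <- function(img, iterations = 10L, kappa = 0.1, step = 0.2,
                         conductance = c("exponential", "rational")) {
  assert_gray(img)
  conductance <- match.arg(conductance)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (kappa <= 0) stop("kappa must be positive")
  if (step <= 0 || step > 0.25) stop("step must be in (0, 0.25]")
  n <- nrow(img)
  m <- ncol(img)
  g <- if (conductance == "exponential") {
    function(d) exp(-(d / kappa)^2)
  } else {
    function(d) 1 / (1 + (d / kappa)^2)
  }
  up    <- c(1L, seq_len(n - 1L))
  down  <- c(seq_len(n - 1L) + 1L, n)
  left  <- c(1L, seq_len(m - 1L))
  right <- c(seq_len(m - 1L) + 1L, m)
  for (it in seq_len(iterations)) {
    dN <- img[up, , drop = FALSE] - img
    dS <- img[down, , drop = FALSE] - img
    dW <- img[, left, drop = FALSE] - img
    dE <- img[, right, drop = FALSE] - img
    img <- img + step * (g(abs(dN)) * dN + g(abs(dS)) * dS +
                           g(abs(dW)) * dW + g(abs(dE)) * dE)
  }
  pmin(pmax(img, 0), 1)
}

#' Mean-shift intensity quantization
#'
#' Mode-seeking over the 1-D intensity distribution: every pixel value is
#' moved uphill (uniform kernel of half-width `bandwidth`) until it reaches a
#' density mode; modes closer than `bandwidth` are merged, and each pixel is
#' replaced by the weighted mean intensity of its mode's support. The result
#' has few distinct levels but sharp region boundaries. Because surviving
#' cluster centers are pairwise more than `bandwidth` apart, the operator is
#' idempotent.
#'
#' Inputs with more than 2048 distinct values are first condensed onto a
#' 2048-level weighted grid, which leaves 8-bit imagery untouched and bounds
#' the cost of mode seeking on float images.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param bandwidth Kernel half-width in intensity units (> 0).
#' @param max_iter Maximum mode-seeking iterations.
#' @param tol Convergence tolerance on the mode position.
#' @return Quantized matrix; distinct values are cluster modes within the
#'   input range.
#' @export
meanshift_quantize <- function(img, bandwidth = 0.1, max_iter = 100L,
                               tol = 1e-6) {
  assert_gray(img)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  vals <- as.vector(img)
  uv <- sort(unique(vals))
  if (length(uv) == 1L) return(img)
  if (length(uv) > 2048L) {
    ## condense onto a weighted grid of bin means
    bins <- findInterval(vals, seq(min(vals), max(vals), length.out = 2049L),
                         rightmost.closed = TRUE, all.inside = TRUE)
    ub <- sort(unique(bins))
    key <- match(bins, ub)
    w <- tabulate(key, nbins = length(ub))
    uv <- as.vector(rowsum(vals, key)) / w
  } else {
    w <- tabulate(match(vals, uv), nbins = length(uv))
    key <- match(vals, uv)
  }
  k <- length(uv)
  ## mode seeking: each starting value climbs to the local weighted mean
  x <- uv
  for (it in seq_len(max_iter)) {
    xn <- vapply(x, function(xi) {
      inw <- abs(uv - xi) <= bandwidth
      sum(w[inw] * uv[inw]) / sum(w[inw])
    }, numeric(1))
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  ## merge modes until all surviving centers are > bandwidth apart;
  ## a center is the weighted mean of its members' ORIGINAL values
  cl <- seq_len(k)
  centers <- x
  repeat {
    ids <- sort(unique(cl))
    cs <- vapply(ids, function(i) centers[match(i, cl)], numeric(1))
    oo <- order(cs)
    gaps <- diff(cs[oo])
    if (length(gaps) == 0L || all(gaps > bandwidth)) break
    j <- which.min(gaps)
    a <- ids[oo][j]
    b <- ids[oo][j + 1L]
    cl[cl == b] <- a
    memb <- cl == a
    centers[memb] <- sum(w[memb] * uv[memb]) / sum(w[memb])
  }
  out <- centers[key]
  matrix(out, nrow = nrow(img))
}

#' Hadamard (elementwise) division of two images
#'
#' Computes `numerator / (denominator + eps)` pixel by pixel and min-max
#' rescales the ratio to `[0, 1]`, so the downstream threshold scan always
#' works on a fixed domain. `eps > 0` guarantees a finite result even where
#' the denominator vanishes.
#'
#' @param numerator,denominator Numeric matrices of equal shape.
#' @param eps Non-negative stabilizer added to the denominator.
#' @return Rescaled ratio matrix in `[0, 1]`.
#' @export
hadamard_divide <- function(numerator, denominator, eps = 1e-6) {
  assert_gray(numerator, "numerator")
  assert_gray(denominator, "denominator")
  if (!identical(dim(numerator), dim(denominator))) {
    stop("numerator and denominator must have identical shapes")
  }
  if (eps < 0) stop("eps must be non-negative")
  r <- numerator / (denominator + eps)
  if (any(!is.finite(r))) stop("non-finite ratio; use eps > 0")
  out <- rescale01(r)
  matrix(out, nrow = nrow(numerator))
}

#' Full preprocessing chain: RGB micrograph to grey image F
#'
#' Applies Perona-Malik diffusion to the red channel, mean-shift quantization
#' to the diffused result, and Hadamard-divides the original image's HSV
#' saturation channel by the quantized red channel. Stomatal interiors
#' (saturated, low red) come out bright; cuticle background comes out dark,
#' which is the polarity the threshold scan expects.
#'
#' @param img `n x m x 3` RGB array in `[0, 1]`.
#' @param pm List of [perona_malik()] parameters
#'   (`iterations`, `kappa`, `step`, `conductance`).
#' @param ms List of [meanshift_quantize()] parameters
#'   (`bandwidth`, `max_iter`, `tol`).
#' @param eps Hadamard stabilizer.
#' @return Grey matrix `F` in `[0, 1]`, same spatial shape as `img`.
#' @export
preprocess_pipeline <- function(img,
                                pm = list(),
                                ms = list(),
                                eps = 1e-6) {
  assert_rgb(img)
  cfg <- drtb_config()
  pm <- utils::modifyList(cfg$pm, pm)
  ms <- utils::modifyList(cfg$meanshift, ms)
  red <- red_channel(img)
  sat <- saturation_channel(img)
  dred <- perona_malik(red, iterations = pm$iterations, kappa = pm$kappa,
                       step = pm$step, conductance = pm$conductance)
  mred <- meanshift_quantize(dred, bandwidth = ms$bandwidth,
                             max_iter = ms$max_iter, tol = ms$tol)
  hadamard_divide(sat, mred, eps = eps)
}
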