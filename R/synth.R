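#' Sample a homogeneous Poisson point pattern (optional hard core)
#'
#' Stomatal centers are modeled as a homogeneous Poisson process of
#' intensity `lambda` on a `width x height` window; its nearest-neighbour
#' distances are exactly Rayleigh with `sigma = 1 / sqrt(2 pi lambda)`,
#' which gives the generator a closed-form oracle. Real stomata obey a
#' one-cell-spacing rule, so an optional hard-core thinning removes points
#' closer than `min_separation` to an already accepted point (the Rayleigh
#' law then holds only approximately).
#'
#' @param intensity Expected points per px^2 (`lambda > 0`).
#' @param width,height Window size in pixels.
#' @param min_separation Hard-core distance in pixels (0 = pure Poisson).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame with columns `x`, `y` (0-based pixel coordinates).
#' @export
sample_poisson_points <- function(intensity, width, height,
                                  min_separation = 0, seed = NULL) {
  if (intensity <= 0) stop("intensity must be positive")
  if (width < 1 || height < 1) stop("window must be at least 1 x 1")
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- intensity * width * height
  if (mu < 3) warning("expected point count below 3; tessellation may fail")
  n <- stats::rpois(1L, mu)
  pts <- data.frame(x = stats::runif(n, 0, width),
                    y = stats::runif(n, 0, height))
  if (min_separation > 0 && n > 1L) {
    keep <- logical(n)
    keep[1L] <- TRUE
    for (i in seq_len(n)[-1L]) {
      acc <- which(keep)
      d2 <- (pts$x[acc] - pts$x[i])^2 + (pts$y[acc] - pts$y[i])^2
      keep[i] <- all(d2 >= min_separation^2)
    }
    pts <- pts[keep, , drop = FALSE]
    rownames(pts) <- NULL
  }
  pts
}

#' Rendering parameters for synthetic stomata micrographs
#'
#' @param width,height Canvas size in pixels.
#' @param axes_range Range of ellipse semi-axes in pixels.
#' @param orientation_range Range of blob orientations in radians.
#' @param fg_color RGB of stoma interiors (green, saturated, low red — the
#'   polarity the preprocessing chain expects).
#' @param bg_color RGB of the cuticle background (brownish, weakly
#'   saturated).
#' @param rim_color RGB of the darker guard-cell rim ring.
#' @param rim_width Rim thickness as a fraction of the semi-axes.
#' @param fg_fade_range Per-blob contrast fade: each blob's foreground and
#'   rim colors are pulled toward the background by a factor drawn uniformly
#'   from this range (1 = full contrast). Emulates the variable focal plane
#'   of real mounts, where out-of-focus stomata lose chromatic contrast.
#' @param texture_amp Amplitude of the low-frequency background texture.
#' @param noise_sd SD of additive per-pixel Gaussian noise on each channel.
#' @param defocus_sigma Gaussian blur SD in pixels emulating out-of-focus
#'   optics (0 = sharp).
#' @return Parameter list for [render_stomata_image()].
#' @export
render_params <- function(width = 512L, height = 512L,
                          axes_range = c(9, 13),
                          orientation_range = c(0, pi),
                          fg_color = c(0.30, 0.62, 0.22),
                          bg_color = c(0.55, 0.47, 0.32),
                          rim_color = c(0.16, 0.17, 0.155),
                          rim_width = 0.25,
                          fg_fade_range = c(1, 1),
                          texture_amp = 0.03,
                          noise_sd = 0.003,
                          defocus_sigma = 0) {
  stopifnot(all(axes_range > 0), all(fg_color >= 0 & fg_color <= 1),
            all(bg_color >= 0 & bg_color <= 1), rim_width >= 0,
            all(fg_fade_range > 0 & fg_fade_range <= 1),
            texture_amp >= 0, noise_sd >= 0, defocus_sigma >= 0)
  list(width = as.integer(width), height = as.integer(height),
       axes_range = axes_range, orientation_range = orientation_range,
       fg_color = fg_color, bg_color = bg_color, rim_color = rim_color,
       rim_width = rim_width, fg_fade_range = fg_fade_range,
       texture_amp = texture_amp,
       noise_sd = noise_sd, defocus_sigma = defocus_sigma)
}

## low-frequency texture: white noise smoothed with a Gaussian, rescaled to
## unit SD (zero mean)
smooth_noise <- function(nrow, ncol, sigma = 12) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  z <- EBImage::gblur(z, sigma = sigma)
  z <- z - mean(z)
  z / stats::sd(z)
}

#' Render a stomata-like RGB micrograph from planted centers
#'
#' Draws one elliptical blob per point — a saturated green interior inside a
#' darker rim — on a textured brown background, then applies an optional
#' defocus blur and additive noise. Fully deterministic given `seed`.
#' Overlapping blobs are allowed.
#'
#' @param points data.frame/matrix of `(x, y)` centers (0-based pixels).
#' @param params List from [render_params()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_stomata_image <- function(points, params = render_params(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- params$height
  w <- params$width
  pts <- as_points(points, "points")
  if (nrow(pts) > 0L &&
      (any(pts[, 1L] < 0 | pts[, 1L] >= w) ||
       any(pts[, 2L] < 0 | pts[, 2L] >= h))) {
    stop("points must lie within the canvas")
  }
  ## multiplicative illumination texture: scales all channels by the same
  ## factor, so background saturation stays uniform while the red channel
  ## still carries low-frequency structure for the diffusion stage
  tex <- 1 + smooth_noise(h, w) * params$texture_amp
  img <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) img[, , c] <- params$bg_color[c] * tex
  n <- nrow(pts)
  if (n > 0L) {
    a <- stats::runif(n, params$axes_range[1L], params$axes_range[2L])
    b <- stats::runif(n, params$axes_range[1L], params$axes_range[2L])
    th <- stats::runif(n, params$orientation_range[1L],
                       params$orientation_range[2L])
    fade <- stats::runif(n, params$fg_fade_range[1L],
                         params$fg_fade_range[2L])
    for (i in seq_len(n)) {
      img <- draw_blob(img, pts[i, 1L], pts[i, 2L], a[i], b[i], th[i],
                       fade[i], params)
    }
  }
  if (params$defocus_sigma > 0) {
    for (c in 1:3) {
      img[, , c] <- EBImage::gblur(img[, , c], sigma = params$defocus_sigma)
    }
  }
  if (params$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = params$noise_sd),
                       dim = dim(img))
  }
  pmin(pmax(img, 0), 1)
}

draw_blob <- function(img, cx, cy, a, b, theta, fade, params) {
  fg <- params$bg_color + fade * (params$fg_color - params$bg_color)
  rimc <- params$bg_color + fade * (params$rim_color - params$bg_color)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rmax <- max(a, b) * (1 + params$rim_width)
  rows <- max(1L, floor(cy - rmax) + 1L):min(h, ceiling(cy + rmax) + 1L)
  cols <- max(1L, floor(cx - rmax) + 1L):min(w, ceiling(cx + rmax) + 1L)
  dy <- (rows - 1L) - cy
  dx <- (cols - 1L) - cx
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
  u <- (DX * cos(theta) + DY * sin(theta)) / a
  v <- (-DX * sin(theta) + DY * cos(theta)) / b
  rr <- u^2 + v^2
  interior <- rr <= 1
  rim <- rr > 1 & rr <= (1 + params$rim_width)^2
  for (c in 1:3) {
    plane <- img[rows, cols, c]
    plane[rim] <- rimc[c]
    plane[interior] <- fg[c]
    img[rows, cols, c] <- plane
  }
  img
}

#' Preset synthetic fixtures
#'
#' Three canonical study conditions, each a Poisson-with-hard-core pattern
#' rendered on an 800 x 800 canvas carrying on the order of a hundred
#' stomata (the density at which stomatal spacing statistics stabilize):
#' \describe{
#'   \item{clean}{the control condition: sharp, noise-free optics so the
#'     geometric machinery is exercised in isolation.}
#'   \item{noisy}{strong per-pixel sensor noise and background texture —
#'     the stress condition (see the methods vignette for why heavy chroma
#'     noise can defeat a spacing-statistics threshold scan).}
#'   \item{defocus}{Gaussian defocus (`sigma = 5` px) with per-blob
#'     chromatic contrast fade (`fg_fade_range = c(0.2, 1)`) — the
#'     out-of-focus degradation that depresses detection on real material,
#'     where part of the epidermis lies outside the focal plane.}
#' }
#'
#' @param preset One of `"clean"`, `"noisy"`, `"defocus"`.
#' @param seed Integer seed controlling both the point pattern and the
#'   render.
#' @return List with `image` (RGB array), `truth` (data.frame `x`, `y`),
#'   `params` (render parameters), `intensity`, `min_separation`, `preset`,
#'   `seed`.
#' @export
synth_preset <- function(preset = c("clean", "noisy", "defocus"), seed = 1L) {
  preset <- match.arg(preset)
  intensity <- 2.3e-4
  min_sep <- 30
  params <- switch(preset,
    clean   = render_params(width = 800L, height = 800L,
                            noise_sd = 0, texture_amp = 0,
                            defocus_sigma = 0),
    noisy   = render_params(width = 800L, height = 800L,
                            noise_sd = 0.03, texture_amp = 0.06,
                            defocus_sigma = 0),
    defocus = render_params(width = 800L, height = 800L,
                            noise_sd = 0, texture_amp = 0,
                            defocus_sigma = 5,
                            fg_fade_range = c(0.2, 1))
  )
  pts <- sample_poisson_points(intensity, params$width, params$height,
                               min_separation = min_sep, seed = seed)
  img <- render_stomata_image(pts, params, seed = seed + 1L)
  list(image = img, truth = pts, params = params, intensity = intensity,
       min_separation = min_sep, preset = preset, seed = seed)
}

#' Planted-threshold grey fixture
#'
#' Builds a grey image whose blobs are separable from the background only on
#' a known threshold band: the background is a periodic cellular texture
#' whose intensities stay below `band[1]`, and every blob plateau sits just
#' above `band[2]`. Any level inside `band` therefore isolates exactly the
#' planted (Poisson-distributed) blobs; levels below it admit the texture's
#' bumps, which form a regular lattice whose Delaunay edge-length histogram
#' is a spike — strongly non-Rayleigh — while levels above it rapidly lose
#' blobs. Used to verify that the threshold scan recovers a level inside the
#' planted band.
#'
#' @param seed Integer seed.
#' @param width,height Canvas size in pixels.
#' @param intensity Blob centers per px^2.
#' @param band Two-element separability band (default `c(0.55, 0.65)`).
#' @return List with `F` (grey matrix), `truth` (planted centers), `band`.
#' @export
synth_band_fixture <- function(seed = 1L, width = 1000L, height = 1000L,
                               intensity = 1.2e-4, band = c(0.55, 0.65)) {
  set.seed(seed)
  pts <- sample_poisson_points(intensity, width, height,
                               min_separation = 35)
  bg_max <- band[1L] - 0.001
  period <- 24
  sy <- sin(2 * pi * (seq_len(height) - 1L) / period)
  sx <- sin(2 * pi * (seq_len(width) - 1L) / period)
  F <- 0.46 + 0.08 * outer(sy, sx) + 0.01 * smooth_noise(height, width)
  F <- pmin(pmax(F, 0.30), bg_max)
  n <- nrow(pts)
  radii_a <- stats::runif(n, 8, 13)
  radii_b <- stats::runif(n, 8, 13)
  theta <- stats::runif(n, 0, pi)
  plateau <- stats::runif(n, band[2L] + 0.01, band[2L] + 0.03)
  for (i in seq_len(n)) {
    rows <- max(1L, floor(pts$y[i] - 14)):min(height, ceiling(pts$y[i] + 14))
    cols <- max(1L, floor(pts$x[i] - 14)):min(width, ceiling(pts$x[i] + 14))
    DY <- matrix((rows - 1L) - pts$y[i], length(rows), length(cols))
    DX <- matrix((cols - 1L) - pts$x[i], length(rows), length(cols),
                 byrow = TRUE)
    u <- (DX * cos(theta[i]) + DY * sin(theta[i])) / radii_a[i]
    v <- (-DX * sin(theta[i]) + DY * cos(theta[i])) / radii_b[i]
    inside <- u^2 + v^2 <= 1
    plane <- F[rows, cols]
    plane[inside] <- plateau[i]
    F[rows, cols] <- plane
  }
  list(F = F, truth = pts, band = band)
}
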