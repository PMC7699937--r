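test_that("diffusion leaves a constant image untouched and composes over iterations", {
  img <- matrix(0.5, 12, 15)
  expect_equal(perona_malik(img, iterations = 7), img)

  set.seed(11)
  noisy <- matrix(runif(300, 0.2, 0.8), 15, 20)
  once <- perona_malik(noisy, iterations = 10)
  twice <- perona_malik(perona_malik(noisy, iterations = 5), iterations = 5)
  expect_equal(once, twice, tolerance = 1e-12)
})

test_that("diffusion denoises flat regions, keeps the edge, matches the reference scheme", {
  set.seed(21)
  img <- matrix(0.3, 40, 40)
  img[, 21:40] <- 0.7
  img <- pmin(pmax(img + matrix(rnorm(1600, 0, 0.05), 40), 0), 1)
  out <- perona_malik(img, iterations = 10, kappa = 0.1, step = 0.2)

  ref <- reference_perona_malik(img, iterations = 10, kappa = 0.1, step = 0.2)
  expect_equal(out, ref, tolerance = 1e-12)

  flat_in <- c(img[5:35, 5:15])
  flat_out <- c(out[5:35, 5:15])
  expect_lt(var(flat_out), var(flat_in))
  grad_col <- function(x) which.max(colMeans(abs(x[, -1] - x[, -ncol(x)])))
  expect_equal(grad_col(out), grad_col(img))
})

test_that("diffusion conserves the image mean and vanishes as the step goes to zero", {
  set.seed(31)
  img <- matrix(runif(400, 0.1, 0.9), 20)
  for (it in 1:3) {
    out <- perona_malik(img, iterations = it, step = 0.2)
    expect_lt(abs(mean(out) - mean(img)), 1e-6 * it + 1e-12)
  }
  tiny <- perona_malik(img, iterations = 1, step = 1e-12)
  expect_equal(tiny, img, tolerance = 1e-9)
  expect_error(perona_malik(img, step = 0.3), "step")
  bad <- img; bad[1, 1] <- NaN
  expect_error(perona_malik(bad), "non-finite")
})

test_that("mean-shift quantization finds the intensity modes", {
  img <- matrix(0.42, 9, 9)
  expect_equal(meanshift_quantize(img, 0.1), img)

  set.seed(41)
  two <- matrix(c(rnorm(600, 0.2, 0.02 / 3), rnorm(600, 0.8, 0.02 / 3)), 30)
  two <- pmin(pmax(two, 0.15), 0.85)
  q <- meanshift_quantize(two, bandwidth = 0.1)
  modes <- sort(unique(as.vector(q)))
  expect_length(modes, 2L)
  expect_lt(abs(modes[1] - 0.2), 0.02)
  expect_lt(abs(modes[2] - 0.8), 0.02)

  ramp <- matrix(seq(0, 1, length.out = 64), 8)
  q1 <- meanshift_quantize(ramp, bandwidth = 1.5)
  expect_length(unique(as.vector(q1)), 1L)
  expect_error(meanshift_quantize(ramp, bandwidth = 0), "bandwidth")
})

test_that("mean-shift quantization is idempotent and range-preserving", {
  set.seed(51)
  for (rep in 1:5) {
    img <- matrix(runif(400), 20)
    q <- meanshift_quantize(img, bandwidth = 0.15)
    q2 <- meanshift_quantize(q, bandwidth = 0.15)
    expect_lt(max(abs(q2 - q)), 1e-9)
    expect_lte(length(unique(as.vector(q))), length(unique(as.vector(img))))
    expect_gte(min(q), min(img) - 1e-12)
    expect_lte(max(q), max(img) + 1e-12)
  }
})

test_that("Hadamard division matches hand computation and stays finite", {
  num <- matrix(c(0.2, 0.6, 0.4, 0.8), 2)
  den <- matrix(0.4, 2, 2)
  expect_equal(hadamard_divide(num, den, eps = 0),
               matrix(c(0, 2 / 3, 1 / 3, 1), 2))

  z <- matrix(0, 3, 3)
  out <- hadamard_divide(matrix(runif(9), 3), z, eps = 1e-6)
  expect_true(all(is.finite(out)))

  same <- matrix(runif(9, 0.3, 0.9), 3)
  expect_equal(hadamard_divide(same, same, eps = 0), matrix(0, 3, 3))
  expect_error(hadamard_divide(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the preprocessing chain separates blobs from background and is deterministic", {
  grey_rgb <- array(0.4, dim = c(16, 16, 3))
  expect_equal(preprocess_pipeline(grey_rgb), matrix(0, 16, 16))

  set.seed(61)
  pts <- data.frame(x = c(30, 80, 120, 60, 130), y = c(30, 40, 100, 110, 30))
  params <- render_params(width = 160L, height = 150L, noise_sd = 0.005)
  img <- render_stomata_image(pts, params, seed = 8)
  F1 <- preprocess_pipeline(img)
  expect_identical(dim(F1), dim(img)[1:2])
  expect_true(all(F1 >= 0 & F1 <= 1))

  blob <- matrix(FALSE, 150, 160)
  for (i in seq_len(nrow(pts))) {
    blob[pts$y[i] + (-4:4) + 1, pts$x[i] + (-4:4) + 1] <- TRUE
  }
  expect_gte(median(F1[blob]) - median(F1[!blob]), 0.2)

  F2 <- preprocess_pipeline(img)
  expect_identical(F1, F2)
})
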