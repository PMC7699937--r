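test_that("Poisson sampling has the right count statistics and reproducibility", {
  p1 <- sample_poisson_points(1e-3, 1000, 1000, seed = 201)
  expect_lt(abs(nrow(p1) - 1000), 3 * sqrt(1000))
  p2 <- sample_poisson_points(1e-3, 1000, 1000, seed = 201)
  expect_identical(p1, p2)
  expect_true(all(p1$x >= 0 & p1$x < 1000))
  expect_true(all(p1$y >= 0 & p1$y < 1000))
  expect_warning(sample_poisson_points(1e-6, 30, 30, seed = 1), "below 3")
})

test_that("hard-core thinning enforces the minimum separation", {
  pts <- sample_poisson_points(8e-4, 500, 500, min_separation = 25,
                               seed = 211)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  expect_gte(min(d), 25)
})

test_that("nearest-neighbour distances follow the closed-form Rayleigh law", {
  lam <- 4e-4
  nn_all <- unlist(lapply(1:6, function(s) {
    pts <- sample_poisson_points(lam, 1000, 1000, seed = 300 + s)
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    apply(d, 1, min)
  }))
  sigma_hat <- sqrt(sum(nn_all^2) / (2 * length(nn_all)))
  expect_lt(abs(sigma_hat - 1 / sqrt(2 * pi * lam)) / (1 / sqrt(2 * pi * lam)),
            0.1)
})

test_that("rendering is deterministic, plants what it claims and degrades with defocus", {
  params <- render_params(width = 200L, height = 180L, noise_sd = 0)
  bg <- render_stomata_image(data.frame(x = numeric(0), y = numeric(0)),
                             params, seed = 5)
  expect_identical(dim(bg), c(180L, 200L, 3L))
  # pure background: only the illumination-scaled background color appears
  expect_lt(max(bg[, , 2]), 0.62)              # never foreground green
  expect_gt(min(bg[, , 1]), 0.40)              # never rim red
  expect_equal(bg[, , 2] / bg[, , 1], matrix(0.47 / 0.55, 180, 200),
               tolerance = 1e-12)              # multiplicative texture

  pts <- data.frame(x = c(40, 120, 160, 60), y = c(50, 40, 130, 140))
  img1 <- render_stomata_image(pts, params, seed = 6)
  img2 <- render_stomata_image(pts, params, seed = 6)
  expect_identical(img1, img2)

  # noiseless sharp render: thresholding the saturation ratio finds exactly
  # the planted blobs, centroids within 1 px
  F <- preprocess_pipeline(img1)
  mid <- (max(F) + min(F)) / 2
  rs <- label_regions(binarize(F, mid), 8)
  cent <- inlier_centroids(rs, min_area = 9)
  expect_equal(nrow(cent), nrow(pts))
  ord <- order(cent$x)
  ord_t <- order(pts$x)
  expect_lt(max(abs(cent$x[ord] - pts$x[ord_t])), 1)
  expect_lt(max(abs(cent$y[ord] - pts$y[ord_t])), 1)

  # boundary gradients shrink monotonically with defocus
  grad_at_blobs <- function(defocus) {
    p <- render_params(width = 200L, height = 180L, noise_sd = 0,
                       defocus_sigma = defocus)
    im <- render_stomata_image(pts, p, seed = 6)
    g <- im[, , 1]
    gx <- abs(g[, -1] - g[, -ncol(g)])
    mean(gx[gx > quantile(gx, 0.99)])
  }
  g0 <- grad_at_blobs(0); g2 <- grad_at_blobs(2); g4 <- grad_at_blobs(4)
  expect_gt(g0, g2)
  expect_gt(g2, g4)
})

test_that("presets agree with their planted truth and reproduce bit-for-bit", {
  fx1 <- synth_preset("clean", seed = 9)
  fx2 <- synth_preset("clean", seed = 9)
  expect_identical(fx1$image, fx2$image)
  expect_identical(fx1$truth, fx2$truth)
  expect_gt(nrow(fx1$truth), 50)

  # planted truth and rendered blob count agree on the noiseless render
  F <- preprocess_pipeline(fx1$image)
  mid <- (max(F) + min(F)) / 2
  n_rendered <- nrow(inlier_centroids(label_regions(binarize(F, mid), 8),
                                      min_area = 9))
  expect_equal(n_rendered, nrow(fx1$truth))
})

test_that("the band fixture is separable exactly on its planted band", {
  fx <- synth_band_fixture(seed = 4, width = 420L, height = 420L,
                           intensity = 4.5e-4)
  in_band <- binarize(fx$F, mean(fx$band))
  rs <- label_regions(in_band, 8)
  cent <- inlier_centroids(rs, min_area = 9)
  expect_equal(nrow(cent), nrow(fx$truth))
  # below the band, the lattice texture floods in
  low <- label_regions(binarize(fx$F, fx$band[1] - 0.06), 8)
  expect_gt(low$n_regions, 3 * nrow(fx$truth))
  # above the band, blobs disappear
  high <- label_regions(binarize(fx$F, fx$band[2] + 0.05), 8)
  expect_lt(high$n_regions, nrow(fx$truth) / 2)
})
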