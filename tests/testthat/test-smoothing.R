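test_that("kernel window size follows the physical support rule", {
  expect_identical(dim(make_kernel(1.25)$weights), c(5L, 5L))          # 4 mm at 1 mm
  expect_identical(dim(make_kernel(1, spacing_mm = 2)$weights), c(3L, 3L))
  expect_identical(dim(make_kernel(1, spacing_mm = 0.5)$weights), c(9L, 9L))
  expect_identical(dim(make_kernel(1, support_mm = 5)$weights), c(5L, 5L))
})

test_that("kernel weights are normalized and 180-degree symmetric", {
  for (sigma in c(0.5, 1.25, 3)) {
    for (spacing in c(0.5, 1, 2)) {
      w <- make_kernel(sigma, spacing_mm = spacing)$weights
      expect_equal(sum(w), 1, tolerance = 1e-12)
      n <- nrow(w)
      expect_equal(w, w[n:1, n:1])
      expect_true(all(w >= 0))
    }
  }
  expect_error(make_kernel(0), "positive")
  expect_error(make_kernel(-1), "positive")
})

test_that("a tiny sigma concentrates nearly all weight at the centre", {
  # direct evaluation of the sampled Gaussian: off-centre taps carry
  # exp(-1/(2*0.05^2)) ~ 1e-87 of the centre weight
  w <- make_kernel(0.05)$weights
  expect_gt(w[3, 3], 0.999)
})

test_that("constant images are fixed points of the filter", {
  img <- intensity_image(matrix(100, 32, 32))
  out <- smooth_gaussian(img, 1.25)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-12)
})

test_that("impulse response reproduces the kernel weights", {
  px <- matrix(0, 21, 21)
  px[11, 11] <- 100
  out <- smooth_gaussian(intensity_image(px), 1.25)
  w <- make_kernel(1.25)$weights
  expect_equal(out$pixels[9:13, 9:13], 100 * w, tolerance = 1e-12)
  expect_equal(sum(out$pixels), 100, tolerance = 1e-9)
})

test_that("reflect padding conserves the image mean", {
  ph <- test_phantom(seed = 7, shape = c(64, 64), noise_sigma = 5)
  for (sigma in c(0.5, 1.25, 2.5)) {
    out <- smooth_gaussian(ph$image, sigma)
    expect_lt(abs(mean(out$pixels) - mean(ph$image$pixels)), 0.5)
  }
})

test_that("psnr matches its closed form and sentinels", {
  a <- intensity_image(matrix(100, 10, 10))
  expect_identical(psnr(a, a), Inf)

  b <- intensity_image(matrix(100 + 255, 10, 10), q_max = 255)
  b$pixels <- a$pixels + 255
  expect_equal(psnr(a, b), 0)

  # pair engineered to an exact MSE of 65.536
  d <- matrix(0, 10, 10); d[1:32] <- sqrt(65.536 * 100 / 32)
  x <- intensity_image(matrix(50, 10, 10))
  y <- intensity_image(matrix(50, 10, 10) + d)
  expect_equal(psnr(x, y), 10 * log10(255^2 / 65.536), tolerance = 1e-10)

  expect_error(psnr(a, intensity_image(matrix(0, 3, 3))), "shape")
})

test_that("sigma sweep returns the exhaustive argmax with small-sigma ties", {
  ph <- test_phantom(seed = 3, shape = c(64, 64), noise_sigma = 0)
  clean <- ph$image
  noisy <- clean
  set.seed(41)
  noisy$pixels <- pmin(pmax(
    clean$pixels + matrix(rnorm(length(clean$pixels), 0, 15), 64, 64), 0), 255)

  grid <- seq(0.5, 3, by = 0.25)
  sw <- sigma_sweep(noisy, clean, grid)
  # oracle: exhaustive evaluation over the same grid
  scores <- vapply(grid, function(s) psnr(clean, smooth_gaussian(noisy, s)),
                   numeric(1))
  expect_equal(sw$table$psnr_db, scores)
  expect_equal(sw$best_sigma, min(grid[scores == max(scores)]))

  # single-point grid
  expect_equal(sigma_sweep(noisy, clean, grid = 1.25)$best_sigma, 1.25)
  expect_error(sigma_sweep(noisy, clean, grid = numeric(0)), "non-empty")
})

test_that("a clean structured image prefers the least smoothing", {
  ph <- test_phantom(seed = 9, shape = c(64, 64), noise_sigma = 0)
  sw <- sigma_sweep(ph$image, ph$image, grid = seq(0.5, 3, by = 0.5))
  expect_equal(sw$best_sigma, 0.5)
  # PSNR decreases monotonically with sigma on a clean phantom
  expect_true(all(diff(sw$table$psnr_db) < 0))
})

test_that("smoothing improves PSNR on noise-corrupted phantoms", {
  improved <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    ph <- test_phantom(seed = s, shape = c(64, 64), noise_sigma = 0)
    noisy <- ph$image
    set.seed(1000 + s)
    noisy$pixels <- pmin(pmax(
      noisy$pixels + matrix(rnorm(64 * 64, 0, 15), 64, 64), 0), 255)
    base <- psnr(ph$image, noisy)
    best <- max(vapply(seq(0.5, 3, 0.5),
                       function(sg) psnr(ph$image, smooth_gaussian(noisy, sg)),
                       numeric(1)))
    if (best > base) improved <- improved + 1L
  }
  expect_gte(improved, ceiling(0.95 * n_seeds))
})
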