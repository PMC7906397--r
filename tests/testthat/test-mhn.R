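test_that("landmarks match a brute-force sorted-list oracle", {
  # foreground is the multiset {1, ..., 100} embedded in a zero background
  px <- matrix(0, 20, 10)
  px[1:100] <- 1:100
  lm <- estimate_landmarks(intensity_image(px))
  s <- sort(px[px > 0])
  n <- length(s)
  p1 <- s[ceiling(0.01 * n)]
  p2 <- s[ceiling(0.99 * n)]
  expect_identical(lm$m1, min(s))
  expect_identical(lm$m2, max(s))
  expect_identical(lm$P1, p1)
  expect_identical(lm$P2, p2)
  expect_equal(lm$mu, mean(s[s >= p1 & s <= p2]))

  # and for assorted percentile settings on a random multiset
  set.seed(11)
  px2 <- matrix(sample(1:200, 400, replace = TRUE), 20, 20)
  for (pcts in list(c(1, 99), c(5, 95), c(10, 90))) {
    lm2 <- estimate_landmarks(intensity_image(px2), 0, pcts[1], pcts[2])
    s2 <- sort(px2[px2 > 0]); n2 <- length(s2)
    expect_identical(lm2$P1, s2[ceiling(pcts[1] / 100 * n2)])
    expect_identical(lm2$P2, s2[ceiling(pcts[2] / 100 * n2)])
  }
})

test_that("degenerate images raise classed landmark errors", {
  expect_error(estimate_landmarks(intensity_image(matrix(0, 8, 8))),
               class = "degenerate_image")
  expect_error(estimate_landmarks(intensity_image(matrix(100, 8, 8))),
               class = "degenerate_histogram")
  # two-valued image whose percentiles coincide
  px <- matrix(100, 10, 10); px[1] <- 101
  expect_error(estimate_landmarks(intensity_image(px)),
               class = "degenerate_histogram")
})

test_that("intensity scaling fixes its anchor points", {
  img <- intensity_image(matrix(c(50, 200, 125, 80), 2, 2))
  g <- intensity_scale(img, 50, 200)
  expect_equal(g[1, 1], 0)
  expect_equal(g[2, 1], 1)
  expect_equal(g[1, 2], 0.5)
  expect_error(intensity_scale(img, 200, 50), "exceed")
})

test_that("stretch-shift maps the landmark interval onto the grayscale", {
  img <- intensity_image(matrix(c(50, 200, 125, 300), 2, 2))
  h <- stretch_shift(img, 50, 200)
  expect_equal(h$pixels[1, 1], 0)     # ROI_low -> q_min
  expect_equal(h$pixels[2, 1], 255)   # ROI_high -> q_max
  expect_equal(h$pixels[1, 2], 127.5) # affine midpoint
  expect_equal(h$pixels[2, 2], 255)   # beyond-landmark value clipped
  expect_true(all(h$pixels >= 0 & h$pixels <= 255))
})

test_that("piecewise map fixes every anchor and is continuous at mu", {
  set.seed(101)
  for (i in 1:50) {
    spec <- random_spec(inner = i %% 2 == 0)
    L <- spec$input
    cl <- function(x) min(max(ceiling(x - 1e-9), spec$Sp1), spec$Sp2)
    expect_identical(piecewise_map(L$P1, spec), cl(spec$S1))
    expect_identical(piecewise_map(L$P2, spec), cl(spec$S2))
    expect_identical(piecewise_map(L$mu, spec), cl(spec$mu_s))
    expect_identical(piecewise_map(L$m1, spec), cl(spec$Sp1))
    expect_identical(piecewise_map(L$m2, spec), cl(spec$Sp2))
    # continuity at the knot: approach mu from both sides
    eps <- 1e-9
    lo <- piecewise_map(L$mu - eps, spec)
    hi <- piecewise_map(L$mu + eps, spec)
    expect_lte(abs(lo - hi), 1)
  }
})

test_that("piecewise map equals the two-point-line oracle on random cases", {
  set.seed(202)
  for (i in 1:40) {
    spec <- random_spec(inner = i %% 2 == 0)
    v <- runif(25, -10, 265)
    got <- piecewise_map(v, spec)
    want <- vapply(v, oracle_map_scalar, numeric(1), spec = spec)
    expect_equal(got, want)
  }
})

test_that("piecewise map is monotone non-decreasing", {
  set.seed(303)
  for (i in 1:25) {
    spec <- random_spec()
    v <- sort(runif(200, -5, 260))
    out <- piecewise_map(v, spec)
    expect_true(all(diff(out) >= 0))
  }
})

test_that("normalizing an image to itself is the identity up to ceiling", {
  for (s in 1:5) {
    ph <- test_phantom(seed = s)
    res <- normalize_mhn(ph$image, ph$image)
    fg <- ph$image$pixels > 0
    expect_lte(max(abs(res$image$pixels[fg] - ph$image$pixels[fg])), 1)
    # background untouched
    expect_identical(res$image$pixels[!fg], ph$image$pixels[!fg])
  }
})

test_that("normalized output reproduces the reference landmarks", {
  for (s in 1:5) {
    base <- phantom_spec(shape = c(96, 96), noise_sigma = 5, seed = s)
    coh <- make_site_cohort(base, n_sites = 3, seed = s)
    ref <- coh$images[[1]]
    lm_ref <- estimate_landmarks(ref)
    for (img in coh$images[-1]) {
      out <- normalize_mhn(img, ref)$image
      lm_out <- estimate_landmarks(out)
      expect_lte(abs(lm_out$P1 - lm_ref$P1), 1)
      expect_lte(abs(lm_out$P2 - lm_ref$P2), 1)
    }
  }
})

test_that("monotone pixel pairs stay ordered through normalization", {
  ph <- test_phantom(seed = 4)
  ref <- test_phantom(seed = 5)$image
  res <- normalize_mhn(ph$image, ref)
  v <- sort(ph$image$pixels[ph$image$pixels > 0])
  out <- piecewise_map(v, res$spec)
  expect_true(all(diff(out) >= 0))
})

test_that("vectorized normalization equals a scalar per-pixel loop", {
  for (s in 1:5) {
    ph <- test_phantom(seed = s, shape = c(64, 64))
    ref <- test_phantom(seed = s + 100, shape = c(64, 64))$image
    res <- normalize_mhn(ph$image, ref)
    # scalar re-application through the audit spec
    px <- ph$image$pixels
    loop <- px
    for (i in seq_along(px)) {
      if (px[i] > 0) loop[i] <- piecewise_map(px[i], res$spec, 0, 255)
    }
    expect_identical(res$image$pixels, loop)
  }
})

test_that("histogram matching reproduces a self- or shifted distribution", {
  ph <- test_phantom(seed = 8)
  img <- ph$image

  self <- normalize_hmn(img, img, bins = 256)
  fg <- img$pixels > 0
  expect_lte(max(abs(self$pixels[fg] - img$pixels[fg])), 255 / 256)

  shifted <- img
  shifted$pixels <- img$pixels + 20   # no clipping: max stays under 255
  expect_lte(max(shifted$pixels), 255)
  back <- normalize_hmn(shifted, img, bins = 256)
  expect_lte(max(abs(back$pixels[fg] - img$pixels[fg])), 2 * 255 / 256)

  expect_error(normalize_hmn(img, img, bins = 1), "at least 2")
})

test_that("coarse histogram matching cannot beat fine matching", {
  for (s in 1:5) {
    base <- phantom_spec(shape = c(96, 96), noise_sigma = 10, seed = s)
    coh <- make_site_cohort(base, n_sites = 2, seed = s)
    ref <- coh$images[[1]]; inp <- coh$images[[2]]
    coarse <- mse(normalize_hmn(inp, ref, bins = 2), ref)
    fine <- mse(normalize_hmn(inp, ref, bins = 256), ref)
    expect_gte(coarse, fine)
  }
})

test_that("histogram report satisfies its normalization identities", {
  # constant image: single occupied bin, CFC a step to 1
  const <- intensity_image(matrix(100, 10, 10))
  h <- histogram_report(const, bins = 16)
  expect_identical(sum(h$count > 0), 1L)
  expect_equal(max(h$cfc), 1)
  expect_true(all(diff(h$cfc) >= 0))

  # ramp: exact per-bin counts from the construction
  ramp <- intensity_image(matrix(rep(seq(0, 255, length.out = 16), each = 16), 16, 16))
  hr <- histogram_report(ramp, bins = 16)
  expect_true(all(hr$count == 16))
  expect_equal(sum(hr$count), 256)
  expect_equal(sum(hr$pdf), 1)

  ph <- test_phantom(seed = 2)
  hp <- histogram_report(ph$image, bins = 64)
  expect_equal(sum(hp$count), length(ph$image$pixels))
  expect_equal(hp$cfc[64], 1)
})
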