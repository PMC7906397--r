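test_that("patch extraction respects count, size, bounds and determinism", {
  ph <- test_phantom(seed = 1, shape = c(256, 256))
  ps <- extract_patches(ph$image, n = 50, size = 64, seed = 17)
  expect_length(ps$patches, 50)
  for (p in ps$patches) {
    expect_identical(dim(p$pixels), c(64L, 64L))
    expect_gte(p$row, 0); expect_lte(p$row, 256 - 64)
    expect_gte(p$col, 0); expect_lte(p$col, 256 - 64)
  }
  # determinism: identical corner lists for the same seed
  ps2 <- extract_patches(ph$image, n = 50, size = 64, seed = 17)
  expect_identical(patch_manifest(ps), patch_manifest(ps2))
  # and different corners for a different seed
  ps3 <- extract_patches(ph$image, n = 50, size = 64, seed = 18)
  expect_false(identical(patch_manifest(ps)$row, patch_manifest(ps3)$row))
})

test_that("patch content is a bit-exact copy of the source window", {
  ph <- test_phantom(seed = 2, shape = c(128, 128))
  ps <- extract_patches(ph$image, n = 10, size = 32, seed = 5)
  for (p in ps$patches) {
    expect_identical(p$pixels,
                     ph$image$pixels[p$row + 1:32, p$col + 1:32])
  }
})

test_that("images smaller than the window are rejected with the axis named", {
  img <- intensity_image(matrix(0, 63, 200))
  expect_error(extract_patches(img, n = 5, size = 64), "rows")
  img2 <- intensity_image(matrix(0, 200, 63))
  expect_error(extract_patches(img2, n = 5, size = 64), "cols")
})

test_that("split arithmetic reproduces the 14:3:3 worked examples", {
  expect_identical(patch_split_counts(390400),
                   c(train = 273280L, val = 58560L, test = 58560L))
  expect_identical(patch_split_counts(20),
                   c(train = 14L, val = 3L, test = 3L))
  # remainder goes to train first
  expect_identical(patch_split_counts(21),
                   c(train = 15L, val = 3L, test = 3L))
  expect_identical(patch_split_counts(22),
                   c(train = 16L, val = 3L, test = 3L))
  expect_identical(patch_split_counts(43),
                   c(train = 31L, val = 6L, test = 6L))
  expect_error(patch_split_counts(10), "cannot realize")
})

test_that("split assignment partitions the set at the requested ratio", {
  ph <- test_phantom(seed = 3, shape = c(128, 128))
  ps <- extract_patches(ph$image, n = 40, size = 32, seed = 9)
  ps <- split_patches(ps, seed = 4)
  expect_identical(as.vector(table(ps$split)), c(28L, 6L, 6L))
  expect_length(ps$split, 40)
  expect_false(anyNA(ps$split))

  # re-splitting with the same seed is reproducible
  ps2 <- split_patches(ps, seed = 4)
  expect_identical(ps$split, ps2$split)
})

test_that("stratified splits preserve each class's ratio-implied counts", {
  ph <- test_phantom(seed = 4, shape = c(128, 128))
  a <- extract_patches(ph$image, n = 40, size = 32, seed = 1,
                       source_id = "dyslexic", label = 1L)
  b <- extract_patches(ph$image, n = 60, size = 32, seed = 2,
                       source_id = "control", label = 0L)
  ps <- split_patches(combine_patch_sets(a, b), seed = 11, stratified = TRUE)
  man <- patch_manifest(ps)
  t1 <- table(man$split[man$label == 1])
  t0 <- table(man$split[man$label == 0])
  expect_identical(as.vector(t1[c("train", "val", "test")]), c(28L, 6L, 6L))
  expect_identical(as.vector(t0[c("train", "val", "test")]), c(42L, 9L, 9L))
})

test_that("kfold blocks are disjoint, exhaustive and balanced", {
  f <- kfold_indices(100, 10, seed = 21)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 10))
  expect_identical(sort(unlist(f)), 1:100)

  g <- kfold_indices(10, 3, seed = 2)
  expect_identical(sort(lengths(g), decreasing = TRUE), c(4L, 3L, 3L))

  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:500, 1); k <- sample(2:9, 1)
    if (k > n) next
    blocks <- kfold_indices(n, k, seed = i)
    expect_identical(sort(unlist(blocks)), seq_len(n))
    expect_lte(diff(range(lengths(blocks))), 1)
  }
  expect_error(kfold_indices(5, 10), "exceeds")
})

test_that("patches resize to classifier input sizes", {
  ph <- test_phantom(seed = 5, shape = c(128, 128))
  ps <- extract_patches(ph$image, n = 3, size = 64, seed = 7)
  p <- intensity_image(ps$patches[[1]]$pixels)
  expect_identical(dim(resize(p, c(117, 117))$pixels), c(117L, 117L))
  expect_identical(dim(resize(p, c(224, 224))$pixels), c(224L, 224L))
})
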