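#' Extract random overlapping patches from an image
#'
#' Draws `n` top-left corners uniformly with replacement from the valid
#' corner lattice (every position at which a `size` x `size` window fits),
#' so patches may overlap. Patch pixel content is copied from the source
#' window bit-exactly; resizing to a classifier input size (117 or 224) is
#' a separate, explicit step via [resize()]. Corners are recorded 0-based.
#'
#' @param img an [intensity_image()].
#' @param n number of patches (default 50).
#' @param size patch side in pixels (default 64).
#' @param seed integer RNG seed; the same `(img, n, size, seed)` always
#'   yields the same corner list.
#' @param source_id label recorded with each patch.
#' @param label binary class label (0/1) inherited by every patch.
#' @return An object of class `patch_set`: list with `patches` (list of
#'   `source_id`, `row`, `col`, `size`, `label`, `pixels`), `size`, `seed`,
#'   and `split` (`NULL` until [split_patches()] is applied).
#' @export
extract_patches <- function(img, n = 50, size = 64, seed = 1L,
                            source_id = "img", label = 0L) {
  stopifnot(inherits(img, "intensity_image"))
  n <- as.integer(n); size <- as.integer(size)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  if (h < size) stop("image rows (", h, ") smaller than patch size ", size, call. = FALSE)
  if (w < size) stop("image cols (", w, ") smaller than patch size ", size, call. = FALSE)
  if (!label %in% c(0L, 1L)) stop("`label` must be 0 or 1", call. = FALSE)
  corners <- with_seed(seed, {
    cbind(row = sample.int(h - size + 1L, n, replace = TRUE) - 1L,
          col = sample.int(w - size + 1L, n, replace = TRUE) - 1L)
  })
  patches <- lapply(seq_len(n), function(i) {
    r <- corners[i, "row"]; c <- corners[i, "col"]
    list(source_id = source_id, row = r, col = c, size = size,
         label = as.integer(label),
         pixels = img$pixels[r + seq_len(size), c + seq_len(size), drop = FALSE])
  })
  structure(list(patches = patches, size = size, seed = as.integer(seed),
                 split = NULL),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %dx%d, seed %d%s\n",
              length(x$patches), x$size, x$size, x$seed,
              if (is.null(x$split)) "" else ", split assigned"))
  invisible(x)
}

#' Combine patch sets
#'
#' @param ... `patch_set` objects with a common patch size.
#' @return A single `patch_set`; any existing split assignment is dropped.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "patch_set")))
  sizes <- unique(vapply(sets, `[[`, integer(1), "size"))
  if (length(sizes) != 1L) stop("patch sizes differ across sets", call. = FALSE)
  structure(list(patches = do.call(c, lapply(sets, `[[`, "patches")),
                 size = sizes, seed = sets[[1]]$seed, split = NULL),
            class = "patch_set")
}

## counts for an N-item split at an integer ratio; the floor remainder
## (at most groups-1 items) goes to the earlier groups in order.
split_counts <- function(n, ratio) {
  s <- sum(ratio)
  counts <- floor(n * ratio / s)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  as.integer(counts)
}

#' Assign train/validation/test splits to a patch set
#'
#' Shuffles the patches with the given seed and partitions them at the
#' integer ratio (default 14:3:3, i.e. 70/15/15). When the patch count is
#' divisible by the ratio total the counts are exact; otherwise the floor
#' remainder goes to train, then validation, then test. Stratified mode
#' (default) applies the ratio within each label class first, so class
#' balance is preserved in every split.
#'
#' @param ps a `patch_set` from [extract_patches()] or
#'   [combine_patch_sets()].
#' @param ratio positive integer triple `(train, val, test)`.
#' @param seed shuffle seed.
#' @param stratified apply the ratio per label class first.
#' @return `ps` with `$split`: a factor over `c("train", "val", "test")`,
#'   one entry per patch.
#' @export
split_patches <- function(ps, ratio = c(14, 3, 3), seed = 1L, stratified = TRUE) {
  stopifnot(inherits(ps, "patch_set"))
  ratio <- as.integer(ratio)
  if (length(ratio) != 3L || any(ratio <= 0L))
    stop("`ratio` must be three positive integers", call. = FALSE)
  n <- length(ps$patches)
  if (n < sum(ratio))
    stop("cannot realize ratio ", paste(ratio, collapse = ":"),
         " with only ", n, " patches", call. = FALSE)
  labels <- vapply(ps$patches, `[[`, integer(1), "label")
  split <- character(n)
  if (stratified && length(unique(labels)) > 1L) {
    for (lv in sort(unique(labels))) {
      idx <- which(labels == lv)
      counts <- split_counts(length(idx), ratio)
      perm <- with_seed(seed + lv, sample(idx))
      split[perm] <- rep(c("train", "val", "test"), counts)
    }
  } else {
    counts <- split_counts(n, ratio)
    perm <- with_seed(seed, sample.int(n))
    split[perm] <- rep(c("train", "val", "test"), counts)
  }
  ps$split <- factor(split, levels = c("train", "val", "test"))
  ps
}

#' Split counts without materializing patches
#'
#' The arithmetic of [split_patches()] on its own: how many items of `n`
#' fall in each of train/val/test at the given ratio.
#'
#' @param n total item count.
#' @param ratio positive integer triple.
#' @return Named integer vector `c(train =, val =, test =)`.
#' @examples
#' patch_split_counts(390400, c(14, 3, 3))
#' @export
patch_split_counts <- function(n, ratio = c(14, 3, 3)) {
  ratio <- as.integer(ratio)
  if (length(ratio) != 3L || any(ratio <= 0L))
    stop("`ratio` must be three positive integers", call. = FALSE)
  if (n < sum(ratio))
    stop("cannot realize ratio with n = ", n, call. = FALSE)
  stats::setNames(split_counts(n, ratio), c("train", "val", "test"))
}

#' Seeded k-fold index blocks
#'
#' A seeded permutation of `1:n_patches` divided into `k` disjoint,
#' exhaustive blocks whose sizes differ by at most one — the folds for a
#' k-fold cross-validation of a patch-level classifier.
#'
#' @param n_patches number of items.
#' @param k number of folds (at least 2, at most `n_patches`).
#' @param seed permutation seed.
#' @return List of `k` integer vectors.
#' @export
kfold_indices <- function(n_patches, k = 10, seed = 1L) {
  n_patches <- as.integer(n_patches); k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (k > n_patches) stop("`k` exceeds the number of items", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_patches))
  sizes <- rep(n_patches %/% k, k)
  extra <- n_patches %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(perm, rep(seq_len(k), sizes)))
}

#' Patch manifest as a data frame
#'
#' @param ps a `patch_set`.
#' @return Data frame with columns `patch_id`, `source_id`, `row`, `col`,
#'   `label` and, when assigned, `split` — the training-ready manifest.
#' @export
patch_manifest <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  out <- data.frame(
    patch_id = seq_along(ps$patches),
    source_id = vapply(ps$patches, `[[`, character(1), "source_id"),
    row = vapply(ps$patches, `[[`, integer(1), "row"),
    col = vapply(ps$patches, `[[`, integer(1), "col"),
    label = vapply(ps$patches, `[[`, integer(1), "label"))
  if (!is.null(ps$split)) out$split <- as.character(ps$split)
  out
}
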