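#' Dice similarity coefficient
#'
#' \eqn{DSC(X, Y) = 2|X \cap Y| / (|X| + |Y|)}: 0 means no spatial overlap
#' between the two binary masks, 1 total overlap.
#'
#' @param x,y [binary_mask()]s on the same grid; at least one non-empty.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  stopifnot(inherits(x, "binary_mask"), inherits(y, "binary_mask"))
  if (!identical(dim(x$pixels), dim(y$pixels)))
    stop("masks must have the same shape", call. = FALSE)
  nx <- sum(x$pixels); ny <- sum(y$pixels)
  if (nx + ny == 0)
    stop("DSC undefined: both masks are empty", call. = FALSE)
  2 * sum(x$pixels * y$pixels) / (nx + ny)
}

#' Mean squared error between two images
#'
#' Mean of squared per-pixel differences over all pixels.
#'
#' @param x_hat,x [intensity_image()]s of the same shape.
#' @return Non-negative MSE.
#' @export
mse <- function(x_hat, x) {
  stopifnot(inherits(x_hat, "intensity_image"), inherits(x, "intensity_image"))
  if (!identical(dim(x_hat$pixels), dim(x$pixels)))
    stop("images must have the same shape", call. = FALSE)
  mean((x_hat$pixels - x$pixels)^2)
}

#' Physical volume of a binary mask
#'
#' Number of 1-pixels times the pixel (voxel) physical size — square
#' millimetres for the 2-D masks used here.
#'
#' @param m a [binary_mask()].
#' @return Volume (area) in mm^2.
#' @export
mask_volume <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$pixels) * prod(m$spacing_mm)
}

## Segment an image into regions by the reference's per-region intensity
## windows; overlap between windows is resolved to the nearest window centre.
segment_by_windows <- function(img, windows, fg_threshold = 0) {
  px <- img$pixels
  centres <- vapply(windows, function(w) mean(w), numeric(1))
  masks <- lapply(windows, function(w) matrix(0L, nrow(px), ncol(px)))
  fg <- which(px > fg_threshold)
  if (length(fg)) {
    v <- px[fg]
    inside <- vapply(windows, function(w) v >= w[1] & v <= w[2],
                     logical(length(v)))
    inside <- matrix(inside, nrow = length(v))
    d <- abs(outer(v, centres, `-`))
    d[!inside] <- Inf
    best <- max.col(-d, ties.method = "first")
    hit <- is.finite(d[cbind(seq_along(v), best)])
    for (r in seq_along(windows)) {
      sel <- fg[hit & best == r]
      masks[[r]][sel] <- 1L
    }
  }
  lapply(masks, binary_mask, spacing_mm = img$spacing_mm)
}

## Reference per-region intensity windows from truth masks: the full value
## range, so an image identical to the reference segments perfectly.
region_windows <- function(reference, truth_masks) {
  lapply(truth_masks, function(m) range(reference$pixels[m$pixels == 1]))
}

#' Evaluate normalization methods against a reference
#'
#' Runs the Table-style comparison end to end on co-registered images: for
#' each input image and each method in `none` (raw), `hmn`
#' ([normalize_hmn()]) and `mhn` ([normalize_mhn()]), the image is
#' normalized to the reference, each region is segmented by the reference's
#' per-region intensity window (the phantom's ground-truth masks provide
#' the windows), and DSC against the truth mask, MSE against the reference,
#' and region volumes are recorded.
#'
#' @param inputs named list of [intensity_image()]s.
#' @param reference the reference [intensity_image()].
#' @param truth_masks named list of [binary_mask()]s (one per region),
#'   shared by all co-registered images.
#' @param methods subset of `c("none", "hmn", "mhn")`.
#' @param bins bin count for the HMN baseline.
#' @param fg_threshold background cut.
#' @return List with `records` (data frame: image_id, method, region, dsc,
#'   mse, volume_mm2) and `summary` (mean and SD of each metric per method
#'   and region; SD is the sample SD).
#' @export
evaluate_methods <- function(inputs, reference, truth_masks,
                             methods = c("none", "hmn", "mhn"),
                             bins = 256, fg_threshold = 0) {
  stopifnot(inherits(reference, "intensity_image"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(truth_masks)) || any(names(truth_masks) == ""))
    stop("`truth_masks` must be a named list of regions", call. = FALSE)
  if (is.null(names(inputs)))
    names(inputs) <- paste0("img", seq_along(inputs))
  windows <- region_windows(reference, truth_masks)
  rows <- list()
  for (id in names(inputs)) {
    img <- inputs[[id]]
    for (method in methods) {
      proc <- switch(method,
        none = img,
        hmn = normalize_hmn(img, reference, bins = bins, fg_threshold = fg_threshold),
        mhn = normalize_mhn(img, reference, fg_threshold = fg_threshold)$image)
      segs <- segment_by_windows(proc, windows, fg_threshold = fg_threshold)
      err <- mse(proc, reference)
      for (region in names(truth_masks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = id, method = method, region = region,
          dsc = dsc(segs[[region]], truth_masks[[region]]),
          mse = err,
          volume_mm2 = mask_volume(segs[[region]]))
      }
    }
  }
  records <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(dsc, mse, volume_mm2) ~ method + region,
                          data = records, FUN = mean)
  names(agg)[3:5] <- c("dsc_mean", "mse_mean", "volume_mean")
  sds <- stats::aggregate(cbind(dsc, mse, volume_mm2) ~ method + region,
                          data = records, FUN = stats::sd)
  agg$dsc_sd <- sds$dsc; agg$mse_sd <- sds$mse; agg$volume_sd <- sds$volume_mm2
  list(records = records, summary = agg)
}
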