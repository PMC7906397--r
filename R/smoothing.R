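#' Build an isotropic Gaussian kernel of fixed physical support
#'
#' The kernel window is the smallest odd pixel count whose physical extent
#' covers `support_mm` at the given spacing (5x5 at 1 mm spacing and the
#' default 4 mm support). Weights are the sampled Gaussian
#' \eqn{\exp(-(dx^2+dy^2)/(2\sigma^2))} renormalized to sum to one, so
#' constant images are fixed points of the filter.
#'
#' @param sigma positive Gaussian scale, in pixels.
#' @param spacing_mm pixel spacing in millimetres (isotropic).
#' @param support_mm physical extent of the window in millimetres; default 4.
#' @return An object of class `gaussian_kernel`: list with `weights` (odd
#'   square matrix summing to 1), `sigma`, `support_mm`.
#' @examples
#' k <- make_kernel(1.25)
#' dim(k$weights); sum(k$weights)
#' @export
make_kernel <- function(sigma, spacing_mm = 1, support_mm = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (spacing_mm <= 0 || support_mm <= 0)
    stop("`spacing_mm` and `support_mm` must be positive", call. = FALSE)
  side <- ceiling(support_mm / spacing_mm)
  if (side %% 2L == 0L) side <- side + 1L
  side <- max(side, 1L)
  r <- (side - 1L) / 2L
  d <- seq(-r, r)
  g2 <- outer(d^2, d^2, `+`)
  w <- exp(-g2 / (2 * sigma^2))
  structure(list(weights = w / sum(w), sigma = sigma, support_mm = support_mm),
            class = "gaussian_kernel")
}

## 2-D correlation with reflect padding. The kernel is symmetric so
## correlation and convolution coincide; implemented as a shift-and-add over
## kernel taps, which is fast for the small fixed-support windows used here.
convolve2_reflect <- function(x, w) {
  side <- nrow(w)
  r <- (side - 1L) %/% 2L
  h <- nrow(x); ww <- ncol(x)
  if (r == 0L) return(x * w[1, 1])
  ## reflect (mirror without repeating the edge sample, ITK/scipy style);
  ## fall back to edge replication when the image is thinner than the radius
  refl <- function(n, r) {
    idx <- seq(1L - r, n + r)
    if (n == 1L) return(rep(1L, length(idx)))
    period <- 2L * (n - 1L)
    m <- (idx - 1L) %% period
    m <- ifelse(m >= n - 1L + 1L, period - m, m)  # fold back
    m + 1L
  }
  ri <- refl(h, r); ci <- refl(ww, r)
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, h, ww)
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      out <- out + w[i, j] * xp[(i - 1L) + seq_len(h), (j - 1L) + seq_len(ww), drop = FALSE]
    }
  }
  out
}

#' Gaussian-smooth an image
#'
#' Convolves the image with the fixed-support isotropic kernel from
#' [make_kernel()], using reflect padding at the borders (no darkening that
#' would bias subsequent histogram landmark estimation). The result is
#' clipped to the image's grayscale range.
#'
#' @param img an [intensity_image()].
#' @param sigma positive Gaussian scale in pixels.
#' @param support_mm physical kernel extent in millimetres; default 4.
#' @return The smoothed [intensity_image()].
#' @export
smooth_gaussian <- function(img, sigma, support_mm = 4) {
  stopifnot(inherits(img, "intensity_image"))
  if (length(img$pixels) == 0L) stop("image is empty", call. = FALSE)
  k <- make_kernel(sigma, spacing_mm = img$spacing_mm[1], support_mm = support_mm)
  out <- convolve2_reflect(img$pixels, k$weights)
  intensity_image(clip_range(out, img$q_min, img$q_max),
                  spacing_mm = img$spacing_mm, q_min = img$q_min, q_max = img$q_max)
}

#' Peak signal-to-noise ratio between two images
#'
#' \eqn{10 \log_{10}(q_{max}^2 / MSE)} in decibels, with the MSE taken over
#' all pixels. Identical images give `Inf`.
#'
#' @param reference,test [intensity_image()]s of the same shape.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test) {
  stopifnot(inherits(reference, "intensity_image"), inherits(test, "intensity_image"))
  if (!identical(dim(reference$pixels), dim(test$pixels)))
    stop("images must have the same shape", call. = FALSE)
  m <- mean((reference$pixels - test$pixels)^2)
  if (m == 0) return(Inf)
  10 * log10(reference$q_max^2 / m)
}

#' Select the smoothing scale by a PSNR sweep
#'
#' Smooths the noisy image at every scale on the grid, scores each result by
#' PSNR against the clean reference, and returns the scale with the highest
#' PSNR (ties broken toward the smaller scale) together with the full sweep
#' table. The runtime column is informational only.
#'
#' @param noisy noisy [intensity_image()].
#' @param reference clean reference of the same shape.
#' @param grid numeric vector of candidate scales; default `seq(0.5, 3, 0.25)`.
#' @param support_mm kernel support passed to [smooth_gaussian()].
#' @return List with `best_sigma` and `table`, a data frame with columns
#'   `sigma`, `psnr_db`, `seconds`.
#' @export
sigma_sweep <- function(noisy, reference, grid = seq(0.5, 3, by = 0.25),
                        support_mm = 4) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (!identical(dim(noisy$pixels), dim(reference$pixels)))
    stop("images must have the same shape", call. = FALSE)
  rows <- lapply(grid, function(s) {
    t0 <- proc.time()[["elapsed"]]
    sm <- smooth_gaussian(noisy, s, support_mm = support_mm)
    data.frame(sigma = s,
               psnr_db = psnr(reference, sm),
               seconds = proc.time()[["elapsed"]] - t0)
  })
  tab <- do.call(rbind, rows)
  best <- min(tab$sigma[tab$psnr_db == max(tab$psnr_db)])
  list(best_sigma = best, table = tab)
}
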