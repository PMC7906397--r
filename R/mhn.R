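#' Estimate histogram landmarks of an image
#'
#' Landmarks are computed on the foreground intensity multiset (pixels
#' strictly above `fg_threshold`): `m1`/`m2` are the foreground minimum and
#' maximum, `P1`/`P2` the nearest-rank low/high percentiles (ties resolve to
#' the lower rank), and `mu` the arithmetic mean of foreground intensities
#' restricted to `[P1, P2]`. These five values anchor the piecewise mapping
#' of [normalize_mhn()]; using percentiles rather than the raw extremes makes
#' the anchors robust to hot pixels.
#'
#' @param img an [intensity_image()].
#' @param fg_threshold grey level; pixels at or below it are background
#'   (default 0, i.e. air in an 8-bit MRI slice).
#' @param low_pct,high_pct landmark percentiles (defaults 1 and 99).
#' @return An object of class `mhn_landmarks`: list with `m1`, `P1`, `mu`,
#'   `P2`, `m2`.
#' @export
estimate_landmarks <- function(img, fg_threshold = 0, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(img, "intensity_image"))
  fg <- img$pixels[img$pixels > fg_threshold]
  if (length(fg) == 0L)
    stop_mhn("degenerate_image", "no foreground pixels above threshold ", fg_threshold)
  if (length(unique(fg)) < 2L)
    stop_mhn("degenerate_histogram", "foreground is constant; landmarks undefined")
  s <- sort(fg)
  n <- length(s)
  nearest_rank <- function(p) s[min(n, max(1L, ceiling(p / 100 * n)))]
  P1 <- nearest_rank(low_pct)
  P2 <- nearest_rank(high_pct)
  if (P1 >= P2)
    stop_mhn("degenerate_histogram",
             "low and high percentile landmarks coincide (P1 = ", P1, ")")
  mu <- mean(s[s >= P1 & s <= P2])
  if (!(P1 < mu && mu < P2))
    stop_mhn("degenerate_histogram",
             "landmark mean does not separate P1 and P2")
  structure(list(m1 = min(s), P1 = P1, mu = mu, P2 = P2, m2 = max(s)),
            class = "mhn_landmarks")
}

#' @export
print.mhn_landmarks <- function(x, ...) {
  cat(sprintf("<mhn_landmarks> m1=%g P1=%g mu=%.3f P2=%g m2=%g\n",
              x$m1, x$P1, x$mu, x$P2, x$m2))
  invisible(x)
}

stop_mhn <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Scale intensities to the unit interval of a landmark span
#'
#' Per-pixel \eqn{g = (f - ROI_{low}) / (ROI_{high} - ROI_{low})}. Values
#' outside `[0, 1]` (pixels beyond the landmarks) are retained, not clipped:
#' the tail segments of the piecewise mapping handle them.
#'
#' @param img an [intensity_image()].
#' @param roi_low,roi_high grey-level landmarks with `roi_high > roi_low`.
#' @return Numeric matrix of unit-scale values.
#' @export
intensity_scale <- function(img, roi_low, roi_high) {
  stopifnot(inherits(img, "intensity_image"))
  if (!(roi_high > roi_low))
    stop("`roi_high` must exceed `roi_low`", call. = FALSE)
  (img$pixels - roi_low) / (roi_high - roi_low)
}

#' Stretch and shift a landmark interval over the full grayscale
#'
#' Affine map taking the landmark interval `[roi_low, roi_high]` onto the
#' standard scale `[q_min, q_max]`, i.e. the composition of
#' [intensity_scale()] with a stretch to the full grayscale:
#' \eqn{h = (f - ROI_{low}) (q_{max} - q_{min}) / (ROI_{high} - ROI_{low}) + q_{min}}.
#' (The printed formulation that subtracts `q_min` from the unit-scale value
#' and divides the ROI span by the grayscale span is dimensionally
#' inconsistent with its own stated intent of covering all grayscale levels;
#' this function implements the intent.) The result is clipped to
#' `[q_min, q_max]`. Exposed as an optional pre-stretch; the normalization
#' pipeline itself uses the piecewise landmark mapping.
#'
#' @inheritParams intensity_scale
#' @param q_min,q_max target grayscale range; defaults taken from `img`.
#' @return An [intensity_image()] covering the standard scale.
#' @export
stretch_shift <- function(img, roi_low, roi_high, q_min = img$q_min, q_max = img$q_max) {
  stopifnot(inherits(img, "intensity_image"))
  if (!(roi_high > roi_low))
    stop("`roi_high` must exceed `roi_low`", call. = FALSE)
  if (!(q_max > q_min)) stop("`q_max` must exceed `q_min`", call. = FALSE)
  g <- intensity_scale(img, roi_low, roi_high)
  h <- g * (q_max - q_min) + q_min
  intensity_image(clip_range(h, q_min, q_max), spacing_mm = img$spacing_mm,
                  q_min = q_min, q_max = q_max)
}

#' Build a mapping specification
#'
#' Bundles the input image's landmarks with the standard-scale anchors drawn
#' from the reference image: `S1`/`S2` are the reference's low/high
#' landmarks (its `ROI_low`/`ROI_high`), `mu_s` its landmark mean, and
#' `Sp1`/`Sp2` the ends of the standard scale (by default `q_min`/`q_max`).
#'
#' @param input `mhn_landmarks` of the image being normalized.
#' @param S1,mu_s,S2 standard anchors from the reference image's landmarks.
#' @param Sp1,Sp2 ends of the standard scale.
#' @return An object of class `mhn_mapping_spec`.
#' @export
mapping_spec <- function(input, S1, mu_s, S2, Sp1 = 0, Sp2 = 255) {
  if (!inherits(input, "mhn_landmarks"))
    stop("`input` must be mhn_landmarks", call. = FALSE)
  ok <- Sp1 <= S1 && S1 < mu_s && mu_s < S2 && S2 <= Sp2
  if (!ok)
    stop("standard anchors must satisfy Sp1 <= S1 < mu_s < S2 <= Sp2", call. = FALSE)
  if (!(input$m1 <= input$P1 && input$P1 < input$mu &&
        input$mu < input$P2 && input$P2 <= input$m2))
    stop("input landmarks must satisfy m1 <= P1 < mu < P2 <= m2", call. = FALSE)
  structure(list(input = input, S1 = S1, mu_s = mu_s, S2 = S2,
                 Sp1 = Sp1, Sp2 = Sp2),
            class = "mhn_mapping_spec")
}

#' @export
print.mhn_mapping_spec <- function(x, ...) {
  cat(sprintf("<mhn_mapping_spec> standard: S'1=%g S1=%g mu_s=%.3f S2=%g S'2=%g\n",
              x$Sp1, x$S1, x$mu_s, x$S2, x$Sp2))
  print(x$input)
  invisible(x)
}

#' Piecewise-linear landmark mapping
#'
#' The normalization map at the heart of MHN: four linear segments send the
#' input landmarks onto the standard anchors —
#' `[m1,P1] -> [Sp1,S1]`, `[P1,mu] -> [S1,mu_s]`, `[mu,P2] -> [mu_s,S2]`,
#' `[P2,m2] -> [S2,Sp2]` — with values outside `[m1, m2]` clamped to the
#' standard-scale ends. The ceiling operator is applied last, then the
#' result is clipped to `[q_min, q_max]`. The map is continuous, fixes the
#' five anchors (up to ceiling), and is monotone non-decreasing.
#'
#' The ceiling is taken with a `1e-9` tolerance (`ceiling(x - 1e-9)`) so
#' that a segment evaluated exactly at an integer anchor cannot be pushed
#' to the next grey level by floating-point round-off.
#'
#' @param value numeric vector of grey levels.
#' @param spec an [mapping_spec()].
#' @param q_min,q_max grayscale range used for the final clip; default the
#'   standard-scale ends of `spec`.
#' @return Mapped grey levels, same length as `value`.
#' @export
piecewise_map <- function(value, spec, q_min = spec$Sp1, q_max = spec$Sp2) {
  if (!inherits(spec, "mhn_mapping_spec"))
    stop("`spec` must be an mhn_mapping_spec", call. = FALSE)
  L <- spec$input
  seg <- function(v, a, b, A, B) {
    if (b > a) A + (v - a) * (B - A) / (b - a) else rep(A, length(v))
  }
  out <- numeric(length(value))
  lo   <- value < L$m1
  tail1 <- value >= L$m1 & value < L$P1
  mid1 <- value >= L$P1 & value <= L$mu
  mid2 <- value > L$mu & value <= L$P2
  tail2 <- value > L$P2 & value <= L$m2
  hi   <- value > L$m2
  out[lo] <- spec$Sp1
  out[tail1] <- seg(value[tail1], L$m1, L$P1, spec$Sp1, spec$S1)
  out[mid1] <- spec$mu_s + (value[mid1] - L$mu) * (spec$S1 - spec$mu_s) / (L$P1 - L$mu)
  out[mid2] <- spec$mu_s + (value[mid2] - L$mu) * (spec$S2 - spec$mu_s) / (L$P2 - L$mu)
  out[tail2] <- seg(value[tail2], L$P2, L$m2, spec$S2, spec$Sp2)
  out[hi] <- spec$Sp2
  ## tolerance ceiling: round-off at an integer anchor must not jump a level
  clip_range(ceiling(out - 1e-9), q_min, q_max)
}

#' Modified histogram normalization (MHN)
#'
#' Maps an input image onto a reference image's standard scale: landmarks
#' are estimated on both images, a [mapping_spec()] is built with the
#' reference's `P1`/`mu`/`P2` as the standard anchors `S1`/`mu_s`/`S2` and
#' the reference's foreground extremes `m1`/`m2` as the standard-scale ends
#' `Sp1`/`Sp2`, and [piecewise_map()] is applied to every foreground pixel.
#' Background pixels (at or below `fg_threshold`) pass through unchanged so
#' air stays black.
#'
#' Taking the standard-scale ends from the reference image (rather than the
#' raw grayscale bounds) makes normalization of an image to itself the
#' identity up to the ceiling operator, and keeps the tail segments from
#' stretching the brightest tissue toward white; the grayscale ends remain
#' available through [mapping_spec()] for callers that want a full-range
#' stretch.
#'
#' Estimating landmarks on Gaussian-smoothed images (see
#' [smooth_gaussian()]) is recommended for noisy data; this function does
#' not smooth implicitly.
#'
#' @param input_img,reference_img [intensity_image()]s; the reference is the
#'   chosen high-quality scan whose intensity scale all inputs should share.
#' @param fg_threshold,low_pct,high_pct landmark settings, see
#'   [estimate_landmarks()].
#' @return List with `image` (normalized [intensity_image()]) and `spec`
#'   (the [mapping_spec()] used, for audit logging).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 1))
#' shifted <- intensity_image(pmin(pmax(ph$image$pixels * 1.1 + 5, 0), 255))
#' out <- normalize_mhn(shifted, ph$image)
#' out$spec
#' @export
normalize_mhn <- function(input_img, reference_img, fg_threshold = 0,
                          low_pct = 1, high_pct = 99) {
  stopifnot(inherits(input_img, "intensity_image"),
            inherits(reference_img, "intensity_image"))
  lm_in <- tryCatch(
    estimate_landmarks(input_img, fg_threshold, low_pct, high_pct),
    error = function(e) stop("input image: ", conditionMessage(e), call. = FALSE))
  lm_ref <- tryCatch(
    estimate_landmarks(reference_img, fg_threshold, low_pct, high_pct),
    error = function(e) stop("reference image: ", conditionMessage(e), call. = FALSE))
  spec <- mapping_spec(lm_in, S1 = lm_ref$P1, mu_s = lm_ref$mu, S2 = lm_ref$P2,
                       Sp1 = lm_ref$m1, Sp2 = lm_ref$m2)
  px <- input_img$pixels
  fg <- px > fg_threshold
  out <- px
  out[fg] <- piecewise_map(px[fg], spec,
                           q_min = input_img$q_min, q_max = input_img$q_max)
  list(image = intensity_image(out, spacing_mm = input_img$spacing_mm,
                               q_min = input_img$q_min, q_max = input_img$q_max),
       spec = spec)
}

#' Histogram-matching normalization (HMN baseline)
#'
#' Classical histogram specification: each input grey level is mapped to the
#' reference grey level with the nearest cumulative frequency, with both
#' cumulative histograms computed on `bins` equal-width bins over the
#' grayscale range of the foreground pixels. Background pixels pass through.
#' Its accuracy depends strongly on the bin count, which is the baseline's
#' known weakness relative to MHN.
#'
#' @param input_img,reference_img [intensity_image()]s.
#' @param bins number of histogram bins (at least 2); default 256.
#' @param fg_threshold background cut, as in [normalize_mhn()].
#' @return The normalized [intensity_image()].
#' @export
normalize_hmn <- function(input_img, reference_img, bins = 256, fg_threshold = 0) {
  stopifnot(inherits(input_img, "intensity_image"),
            inherits(reference_img, "intensity_image"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be at least 2", call. = FALSE)
  q_min <- input_img$q_min; q_max <- input_img$q_max
  edges <- seq(q_min, q_max, length.out = bins + 1L)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  cdf_of <- function(img) {
    fg <- img$pixels[img$pixels > fg_threshold]
    if (length(fg) == 0L) stop_mhn("degenerate_image", "no foreground pixels")
    b <- findInterval(clip_range(fg, q_min, q_max), edges, rightmost.closed = TRUE)
    counts <- tabulate(b, nbins = bins)
    ## representative grey per bin: mean of the image's own values in the
    ## bin (the geometric centre when a bin is empty)
    grey <- centers
    occ <- counts > 0L
    agg <- rowsum(fg, b)
    sums <- numeric(bins)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    grey[occ] <- sums[occ] / counts[occ]
    list(cdf = cumsum(counts) / sum(counts), grey = grey)
  }
  cin <- cdf_of(input_img)
  cref <- cdf_of(reference_img)
  ## for each input bin pick the reference grey level with the nearest
  ## cumulative frequency
  lut <- vapply(cin$cdf, function(ci) cref$grey[which.min(abs(cref$cdf - ci))],
                numeric(1))
  px <- input_img$pixels
  fg <- px > fg_threshold
  b <- findInterval(clip_range(px[fg], q_min, q_max), edges, rightmost.closed = TRUE)
  out <- px
  out[fg] <- lut[b]
  intensity_image(clip_range(out, q_min, q_max), spacing_mm = input_img$spacing_mm,
                  q_min = q_min, q_max = q_max)
}

#' Histogram, cumulative frequency curve, and empirical pdf
#'
#' Diagnostic summaries used to inspect normalization quality: bin counts
#' over the grayscale range, the cumulative frequency curve (CFC, ending at
#' 1), and the empirical pdf (counts over total pixels).
#'
#' @param img an [intensity_image()].
#' @param bins number of equal-width bins over `[q_min, q_max]`; default 256.
#' @return Object of class `mhn_histogram`: data frame with columns `mid`
#'   (bin centre), `count`, `pdf`, `cfc`, plus attributes `breaks` and `n`.
#' @export
histogram_report <- function(img, bins = 256) {
  stopifnot(inherits(img, "intensity_image"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be at least 2", call. = FALSE)
  edges <- seq(img$q_min, img$q_max, length.out = bins + 1L)
  counts <- tabulate(findInterval(clip_range(img$pixels, img$q_min, img$q_max),
                                  edges, rightmost.closed = TRUE), nbins = bins)
  n <- length(img$pixels)
  out <- data.frame(mid = (edges[-1] + edges[-(bins + 1L)]) / 2,
                    count = counts,
                    pdf = counts / n,
                    cfc = cumsum(counts) / n)
  attr(out, "breaks") <- edges
  attr(out, "n") <- n
  class(out) <- c("mhn_histogram", "data.frame")
  out
}

#' Plot histogram / CFC diagnostics
#'
#' @param x an object from [histogram_report()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.mhn_histogram <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$mid, x$count, type = "h", xlab = "grey level",
                 ylab = "count", main = "histogram", ...)
  graphics::plot(x$mid, x$cfc, type = "l", xlab = "grey level",
                 ylab = "cumulative frequency", main = "CFC", ylim = c(0, 1), ...)
  invisible(x)
}
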