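#' Specification of a synthetic brain phantom
#'
#' Describes a 2-D multi-tissue phantom emulating an axial brain MRI slice:
#' three nested elliptical tissue compartments (an outer CSF ring, a GM
#' ring, a WM core) with distinct mean intensities, a smooth multiplicative
#' bias field, a per-site affine/gamma intensity transform, and Rician
#' noise (the magnitude-image MRI noise model: zero-mean uncorrelated
#' Gaussian noise of equal variance in both quadrature channels).
#'
#' Defaults emulate a T1-weighted contrast on the 8-bit scale: CSF dark
#' (60), GM intermediate (110), WM bright (160), a 10% bias-field
#' amplitude, and Rician channel SD 10 grey levels.
#'
#' @param shape integer pair, canvas size in pixels.
#' @param tissue_means named numeric vector `c(csf=, gm=, wm=)`, strictly
#'   increasing.
#' @param axes_frac fractions of the half-canvas giving the outer (CSF), GM
#'   and WM ellipse semi-axes.
#' @param bias_amplitude bias-field amplitude as a fraction in `[0, 0.5]`.
#' @param site_gain,site_offset,site_gamma site intensity transform
#'   `clip(gain * (I/q_max)^gamma * q_max + offset)`.
#' @param noise_sigma Rician channel SD in grey levels (0 disables noise).
#' @param seed RNG seed for the noise.
#' @param spacing_mm pixel spacing.
#' @param q_min,q_max grayscale range.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128),
                         tissue_means = c(csf = 60, gm = 110, wm = 160),
                         axes_frac = c(0.84, 0.66, 0.42),
                         bias_amplitude = 0.1,
                         site_gain = 1, site_offset = 0, site_gamma = 1,
                         noise_sigma = 10, seed = 1L,
                         spacing_mm = c(1, 1), q_min = 0L, q_max = 255L) {
  shape <- as.integer(rep_len(shape, 2L))
  if (any(shape < 16L)) stop("phantom canvas must be at least 16 pixels", call. = FALSE)
  tissue_means <- tissue_means[c("csf", "gm", "wm")]
  if (any(is.na(tissue_means)) || any(diff(tissue_means) <= 0))
    stop("tissue means must be named csf/gm/wm and strictly increasing", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude > 0.5)
    stop("`bias_amplitude` must lie in [0, 0.5]", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  if (any(axes_frac <= 0) || any(axes_frac >= 1) || any(diff(axes_frac) >= 0))
    stop("`axes_frac` must be strictly decreasing fractions in (0, 1)", call. = FALSE)
  structure(list(shape = shape, tissue_means = tissue_means,
                 axes_frac = axes_frac, bias_amplitude = bias_amplitude,
                 site_gain = site_gain, site_offset = site_offset,
                 site_gamma = site_gamma, noise_sigma = noise_sigma,
                 seed = as.integer(seed), spacing_mm = rep_len(spacing_mm, 2L),
                 q_min = as.numeric(q_min), q_max = as.numeric(q_max)),
            class = "phantom_spec")
}

ellipse_mask <- function(shape, frac) {
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  ay <- frac * shape[1] / 2; ax <- frac * shape[2] / 2
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((y - cy) / ay)^2 + ((x - cx) / ax)^2 <= 1
}

#' Generate a synthetic brain phantom
#'
#' Paints the nested tissue ellipses at their mean intensities, multiplies
#' by the smooth low-order bias surface
#' \eqn{1 + A \sin(\pi y / H) \cos(\pi x / W)}, applies the site transform
#' `clip(gain * (I/q_max)^gamma * q_max + offset)`, and finally adds Rician
#' noise \eqn{I' = \sqrt{(I + n_1)^2 + n_2^2}} with seeded
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)} — corruption in scanner order.
#' Ground-truth masks reflect the pre-noise geometry.
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` (an [intensity_image()]), `masks` (named list
#'   of [binary_mask()]s for `csf`, `gm`, `wm`), and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0))
#' sort(unique(as.vector(ph$image$pixels)))
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  outer_m <- ellipse_mask(sh, spec$axes_frac[1])
  gm_m <- ellipse_mask(sh, spec$axes_frac[2])
  wm_m <- ellipse_mask(sh, spec$axes_frac[3])
  csf <- outer_m & !gm_m
  gm <- gm_m & !wm_m
  wm <- wm_m
  img <- matrix(0, sh[1], sh[2])
  img[csf] <- spec$tissue_means[["csf"]]
  img[gm] <- spec$tissue_means[["gm"]]
  img[wm] <- spec$tissue_means[["wm"]]
  if (spec$bias_amplitude > 0) {
    y <- matrix(seq_len(sh[1]), sh[1], sh[2])
    x <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    bias <- 1 + spec$bias_amplitude * sin(pi * y / sh[1]) * cos(pi * x / sh[2])
    img <- img * bias
  }
  ## site (scanner) transform, then Rician noise: corruption in scanner
  ## order. The transform acts on signal-carrying pixels only — air has no
  ## signal, so a scanner's intensity scaling cannot lift it off zero.
  if (spec$site_gain != 1 || spec$site_offset != 0 || spec$site_gamma != 1) {
    sig <- img > 0
    img[sig] <- spec$site_gain * (img[sig] / spec$q_max)^spec$site_gamma *
      spec$q_max + spec$site_offset
    img <- clip_range(img, spec$q_min, spec$q_max)
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      n1 <- matrix(stats::rnorm(length(img), 0, spec$noise_sigma), sh[1], sh[2])
      n2 <- matrix(stats::rnorm(length(img), 0, spec$noise_sigma), sh[1], sh[2])
      sqrt((img + n1)^2 + n2^2)
    })
    img <- clip_range(img, spec$q_min, spec$q_max)
  }
  list(image = intensity_image(img, spacing_mm = spec$spacing_mm,
                               q_min = spec$q_min, q_max = spec$q_max),
       masks = list(csf = binary_mask(csf, spec$spacing_mm),
                    gm = binary_mask(gm, spec$spacing_mm),
                    wm = binary_mask(wm, spec$spacing_mm)),
       spec = spec)
}

#' Generate a multi-site phantom cohort
#'
#' Emulates the same subject scanned at several sites with inconsistent
#' scanner settings. Site 1 is the undistorted reference ("high-quality"
#' image: gain 1, offset 0); every further site draws a multiplicative gain
#' and additive offset uniformly from the given ranges. All sites share the
#' phantom geometry, so the ground-truth masks are common.
#'
#' @param base a [phantom_spec()]; its `site_gain`/`site_offset` are
#'   overridden per site.
#' @param n_sites number of sites including the reference (at least 2).
#' @param gain_range,offset_range uniform sampling intervals for the site
#'   transforms; defaults `[0.8, 1.2]` and `[-20, 20]`.
#' @param seed seed for the site-parameter draws; per-site noise seeds are
#'   derived from it.
#' @return List with `images` (list of [intensity_image()], element 1 the
#'   reference), `masks` (shared ground truth), and `sites` (data frame of
#'   the true per-site gain/offset).
#' @export
make_site_cohort <- function(base, n_sites = 4, gain_range = c(0.8, 1.2),
                             offset_range = c(-20, 20), seed = 1L) {
  stopifnot(inherits(base, "phantom_spec"))
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("`n_sites` must be at least 2", call. = FALSE)
  if (gain_range[2] < gain_range[1] || offset_range[2] < offset_range[1])
    stop("degenerate gain/offset range", call. = FALSE)
  draws <- with_seed(seed, cbind(
    gain = stats::runif(n_sites - 1L, gain_range[1], gain_range[2]),
    offset = stats::runif(n_sites - 1L, offset_range[1], offset_range[2])))
  gains <- c(1, draws[, "gain"])
  offsets <- c(0, draws[, "offset"])
  phantoms <- lapply(seq_len(n_sites), function(i) {
    sp <- base
    sp$site_gain <- gains[i]
    sp$site_offset <- offsets[i]
    sp$seed <- base$seed + (i - 1L) * 1000L
    make_phantom(sp)
  })
  list(images = lapply(phantoms, `[[`, "image"),
       masks = phantoms[[1]]$masks,
       sites = data.frame(site = seq_len(n_sites), gain = gains, offset = offsets))
}
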