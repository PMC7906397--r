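---
title: "Landmark-based intensity harmonization for multi-site MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based intensity harmonization for multi-site MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhnorm)
```

## The problem

Brain MRI intensities are recorded in arbitrary units. Two scans of the
same head taken on different scanners — or on the same scanner with
different settings — place the same tissue at different grey levels, so
any downstream step that keys on intensity (tissue segmentation, volume
estimation, patch-based classifier training) degrades when a study pools
data from several sites. `mhnorm` harmonizes such data by mapping every
image onto the intensity scale of one chosen high-quality **reference**
image, after Gaussian denoising.

## The model

### Landmarks

For an image with foreground pixels (those above a threshold separating
air from tissue) we estimate five landmarks of the foreground intensity
multiset:

* `m1`, `m2` — the foreground minimum and maximum;
* `P1`, `P2` — the low/high nearest-rank percentiles (default 1st and
  99th, ties resolved to the lower rank);
* `mu` — the arithmetic mean of foreground values restricted to
  `[P1, P2]`.

Percentile landmarks rather than raw extremes make the anchors robust to
hot pixels; restricting the mean to the landmark interval keeps a few
extreme values from dragging it.

### The piecewise-linear map

The reference image supplies the *standard scale*: its landmarks become
the anchors `S1 = P1_ref`, `mu_s = mu_ref`, `S2 = P2_ref`, with the
standard-scale ends `S'1 = m1_ref` and `S'2 = m2_ref`. An input image
with landmarks `(m1, P1, mu, P2, m2)` is mapped by four linear segments

```
[m1, P1] -> [S'1, S1]
[P1, mu] -> [S1, mu_s]
[mu, P2] -> [mu_s, S2]
[P2, m2] -> [S2, S'2]
```

with values outside `[m1, m2]` clamped to the standard-scale ends, a
ceiling applied last, and the result clipped to the grayscale range
`[q_min, q_max]` (default `[0, 255]`). The map is continuous, monotone
non-decreasing, and fixes all five anchors up to the ceiling. Background
pixels bypass the map entirely so air stays black.

A design choice deserves emphasis: the standard-scale ends are the
**reference's own foreground extremes**, not the grayscale bounds. Had
the tails been stretched to `[q_min, q_max]`, normalizing an image to
itself would push its brightest tissue toward white (the tail segment
`[P2, m2] -> [S2, 255]` has slope well above one whenever the image does
not already reach 255). With the reference extremes as ends,
self-normalization is the identity up to the ceiling — a property the
test suite checks on every phantom — and the brightest and darkest
tissues of the input land exactly where the reference's do. Callers who
want a full-range stretch can still build a `mapping_spec()` with
`Sp1 = 0, Sp2 = 255` explicitly, or apply `stretch_shift()`.

`stretch_shift()` implements the companion single-affine normalization,
taking the landmark interval `[ROI_low, ROI_high]` onto the full
grayscale. (A formulation circulates that subtracts `q_min` from the
*unit-scale* value and divides the landmark span by the grayscale span;
that is dimensionally inconsistent with its own stated intent of
covering all grey levels, so the function implements the intent.) It is
exposed as an optional pre-stretch and is off by default: the pipeline's
operative map is the piecewise one, which operates directly on grey
levels.

### The baseline: histogram matching

`normalize_hmn()` is classical histogram specification: cumulative
histograms of input and reference foregrounds are computed on `bins`
equal-width bins (default 256) and each input grey level is sent to the
reference grey level with the nearest cumulative frequency. The
"reference grey level" of a bin is the mean of the reference's own
values in that bin, so matching a distribution to itself is exact rather
than quantized to bin centres. The baseline's accuracy decays with
coarser binning, which the tests demonstrate directly (2 vs 256 bins).

### Gaussian smoothing and scale selection

Landmarks are estimated from histograms of *smoothed* images: magnitude
MRI noise is Rician (zero-mean uncorrelated Gaussian noise of equal
variance in both quadrature channels), and a linear low-pass filter
suppresses it before landmark estimation. The kernel is an isotropic
sampled Gaussian on a window whose physical extent covers a fixed
support (default 4 mm; the smallest odd pixel count at the image's
spacing, 5×5 at 1 mm), renormalized to unit sum so constant images are
fixed points. Borders use reflect padding — zero padding would darken the
margins and bias the low landmarks. The smoothing scale is chosen by
sweeping sigma over a grid (default 0.5–3.0 in steps of 0.25) and
maximizing PSNR against a clean reference, ties going to the smaller
sigma; PSNR uses the declared peak `q_max`, not the observed maximum,
so values are comparable across images.

## Evaluation harness

`evaluate_methods()` reproduces the standard comparison table on
phantoms: for each image and each of `none` / `hmn` / `mhn`, it segments
each tissue by the reference's per-region intensity window (the full
range of reference values inside the ground-truth mask; overlapping
windows are resolved to the nearest window centre), then records Dice
overlap against ground truth, MSE against the reference, and region
volumes (pixel count × pixel area). Summaries are mean ± sample SD
(n − 1).

## The phantom generator

`make_phantom()` emulates an axial T1-weighted slice on the 8-bit scale:
three nested elliptical compartments — CSF ring (mean 60), GM ring
(110), WM core (160) — inside a zero background, corrupted in scanner
order by

1. a smooth multiplicative bias field `1 + A sin(pi y/H) cos(pi x/W)`
   (default amplitude 10%),
2. a per-site intensity transform
   `clip(gain * (I/q_max)^gamma * q_max + offset)` applied to
   signal-carrying pixels only — air has no MR signal, so a scanner's
   intensity scaling cannot lift it off zero,
3. Rician noise `sqrt((I + n1)^2 + n2^2)` with seeded
   `n1, n2 ~ N(0, sigma^2)` (default channel SD 10 grey levels).

`make_site_cohort()` draws per-site gains uniformly from `[0.8, 1.2]`
and offsets from `[-20, 20]`, with site 1 the undistorted reference; all
sites share geometry so the ground-truth masks are common. These ranges,
the noise level, and the tissue means are the package's fixed study
conditions; tests and the acceptance script use cohorts of 100 seeds at
96×96 pixels (64×64 where only per-pixel equality is at stake), sizes at
which every intensity statistic of interest is stable.

What the phantom deliberately does **not** model: real cortical
geometry, partial-volume mixing beyond what smoothing induces, spatially
varying noise, motion or registration error. Passing tests therefore
demonstrate the correctness and the qualitative behaviour of the
algorithms — landmark recovery, scanner-effect collapse, split
arithmetic — not clinical performance on real scans.

## Numerical choices

* **Tolerance ceiling.** The mapping's segments evaluated exactly at an
  integer anchor can return `S1 + 2e-16` in floating point; a raw
  ceiling would then jump a full grey level. The ceiling is taken as
  `ceiling(x - 1e-9)`.
* **Degenerate inputs.** No foreground → classed `degenerate_image`
  error; constant foreground or coinciding percentile landmarks →
  `degenerate_histogram`. Degenerate tail segments (`m1 = P1` or
  `P2 = m2`) collapse to their anchor value.
* **Split remainders.** When a patch count is not divisible by the ratio
  total, the floor remainder (at most two items for a three-way split)
  goes to train, then validation, then test. Stratified splitting
  applies the ratio within each label class first.
* **Patch corners** are drawn uniformly with replacement from the valid
  corner lattice and recorded 0-based (half-open windows), the simplest
  reading of "randomly overlapping"; k-fold blocks are returned as
  1-based R index vectors.
* **Seeds.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state, so pipelines are reproducible
  byte-for-byte and library use never perturbs a session's RNG.

## Known limitations

* On these phantoms, 256-bin CDF matching attains slightly lower
  per-pixel MSE than the landmark map: the ceiling adds a ~+0.5 grey
  bias, and when scanner noise does not scale with the site gain the
  noise-floor landmarks are not affine images of the reference's. The
  landmark method's strengths — a three-anchor map that is robust,
  auditable (the `mapping_spec` is returned for logging), and
  independent of bin-count choices — do not show up in a per-pixel MSE
  on geometry-identical phantoms. The acceptance suite reports both
  methods' numbers as computed.
* Only 2-D slices are processed; 3-D volumes are read by taking the
  central axial slice.
* The foreground threshold (default 0) separates air from tissue only
  when the background is genuinely darker than all tissue; heavily
  noise-floored data may need a higher threshold, chosen by the user.

## A minimal session

```{r example, eval = FALSE}
base <- phantom_spec(shape = c(96, 96), noise_sigma = 10, seed = 7)
cohort <- make_site_cohort(base, n_sites = 4, seed = 7)
smoothed <- lapply(cohort$images, smooth_gaussian, sigma = 1.25)
reference <- smoothed[[1]]

res <- normalize_mhn(smoothed[[2]], reference)
res$spec                     # the audit record of the mapping used

ev <- evaluate_methods(list(site2 = smoothed[[2]], site3 = smoothed[[3]]),
                       reference, cohort$masks)
ev$summary
```
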