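# mhnorm

Intensity harmonization for multi-site brain MRI.

MRI grey values are arbitrary units: the same tissue lands at different
intensities on different scanners, which corrupts any pooled analysis that
keys on intensity — tissue segmentation, grey-matter volume estimation, or
training a patch-based classifier on slices collected at several sites.
`mhnorm` maps every image onto the intensity scale of one chosen
high-quality *reference* image using a **modified histogram normalization
(MHN)**: a continuous piecewise-linear map anchored at five histogram
landmarks, applied after Gaussian denoising.

For an input image with foreground landmarks `(m1, P1, mu, P2, m2)` —
foreground minimum, 1st percentile, landmark-interval mean, 99th
percentile, maximum — and a reference with landmarks
`(m1', P1', mu', P2', m2')`, the map sends

```
[m1, P1] -> [m1', P1']      (lower tail)
[P1, mu] -> [P1', mu']      N(v) = ceil( mu' + (v - mu) * (P1' - mu') / (P1 - mu) )
[mu, P2] -> [mu', P2']      N(v) = ceil( mu' + (v - mu) * (P2' - mu') / (P2 - mu) )
[P2, m2] -> [P2', m2']      (upper tail)
```

clamping values outside `[m1, m2]` to the standard-scale ends and leaving
background (air) pixels untouched. The map is monotone, fixes every
anchor, and normalizing an image to itself is the identity up to the
ceiling.

The package also provides:

* `smooth_gaussian()` / `sigma_sweep()` — isotropic Gaussian denoising
  with a fixed 4 mm physical support and PSNR-driven selection of the
  scale over a grid (default 0.5–3.0);
* `normalize_hmn()` — the classical histogram-matching baseline
  (CDF specification on `bins` histogram bins);
* `dsc()`, `mse()`, `psnr()`, `mask_volume()`, `evaluate_methods()` —
  Dice overlap, mean squared error, and the none-vs-HMN-vs-MHN
  comparison table;
* `extract_patches()`, `split_patches()`, `kfold_indices()` — random
  overlapping 64×64 patch extraction, stratified 14:3:3
  train/validation/test splits, and k-fold blocks for classifier
  dataset preparation;
* `make_phantom()` / `make_site_cohort()` — synthetic multi-tissue brain
  phantoms (CSF/GM/WM ellipses, bias field, per-site gain/offset,
  Rician noise) with ground-truth masks, so the whole pipeline is
  testable without any external data;
* `run_pipeline()` plus a thin command-line wrapper
  (`inst/cli/mhnorm.R`) with subcommands `smooth`, `sweep`, `normalize`,
  `hist`, `patch`, `split`, `phantom`, `pipeline`.

I/O covers NIfTI-1 (`.nii`/`.nii.gz`), MetaImage (`.mha`, `.mhd`+`.raw`),
PNG and JPEG, with masks as 0/1 rasters.

## Worked example

Simulate one subject scanned at four sites, harmonize sites 2–4 to site 1,
and compare raw, histogram-matched and landmark-normalized images:

```r
library(mhnorm)

base   <- phantom_spec(shape = c(96, 96), noise_sigma = 10, seed = 7)
cohort <- make_site_cohort(base, n_sites = 4, seed = 7)
cohort$sites
#>   site      gain    offset
#> 1    1 1.0000000   0.00000
#> 2    2 1.1955637 -17.21005
#> 3    3 0.9590982 -10.25002
#> 4    4 0.8462791  11.68042

smoothed  <- lapply(cohort$images, smooth_gaussian, sigma = 1.25)
reference <- smoothed[[1]]

res <- normalize_mhn(smoothed[[2]], reference)
res$spec     # the audit record: input landmarks and standard anchors
#> <mhn_mapping_spec> standard: S'1=6.98905 S1=9.45297 mu_s=62.691 S2=167.468 S'2=175.772
#> <mhn_landmarks> m1=7.20005 P1=9.54817 mu=64.127 P2=183.037 m2=189.385
```

Site 2 was scanned with gain 1.20 and offset −17.2; its grey-matter mean
sits at 113.5 before normalization and 106.7 after, against 109.7 in the
reference — the scanner effect is collapsed to a few grey levels. The
evaluation table tells the same story for segmentation overlap (Dice
against the ground-truth masks) and per-pixel error:

```r
ev <- evaluate_methods(list(site2 = smoothed[[2]], site3 = smoothed[[3]],
                            site4 = smoothed[[4]]),
                       reference, cohort$masks)
ev$summary[, c("method", "region", "dsc_mean", "mse_mean")]
#>   method region dsc_mean mse_mean
#> 1    hmn    csf    0.979     9.39
#> 2    mhn    csf    0.972    17.61
#> 3   none    csf    0.954    69.24
#> 4    hmn     gm    0.975     9.39
#> 5    mhn     gm    0.970    17.61
#> 6   none     gm    0.939    69.24
#> 7    hmn     wm    0.984     9.39
#> 8    mhn     wm    0.984    17.61
#> 9   none     wm    0.893    69.24
```

Both normalization methods recover segmentation accuracy that the raw
site images lose (e.g. WM Dice 0.89 → 0.98); on these geometry-identical
phantoms the CDF-matching baseline attains a somewhat lower per-pixel MSE
than the landmark map — see the methods vignette
(`vignettes/mhnorm-methods.Rmd`) for why, and for every modelling and
numerical choice.

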