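# Shared fixture builders; all randomness is locally seeded.

# Small noisy phantom used across suites.
test_phantom <- function(seed = 1L, shape = c(96, 96), noise_sigma = 10,
                         ...) {
  make_phantom(phantom_spec(shape = shape, noise_sigma = noise_sigma,
                            seed = seed, ...))
}

# A random valid mapping spec on the 8-bit scale. Standard-scale ends are
# the grayscale bounds unless inner = TRUE, which draws them strictly
# inside the range.
random_spec <- function(inner = FALSE) {
  repeat {
    lm <- sort(sample(0:255, 5))
    if (lm[2] < lm[3] && lm[3] < lm[4]) break
  }
  landmarks <- structure(
    list(m1 = lm[1], P1 = lm[2], mu = lm[3] + stats::runif(1, -0.49, 0.49),
         P2 = lm[4], m2 = lm[5]),
    class = "mhn_landmarks")
  repeat {
    st <- sort(sample(0:255, 3))
    if (st[1] < st[2] && st[2] < st[3]) break
  }
  if (inner) {
    sp1 <- stats::runif(1, 0, st[1]); sp2 <- stats::runif(1, st[3], 255)
  } else {
    sp1 <- 0; sp2 <- 255
  }
  mapping_spec(landmarks, S1 = st[1], mu_s = st[2] + stats::runif(1, -0.49, 0.49),
               S2 = st[3], Sp1 = sp1, Sp2 = sp2)
}

# Straight-line-through-two-points oracle for the piecewise mapping,
# evaluated segment by segment with the generic two-point formula; kept
# deliberately independent of piecewise_map's vectorized arithmetic.
oracle_map_scalar <- function(v, spec) {
  L <- spec$input
  line <- function(v, x1, y1, x2, y2) y1 + (v - x1) * (y2 - y1) / (x2 - x1)
  y <- if (v < L$m1) spec$Sp1
  else if (v < L$P1) line(v, L$m1, spec$Sp1, L$P1, spec$S1)
  else if (v <= L$mu) line(v, L$P1, spec$S1, L$mu, spec$mu_s)
  else if (v <= L$P2) line(v, L$mu, spec$mu_s, L$P2, spec$S2)
  else if (v <= L$m2) line(v, L$P2, spec$S2, L$m2, spec$Sp2)
  else spec$Sp2
  min(max(ceiling(y - 1e-9), spec$Sp1), spec$Sp2)
}
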