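#' Shape parameters for a synthetic seed class
#'
#' A synthetic seed class is defined directly in normalized elliptic-Fourier
#' coefficient space: the first-harmonic ellipse fixes overall length and the
#' breadth:length (B:L) ratio, low harmonics encode the pyriform "stalk"
#' bulge that distinguishes elongated cultivated pips from rounder wild ones,
#' and Gaussian spread on the coefficients generates within-class variation.
#' Charring is modelled as the two effects reported for carbonised grape
#' seeds — an additive increase in B:L and an isotropic shrinkage — plus
#' optional high-harmonic boundary jitter.
#'
#' @param class_label class token, e.g. `"WILD"` or `"CULTIVATED"`.
#' @param scale_mm mean seed length (mm).
#' @param aspect breadth:length ratio in (0, 1].
#' @param stalk_amplitude strength of the harmonic-2/3 stalk bulge
#'   (normalized coefficient units, >= 0).
#' @param coeff_sd per-coefficient within-class Gaussian sd (normalized
#'   units, harmonics 1-6).
#' @param charring_bl_shift additive B:L increase applied when a seed is
#'   generated charred.
#' @param charring_shrink multiplicative size factor in (0, 1] applied when
#'   charred.
#' @param boundary_noise_sd sd of random high-harmonic (7-12) coefficients,
#'   a proxy for charring-induced surface irregularity.
#' @return an object of class `shape_params` (a named list).
#' @export
shape_params <- function(class_label,
                         scale_mm = 5.5,
                         aspect = 0.65,
                         stalk_amplitude = 0.08,
                         coeff_sd = 0.02,
                         charring_bl_shift = 0.08,
                         charring_shrink = 0.90,
                         boundary_noise_sd = 0.004) {
  stopifnot(is.character(class_label), length(class_label) == 1)
  if (!(aspect > 0 && aspect <= 1)) abort("aspect must be in (0, 1]")
  if (!(charring_shrink > 0 && charring_shrink <= 1))
    abort("charring_shrink must be in (0, 1]")
  if (scale_mm <= 0) abort("scale_mm must be positive")
  if (stalk_amplitude < 0 || coeff_sd < 0 || boundary_noise_sd < 0 ||
      charring_bl_shift < 0)
    abort("amplitudes and standard deviations must be >= 0")
  structure(
    list(class_label = class_label, scale_mm = scale_mm, aspect = aspect,
         stalk_amplitude = stalk_amplitude, coeff_sd = coeff_sd,
         charring_bl_shift = charring_bl_shift,
         charring_shrink = charring_shrink,
         boundary_noise_sd = boundary_noise_sd),
    class = "shape_params")
}

#' Default wild and cultivated seed classes
#'
#' Returns the two default shape classes at a chosen separation. Wild grape
#' pips are shorter and rounder with a short stalk; cultivated pips are
#' longer, narrower and markedly pyriform. `separation = 1` gives the full
#' default contrast; `separation = 0` collapses both classes onto their
#' midpoint (identical distributions, useful as a null model); intermediate
#' values interpolate linearly.
#'
#' @param separation contrast multiplier in `[0, 1]` (values > 1 extrapolate).
#' @param coeff_sd within-class coefficient sd shared by both classes.
#' @return named list with elements `WILD` and `CULTIVATED`, each a
#'   [shape_params()] object.
#' @export
seed_classes <- function(separation = 1, coeff_sd = 0.02) {
  wild <- c(scale_mm = 4.8, aspect = 0.74, stalk = 0.05)
  cult <- c(scale_mm = 6.2, aspect = 0.56, stalk = 0.13)
  mid <- (wild + cult) / 2
  w <- mid + separation * (wild - mid)
  k <- mid + separation * (cult - mid)
  list(
    WILD = shape_params("WILD", scale_mm = w[["scale_mm"]],
                        aspect = w[["aspect"]],
                        stalk_amplitude = w[["stalk"]], coeff_sd = coeff_sd),
    CULTIVATED = shape_params("CULTIVATED", scale_mm = k[["scale_mm"]],
                              aspect = k[["aspect"]],
                              stalk_amplitude = k[["stalk"]],
                              coeff_sd = coeff_sd))
}

# Template of normalized EFD coefficients for a class (harmonics x 4).
# Harmonic 2/3 terms carry the stalk bulge; the a2 term is kept positive so
# the extractor's a2 >= 0 branch convention matches the generator.
seed_template_coeffs <- function(aspect, stalk_amplitude, n_harmonics = 6) {
  cf <- matrix(0, n_harmonics, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  cf[1, ] <- c(1, 0, 0, aspect)
  cf[2, 1] <- stalk_amplitude          # egg asymmetry along the major axis
  cf[3, 4] <- 0.35 * stalk_amplitude   # pinched stalk end
  cf[3, 1] <- 0.15 * stalk_amplitude
  cf
}

#' Sample one synthetic seed outline
#'
#' Evaluates a truncated elliptic-Fourier series whose first-harmonic ellipse
#' has semi-axes `scale_mm/2` and `aspect * scale_mm/2`, perturbed by
#' Gaussian noise on the free coefficients, and returns the outline polygon
#' in mm. Uses the current RNG state; callers wanting reproducibility set
#' `set.seed()` (the dataset generator assigns one substream per seed id).
#'
#' @param params a [shape_params()] object.
#' @param charred if `TRUE`, `aspect` is increased by `charring_bl_shift` and
#'   the scale multiplied by `charring_shrink` before evaluation, and
#'   boundary jitter is added.
#' @param n_points vertices in the returned polygon.
#' @param mirrored if `TRUE` the outline is reflected across its major axis
#'   (used for the second scanned side of a seed).
#' @param max_retries resampling attempts when noise produces a
#'   self-intersecting outline.
#' @return an `n_points` x 2 matrix (mm, counter-clockwise, centred at the
#'   origin) of class `seed_outline`, with attributes `params`, `charred`
#'   and `truth` (the exact generating polygon's arc-length normalized EFD,
#'   for recovery tests).
#' @export
sample_outline <- function(params, charred = FALSE, n_points = 256,
                           mirrored = FALSE, max_retries = 10) {
  stopifnot(inherits(params, "shape_params"))
  aspect <- params$aspect + if (charred) params$charring_bl_shift else 0
  aspect <- min(aspect, 0.99)
  scale <- params$scale_mm * (if (charred) params$charring_shrink else 1)

  for (attempt in seq_len(max_retries)) {
    cf <- seed_template_coeffs(aspect, params$stalk_amplitude, 6)
    if (params$coeff_sd > 0) {
      noise <- matrix(rnorm(length(cf), 0, params$coeff_sd), nrow(cf), 4)
      noise[1, 1:3] <- 0  # keep the normalization frame fixed
      cf <- cf + noise
    }
    if (charred && params$boundary_noise_sd > 0) {
      hi <- matrix(rnorm(6 * 4, 0, params$boundary_noise_sd), 6, 4)
      cf <- rbind(cf, hi)
    }
    if (mirrored) cf[, 3:4] <- -cf[, 3:4]
    cf <- cf * (scale / 2)
    poly <- reconstruct_efd(cf, n_points)
    if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    if (polygon_is_simple(poly)) {
      truth <- normalize_efd(compute_efd(poly, min(20, floor(n_points / 2))))
      return(structure(poly, class = c("seed_outline", class(poly)),
                       params = params, charred = charred,
                       mirrored = mirrored, truth = truth))
    }
  }
  abort(sprintf("could not generate a simple outline for class %s after %d attempts",
                params$class_label, max_retries))
}
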