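#' Synthetic linescan specification
#'
#' Describes a synthetic straightened-cord image: a uniform background plus a
#' cord signal spanning the linescan, bearing isotropic 2D Gaussian puncta of
#' known positions, amplitudes and widths on the midline, with additive
#' Gaussian or Poisson noise, quantized to the stated bit depth. The
#' defaults are the package's standard validation fixture: an 8-bit
#' widefield-like linescan, 1200 x 21 px at 0.1 um/px, with 20 well-resolved
#' puncta (amplitudes 80-160 = 20-40x the noise SD of 4; sigma 1.5-3 px;
#' >= 30 px separation, i.e. >= 10 sigma_max).
#'
#' @param length_px,width_px image size (columns, rows).
#' @param background_level,cord_level additive intensity levels; the cord
#'   spans the whole linescan.
#' @param background_noise_sd Gaussian noise SD (ignored for Poisson noise).
#' @param n_puncta number of puncta.
#' @param punctum_amplitudes,punctum_sigmas_px length-`n_puncta` vectors, or
#'   `NULL` to draw uniformly from `amplitude_range` / `sigma_range`.
#' @param punctum_positions_px column centres (0-based), or `NULL` to place
#'   uniformly at random with minimum separation `min_separation_px` and an
#'   edge margin of `margin_px`.
#' @param amplitude_range,sigma_range sampling ranges for random draws.
#' @param min_separation_px,margin_px placement constraints.
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param bit_depth 8, 16 or `"float"` (no quantization).
#' @param pixel_size um/px or `NULL`.
#' @param seed RNG seed; a fixed seed makes [generate_synthetic()]
#'   bit-reproducible.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(length_px = 1200L, width_px = 21L,
                       background_level = 20, cord_level = 30,
                       background_noise_sd = 4, n_puncta = 20L,
                       punctum_amplitudes = NULL, punctum_sigmas_px = NULL,
                       punctum_positions_px = NULL,
                       amplitude_range = c(80, 160),
                       sigma_range = c(1.5, 3),
                       min_separation_px = 30, margin_px = 30,
                       noise_model = c("gaussian", "poisson"),
                       bit_depth = 8, pixel_size = 0.1, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length_px >= 1, width_px >= 1, background_level >= 0,
            cord_level >= 0, background_noise_sd >= 0, n_puncta >= 0)
  if (!is.null(punctum_amplitudes) && any(punctum_amplitudes <= 0))
    stop("punctum amplitudes must be > 0")
  spec <- structure(as.list(environment()), class = "synth_spec")
  spec
}

#' Generate a synthetic linescan with ground truth
#'
#' Renders the image described by a [synth_spec] and returns it together
#' with the true punctum table (centre, sigma, FWHM, amplitude). Output is
#' bit-identical for a fixed seed. Explicit positions closer than the
#' minimum separation produce a warning, not an error.
#'
#' @param spec a [synth_spec].
#' @return List: `image` (a [straightened_image]) and `truth` (data.frame
#'   `punctum, center_px, sigma_px, fwhm_px, amplitude` with attributes
#'   `n_puncta` and `length_px`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_puncta
  L <- spec$length_px
  amp <- spec$punctum_amplitudes
  sig <- spec$punctum_sigmas_px
  pos <- spec$punctum_positions_px
  if (n > 0) {
    if (is.null(amp))
      amp <- stats::runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
    if (is.null(sig))
      sig <- stats::runif(n, spec$sigma_range[1], spec$sigma_range[2])
    if (is.null(pos)) {
      # uniform placement with a hard minimum gap: draw sorted uniforms on the
      # gap-free interval, then re-insert the gaps
      free <- (L - 1 - 2 * spec$margin_px) - (n - 1) * spec$min_separation_px
      if (free < 0) stop("image too short for n_puncta at this separation")
      u <- sort(stats::runif(n, 0, free))
      pos <- spec$margin_px + u + (seq_len(n) - 1) * spec$min_separation_px
    } else if (n > 1 && any(diff(sort(pos)) < spec$min_separation_px)) {
      warning("explicit punctum positions closer than min_separation_px")
    }
    stopifnot(length(amp) == n, length(sig) == n, length(pos) == n)
  }

  base <- spec$background_level + spec$cord_level
  img <- matrix(base, spec$width_px, L)
  mid <- (spec$width_px - 1) / 2   # 0-based midline row
  rows0 <- seq_len(spec$width_px) - 1
  cols0 <- seq_len(L) - 1
  for (j in seq_len(n)) {
    gr <- exp(-(rows0 - mid)^2 / (2 * sig[j]^2))
    gc <- exp(-(cols0 - pos[j])^2 / (2 * sig[j]^2))
    img <- img + amp[j] * outer(gr, gc)
  }
  if (spec$noise_model == "gaussian") {
    if (spec$background_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$background_noise_sd),
                          nrow(img), ncol(img))
  } else {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  }
  if (!identical(spec$bit_depth, "float")) {
    img <- pmin(pmax(round(img), 0), 2^spec$bit_depth - 1)
  } else {
    img <- pmax(img, 0)
  }

  truth <- data.frame(punctum = seq_len(n),
                      center_px = if (n) pos else numeric(0),
                      sigma_px = if (n) sig else numeric(0),
                      fwhm_px = if (n) FWHM_FACTOR * sig else numeric(0),
                      amplitude = if (n) amp else numeric(0))
  attr(truth, "n_puncta") <- n
  attr(truth, "length_px") <- L
  list(image = straightened_image(img, spec$bit_depth, spec$pixel_size,
                                  sprintf("synth_seed%d", spec$seed)),
       truth = truth)
}

#' Low-contrast variant of a synthetic spec
#'
#' Emulates the failure-mode regime where very small puncta have intensities
#' close to the background linescan: amplitudes are scaled by
#' `contrast_factor` and sigmas shrunk by its square root, so a fixed
#' parameter set detects progressively fewer puncta as the factor decreases.
#'
#' @param spec a [synth_spec].
#' @param contrast_factor in (0, 1]; 1 returns the spec unchanged.
#' @return A modified [synth_spec].
#' @export
low_contrast_variant <- function(spec, contrast_factor) {
  stopifnot(inherits(spec, "synth_spec"),
            contrast_factor > 0, contrast_factor <= 1)
  if (contrast_factor == 1) return(spec)
  sc <- function(x) if (is.null(x)) NULL else x * contrast_factor
  spec$punctum_amplitudes <- sc(spec$punctum_amplitudes)
  spec$amplitude_range <- spec$amplitude_range * contrast_factor
  shrink <- sqrt(contrast_factor)
  if (!is.null(spec$punctum_sigmas_px))
    spec$punctum_sigmas_px <- spec$punctum_sigmas_px * shrink
  spec$sigma_range <- spec$sigma_range * shrink
  spec
}

#' Write a ground-truth table as CSV
#'
#' @param truth data.frame from [generate_synthetic()].
#' @param path output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  write_csv6(truth, path)
}
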