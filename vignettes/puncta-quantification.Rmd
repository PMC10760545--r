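---
title: "Quantifying fluorescent puncta in linear cellular structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent puncta in linear cellular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaline)
```

## The problem

Fluorescently tagged synaptic and trafficking proteins accumulate as
discrete bright spots — *puncta* — along linear structures such as the
ventral and dorsal nerve cords of *C. elegans*. Typical questions are: how
many puncta per micrometre of cord, how bright is each punctum, and how
wide is it? `punctaline` implements a batch pipeline for these
measurements: maximum-intensity projection of TIFF stacks, straightening of
a user-traced cord path into a linescan, punctum detection by local
adaptive thresholding, per-punctum measurement (maximum intensity,
Gaussian-fit full width at half maximum), and per-image density. Everything
is scriptable and deterministic; there is no interactive step, so traced
paths and quality-control decisions enter as coordinate files.

## The pipeline, stage by stage

### Projection and straightening

Stacks are collapsed by maximum-intensity projection (per pixel, the
maximum across z-planes). The cord is described by a polyline with 0-based
`(row, col)` vertices and an odd straightening width \(w\). The
straightened image has \(w\) rows and `round(L)` columns, where \(L\) is
the polyline's arc length in pixels: column \(j\) is the perpendicular
cross-section at arc length \(j\), sampled by bilinear interpolation in
1-pixel steps. Numerical choices worth knowing:

* **No spline smoothing.** The raw polyline is sampled; the perpendicular at
  a sample is its segment's normal, and samples landing exactly on an
  interior vertex use the normalized bisector of the adjacent normals. This
  keeps the operation deterministic and exactly testable: an axis-aligned
  path is bit-identical to a crop.
* **Row orientation.** Row 0 lies to the *left* of the direction of travel,
  which is what makes a left-to-right path reduce to a crop with rows in
  natural order.
* **Interpolation is written in incremental form**
  \(v = v_{00} + f_c\,\Delta_c + f_r\,\Delta_r + f_rf_c\,\Delta_{rc}\), so a
  constant image straightens to exactly that constant and integer-grid
  samples are exact — no one-ulp surprises in bit-exactness tests.
* **Out-of-bounds samples** are zero-filled with a warning, keeping outputs
  rectangular.
* **Reversal caveat.** Because sampling happens at integer arc lengths
  \(0, 1, \dots, n-1\), the reversed path samples at \(L - j\); for an
  integer-length path the mirrored reversal equals the forward image
  shifted by exactly one column on the interior. The test suite asserts
  this exact relation rather than a naive mirror; a sampling scheme that
  made reversal an exact mirror would have to give up the crop identity.

### Detection

Detection runs on a Gaussian-blurred copy (the blur is *only* for threshold
computation; all measurements use the original image):

1. **Gaussian blur**, standard deviation `sigma` px, separable sampled
   kernel truncated at \(4\sigma\), reflective boundaries. `sigma = 0`
   disables.
2. **Phansalkar local threshold.** Intensities are normalized to \([0,1]\)
   by the bit-depth maximum; pixel value \(t\) is foreground iff
   \[ t > \mu\,\bigl(1 + p\,e^{-q\mu} + k(\sigma_w/r - 1)\bigr), \]
   with \(\mu, \sigma_w\) the mean and *population* standard deviation over
   a circular window of the stated radius (truncated at borders). The
   constants default to the ImageJ Auto Local Threshold values
   \(k = 0.25, r = 0.5, p = 2, q = 10\) and are exposed in
   `detection_params()`. A global Otsu threshold ships as a sanity
   baseline. The implementation is required (and tested) to be
   bit-identical to a per-pixel brute-force evaluation of the formula.
3. **Connected components** (8-connected by default, 4 available) with a
   minimum-area filter. `min_size` is read as \(\mu m^2\) when the image
   has a pixel size, else as \(px^2\); the output tables always carry a
   units column. Surviving regions are numbered left to right along the
   cord (ties: top edge, then first pixel in row-major order).

The behaviour of the Phansalkar rule is worth internalizing: for dim images
(normalized mean below about 0.21) the \(p\,e^{-q\mu}\) term pushes the
threshold *above* the local mean, while for brighter regions the
\(k(\sigma_w/r - 1)\) term pulls it slightly below. A 16-bit image using a
small fraction of its range therefore thresholds very differently from the
same data scaled to 8-bit — one reason parameters must be tuned per
dataset, and the mechanism behind the low-contrast failure mode discussed
below.

### Measurement and the discard rule

For each ROI the horizontal intensity profile is the per-column mean over
the bounding-box rows of the *original* straightened image. A 4-parameter
peak model
\[ y(x) = a + (b - a)\,e^{-(x-c)^2 / (2d^2)} \]
is fitted by unweighted least squares (Levenberg–Marquardt, analytic
Jacobian, deterministic initialization \(a=\min, b=\max, c=\arg\max,
d=\text{span}/4\), at most 1000 iterations, relative tolerance \(10^{-8}\),
no restarts). Then \(\mathrm{FWHM} = 2\sqrt{2\ln 2}\,d \approx 2.3548\,d\).

Profiles that ascend strongly to one side and cut off — a punctum at the
edge of the traced region, or overlapping neighbours — misfit, giving an
unrealistically wide FWHM. The pipeline flags `discard = 1` whenever the
fitted FWHM exceeds the ROI's bounding-box width, and treats fit failures
(short or flat profiles, non-finite \(d\)) the same way. With
`replace_discarded = TRUE` the FWHM of flagged records is replaced by the
ROI width and `fwhm_replaced` is set, so both downstream conventions
(filter or replace) are available.

### Density

Per image, density = number of ROIs divided by the length of the
straightened image (column count × pixel size). Discarded puncta count by
default — they are detected regions; the discard flag concerns only the
FWHM model fit — and `include_discarded = FALSE` matches the filtered
reading. Densities are reported per µm when calibrated, per px otherwise.

## The synthetic fixture: a stated world

`synth_spec()` describes a synthetic linescan with known ground truth; its
defaults are the package's standard validation fixture and were chosen
once, as a realistic widefield-like scene, before any tests were run:

* 8-bit, 1200 × 21 px at 0.1 µm/px;
* uniform background 20 plus cord signal 30 (the cord spans the linescan);
* additive Gaussian noise, SD 4 (Poisson available);
* 20 puncta: isotropic 2D Gaussians on the midline, amplitudes uniform in
  80–160 (20–40× the noise SD), σ uniform in 1.5–3 px, minimum separation
  30 px (≥ 10 σ\(_{max}\)), 30 px edge margins.

The 8-bit choice is deliberate: with these level ratios the normalized cord
intensity (≈ 0.2) sits where the Phansalkar rule behaves as it does in
practice. The same scene rendered into a 16-bit range it barely uses drives
the \(p\,e^{-q\mu}\) term toward 2 and suppresses detection entirely —
which is not a bug but the documented low-contrast failure regime.

`low_contrast_variant()` emulates that regime explicitly: amplitudes are
scaled by a contrast factor and σ shrunk by its square root, mimicking
datasets whose small dim puncta approach the background linescan. Detected
counts fall monotonically as the factor decreases; at factor 0.1 the
pipeline finds fewer puncta than exist. A green recovery test on the
standard fixture therefore establishes correct behaviour *in the
well-resolved regime only* — it says nothing about dim, overlapping, or
non-Gaussian puncta, uneven cord background, or tracing error, none of
which the generator emulates.

## Calibrating the fixture's detection preset

The analysis workflow this package implements includes a settings-preview
step: a small grid of
candidate parameter sets is run on representative images and inspected
before batch analysis. The package mirrors this with `preview_settings()`,
and the shipped `"synthetic"` preset (min size 0.35 µm², sigma 3,
radius 15, Phansalkar) was chosen exactly that way, on dedicated
calibration seeds (901–960) disjoint from every seed used in the tests:

* smaller blurs/min sizes let occasional ≥ 20 px noise clusters through
  (21–22 detections instead of 20);
* larger blurs widen the thresholded region, and a larger window radius
  keeps the local threshold anchored to the background near a punctum;
  both widen the ROI bounding box, which is what conditions the 4-parameter
  fit (a box spanning ~2 FWHM leaves the baseline and width nearly
  degenerate — the fitted-width error is noise-limited near 10% there, and
  shrinks as the box widens).

With the chosen preset, all 40 held-out calibration seeds recover exactly
20/20 puncta with centre error ≤ 0.15 px and worst-case FWHM error ≤ 9.8%.
The reporter presets `"nuIs24"` (min size 0.2, sigma 1, radius 6) and
`"nuIs152"` (min size 0.3, sigma 0.75, radius 1) are shipped verbatim for
real data of those types; they were tuned on microscope images, not on this
fixture, and are not expected to be optimal for it.

## Worked example

```{r example}
g <- generate_synthetic(synth_spec(seed = 1))
rois <- detect_puncta(g$image, detection_preset("synthetic"))
rec <- measure_puncta(g$image, rois)
head(rec[c("roi_id", "roi_width", "max_intensity", "fwhm", "discard")])
compute_density(rec, straightened_lengths(list(g$image)))
```

## Known limitations

* TIFF only (uncompressed grayscale 8/16-bit); proprietary formats must be
  exported upstream. Interactive tracing and review are out of scope by
  design — paths and crops are coordinate files.
* One parameter set per run: bimodal datasets mixing well-resolved and
  near-background puncta may not be analysable with a single setting (the
  low-contrast regime above).
* FWHM is estimated from the bounding-box-limited profile; for boxes
  spanning less than ~3 FWHM the estimate is noise-limited (see the
  calibration section). Inter-punctum (cord) fluorescence is deliberately
  not reported.
* `min_size` units for uncalibrated images fall back to px²; the units
  column in every output records which was used.
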