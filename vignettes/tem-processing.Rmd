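---
title: "Methods: TEM micrograph processing and particle morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TEM micrograph processing and particle morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrographr)
```

This vignette documents the models, conventions and numerical choices
behind `micrographr`, in the order a typical workflow meets them. Every
claim made here is exercised by the package's test suite; nothing below
reports a number the tests do not themselves compute.

## Data model and coordinates

A `micrograph` is a numeric matrix of intensities plus an optional
physical pixel size (`nm`, `µm`, `Å`) and a metadata list; a `microvideo`
is an ordered list of same-shaped frames with a playback rate. All
processing is done in double precision regardless of the stored bit
depth, and quantisation happens only on save: loading a 16-bit TIFF gives
values 0..65535, not a silently rescaled 8-bit copy.

Coordinates are pinned once for the whole package, because particle
geometry is meaningless without them: row-major storage, origin at the
top-left, 0-based indices, pixel centres at integer coordinates, and
`x = column`, `y = row` in all reported positions. Pixel sizes follow the
MRC container's convention (Ångström in the header cell dimensions), so a
2 nm/px image saved to MRC reloads as 20 Å/px; `convert_scale_unit()`
moves between nm, µm and Å exactly.

## Contrast

`clip_contrast()` implements saturation stretching: a saturation of
*s* percent allows *s* percent of pixels to clip, split evenly between
the tails (*s*/2 below black, *s*/2 above white). The black and white
points are the (*s*/2)-th and (100 − *s*/2)-th percentiles, computed with
linear interpolation between order statistics (`quantile(type = 7)`) —
the interpolation rule is pinned so the clipped-pixel counts on an
analytic ramp are exactly predictable. Conversion to 8 bits rounds
half-to-even, making results platform-independent; `saturation = 0`
reproduces `to_8bit()` bit for bit. The symmetric tail split is a design
choice: an asymmetric split would need a second parameter and the
symmetric default is the least surprising for automated pipelines.

`local_normalisation()` targets the radial illumination falloff of TEM
optics. The image is divided into an n×n grid of nearly equal slices
(sizes differ by at most one pixel), and each patch is multiplied by
`global_median / patch_median`. Because the scaling is linear and
positive, the median of the scaled patch equals the global median
*exactly* — for any patch size — which is the property the tests pin.
With `pad > 0` each patch is extended symmetrically (truncated at
borders) and overlapping contributions are averaged, trading exactness of
the patch medians for fewer seam artefacts. Patch medians must be
positive; zero-median patches raise an error directing the caller to
offset intensities, rather than silently producing infinities. Output
stays on the input intensity scale — display conversion is a separate,
explicit step — because normalisation and display contrast are different
decisions.

## Filters

Median, Gaussian and Wiener filters use half-sample symmetric
(reflective) borders, so a constant image is a fixed point of every
filter. The Gaussian is separable with kernel width `k` and
`sigma = 0.3((k−1)/2 − 1) + 0.8` when unset — the convention of the
OpenCV ecosystem many EM users come from. The Wiener filter is the
classic local-statistics form: local mean and variance over k×k windows,
noise power estimated as the mean local variance when not supplied, and
pixels in windows with variance at or below the noise floor replaced by
the local mean. Non-local means uses patch width 7 and search window 21
by default with the strength `h` required from the caller, since no
universal default survives contact with real noise levels.

The low-pass filter multiplies the spectrum by a hard-edged circular
mask (a raised-cosine edge is available but off by default) and returns
the real part of the inverse transform. The cut-off is specified as a
fraction of the *maximal representable frequency* — the spectrum corner —
rather than the per-axis Nyquist: this makes `radius_fraction = 1` an
exact identity (every frequency kept), which is the natural calibration
point and is tested against a direct O(N²) DFT oracle. Masking is
idempotent by construction.

## Scale bars

The bar length is the largest value of the form {1, 2, 5} × 10^k whose
pixel length does not exceed a set fraction of the image width (default
0.25): untruncated lengths like 237 nm are not usable scale bars. Labels
promote units for readability (2000 nm prints as "2 μm"). Colour is
chosen by a pinned, testable proxy for "significantly darker": white if
the bar region's mean is below the image mean minus 0.1× the intensity
range, black otherwise. The decision is deterministic and flips under
intensity inversion whenever the region is clearly dark or bright; for
regions within 0.1×range of the image mean both polarities give black,
which we accept as the conservative default. Rendering uses a bundled
5×7 bitmap font scaled to ~3% of the image height, so annotation is
bit-reproducible; bar height is 1.5% of the image height, anchored
bottom-left with a 2% margin. Only the bar and text bounding boxes are
touched.

## Video operations

Averaging modes: `chunk` (groups of n, the last smaller group averaged
as-is rather than dropped — discarding frames loses data), `sliding`
(window of n, F − n + 1 output frames) and `all`. Averages are computed
in floating point; chunk averaging of i.i.d. noise reduces variance by
1/n, which the tests verify to within three standard errors under a
fixed seed.

`normalise_video()` multiplies each frame by `global_stat / frame_stat`.
The default statistic is the median — robust to a dark outlier frame,
e.g. a beam-blanked frame — and the operation is idempotent. Video
contrast can compute its percentiles jointly over all frames (default:
flicker-safe, preserves inter-frame brightness ordering) or per frame;
both are exposed because per-frame stretching is occasionally what a
flickering acquisition needs for preview purposes.

## Particle analysis

Thresholding marks pixels below (dark particles, the stained-EM default)
or above a cut-off, given directly or found by Otsu's method (exhaustive
search over a 256-bin histogram maximising between-class variance).
Components are 8-connected with 4-connected background — the standard
duality that avoids topological paradoxes — interior holes are filled
(negative-stain particles often image with bright cores), and the outer
boundary is traced with Moore-neighbour tracing, stopping when the
initial move repeats. Particles are ordered by their topmost-leftmost
boundary pixel so output tables are deterministic. A label image from an
external segmentation tool can be supplied instead; labels, not
connectivity, then decide particle identity.

Measurements, per particle:

* **area** — filled pixel count × pixel_size²; exact for the synthetic
  rasteriser by construction.
* **perimeter** — chain length of the traced boundary with the
  Vossepoel–Smeulders correction, 0.948·N_even + 1.340·N_diagonal. The
  naive chain (unit and √2 steps) overestimates smooth digital contours
  by ~5%, which would bias circularity to ~0.91 for a perfect disc; the
  corrected estimator reproduces analytic perimeters of discs and
  ellipses within 0.5%, at the cost of slightly overshooting on
  axis-aligned rectangles. Circularity is 4πA/P², reported without
  clamping; digital discs land at 1.00–1.01 and values may exceed 1 by a
  few percent for small particles (discretisation, not an error).
  Particles with fewer than five boundary points get circularity 1 and a
  degeneracy flag, as no perimeter estimate is stable at that size.
* **axes** — full major/minor axis lengths of the best-fit ellipse from
  second central moments of the filled pixels (with the 1/12 per-pixel
  variance term), i.e. `4·sqrt(eigenvalue)`.
* **diameter profile** — every unordered pair of boundary points is
  considered once; a pair whose angle at the filled-pixel centroid is at
  least 180° − tol (planar angles cannot exceed 180°, so the window is
  one-sided; tol defaults to 1°) contributes the point distance as one
  diameter measurement. The summary reports max, min, mean, *population*
  standard deviation and the count. Angles are compared on the cosine
  with a 1e-9 slack so exactly antipodal lattice pairs survive
  `tol = 0`. For very large particles the O(B²) enumeration can be
  capped by uniform boundary subsampling (default 720 points; pass `Inf`
  to disable — the tests do).

Two discretisation effects are worth knowing. The diameter mean of a
digital disc of radius r sits ~1% below 2r (boundary pixel centres lie
inside the analytic circle). And for ellipses the minimum diameter can
undercut the minor axis by ~2 px: edge-pixel centres of the flat
extremal rows pair at exactly 180° with length `sqrt((2b−2)² + (2k)²)`.
Both effects shrink as 1/size and both are reproduced exactly by the
brute-force pair-enumeration oracle in the tests.

## Synthetic fixtures

The generator emulates what matters for this pipeline: stained-particle
fields (dark discs/ellipses on a bright background, default 50 on 200),
additive Gaussian and Poisson noise, radial multiplicative vignetting,
and videos with per-frame drift and gain under fresh per-frame noise.
Rasterisation uses the pixel-centre rule, making truth areas exact
integers. Defaults (256² images, non-overlapping placement with a 4 px
margin, radius 8–20 px) describe a well-behaved negative-stain
acquisition. What it does **not** emulate: contrast-transfer-function
oscillations, beam damage, astigmatism, structured backgrounds (carbon
film texture), or touching/overlapping particles — so green tests
demonstrate correctness of the algorithms on their stated model, not
segmentation robustness on adversarial real-world images.

All randomness flows through a single seed; fixed seed means
byte-identical images, and the generator restores the caller's RNG
state.

## Documents, batch runs and I/O corners

Contact sheets are deliberately timestamp-free so identical inputs give
byte-identical HTML — reproducibility extends to reports. PDFs embed
images via the base R PDF device at 2×2 per A4 page; videos appear as
their average frame. In batch processing one unreadable file is logged
and skipped, never aborting the folder, and the run exits with a
partial-success code.

Format support is honest about its limits: integer TIFFs and JPEG go
through libtiff/libjpeg; IEEE-float 32-bit TIFF output uses a minimal
built-in writer (single strip, uncompressed, SampleFormat 3) because the
R `tiff` writer only stores [0,1]-scaled integers; MRC2014 modes
0/1/2/6 are read and mode 2 written; AVI output is uncompressed 8-bit
palettised DIB, bit-exact on round trip. MP4 needs an external `ffmpeg`
on the PATH and fails with a typed error otherwise. Proprietary
acquisition containers (e.g. Digital Micrograph) are out of scope for
the core and enter through `register_reader()` plugins. Saving to 8-bit
formats never rescales silently — out-of-range intensities are an error,
because implicit contrast decisions are how quantitative data get
corrupted.

## Problem sizes in the test suite

The suite runs its geometry checks on discs of radius up to 50 px
(boundary ≈ 330 points, ~55k pair enumerations), DFT oracles on images up
to 16×16, and the noise-law checks on 128² frames — sizes chosen so the
whole suite completes in well under a minute while keeping every
discretisation effect visible at its tested tolerance.
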