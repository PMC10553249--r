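# Contrast manipulation, bit-depth conversion, binning, cropping and
# Fourier-spectrum display. All operations return a new micrograph; the
# input object is never modified.

# round-half-to-even linear map of [lo, hi] -> [0, 255]
scale_to_8bit <- function(px, lo, hi) {
  out <- round((px - lo) * 255 / (hi - lo))
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Convert to 8-bit
#'
#' Linearly maps the full intensity range `[min, max]` onto `[0, 255]`,
#' rounding half-to-even. A constant image maps to all zeros with a warning.
#'
#' @param m a [micrograph()].
#' @return a new 8-bit `micrograph`.
#' @export
to_8bit <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  lo <- min(m$pixels); hi <- max(m$pixels)
  if (hi == lo) {
    warning("constant image: to_8bit maps it to all zeros")
    return(mg_with_pixels(m, matrix(0, nrow(m$pixels), ncol(m$pixels))))
  }
  mg_with_pixels(m, scale_to_8bit(m$pixels, lo, hi))
}

#' Contrast specification
#'
#' Either absolute black/white points (`vmin`/`vmax`) or a saturation
#' percentage `s`: the share of pixels allowed to clip, split evenly
#' between the two tails (`s/2` % below black, `s/2` % above white).
#' Percentiles use linear interpolation between order statistics
#' (`quantile(type = 7)`).
#'
#' @param saturation percentage in `[0, 100)`.
#' @param vmin,vmax absolute intensity bounds, `vmin < vmax`.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(saturation = NULL, vmin = NULL, vmax = NULL) {
  if (!is.null(saturation)) {
    if (!is.null(vmin) || !is.null(vmax))
      mg_stop("mg_invalid_spec", "give either saturation or vmin/vmax, not both")
    if (saturation < 0 || saturation >= 100)
      mg_stop("mg_invalid_spec", "saturation must be in [0, 100)")
    structure(list(mode = "saturation", s = saturation),
              class = "contrast_spec")
  } else {
    if (is.null(vmin) || is.null(vmax))
      mg_stop("mg_invalid_spec", "absolute mode needs both vmin and vmax")
    if (vmin >= vmax)
      mg_stop("mg_invalid_spec", "vmin must be < vmax")
    structure(list(mode = "absolute", vmin = vmin, vmax = vmax),
              class = "contrast_spec")
  }
}

# resolve a contrast_spec against a pixel population -> c(vmin, vmax)
resolve_contrast <- function(px, spec) {
  if (spec$mode == "absolute") return(c(spec$vmin, spec$vmax))
  p <- spec$s / 200  # s/2 per tail, as a fraction
  v <- stats::quantile(px, probs = c(p, 1 - p), names = FALSE, type = 7)
  if (v[1] >= v[2])
    mg_stop("mg_degenerate_histogram",
            sprintf(paste("degenerate histogram: %g-th percentile (%g) >=",
                          "%g-th percentile (%g); lower the saturation"),
                    100 * p, v[1], 100 * (1 - p), v[2]))
  v
}

#' Percentile ("saturation") contrast stretch
#'
#' Clips intensities into `[vmin, vmax]` — given directly or derived from
#' the saturation percentage — then rescales linearly to 8-bit. With
#' `saturation = 0` the result equals [to_8bit()] exactly.
#'
#' @param m a [micrograph()].
#' @param spec a [contrast_spec()].
#' @return a new 8-bit `micrograph`.
#' @export
clip_contrast <- function(m, spec) {
  stopifnot(inherits(m, "micrograph"), inherits(spec, "contrast_spec"))
  v <- resolve_contrast(m$pixels, spec)
  px <- pmin(pmax(m$pixels, v[1]), v[2])
  mg_with_pixels(m, scale_to_8bit(px, v[1], v[2]))
}

#' Patch-grid specification for local normalisation
#'
#' @param n patches per side (the image is split into an n x n grid of
#'   nearly equal slices, sizes differing by at most one pixel).
#' @param pad overlap half-width in pixels: each patch is extended by `pad`
#'   on every side (truncated at the borders) and overlapping contributions
#'   are averaged.
#' @return an object of class `patch_grid`.
#' @export
patch_grid <- function(n, pad = 0) {
  if (n < 1 || n != floor(n)) mg_stop("mg_invalid_spec", "n must be >= 1")
  if (pad < 0) mg_stop("mg_invalid_spec", "pad must be >= 0")
  structure(list(n = n, pad = pad), class = "patch_grid")
}

# n nearly equal half-open slices of 1..len (returned as inclusive bounds)
slice_bounds <- function(len, n) {
  cuts <- floor(len * (0:n) / n)
  cbind(lo = cuts[-(n + 1)] + 1, hi = cuts[-1])
}

#' Patch-median illumination normalisation
#'
#' Evens out slowly varying illumination (the bright-centre / dark-corner
#' vignette of many TEM images): the image is split into an n x n grid and
#' every pixel in a patch is multiplied by `global_median / patch_median`,
#' so that (with `pad = 0`) each patch's median equals the global median of
#' the input exactly. With `pad > 0` patches overlap and shared pixels take
#' the mean of the competing patch values, reducing seam artefacts. Output
#' keeps the input intensity scale; convert for display afterwards.
#'
#' @param m a [micrograph()]; all patch medians must be positive.
#' @param grid a [patch_grid()].
#' @return a new `micrograph`, same shape and scale.
#' @export
local_normalisation <- function(m, grid) {
  stopifnot(inherits(m, "micrograph"), inherits(grid, "patch_grid"))
  px <- m$pixels
  H <- nrow(px); W <- ncol(px)
  if (grid$n > min(H, W))
    mg_stop("mg_invalid_spec", "more patches than pixels per side")
  gmed <- stats::median(px)
  rows <- slice_bounds(H, grid$n)
  cols <- slice_bounds(W, grid$n)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(grid$n)) for (j in seq_len(grid$n)) {
    r0 <- max(1, rows[i, "lo"] - grid$pad); r1 <- min(H, rows[i, "hi"] + grid$pad)
    c0 <- max(1, cols[j, "lo"] - grid$pad); c1 <- min(W, cols[j, "hi"] + grid$pad)
    patch <- px[r0:r1, c0:c1, drop = FALSE]
    pmed <- stats::median(patch)
    if (pmed <= 0)
      mg_stop("mg_zero_median",
              "a patch median is <= 0; offset intensities to be positive first")
    acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + patch * (gmed / pmed)
    cnt[r0:r1, c0:c1] <- cnt[r0:r1, c0:c1] + 1
  }
  mg_with_pixels(m, acc / cnt)
}

#' Bin (downscale by block averaging)
#'
#' Mean-pools `factor` x `factor` blocks; edge blocks may be partial. The
#' pixel size is multiplied by the factor so physical scale is preserved.
#'
#' @param m a [micrograph()].
#' @param factor integer >= 2.
#' @return a new `micrograph` of size `ceiling(dim / factor)`.
#' @export
bin_image <- function(m, factor) {
  stopifnot(inherits(m, "micrograph"))
  if (!is.numeric(factor) || factor < 2 || factor != floor(factor))
    mg_stop("mg_invalid_spec", "bin factor must be an integer >= 2")
  px <- m$pixels
  gi <- (seq_len(nrow(px)) - 1) %/% factor
  gj <- (seq_len(ncol(px)) - 1) %/% factor
  sums <- rowsum(t(rowsum(px, gi)), gj)            # block sums, transposed
  n <- tcrossprod(tabulate(gj + 1), tabulate(gi + 1))  # block pixel counts
  out <- t(sums / n)
  dimnames(out) <- NULL
  ps <- if (is.na(m$pixel_size)) NA_real_ else m$pixel_size * factor
  micrograph(out, pixel_size = ps, unit = m$unit, metadata = m$metadata,
             source_path = m$source_path)
}

#' Crop
#'
#' @param m a [micrograph()].
#' @param row0,col0,row1,col1 half-open 0-based box: rows `row0 .. row1-1`,
#'   columns `col0 .. col1-1`.
#' @return the exact sub-image; pixel size unchanged.
#' @export
crop <- function(m, row0, col0, row1, col1) {
  stopifnot(inherits(m, "micrograph"))
  H <- nrow(m$pixels); W <- ncol(m$pixels)
  if (row0 < 0 || col0 < 0 || row1 > H || col1 > W)
    mg_stop("mg_index_error", "crop box out of bounds")
  if (row1 <= row0 || col1 <= col0)
    mg_stop("mg_index_error", "crop box is empty")
  mg_with_pixels(m, m$pixels[(row0 + 1):row1, (col0 + 1):col1, drop = FALSE])
}

# swap quadrants so the DC component sits at (floor(H/2)+1, floor(W/2)+1)
fftshift2 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  x[c((floor(H / 2) + 1):H, 1:floor(H / 2)),
    c((floor(W / 2) + 1):W, 1:floor(W / 2))]
}

#' Centred log-magnitude Fourier spectrum for display
#'
#' Computes `log(1 + |F|)` of the centred 2-D DFT and rescales it to 8-bit.
#'
#' @param m a [micrograph()].
#' @return an 8-bit `micrograph` of the same shape (unit px: frequency
#'   space has no physical pixel size).
#' @export
fft_magnitude <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  mag <- log1p(Mod(fftshift2(stats::fft(m$pixels))))
  lo <- min(mag); hi <- max(mag)
  px <- if (hi == lo) matrix(0, nrow(mag), ncol(mag))
        else scale_to_8bit(mag, lo, hi)
  micrograph(px, metadata = m$metadata, source_path = m$source_path)
}
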