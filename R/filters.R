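# Spatial and frequency-domain denoising. All filters preserve shape and
# pixel size; video input is filtered frame by frame.

#' Filter specification
#'
#' @param kind one of `"median"`, `"gaussian"`, `"wiener"`, `"lowpass"`,
#'   `"nlm"` (non-local means).
#' @param k odd kernel width >= 3 (median / gaussian / wiener).
#' @param sigma Gaussian standard deviation in pixels; when unset it is
#'   derived from `k` as `0.3 * ((k - 1)/2 - 1) + 0.8`.
#' @param radius_fraction low-pass cut-off as a fraction in `(0, 1]` of the
#'   maximal representable spatial frequency (the spectrum corner); 1 keeps
#'   every frequency.
#' @param h non-local-means filtering strength (> 0); no default.
#' @param patch,search non-local-means patch width and search-window width
#'   (odd; defaults 7 and 21).
#' @param soft_edge if `TRUE` the low-pass mask gets a raised-cosine edge
#'   instead of the default hard binary edge.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("median", "gaussian", "wiener", "lowpass", "nlm"),
                        k = NULL, sigma = NULL, radius_fraction = NULL,
                        h = NULL, patch = 7, search = 21, soft_edge = FALSE) {
  kind <- match.arg(kind)
  if (kind %in% c("median", "gaussian", "wiener")) {
    if (is.null(k)) k <- 3
    if (k < 3 || k %% 2 == 0)
      mg_stop("mg_invalid_spec", "kernel width k must be odd and >= 3")
  }
  if (kind == "gaussian" && is.null(sigma))
    sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  if (kind == "lowpass") {
    if (is.null(radius_fraction))
      mg_stop("mg_invalid_spec", "lowpass needs radius_fraction")
    if (radius_fraction <= 0 || radius_fraction > 1)
      mg_stop("mg_invalid_spec", "radius_fraction must be in (0, 1]")
  }
  if (kind == "nlm") {
    if (is.null(h) || h <= 0)
      mg_stop("mg_invalid_spec", "nlm needs strength h > 0")
    if (patch %% 2 == 0 || search %% 2 == 0)
      mg_stop("mg_invalid_spec", "patch and search widths must be odd")
  }
  structure(list(kind = kind, k = k, sigma = sigma,
                 radius_fraction = radius_fraction, h = h, patch = patch,
                 search = search, soft_edge = soft_edge),
            class = "filter_spec")
}

# Symmetric (half-sample reflective) padding: a b c | c b a.
pad_reflect <- function(px, p) {
  H <- nrow(px); W <- ncol(px)
  ridx <- c(rev(seq_len(min(p, H))), seq_len(H),
            H + 1 - seq_len(min(p, H)))
  if (p > H) ridx <- pmin(pmax(ridx, 1), H)  # degenerate tiny images
  cidx <- c(rev(seq_len(min(p, W))), seq_len(W),
            W + 1 - seq_len(min(p, W)))
  if (p > W) cidx <- pmin(pmax(cidx, 1), W)
  px[ridx, cidx, drop = FALSE]
}

# Stack all k*k shifted views of the padded image: rows = pixels, cols = taps.
window_matrix <- function(px, k) {
  p <- (k - 1) / 2
  pad <- pad_reflect(px, p)
  H <- nrow(px); W <- ncol(px)
  out <- matrix(0, H * W, k * k)
  t <- 0
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    t <- t + 1
    out[, t] <- pad[di + seq_len(H), dj + seq_len(W)]
  }
  out
}

filter_median <- function(px, k) {
  wm <- window_matrix(px, k)
  matrix(apply(wm, 1, stats::median), nrow(px), ncol(px))
}

gaussian_kernel1d <- function(k, sigma) {
  x <- seq_len(k) - (k + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable convolution with symmetric padding
filter_gaussian <- function(px, k, sigma) {
  g <- gaussian_kernel1d(k, sigma)
  p <- (k - 1) / 2
  pad <- pad_reflect(px, p)
  H <- nrow(px); W <- ncol(px)
  tmp <- matrix(0, H, ncol(pad))
  for (i in seq_len(k))  # collapse rows
    tmp <- tmp + g[i] * pad[(i - 1) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_len(k))
    out <- out + g[j] * tmp[, (j - 1) + seq_len(W), drop = FALSE]
  out
}

# box mean with symmetric padding (building block for wiener)
box_mean <- function(px, k) {
  wm <- window_matrix(px, k)
  matrix(rowMeans(wm), nrow(px), ncol(px))
}

# Adaptive local-statistics (Wiener) filter: local mean/variance over k x k
# neighbourhoods; noise power = mean local variance when not supplied.
filter_wiener <- function(px, k, noise = NULL) {
  mu <- box_mean(px, k)
  varl <- box_mean(px^2, k) - mu^2
  varl[varl < 0] <- 0
  if (is.null(noise)) noise <- mean(varl)
  out <- mu
  gt <- varl > noise
  out[gt] <- mu[gt] + (varl[gt] - noise) / varl[gt] * (px[gt] - mu[gt])
  out
}

# binary (or raised-cosine) circular low-pass mask on the centred spectrum
lowpass_mask <- function(H, W, r, soft_edge = FALSE) {
  fy <- 0:(H - 1); fy[fy > H / 2] <- fy[fy > H / 2] - H
  fx <- 0:(W - 1); fx[fx > W / 2] <- fx[fx > W / 2] - W
  d <- sqrt(outer(fy^2, fx^2, "+"))
  dmax <- max(d)
  cut <- r * dmax
  if (!soft_edge) return((d <= cut + 1e-9) * 1)
  w <- 0.05 * dmax  # transition half-width of the cosine edge
  m <- matrix(0, H, W)
  m[d <= cut - w] <- 1
  tr <- d > cut - w & d < cut + w
  m[tr] <- 0.5 * (1 + cos(pi * (d[tr] - (cut - w)) / (2 * w)))
  m
}

filter_lowpass <- function(px, r, soft_edge = FALSE) {
  mask <- lowpass_mask(nrow(px), ncol(px), r, soft_edge)
  Re(stats::fft(stats::fft(px) * mask, inverse = TRUE)) / length(px)
}

# cumulative-sum box filter over a symmetric-padded image (sum, not mean)
box_sum_padded <- function(px, k) {
  p <- (k - 1) / 2
  pad <- pad_reflect(px, p)
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  z <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  z[-1, -1] <- cs
  H <- nrow(px); W <- ncol(px)
  i1 <- seq_len(H); j1 <- seq_len(W)
  z[i1 + k, j1 + k, drop = FALSE] - z[i1, j1 + k, drop = FALSE] -
    z[i1 + k, j1, drop = FALSE] + z[i1, j1, drop = FALSE]
}

# Vectorised non-local means: for every search-window offset, patch
# distances for all pixels at once via a box filter of the squared
# difference image; weights exp(-d2 / (h^2 * patch^2)).
filter_nlm <- function(px, h, patch, search) {
  H <- nrow(px); W <- ncol(px)
  s <- (search - 1) / 2
  pad <- pad_reflect(px, s)
  wsum <- matrix(0, H, W)
  vsum <- matrix(0, H, W)
  for (dy in -s:s) for (dx in -s:s) {
    shifted <- pad[dy + s + seq_len(H), dx + s + seq_len(W), drop = FALSE]
    d2 <- box_sum_padded((px - shifted)^2, patch)
    w <- exp(-d2 / (h^2 * patch^2))
    wsum <- wsum + w
    vsum <- vsum + w * shifted
  }
  vsum / wsum
}

apply_filter_matrix <- function(px, spec) {
  switch(spec$kind,
    median   = filter_median(px, spec$k),
    gaussian = filter_gaussian(px, spec$k, spec$sigma),
    wiener   = filter_wiener(px, spec$k),
    lowpass  = filter_lowpass(px, spec$radius_fraction, spec$soft_edge),
    nlm      = filter_nlm(px, spec$h, spec$patch, spec$search))
}

#' Apply a denoising filter
#'
#' Median, Gaussian and Wiener filters use symmetric (reflective) border
#' handling; the low-pass filter multiplies the spectrum by a circular
#' mask and returns the real part of the inverse transform. A video is
#' filtered frame by frame.
#'
#' @param x a [micrograph()] or [micro_video()].
#' @param spec a [filter_spec()].
#' @return an object of the same class as `x`.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "micrograph"))
    return(mg_with_pixels(x, apply_filter_matrix(x$pixels, spec)))
  if (inherits(x, "microvideo"))
    return(mv_with_frames(x, lapply(x$frames, apply_filter_matrix, spec)))
  mg_stop("mg_invalid_image", "x must be a micrograph or microvideo")
}

#' Hook for an external deep-learning denoiser
#'
#' Plugin point for an externally installed denoising tool (e.g. a trained
#' neural-network denoiser invoked as a command). The image is written to a
#' temporary TIFF, the command template is expanded with `{in}`/`{out}`
#' placeholders, run, and the result read back. Nothing in this package
#' depends on the tool being present.
#'
#' @param m a [micrograph()].
#' @param command template string containing `{in}` and `{out}`.
#' @return the denoised `micrograph`.
#' @export
external_denoise <- function(m, command) {
  stopifnot(inherits(m, "micrograph"))
  fin <- tempfile(fileext = ".tif"); fout <- tempfile(fileext = ".tif")
  save_image(m, fin, format = "tif32")
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(fout))
    mg_stop("mg_external_tool", sprintf("external denoiser failed: %s", cmd))
  out <- load_image(fout)
  mg_with_pixels(m, out$pixels)
}
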