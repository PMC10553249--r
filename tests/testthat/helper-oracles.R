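# Independent oracles, implemented as directly (and slowly) as possible;
# they share no code with the package internals they check.

# direct O(N^2) 2-D DFT
dft2_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0 + 0i, H, W)
  for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
    s <- 0 + 0i
    for (i in 0:(H - 1)) for (j in 0:(W - 1))
      s <- s + x[i + 1, j + 1] * exp(-2i * pi * (u * i / H + v * j / W))
    out[u + 1, v + 1] <- s
  }
  out
}

idft2_oracle <- function(X) {
  H <- nrow(X); W <- ncol(X)
  out <- matrix(0 + 0i, H, W)
  for (i in 0:(H - 1)) for (j in 0:(W - 1)) {
    s <- 0 + 0i
    for (u in 0:(H - 1)) for (v in 0:(W - 1))
      s <- s + X[u + 1, v + 1] * exp(2i * pi * (u * i / H + v * j / W))
    out[i + 1, j + 1] <- s / (H * W)
  }
  out
}

# brute-force median filter with symmetric (half-sample reflect) borders
median_oracle <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  p <- (k - 1) / 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    vals <- numeric(0)
    for (di in -p:p) for (dj in -p:p)
      vals <- c(vals, x[reflect(i + di, H), reflect(j + dj, W)])
    out[i, j] <- median(vals)
  }
  out
}

# brute-force near-antipodal diameter statistics: double loop over pairs
diameter_oracle <- function(boundary, centroid_rc, tol_deg) {
  n <- nrow(boundary)
  d <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- boundary[i, ] - centroid_rc
    b <- boundary[j, ] - centroid_rc
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) next
    cos_ab <- sum(a * b) / (na * nb)
    if (cos_ab <= cos((180 - tol_deg) * pi / 180) + 1e-9)
      d <- c(d, sqrt(sum((boundary[i, ] - boundary[j, ])^2)))
  }
  d
}

# brute-force "nice length" ladder: largest {1,2,5}*10^k fitting f*width
nice_length_oracle <- function(pixel_size, width, f) {
  cand <- sort(as.vector(outer(c(1, 2, 5), 10^(-12:12))))
  fit <- cand[round(cand / pixel_size) >= 1 &
              round(cand / pixel_size) <= f * width]
  max(fit)
}

# exhaustive Otsu over 256 levels of an 8-bit image: maximise
# between-class variance by trying every threshold
otsu_oracle_8bit <- function(px) {
  best_t <- NA; best_v <- -1
  for (t in 1:255) {
    lo <- px[px < t]; hi <- px[px >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# rasterised disc pixel count (pixel-centre rule), independent loop
disc_pixels_oracle <- function(cx, cy, r, H, W) {
  n <- 0
  for (y in 0:(H - 1)) for (x in 0:(W - 1))
    if ((x - cx)^2 + (y - cy)^2 <= r^2) n <- n + 1
  n
}

md5_of <- function(x) digest_vec(serialize(x, NULL))
digest_vec <- function(raw) paste(as.character(tools::md5sum(
  { f <- tempfile(); writeBin(raw, f); f })), collapse = "")

make_disc_image <- function(r = 50, pad = 10, fg = 50, bg = 200) {
  sz <- 2 * (r + pad) + 1
  make_particle_field(field_spec(
    width = sz, height = sz,
    shapes = list(list(kind = "disc", cx = r + pad, cy = r + pad, r = r)),
    fg = fg, bg = bg))
}
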