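test_that("to_8bit maps the range linearly with half-to-even rounding", {
  m <- micrograph(matrix(c(0, 50, 100, 0), 2, 2))
  out <- to_8bit(m)
  expect_setequal(unique(as.vector(out$pixels)), c(0, 128, 255))
  # already 8-bit input is unchanged
  m8 <- micrograph(matrix(c(0, 100, 200, 255), 2, 2))
  expect_identical(to_8bit(m8)$pixels, m8$pixels)
  # endpoints pinned for any input
  set.seed(1)
  mr <- micrograph(matrix(rnorm(400) * 37 + 5, 20, 20))
  o <- to_8bit(mr)
  expect_equal(min(o$pixels), 0)
  expect_equal(max(o$pixels), 255)
  expect_true(all(o$pixels == floor(o$pixels)))
  expect_warning(to_8bit(micrograph(matrix(7, 3, 3))), "constant")
})

test_that("saturation clipping hits the order-statistic percentiles", {
  ramp <- make_gradient_image(1, 1000)  # values 0..999
  out <- clip_contrast(ramp, contrast_spec(saturation = 10))
  # oracle: type-7 percentiles of the ramp, then the same linear map
  x <- 0:999
  v <- quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
  expected <- round((pmin(pmax(x, v[1]), v[2]) - v[1]) * 255 / (v[2] - v[1]))
  expect_equal(as.vector(out$pixels), expected)
  # ~5% of pixels land in each clipped tail (exact counts via the oracle)
  expect_equal(sum(out$pixels == 0), sum(expected == 0))
  expect_equal(sum(out$pixels == 255), sum(expected == 255))
  expect_equal(sum(expected == 0) / 1000, 0.05, tolerance = 0.05)
  expect_equal(sum(expected == 255) / 1000, 0.05, tolerance = 0.05)
  # strictly clipped pixels obey the s/100 + 1/N bound
  expect_lte(sum(ramp$pixels < v[1]) / 1000, 0.05 + 1 / 1000)
})

test_that("clip_contrast limit and consistency cases match to_8bit", {
  set.seed(2)
  m <- micrograph(matrix(runif(900) * 123, 30, 30))
  expect_identical(clip_contrast(m, contrast_spec(saturation = 0))$pixels,
                   to_8bit(m)$pixels)
  expect_identical(
    clip_contrast(m, contrast_spec(vmin = min(m$pixels),
                                   vmax = max(m$pixels)))$pixels,
    to_8bit(m)$pixels)
  # clipped fraction bounded by s/100 + 1/N for arbitrary inputs
  for (s in c(1, 5, 20)) {
    v <- micrographr:::resolve_contrast(m$pixels, contrast_spec(saturation = s))
    clipped <- mean(m$pixels < v[1] | m$pixels > v[2])
    expect_lte(clipped, s / 100 + 1 / length(m$pixels))
  }
  expect_error(
    clip_contrast(micrograph(matrix(5, 10, 10)),
                  contrast_spec(saturation = 10)),
    class = "mg_degenerate_histogram")
})

test_that("local normalisation equalises patch medians to the global median", {
  # constant image: global = local median everywhere
  cm <- micrograph(matrix(42, 8, 8))
  expect_equal(local_normalisation(cm, patch_grid(2))$pixels, cm$pixels)

  # 4-quadrant fixture: all output quadrants constant and equal to the
  # global median of the input (here mean of 20 and 40 = 30)
  q <- rbind(cbind(matrix(10, 4, 4), matrix(20, 4, 4)),
             cbind(matrix(40, 4, 4), matrix(80, 4, 4)))
  out <- local_normalisation(micrograph(q), patch_grid(2))
  expect_equal(unique(as.vector(out$pixels)), 30)

  # property: pad = 0 makes every patch median exactly the global median
  set.seed(8)
  for (n in c(2, 3, 5)) {
    m <- micrograph(matrix(runif(90 * 110, 10, 200), 90, 110))
    o <- local_normalisation(m, patch_grid(n))
    g <- median(m$pixels)
    rb <- micrographr:::slice_bounds(90, n)
    cb <- micrographr:::slice_bounds(110, n)
    for (i in 1:n) for (j in 1:n)
      expect_equal(median(o$pixels[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]]), g)
  }

  expect_error(
    local_normalisation(micrograph(matrix(0, 10, 10) + rep(c(0, 5), each = 50)),
                        patch_grid(2)),
    class = "mg_zero_median")
})

test_that("local normalisation flattens a vignetted field", {
  f <- make_particle_field(field_spec(width = 120, height = 120,
                                      n_random = 4, seed = 5,
                                      vignette = 0.5))
  spread <- function(px, n) {
    rb <- micrographr:::slice_bounds(nrow(px), n)
    cb <- micrographr:::slice_bounds(ncol(px), n)
    meds <- sapply(1:n, function(i) sapply(1:n, function(j)
      median(px[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]])))
    max(meds) / min(meds)
  }
  before <- spread(f$image$pixels, 4)
  after <- spread(local_normalisation(f$image, patch_grid(4))$pixels, 4)
  expect_gt(before, 1.1)
  expect_lt(after, before)
  expect_lt(abs(after - 1), abs(before - 1))

  # padded patches still cover the image exactly once on average
  o <- local_normalisation(f$image, patch_grid(4, pad = 6))
  expect_identical(dim(o$pixels), dim(f$image$pixels))
})

test_that("binning pools blocks, conserves the mean and scales pixel size", {
  m <- micrograph(matrix(3, 4, 4), pixel_size = 1, unit = "nm")
  out <- bin_image(m, 2)
  expect_identical(out$pixels, matrix(3, 2, 2))
  expect_equal(bin_image(m, 4)$pixel_size, 4)
  set.seed(4)
  m2 <- micrograph(matrix(runif(64 * 64), 64, 64))
  expect_equal(mean(bin_image(m2, 4)$pixels), mean(m2$pixels))
  # ragged edges: ceil-sized output, partial blocks averaged as-is
  m3 <- micrograph(matrix(runif(7 * 9), 7, 9))
  o3 <- bin_image(m3, 2)
  expect_identical(dim(o3$pixels), c(4L, 5L))
  expect_equal(o3$pixels[4, 5], m3$pixels[7, 9])
  expect_error(bin_image(m2, 1), class = "mg_invalid_spec")
})

test_that("crop composes and respects bounds", {
  set.seed(6)
  m <- micrograph(matrix(runif(100), 10, 10), pixel_size = 2, unit = "nm")
  expect_identical(crop(m, 0, 0, 10, 10)$pixels, m$pixels)
  expect_equal(crop(m, 0, 0, 1, 1)$pixels, m$pixels[1, 1, drop = FALSE])
  expect_equal(crop(m, 0, 0, 1, 1)$pixel_size, 2)
  expect_identical(crop(crop(m, 1, 2, 9, 9), 1, 1, 4, 4)$pixels,
                   crop(m, 2, 3, 5, 6)$pixels)
  expect_error(crop(m, 0, 0, 11, 10), class = "mg_index_error")
  expect_error(crop(m, 3, 3, 3, 5), class = "mg_index_error")
})

test_that("fft display matches a direct DFT oracle and its contracts", {
  # constant image: all energy in the DC bin at the centre
  cm <- micrograph(matrix(5, 8, 8))
  out <- fft_magnitude(cm)
  expect_equal(out$pixels[5, 5], 255)
  expect_true(all(out$pixels[-(4 * 8 + 5)] == 0))

  # horizontal sinusoid of period p: peak pair at +/- width/p off centre
  W <- 32; p <- 8
  sin_img <- micrograph(t(matrix(sin(2 * pi * (0:(W - 1)) / p), W, W)))
  sp <- fft_magnitude(sin_img)$pixels
  centre <- c(W / 2 + 1, W / 2 + 1)
  peaks <- which(sp == 255, arr.ind = TRUE)
  expect_equal(nrow(peaks), 2)
  expect_setequal(peaks[, 2] - centre[2], c(-W / p, W / p))
  expect_true(all(peaks[, 1] == centre[1]))

  # magnitudes agree with the O(N^2) DFT oracle before display scaling
  set.seed(9)
  x <- matrix(runif(12 * 12), 12, 12)
  expect_lt(max(Mod(stats::fft(x) - dft2_oracle(x))) / max(Mod(dft2_oracle(x))),
            1e-6)
  out2 <- fft_magnitude(micrograph(x))
  oracle_mag <- log1p(Mod(micrographr:::fftshift2(dft2_oracle(x))))
  rescaled <- round((oracle_mag - min(oracle_mag)) * 255 /
                    (max(oracle_mag) - min(oracle_mag)))
  expect_equal(out2$pixels, rescaled)
  expect_equal(min(out2$pixels), 0)
  expect_equal(max(out2$pixels), 255)
})

test_that("enhance operations never modify their input", {
  set.seed(10)
  m <- micrograph(matrix(runif(400, 1, 100), 20, 20), pixel_size = 1,
                  unit = "nm")
  before <- serialize(m$pixels, NULL)
  invisible(to_8bit(m))
  invisible(clip_contrast(m, contrast_spec(saturation = 5)))
  invisible(local_normalisation(m, patch_grid(2)))
  invisible(bin_image(m, 2))
  invisible(crop(m, 1, 1, 10, 10))
  invisible(fft_magnitude(m))
  expect_identical(serialize(m$pixels, NULL), before)
})
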