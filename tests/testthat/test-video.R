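test_that("averaging produces the expected frame counts and means", {
  set.seed(41)
  frames <- lapply(1:10, function(i) matrix(rnorm(40 * 40, mean = i), 40, 40))
  v <- micro_video(frames, pixel_size = 1.2, unit = "nm")
  expect_equal(n_frames(average(v, average_spec("chunk", 5))), 2)
  expect_equal(n_frames(average(v, average_spec("sliding", 3))), 8)
  allm <- average(v, average_spec("all"))
  expect_s3_class(allm, "micrograph")
  expect_equal(allm$pixel_size, 1.2)
  # all == chunk with n = F, bit for bit
  expect_identical(allm$pixels, average(v, average_spec("chunk", 10))$frames[[1]])
  # global mean conserved when n divides F
  ch <- average(v, average_spec("chunk", 5))
  expect_equal(mean(unlist(ch$frames)), mean(unlist(frames)))
  # sliding frame i is the mean of its window
  sl <- average(v, average_spec("sliding", 3))
  expect_equal(sl$frames[[4]], (frames[[4]] + frames[[5]] + frames[[6]]) / 3)
  expect_error(average(v, average_spec("sliding", 11)),
               class = "mg_invalid_spec")
})

test_that("chunk averaging of i.i.d. noise follows the 1/n variance law", {
  set.seed(42)
  F <- 8; n <- 4; N <- 128 * 128
  v <- micro_video(lapply(1:F, function(i) matrix(rnorm(N), 128, 128)))
  out <- average(v, average_spec("chunk", n))
  vs <- sapply(out$frames, function(f) var(as.vector(f)))
  # var of a sample variance over N pixels ~ 2 sigma^4 / (N-1)
  se <- sqrt(2 / (N - 1)) / n
  for (s in vs) expect_lt(abs(s - 1 / n), 3 * se)
})

test_that("gain normalisation equalises frame statistics and is idempotent", {
  g <- make_video(field_spec(width = 60, height = 60,
                             shapes = list(list(kind = "disc", cx = 30,
                                                cy = 30, r = 10))),
                  3, gain = c(1, 2, 4))
  nv <- normalise_video(g$video)
  meds <- sapply(nv$frames, median)
  expect_equal(max(meds) - min(meds), 0)
  again <- normalise_video(nv)
  expect_equal(again$frames, nv$frames, tolerance = 1e-12)
  # mean statistic: planted means {1,2,4} equalise
  vm <- micro_video(lapply(c(1, 2, 4), function(g) matrix(g, 10, 10)))
  nm <- normalise_video(vm, stat = "mean")
  expect_equal(sapply(nm$frames, mean), rep(7 / 3, 3))
  # uniform video unchanged
  u <- micro_video(lapply(1:3, function(i) matrix(5, 6, 6)))
  expect_equal(normalise_video(u)$frames, u$frames)
  # sinusoidal flicker: coefficient of variation ~ 0 afterwards
  set.seed(43)
  base <- matrix(runif(900, 50, 100), 30, 30)
  fl <- micro_video(lapply(1:8, function(i) base * (1 + 0.3 * sin(i))))
  nf <- normalise_video(fl)
  fmeans <- sapply(nf$frames, mean)
  expect_lt(sd(fmeans) / mean(fmeans), 1e-6)
  z <- micro_video(list(matrix(0, 4, 4)))
  expect_error(normalise_video(z), class = "mg_zero_statistic")
})

test_that("video contrast: joint percentiles preserve frame ordering", {
  set.seed(44)
  base <- matrix(runif(400, 10, 100), 20, 20)
  single <- micro_video(list(base))
  spec <- contrast_spec(saturation = 4)
  for (scope in c("global", "per_frame"))
    expect_identical(frame(video_contrast(single, spec, scope), 0)$pixels,
                     clip_contrast(micrograph(base), spec)$pixels)
  # constant gain: both scopes coincide
  cg <- micro_video(lapply(1:3, function(i) base))
  expect_identical(video_contrast(cg, spec, "global")$frames,
                   video_contrast(cg, spec, "per_frame")$frames)
  # flicker: global keeps the brightness ordering, per-frame erases it
  fl <- micro_video(lapply(c(0.5, 1, 2), function(g) base * g))
  gm <- sapply(video_contrast(fl, spec, "global")$frames, mean)
  pm <- sapply(video_contrast(fl, spec, "per_frame")$frames, mean)
  expect_true(all(diff(gm) > 0))
  expect_false(all(diff(pm) > 0))
})

test_that("frame extraction is bit-exact and bounds-checked", {
  set.seed(45)
  frames <- lapply(1:4, function(i) matrix(runif(36), 6, 6))
  v <- micro_video(frames, pixel_size = 3, unit = "um",
                   metadata = list(voltage_kV = 200))
  for (i in 0:3) expect_identical(frame(v, i)$pixels, frames[[i + 1]])
  f0 <- frame(v, 0)
  expect_equal(f0$pixel_size, 3)
  expect_equal(f0$metadata$voltage_kV, 200)
  v1 <- micro_video(frames[1])
  expect_identical(frame(v1, 0)$pixels, frames[[1]])
  expect_error(frame(v, -1), class = "mg_index_error")
  expect_error(frame(v, 4), class = "mg_index_error")
})
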