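test_that("fixed-value and Otsu thresholding separate a bimodal field", {
  f <- make_particle_field(field_spec(width = 100, height = 100,
                                      n_random = 3, seed = 51,
                                      fg = 50, bg = 200))
  truth_mask <- f$image$pixels < 125
  bm <- threshold(f$image, value = 125, polarity = "dark")
  expect_identical(bm$mask, truth_mask)
  expect_equal(bm$threshold_used, 125)

  ot <- threshold(f$image, method = "otsu", polarity = "dark")
  expect_identical(ot$mask, truth_mask)
  # cross-check against the exhaustive 8-bit oracle and EBImage
  t_oracle <- otsu_oracle_8bit(f$image$pixels)
  expect_identical(f$image$pixels < t_oracle, truth_mask)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    t_eb <- EBImage::otsu(EBImage::Image(t(f$image$pixels) / 255),
                          range = c(0, 1), levels = 256) * 255
    expect_identical(f$image$pixels < t_eb, truth_mask)
  }

  empty <- threshold(micrograph(matrix(c(200, 201), 10, 10)), value = 100)
  expect_false(any(empty$mask))
  bright <- threshold(f$image, value = 125, polarity = "bright")
  expect_identical(bright$mask, f$image$pixels > 125)
  expect_error(threshold(f$image), class = "mg_invalid_spec")
})

test_that("particle location applies area and edge filters", {
  # three discs with known rasterised areas ~80 / ~700 / ~7000 px^2
  f <- make_particle_field(field_spec(width = 300, height = 300,
    shapes = list(list(kind = "disc", cx = 40, cy = 40, r = 5),
                  list(kind = "disc", cx = 150, cy = 60, r = 15),
                  list(kind = "disc", cx = 150, cy = 200, r = 47))))
  bm <- threshold(f$image, value = 125)
  expect_equal(length(find_particles(bm)), 3)
  kept <- find_particles(bm, min_area = 100, max_area = 5000)
  expect_equal(length(kept), 1)
  expect_equal(length(kept$particles[[1]]$filled_idx), f$truth$area_px[2])

  # a disc crossing the border is removed by the edge filter
  fe <- make_particle_field(field_spec(width = 100, height = 100,
    shapes = list(list(kind = "disc", cx = 50, cy = 50, r = 10),
                  list(kind = "disc", cx = 2, cy = 50, r = 10))))
  bme <- threshold(fe$image, value = 125)
  expect_equal(length(find_particles(bme)), 2)
  inner <- find_particles(bme, exclude_edges = TRUE)
  expect_equal(length(inner), 1)
  expect_false(inner$particles[[1]]$touches_edge)
  expect_error(find_particles(bm, min_area = 10, max_area = 5),
               class = "mg_invalid_spec")
})

test_that("interior holes are filled before measuring", {
  # annulus: disc r=20 with a r=8 hole; filled area = full disc area
  g <- micrographr:::coord_grids(60, 60)
  d2 <- (g$x - 30)^2 + (g$y - 30)^2
  annulus <- d2 <= 20^2 & d2 > 8^2
  set <- find_particles(annulus)
  expect_equal(length(set), 1)
  expect_equal(length(set$particles[[1]]$filled_idx),
               disc_pixels_oracle(30, 30, 20, 60, 60))
})

test_that("label images give one particle per label, matching the mask route", {
  lab <- matrix(0L, 20, 20)
  lab[5:10, 5:10] <- 1L
  set <- from_labels(lab)
  expect_equal(length(set), 1)
  expect_equal(measure(set$particles[[1]])$area, 36)
  # adjacent labels stay distinct even though they touch
  lab2 <- matrix(0L, 10, 10)
  lab2[2:5, 2:5] <- 1L
  lab2[6:9, 2:5] <- 2L
  expect_equal(length(from_labels(lab2)), 2)
  expect_error(from_labels(matrix(-1L, 3, 3)), class = "mg_invalid_spec")

  # route equivalence: labels vs threshold+find on the same disc field
  f <- make_particle_field(field_spec(width = 150, height = 150,
                                      n_random = 3, seed = 52))
  bm <- threshold(f$image, value = 125)
  via_mask <- find_particles(bm)
  lab3 <- micrographr:::label_components(bm$mask)
  via_labels <- from_labels(lab3)
  a1 <- sort(sapply(via_mask$particles, function(p) length(p$filled_idx)))
  a2 <- sort(sapply(via_labels$particles, function(p) length(p$filled_idx)))
  expect_identical(a1, a2)
})

test_that("disc and ellipse morphometry match analytic geometry", {
  f <- make_disc_image(r = 50)
  bm <- threshold(f$image, value = 125)
  rec <- measure_all(find_particles(bm), max_boundary_points = Inf)[[1]]
  expect_equal(rec$area, f$truth$area_px)            # exact, oracle count
  expect_equal(rec$area, pi * 50^2, tolerance = 0.02)
  expect_gte(rec$circularity, 0.92)
  expect_lte(rec$circularity, 1.05)
  expect_gte(rec$axis_ratio, 1.0)
  expect_lte(rec$axis_ratio, 1.05)
  expect_equal(rec$major_axis, 100, tolerance = 0.02)

  fe <- make_particle_field(field_spec(width = 200, height = 160,
    shapes = list(list(kind = "ellipse", cx = 100, cy = 80, a = 60, b = 30,
                       angle = 25))))
  bme <- threshold(fe$image, value = 125)
  rece <- measure_all(find_particles(bme), max_boundary_points = Inf)[[1]]
  expect_equal(rece$axis_ratio, 2, tolerance = 0.05)
  expect_equal(rece$circularity, 0.84, tolerance = 0.02)  # analytic 4*pi*A/P^2

  # 1-px particle: degenerate conventions
  one <- find_particles(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)), 5, 5))
  rec1 <- measure(one$particles[[1]], pixel_size = 2, unit = "nm")
  expect_equal(rec1$area, 4)  # 1 px * (2 nm)^2
  expect_equal(rec1$circularity, 1.0)
  expect_true(rec1$degenerate)
})

test_that("diameter statistics match the brute-force pair oracle", {
  f <- make_disc_image(r = 50)
  bm <- threshold(f$image, value = 125)
  set <- find_particles(bm)
  p <- set$particles[[1]]
  rec <- diameter_profile(p, max_boundary_points = Inf)
  H <- p$shape[1]
  ctr <- c(mean((p$filled_idx - 1) %% H), mean((p$filled_idx - 1) %/% H))
  d_oracle <- diameter_oracle(p$boundary, ctr, 1)
  expect_equal(rec$n_diameter_measurements, length(d_oracle))
  expect_equal(rec$diam_mean, mean(d_oracle))
  expect_equal(rec$diam_max, max(d_oracle))
  expect_equal(rec$diam_min, min(d_oracle))
  expect_equal(rec$diam_std, sqrt(mean((d_oracle - mean(d_oracle))^2)))
  expect_equal(rec$diam_mean, 100, tolerance = 0.02)
  expect_lt(rec$diam_std / rec$diam_mean, 0.02)

  # 2:1 ellipse: extremes near the analytic axes
  fe <- make_particle_field(field_spec(width = 200, height = 160,
    shapes = list(list(kind = "ellipse", cx = 100, cy = 80, a = 60, b = 30,
                       angle = 0))))
  pe <- find_particles(threshold(fe$image, value = 125))$particles[[1]]
  rece <- diameter_profile(pe, max_boundary_points = Inf)
  expect_equal(rece$diam_max, 120, tolerance = 0.03)
  # near-antipodal chords across the minor axis undercut 2b by ~2 px:
  # edge-pixel centres of the flat rows pair at exactly 180 degrees with
  # length sqrt((2b-2)^2 + (2k)^2), a relative bias of order 1/b
  expect_equal(rece$diam_min, 60, tolerance = 0.04)
  expect_equal(rece$diam_max / rece$diam_min, 2, tolerance = 0.04)
  # the bias shrinks with particle size: a 2x larger ellipse is within 2%
  f2 <- make_particle_field(field_spec(width = 300, height = 280,
    shapes = list(list(kind = "ellipse", cx = 150, cy = 140, a = 120,
                       b = 60, angle = 0))))
  p2 <- find_particles(threshold(f2$image, value = 125))$particles[[1]]
  r2 <- diameter_profile(p2, max_boundary_points = Inf)
  expect_equal(r2$diam_max / r2$diam_min, 2, tolerance = 0.02)
})

test_that("zero tolerance keeps only exactly antipodal pairs", {
  # a square has even symmetry: each boundary point has its point
  # reflection through the centroid on the boundary
  sq <- matrix(FALSE, 15, 15)
  sq[3:13, 3:13] <- TRUE
  p <- find_particles(sq)$particles[[1]]
  rec <- diameter_profile(p, tol_deg = 0, max_boundary_points = Inf)
  B <- nrow(p$boundary)
  expect_equal(rec$n_diameter_measurements, B / 2)
  # agreement with the brute-force oracle at zero tolerance
  H <- p$shape[1]
  ctr <- c(mean((p$filled_idx - 1) %% H), mean((p$filled_idx - 1) %/% H))
  d <- diameter_oracle(p$boundary, ctr, 0)
  expect_equal(rec$n_diameter_measurements, length(d))
  expect_equal(rec$diam_mean, mean(d))
})

test_that("diameter profile flags particles with no antipodal pair", {
  # a 2-pixel domino has only 2 boundary points
  mask <- matrix(FALSE, 5, 5)
  mask[2, 2:3] <- TRUE
  p <- find_particles(mask)$particles[[1]]
  rec <- diameter_profile(p)
  expect_true(is.na(rec$diam_mean))
  expect_match(rec$diameter_flag, "boundary")
})

test_that("measurements scale exactly with pixel size", {
  f <- make_disc_image(r = 20)
  bm <- threshold(f$image, value = 125)
  p <- find_particles(bm)$particles[[1]]
  r1 <- diameter_profile(p, measure(p, pixel_size = 1, unit = "nm"),
                         max_boundary_points = Inf)
  r2b <- diameter_profile(p, measure(p, pixel_size = 2, unit = "nm"),
                          max_boundary_points = Inf)
  expect_identical(r2b$area, 4 * r1$area)
  expect_identical(r2b$perimeter, 2 * r1$perimeter)
  expect_identical(r2b$major_axis, 2 * r1$major_axis)
  expect_identical(r2b$diam_mean, 2 * r1$diam_mean)
  expect_identical(r2b$circularity, r1$circularity)  # dimensionless
})

test_that("diameter means are stable under 90-degree rotations", {
  f <- make_disc_image(r = 30)
  px <- f$image$pixels
  means <- sapply(list(px, t(px[nrow(px):1, ]),
                       px[nrow(px):1, ncol(px):1],
                       t(px)[nrow(px):1, ]), function(im) {
    p <- find_particles(threshold(micrograph(im), value = 125))$particles[[1]]
    diameter_profile(p, max_boundary_points = Inf)$diam_mean
  })
  expect_lt((max(means) - min(means)) / mean(means), 0.02)
})

test_that("near-antipodal max equals the Feret maximum for convex shapes", {
  f <- make_disc_image(r = 25)
  p <- find_particles(threshold(f$image, value = 125))$particles[[1]]
  rec <- diameter_profile(p, max_boundary_points = Inf)
  b <- p$boundary
  feret <- max(dist(b))
  expect_lte(rec$diam_max, feret + 1e-9)
  expect_equal(rec$diam_max, feret, tolerance = 0.02)
})

test_that("morphometry tables are deterministic and round-trip via CSV", {
  f <- make_particle_field(field_spec(width = 200, height = 200,
                                      n_random = 3, seed = 53))
  bm <- threshold(f$image, value = 125)
  recs <- measure_all(find_particles(bm))
  d <- withr::local_tempdir()
  tab <- to_table(recs, file.path(d, "m.csv"))
  expect_equal(nrow(tab), 3)
  back <- read.csv(file.path(d, "m.csv"))
  for (col in c("area", "perimeter", "circularity", "diam_mean", "diam_std"))
    expect_equal(signif(back[[col]], 6), signif(tab[[col]], 6))
  # byte-identical on re-write
  to_table(recs, file.path(d, "m2.csv"))
  expect_identical(readBin(file.path(d, "m.csv"), "raw", 1e6),
                   readBin(file.path(d, "m2.csv"), "raw", 1e6))
  # empty set: header-only CSV
  empty <- to_table(list(), file.path(d, "e.csv"))
  expect_equal(nrow(empty), 0)
  expect_equal(length(readLines(file.path(d, "e.csv"))), 1)
})

test_that("the full pipeline recovers every planted particle exactly", {
  f <- make_particle_field(field_spec(width = 300, height = 300,
                                      n_random = 6, seed = 54,
                                      r_range = c(8, 18), margin = 6))
  bm <- threshold(f$image, method = "otsu")
  set <- find_particles(bm, min_area = 10, exclude_edges = TRUE)
  expect_equal(length(set), 6)
  areas <- sort(sapply(set$particles, function(p) length(p$filled_idx)))
  expect_identical(areas, sort(f$truth$area_px))
  # areas within 2% of the analytic pi r^2
  analytic <- sort(pi * f$truth$r^2)
  expect_true(all(abs(areas - analytic) / analytic < 0.02))
  if (requireNamespace("EBImage", quietly = TRUE)) {
    nlab <- max(EBImage::bwlabel(EBImage::Image(t(bm$mask) * 1)))
    expect_equal(length(set), nlab)
  }
})
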