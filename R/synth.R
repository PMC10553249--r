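# Deterministic synthetic fixtures with exact geometric ground truth.
#
# Rasterisation rule (pinned): a pixel belongs to a shape iff its CENTRE
# (integer coordinate, 0-based, x = column, y = row) lies inside or on the
# analytic boundary. Truth-table areas are therefore exact integer pixel
# counts by construction.

#' Specify a synthetic particle field
#'
#' Describes a noisy grayscale image of non-overlapping discs/ellipses on a
#' flat background, optionally vignetted (radial multiplicative falloff, the
#' bright-centre/dark-corner pattern typical of TEM), with additive Gaussian
#' and/or Poisson noise. Used by [make_particle_field()].
#'
#' @param width,height image size in pixels.
#' @param shapes list of shapes; each is `list(kind = "disc", cx, cy, r)` or
#'   `list(kind = "ellipse", cx, cy, a, b, angle)` with `angle` in degrees
#'   (`a`, `b` are SEMI-axes). Coordinates are 0-based pixel-centre
#'   coordinates (x = column, y = row).
#' @param n_random number of random non-overlapping discs to place when
#'   `shapes` is `NULL`.
#' @param r_range radius range for random discs.
#' @param margin minimum gap (px) kept between random shapes and between a
#'   shape and the image border.
#' @param fg,bg foreground (particle) and background intensity. Dark
#'   particles on a bright background, the stained-EM default, is `fg < bg`.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param poisson_scale if > 0, pixel values are replaced by
#'   `rpois(value * scale) / scale` (shot-noise model).
#' @param vignette strength in `[0, 1)`: the image is multiplied by
#'   `1 - vignette * (d / d_max)^2` with `d` the distance to the centre.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(width = 256, height = 256, shapes = NULL,
                       n_random = 0, r_range = c(8, 20), margin = 4,
                       fg = 50, bg = 200, noise_sd = 0, poisson_scale = 0,
                       vignette = 0, seed = 1) {
  if (vignette < 0 || vignette >= 1)
    mg_stop("mg_invalid_spec", "vignette must be in [0, 1)")
  structure(list(width = width, height = height, shapes = shapes,
                 n_random = n_random, r_range = r_range, margin = margin,
                 fg = fg, bg = bg, noise_sd = noise_sd,
                 poisson_scale = poisson_scale, vignette = vignette,
                 seed = seed),
            class = "field_spec")
}

# coordinate grids, 0-based; x = column, y = row
coord_grids <- function(height, width) {
  list(x = matrix(rep(0:(width - 1), each = height), height, width),
       y = matrix(rep(0:(height - 1), width), height, width))
}

rasterise_shape <- function(shape, height, width) {
  g <- coord_grids(height, width)
  if (shape$kind == "disc") {
    (g$x - shape$cx)^2 + (g$y - shape$cy)^2 <= shape$r^2
  } else if (shape$kind == "ellipse") {
    th <- shape$angle * pi / 180
    dx <- g$x - shape$cx; dy <- g$y - shape$cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / shape$a)^2 + (v / shape$b)^2 <= 1
  } else {
    mg_stop("mg_invalid_spec", paste("unknown shape kind:", shape$kind))
  }
}

# run fn with a private RNG stream; restores the caller's .Random.seed
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

place_random_discs <- function(spec) {
  shapes <- list()
  tries <- 0
  while (length(shapes) < spec$n_random) {
    tries <- tries + 1
    if (tries > 200 * spec$n_random)
      mg_stop("mg_placement_error",
              "could not place non-overlapping particles; reduce count or radii")
    r <- stats::runif(1, spec$r_range[1], spec$r_range[2])
    lo <- r + spec$margin
    cx <- stats::runif(1, lo, spec$width - 1 - lo)
    cy <- stats::runif(1, lo, spec$height - 1 - lo)
    ok <- TRUE
    for (s in shapes) {
      if (sqrt((s$cx - cx)^2 + (s$cy - cy)^2) < s$r + r + spec$margin) {
        ok <- FALSE; break
      }
    }
    if (ok) shapes[[length(shapes) + 1]] <-
        list(kind = "disc", cx = cx, cy = cy, r = r)
  }
  shapes
}

#' Render a synthetic particle field with ground truth
#'
#' @param spec a [field_spec()].
#' @param pixel_size,unit optional physical scale attached to the output.
#' @return list with elements `image` (a [micrograph()]) and `truth`, a
#'   data.frame with one row per particle: centre, shape parameters and the
#'   exact rasterised pixel area.
#' @export
make_particle_field <- function(spec, pixel_size = NA_real_, unit = "px") {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, function() {
    shapes <- spec$shapes
    if (is.null(shapes)) shapes <- place_random_discs(spec)
    H <- spec$height; W <- spec$width
    img <- matrix(spec$bg, H, W)
    truth <- data.frame(id = integer(), kind = character(), cx = double(),
                        cy = double(), r = double(), a = double(),
                        b = double(), angle = double(), area_px = integer())
    for (i in seq_along(shapes)) {
      s <- shapes[[i]]
      mask <- rasterise_shape(s, H, W)
      if (!any(mask))
        mg_stop("mg_placement_error", "a shape rasterised to zero pixels")
      img[mask] <- spec$fg
      truth[i, ] <- list(i, s$kind, s$cx, s$cy,
                         if (s$kind == "disc") s$r else NA_real_,
                         if (s$kind == "ellipse") s$a else NA_real_,
                         if (s$kind == "ellipse") s$b else NA_real_,
                         if (s$kind == "ellipse") s$angle else NA_real_,
                         sum(mask))
    }
    if (spec$vignette > 0) {
      g <- coord_grids(H, W)
      cx <- (W - 1) / 2; cy <- (H - 1) / 2
      d2 <- (g$x - cx)^2 + (g$y - cy)^2
      img <- img * (1 - spec$vignette * d2 / max(d2))
    }
    if (spec$poisson_scale > 0)
      img <- matrix(stats::rpois(length(img), img * spec$poisson_scale),
                    H, W) / spec$poisson_scale
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd), H, W)
    list(image = micrograph(img, pixel_size = pixel_size, unit = unit,
                            source_path = "<synthetic>"),
         truth = truth)
  })
}

#' Render a synthetic video (drifting, gain-modulated particle field)
#'
#' Frame `i` is the field of `base` with every shape translated by
#' `drift[i, ]`, multiplied by `gain[i]`, with fresh noise per frame.
#'
#' @param base a [field_spec()]; its `seed` seeds the whole video.
#' @param n_frames number of frames F.
#' @param drift F x 2 matrix of per-frame (dx, dy) pixel offsets (default 0).
#' @param gain length-F multiplicative per-frame gain (default 1).
#' @param fps playback rate recorded in the result.
#' @return list with `video` (a [micro_video()]), `drift` and `gain`.
#' @export
make_video <- function(base, n_frames, drift = NULL, gain = NULL, fps = 10) {
  stopifnot(inherits(base, "field_spec"))
  if (is.null(drift)) drift <- matrix(0, n_frames, 2)
  if (is.null(gain)) gain <- rep(1, n_frames)
  stopifnot(nrow(drift) == n_frames, length(gain) == n_frames)
  shapes <- base$shapes
  if (is.null(shapes))
    shapes <- with_seed(base$seed, function() place_random_discs(base))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    moved <- lapply(shapes, function(s) {
      s$cx <- s$cx + drift[i, 1]; s$cy <- s$cy + drift[i, 2]
      ext <- if (s$kind == "disc") s$r else max(s$a, s$b)
      if (s$cx - ext < 0 || s$cx + ext > base$width - 1 ||
          s$cy - ext < 0 || s$cy + ext > base$height - 1)
        mg_stop("mg_placement_error", "drift pushes a shape out of bounds")
      s
    })
    fspec <- base
    fspec$shapes <- moved
    fspec$seed <- base$seed + i  # fresh noise each frame, still deterministic
    frames[[i]] <- make_particle_field(fspec)$image$pixels * gain[i]
  }
  list(video = micro_video(frames, fps = fps, source_path = "<synthetic>"),
       drift = drift, gain = gain)
}

#' Exact linear intensity ramp
#'
#' A gradient image whose order statistics are known in closed form; the
#' standard fixture for percentile-clipping tests.
#'
#' @param height,width image size.
#' @param axis `"x"` (ramp along columns) or `"y"` (along rows).
#' @return a [micrograph()] with values `0 .. len-1` along the ramp axis.
#' @export
make_gradient_image <- function(height, width, axis = c("x", "y")) {
  axis <- match.arg(axis)
  g <- coord_grids(height, width)
  micrograph(if (axis == "x") g$x else g$y, source_path = "<synthetic>")
}
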