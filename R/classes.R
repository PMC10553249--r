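# Typed condition helper: every user-facing error carries a subclass so
# callers can condition on the failure mode rather than on message text.
mg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "micrographr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

mg_units <- c("nm", "um", "A", "px")

# Physical length of one unit, expressed in nanometres. px has no physical
# meaning and is handled separately everywhere.
unit_in_nm <- c(nm = 1, um = 1000, A = 0.1)

# Display names (the label burned into scale bars).
unit_label <- function(unit) {
  switch(unit, nm = "nm", um = "μm", A = "Å", px = "px", unit)
}

#' Construct a micrograph
#'
#' A micrograph is the unit of all single-image operations: a 2-D grayscale
#' intensity matrix plus an optional physical pixel size, its unit, and a
#' free-form metadata list. Coordinates are row-major with the origin at the
#' top-left corner; pixel centres sit at integer coordinates and all indices
#' exposed by the API are 0-based.
#'
#' @param pixels numeric matrix (rows x cols) of finite intensities.
#' @param pixel_size physical length of one pixel edge (> 0), or `NA` when
#'   the scale is unknown.
#' @param unit one of `"nm"`, `"um"`, `"A"`, `"px"`. When `pixel_size` is
#'   unset the unit is forced to `"px"`.
#' @param metadata named list of acquisition metadata (magnification,
#'   voltage_kV, exposure_s, acquisition_date, acquisition_time, ...).
#' @param source_path provenance string (file the data came from).
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size = NA_real_, unit = "px",
                       metadata = list(), source_path = "") {
  if (!is.matrix(pixels) || length(pixels) == 0)
    mg_stop("mg_invalid_image", "pixels must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    mg_stop("mg_invalid_image", "pixels must all be finite")
  if (is.na(pixel_size)) {
    unit <- "px"
  } else {
    if (!is.numeric(pixel_size) || pixel_size <= 0)
      mg_stop("mg_invalid_scale", "pixel_size must be > 0")
    unit <- match.arg(unit, mg_units)
  }
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 unit = unit, metadata = metadata,
                 source_path = source_path),
            class = "micrograph")
}

#' Construct a video (ordered frame stack)
#'
#' @param frames list of same-shaped numeric matrices (F >= 1).
#' @param fps playback rate in frames per second.
#' @param pixel_size,unit,metadata,source_path as in [micrograph()].
#' @return an object of class `microvideo`.
#' @export
micro_video <- function(frames, fps = 10, pixel_size = NA_real_, unit = "px",
                        metadata = list(), source_path = "") {
  if (!is.list(frames) || length(frames) == 0)
    mg_stop("mg_invalid_video", "frames must be a non-empty list of matrices")
  dims <- lapply(frames, dim)
  if (any(vapply(dims, is.null, logical(1))))
    mg_stop("mg_invalid_video", "every frame must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    mg_stop("mg_frame_shape_mismatch", "all frames must share one shape")
  frames <- lapply(frames, function(f) { storage.mode(f) <- "double"; f })
  if (is.na(pixel_size)) unit <- "px" else unit <- match.arg(unit, mg_units)
  structure(list(frames = frames, fps = as.numeric(fps),
                 pixel_size = as.numeric(pixel_size), unit = unit,
                 metadata = metadata, source_path = source_path),
            class = "microvideo")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  scale <- if (is.na(x$pixel_size)) "unset" else
    sprintf("%g %s/px", x$pixel_size, unit_label(x$unit))
  cat(sprintf("<micrograph> %d x %d px, intensities [%g, %g], scale %s\n",
              d[1], d[2], min(x$pixels), max(x$pixels), scale))
  invisible(x)
}

#' @export
print.microvideo <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<microvideo> %d frames of %d x %d px, %g fps\n",
              length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' Number of frames in a video
#' @param v a `microvideo`.
#' @return integer frame count.
#' @export
n_frames <- function(v) {
  stopifnot(inherits(v, "microvideo"))
  length(v$frames)
}

#' Extract one frame of a video as a micrograph
#'
#' @param v a `microvideo`.
#' @param i 0-based frame index.
#' @return a [micrograph()] with the video's pixel size and metadata.
#' @export
frame <- function(v, i) {
  stopifnot(inherits(v, "microvideo"))
  if (!is.numeric(i) || length(i) != 1 || i != floor(i) || i < 0 ||
      i >= length(v$frames))
    mg_stop("mg_index_error",
            sprintf("frame index %s out of range [0, %d)", toString(i),
                    length(v$frames)))
  micrograph(v$frames[[i + 1]], pixel_size = v$pixel_size, unit = v$unit,
             metadata = v$metadata, source_path = v$source_path)
}

# Rebuild a micrograph with new pixels, keeping scale + metadata.
mg_with_pixels <- function(m, px) {
  micrograph(px, pixel_size = m$pixel_size, unit = m$unit,
             metadata = m$metadata, source_path = m$source_path)
}

mv_with_frames <- function(v, frames, fps = v$fps) {
  micro_video(frames, fps = fps, pixel_size = v$pixel_size, unit = v$unit,
              metadata = v$metadata, source_path = v$source_path)
}

# TRUE when intensities are already integers in [0, 255].
is_8bit <- function(px) {
  if (inherits(px, "micrograph")) px <- px$pixels
  all(px >= 0) && all(px <= 255) && all(px == floor(px))
}
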