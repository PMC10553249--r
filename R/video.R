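# Temporal operations for in-situ videos. All averaging is done in double
# precision regardless of input depth; conversion happens only on save.

#' Frame-averaging specification
#'
#' @param mode `"chunk"` (non-overlapping groups of `n`), `"sliding"`
#'   (moving window of width `n`) or `"all"` (single mean image).
#' @param n frames per group / window width (ignored for `"all"`).
#' @return an object of class `average_spec`.
#' @export
average_spec <- function(mode = c("chunk", "sliding", "all"), n = 1) {
  mode <- match.arg(mode)
  if (n < 1 || n != floor(n)) mg_stop("mg_invalid_spec", "n must be an integer >= 1")
  structure(list(mode = mode, n = n), class = "average_spec")
}

mean_frames <- function(frames)
  Reduce(`+`, frames) / length(frames)

#' Average video frames
#'
#' Chunk mode yields `ceiling(F/n)` frames, each the arithmetic mean of
#' its group (a smaller final group is averaged as-is, not dropped);
#' sliding mode yields `F - n + 1` frames (frame i = mean of frames
#' i..i+n-1); `"all"` collapses the video to a single [micrograph()].
#'
#' @param v a [micro_video()].
#' @param spec an [average_spec()].
#' @return a `microvideo`, or a `micrograph` for mode `"all"`.
#' @export
average <- function(v, spec) {
  stopifnot(inherits(v, "microvideo"), inherits(spec, "average_spec"))
  F <- length(v$frames)
  if (spec$mode == "all")
    return(micrograph(mean_frames(v$frames), pixel_size = v$pixel_size,
                      unit = v$unit, metadata = v$metadata,
                      source_path = v$source_path))
  if (spec$mode == "chunk") {
    groups <- split(seq_len(F), (seq_len(F) - 1) %/% spec$n)
    out <- lapply(groups, function(ix) mean_frames(v$frames[ix]))
    return(mv_with_frames(v, unname(out)))
  }
  # sliding
  if (spec$n > F)
    mg_stop("mg_invalid_spec",
            sprintf("sliding window n=%d exceeds frame count F=%d", spec$n, F))
  out <- lapply(seq_len(F - spec$n + 1), function(i)
    mean_frames(v$frames[i:(i + spec$n - 1)]))
  mv_with_frames(v, out)
}

#' Normalise per-frame gain
#'
#' Removes frame-to-frame brightness flicker: each frame is multiplied by
#' `global_stat / frame_stat`, where the global statistic is taken over
#' all pixels of all frames jointly. Afterwards every frame's statistic
#' equals the global one, and the operation is idempotent. The default
#' statistic is the median (robust to dark outlier frames).
#'
#' @param v a [micro_video()].
#' @param stat `"median"` or `"mean"`.
#' @return a normalised `microvideo`.
#' @export
normalise_video <- function(v, stat = c("median", "mean")) {
  stopifnot(inherits(v, "microvideo"))
  stat <- match.arg(stat)
  fstat <- if (stat == "median") function(x) stats::median(x) else mean
  g <- fstat(unlist(v$frames))
  out <- lapply(v$frames, function(f) {
    s <- fstat(f)
    if (s <= 0)
      mg_stop("mg_zero_statistic",
              "a frame statistic is <= 0; offset intensities first")
    f * (g / s)
  })
  mv_with_frames(v, out)
}

#' Contrast-stretch a whole video
#'
#' `scope = "global"` (default) computes the clip bounds once over all
#' frames jointly — flicker-safe, preserves inter-frame brightness
#' ordering; `scope = "per_frame"` applies [clip_contrast()] to each frame
#' independently.
#'
#' @param v a [micro_video()].
#' @param spec a [contrast_spec()].
#' @param scope `"global"` or `"per_frame"`.
#' @return an 8-bit `microvideo`.
#' @export
video_contrast <- function(v, spec, scope = c("global", "per_frame")) {
  stopifnot(inherits(v, "microvideo"), inherits(spec, "contrast_spec"))
  scope <- match.arg(scope)
  if (scope == "global") {
    vlim <- resolve_contrast(unlist(v$frames), spec)
    out <- lapply(v$frames, function(f)
      scale_to_8bit(pmin(pmax(f, vlim[1]), vlim[2]), vlim[1], vlim[2]))
  } else {
    out <- lapply(v$frames, function(f) {
      vlim <- resolve_contrast(f, spec)
      scale_to_8bit(pmin(pmax(f, vlim[1]), vlim[2]), vlim[1], vlim[2])
    })
  }
  mv_with_frames(v, out)
}

#' Convert every frame of a video to 8-bit jointly
#'
#' Single linear map of the video's global `[min, max]` onto 0..255, so
#' relative frame brightness is preserved.
#'
#' @param v a [micro_video()].
#' @return an 8-bit `microvideo`.
#' @export
video_to_8bit <- function(v) {
  stopifnot(inherits(v, "microvideo"))
  lo <- min(vapply(v$frames, min, numeric(1)))
  hi <- max(vapply(v$frames, max, numeric(1)))
  if (hi == lo) {
    warning("constant video: mapping to all zeros")
    return(mv_with_frames(v, lapply(v$frames, function(f) f * 0)))
  }
  mv_with_frames(v, lapply(v$frames, scale_to_8bit, lo, hi))
}

#' Hook for external motion correction
#'
#' Command-template hook for an external motion-correction binary. The
#' video is written as an MRC stack, the template is expanded with
#' `{in}`/`{out}`, run, and the corrected stack read back. The package
#' never requires the binary to exist.
#'
#' @param v a [micro_video()].
#' @param command template containing `{in}` and `{out}`.
#' @return the corrected `microvideo`.
#' @export
external_motion_correct <- function(v, command) {
  stopifnot(inherits(v, "microvideo"))
  fin <- tempfile(fileext = ".mrc"); fout <- tempfile(fileext = ".mrc")
  write_mrc(v$frames, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(fout))
    mg_stop("mg_external_tool",
            sprintf("external motion correction failed: %s", cmd))
  mrc <- read_mrc(fout)
  mv_with_frames(v, mrc$frames)
}
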