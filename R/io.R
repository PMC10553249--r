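# Loading and saving micrographs/videos; metadata tabulation.
#
# Core guarantees cover TIFF (incl. 32-bit float), MRC2014 and raw AVI.
# Other formats (e.g. proprietary Digital Micrograph containers) enter
# through the optional reader-plugin registry; MP4 goes through an external
# ffmpeg when one is installed.

.mg_readers <- new.env(parent = emptyenv())

#' Register an optional format reader plugin
#'
#' Extends [load_image()]/[load_video()] to formats the core does not parse
#' itself (e.g. proprietary acquisition containers). The reader is tried
#' when the core formats do not match.
#'
#' @param name plugin name (used for unregistering / diagnostics).
#' @param can_read `function(path) -> logical`.
#' @param read `function(path) -> list(frames = list of matrices,
#'   pixel_size = numeric or NA, unit = string, metadata = list)`.
#' @export
register_reader <- function(name, can_read, read) {
  assign(name, list(can_read = can_read, read = read), envir = .mg_readers)
  invisible(name)
}

find_plugin <- function(path) {
  for (nm in ls(.mg_readers)) {
    pl <- get(nm, envir = .mg_readers)
    ok <- tryCatch(isTRUE(pl$can_read(path)), error = function(e) FALSE)
    if (ok) return(pl)
  }
  NULL
}

check_exists <- function(path) {
  if (!file.exists(path))
    mg_stop("mg_missing_file", sprintf("file not found: %s", path))
}

# native-depth TIFF decode -> list of matrices. Integer TIFFs are read
# as.is (raw stored integers); float TIFFs already come back unscaled.
read_tiff_frames <- function(path) {
  frames <- tryCatch({
    info <- tiff::readTIFF(path, payload = FALSE)
    if (is.data.frame(info) && nrow(info) > 1) info <- info[1, ]
    is_float <- !is.null(info$sample.format) &&
      identical(info$sample.format, "float")
    tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  },
    error = function(e)
      mg_stop("mg_corrupt_file",
              sprintf("could not decode TIFF %s: %s", path, conditionMessage(e))))
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- apply(f, c(1, 2), mean)  # channel mean
    storage.mode(f) <- "double"
    f
  })
}

#' Load a single-frame image
#'
#' Reads TIFF (any bit depth, intensities preserved as stored) or MRC;
#' JPEG and registered plugin formats are also accepted. Pixel size is
#' taken from file metadata when the container carries one (MRC cell
#' dimensions, reported in Angstrom), else from the arguments, else left
#' unset. A multi-frame file raises a typed condition
#' (`mg_multiframe_error`) directing the caller to [load_video()].
#'
#' @param path file path.
#' @param pixel_size,unit fallback physical scale when the file has none.
#' @return a [micrograph()].
#' @export
load_image <- function(path, pixel_size = NA_real_, unit = "px") {
  check_exists(path)
  meta <- list()
  file_ps <- NA_real_; file_unit <- "px"
  if (is_tiff(path)) {
    frames <- read_tiff_frames(path)
  } else if (is_mrc(path)) {
    mrc <- read_mrc(path)
    frames <- mrc$frames
    if (!is.na(mrc$pixel_size_ang)) { file_ps <- mrc$pixel_size_ang; file_unit <- "A" }
  } else if (is_jpeg(path)) {
    f <- jpeg::readJPEG(path)
    if (length(dim(f)) == 3) f <- apply(f, c(1, 2), mean)
    frames <- list(round(f * 255))
  } else {
    pl <- find_plugin(path)
    if (is.null(pl))
      mg_stop("mg_format_error",
              sprintf("unrecognised image format: %s", path))
    res <- pl$read(path)
    frames <- res$frames
    if (!is.null(res$pixel_size) && !is.na(res$pixel_size)) {
      file_ps <- res$pixel_size; file_unit <- res$unit
    }
    meta <- if (is.null(res$metadata)) list() else res$metadata
  }
  if (length(frames) > 1)
    mg_stop("mg_multiframe_error",
            sprintf("%s holds %d frames; use load_video()", path,
                    length(frames)))
  if (!is.na(file_ps)) { pixel_size <- file_ps; unit <- file_unit }
  micrograph(frames[[1]], pixel_size = pixel_size, unit = unit,
             metadata = meta, source_path = path)
}

#' Load a video
#'
#' Accepts a multi-frame TIFF or MRC stack, a raw AVI file, an MP4 (via an
#' external `ffmpeg` on the PATH), or an ordered character vector of
#' single-frame image paths of identical shape. Colour movie frames are
#' converted to grayscale by the unweighted channel mean.
#'
#' @param source file path or character vector of frame paths.
#' @param fps fallback playback rate when the container has none.
#' @return a [micro_video()].
#' @export
load_video <- function(source, fps = 10) {
  if (length(source) == 0)
    mg_stop("mg_invalid_spec", "empty source list")
  if (length(source) > 1) {
    mgs <- lapply(source, load_image)
    shapes <- vapply(mgs, function(m) paste(dim(m$pixels), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1)
      mg_stop("mg_frame_shape_mismatch",
              "sequence frames have mixed shapes")
    m1 <- mgs[[1]]
    return(micro_video(lapply(mgs, `[[`, "pixels"), fps = fps,
                       pixel_size = m1$pixel_size, unit = m1$unit,
                       metadata = m1$metadata, source_path = source[1]))
  }
  path <- source
  check_exists(path)
  ps <- NA_real_; unit <- "px"
  if (is_tiff(path)) {
    frames <- read_tiff_frames(path)
  } else if (is_mrc(path)) {
    mrc <- read_mrc(path)
    frames <- mrc$frames
    if (!is.na(mrc$pixel_size_ang)) { ps <- mrc$pixel_size_ang; unit <- "A" }
  } else if (is_riff_avi(path)) {
    avi <- read_avi_raw(path)
    frames <- avi$frames
    fps <- avi$fps
  } else if (grepl("\\.(mp4|mov)$", path, ignore.case = TRUE)) {
    frames <- read_movie_ffmpeg(path)
  } else {
    pl <- find_plugin(path)
    if (is.null(pl))
      mg_stop("mg_format_error", sprintf("unrecognised video format: %s", path))
    res <- pl$read(path)
    frames <- res$frames
    if (!is.null(res$pixel_size) && !is.na(res$pixel_size)) {
      ps <- res$pixel_size; unit <- res$unit
    }
  }
  micro_video(frames, fps = fps, pixel_size = ps, unit = unit,
              source_path = path)
}

ffmpeg_path <- function() Sys.which("ffmpeg")

read_movie_ffmpeg <- function(path) {
  ff <- ffmpeg_path()
  if (ff == "")
    mg_stop("mg_external_tool",
            "decoding MP4/MOV requires ffmpeg on the PATH; none was found")
  dir <- tempfile("frames"); dir.create(dir)
  status <- system2(ff, c("-loglevel", "quiet", "-i", shQuote(path),
                          file.path(dir, "f%06d.tif")))
  if (status != 0)
    mg_stop("mg_corrupt_file", sprintf("ffmpeg failed to decode %s", path))
  files <- sort(list.files(dir, full.names = TRUE))
  unlist(lapply(files, read_tiff_frames), recursive = FALSE)
}

#' Save a micrograph
#'
#' `tif8` and `jpeg` require intensities already in 0..255 (apply
#' [to_8bit()] or [clip_contrast()] first — there is no silent rescale);
#' `tif32` stores IEEE float32 losslessly; `mrc` writes an MRC2014 mode-2
#' file carrying the pixel size in its header.
#'
#' @param m a [micrograph()].
#' @param path output path.
#' @param format one of `"tif8"`, `"tif32"`, `"jpeg"`, `"mrc"`.
#' @param quality JPEG quality 1..100 (default 95).
#' @return the output path, invisibly.
#' @export
save_image <- function(m, path, format = c("tif8", "tif32", "jpeg", "mrc"),
                       quality = 95) {
  stopifnot(inherits(m, "micrograph"))
  format <- match.arg(format)
  px <- m$pixels
  if (format %in% c("tif8", "jpeg") && !is_8bit(px))
    mg_stop("mg_range_error",
            sprintf("%s needs intensities to be integers in 0..255; apply to_8bit() or clip_contrast() first",
                    format))
  switch(format,
    tif8 = tiff::writeTIFF(px / 255, path, bits.per.sample = 8L,
                           compression = "none"),
    tif32 = write_tiff_float32(px, path),
    jpeg = jpeg::writeJPEG(px / 255, path, quality = quality / 100),
    mrc = write_mrc(px, path, pixel_size_ang = pixel_size_in_ang(m)))
  invisible(path)
}

pixel_size_in_ang <- function(m) {
  if (is.na(m$pixel_size) || m$unit == "px") return(0)
  m$pixel_size * unit_in_nm[[m$unit]] * 10
}

#' Save a video
#'
#' @param v a [micro_video()].
#' @param path output path; for `tif_sequence` a template directory/prefix
#'   (frames are written as `<path>_000001.tif`, ... so lexicographic order
#'   equals frame order).
#' @param mode `"tif_stack"`, `"tif_sequence"`, `"mp4"` (external ffmpeg)
#'   or `"avi_raw"` (uncompressed, lossless).
#' @param fps frame rate written to movie containers (default: the video's).
#' @return character vector of written path(s), invisibly.
#' @export
save_video <- function(v, path, mode = c("tif_stack", "tif_sequence", "mp4",
                                         "avi_raw"), fps = NULL) {
  stopifnot(inherits(v, "microvideo"))
  mode <- match.arg(mode)
  if (is.null(fps)) fps <- v$fps
  frames <- v$frames
  if (mode %in% c("mp4", "avi_raw")) {
    if (!all(vapply(frames, is_8bit, logical(1))))
      mg_stop("mg_range_error",
              sprintf("%s needs 8-bit frames; convert the video first", mode))
    if (length(frames) == 1)
      warning("writing a movie with a single frame")
  }
  out <- switch(mode,
    tif_stack = {
      if (all(vapply(frames, is_8bit, logical(1))))
        tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                        bits.per.sample = 8L, compression = "none")
      else if (all(vapply(frames, function(f)
                   all(f >= 0 & f <= 65535 & f == floor(f)), logical(1))))
        tiff::writeTIFF(lapply(frames, function(f) f / 65535), path,
                        bits.per.sample = 16L, compression = "none")
      else
        write_tiff_float32(frames, path)
      path
    },
    tif_sequence = {
      n <- length(frames)
      files <- sprintf("%s_%06d.tif", path, seq_len(n))
      for (i in seq_len(n))
        save_frame_tiff(frames[[i]], files[i])
      files
    },
    avi_raw = write_avi_raw(frames, path, fps = fps),
    mp4 = save_mp4_ffmpeg(frames, path, fps))
  invisible(out)
}

save_frame_tiff <- function(f, file) {
  if (is_8bit(f))
    tiff::writeTIFF(f / 255, file, bits.per.sample = 8L, compression = "none")
  else if (all(f >= 0 & f <= 65535 & f == floor(f)))
    tiff::writeTIFF(f / 65535, file, bits.per.sample = 16L,
                    compression = "none")
  else write_tiff_float32(f, file)
  file
}

save_mp4_ffmpeg <- function(frames, path, fps) {
  ff <- ffmpeg_path()
  if (ff == "")
    mg_stop("mg_external_tool",
            "writing MP4 requires ffmpeg on the PATH; none was found; use mode 'avi_raw' or a TIFF mode instead")
  dir <- tempfile("mp4frames"); dir.create(dir)
  for (i in seq_along(frames))
    tiff::writeTIFF(frames[[i]] / 255, file.path(dir, sprintf("f%06d.tif", i)),
                    bits.per.sample = 8L)
  status <- system2(ff, c("-loglevel", "quiet", "-y", "-framerate", fps,
                          "-i", file.path(dir, "f%06d.tif"),
                          "-pix_fmt", "yuv420p", shQuote(path)))
  if (status != 0)
    mg_stop("mg_external_tool", "ffmpeg failed to encode MP4")
  path
}

metadata_columns <- c("filename", "magnification", "voltage_kV",
                      "exposure_s", "acquisition_date", "acquisition_time",
                      "pixel_size", "unit", "width", "height", "status")

#' Tabulate metadata for a set of files
#'
#' One row per input file, in input order. Formats that carry no
#' acquisition metadata yield rows with the dimensions filled in and the
#' acquisition fields missing (`NA`); unreadable files give a row flagged
#' `"unreadable"` in the `status` column — they never abort the batch.
#'
#' @param paths character vector of file paths.
#' @param csv optional path: also write the table as RFC-4180 CSV.
#' @return a data.frame with columns filename, magnification, voltage_kV,
#'   exposure_s, acquisition_date, acquisition_time, pixel_size, unit,
#'   width, height, status.
#' @export
extract_metadata <- function(paths, csv = NULL) {
  rows <- lapply(paths, function(p) {
    row <- as.list(stats::setNames(rep(NA, length(metadata_columns)),
                                   metadata_columns))
    row$filename <- basename(p)
    row$status <- "ok"
    got <- tryCatch({
      if (!file.exists(p)) stop("missing")
      if (is_tiff(p)) {
        info <- tiff::readTIFF(p, payload = FALSE)
        if (is.data.frame(info) && nrow(info) > 1) info <- info[1, ]
        row$width <- info$width
        row$height <- info$length
        row$unit <- "px"
      } else if (is_mrc(p)) {
        mrc <- read_mrc(p)
        row$width <- ncol(mrc$frames[[1]])
        row$height <- nrow(mrc$frames[[1]])
        if (!is.na(mrc$pixel_size_ang)) {
          row$pixel_size <- mrc$pixel_size_ang
          row$unit <- "A"
        } else row$unit <- "px"
      } else if (is_jpeg(p)) {
        f <- jpeg::readJPEG(p)
        row$width <- dim(f)[2]; row$height <- dim(f)[1]
        row$unit <- "px"
      } else {
        pl <- find_plugin(p)
        if (is.null(pl)) stop("unrecognised")
        res <- pl$read(p)
        row$width <- ncol(res$frames[[1]]); row$height <- nrow(res$frames[[1]])
        md <- res$metadata
        for (key in c("magnification", "voltage_kV", "exposure_s",
                      "acquisition_date", "acquisition_time"))
          if (!is.null(md[[key]])) row[[key]] <- md[[key]]
        if (!is.null(res$pixel_size) && !is.na(res$pixel_size)) {
          row$pixel_size <- res$pixel_size; row$unit <- res$unit
        }
      }
      TRUE
    }, error = function(e) FALSE)
    if (!got) row$status <- "unreadable"
    row
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (!is.null(csv)) write_metadata_csv(tab, csv)
  tab
}

#' Write a metadata table as RFC-4180 CSV
#' @param tab the data.frame from [extract_metadata()].
#' @param path output path.
#' @export
write_metadata_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "", eol = "\r\n")
  invisible(path)
}
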