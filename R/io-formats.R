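# Low-level container support.
#
# - TIFF reading and integer TIFF writing go through the tiff package
#   (libtiff). libtiff reads IEEE-float TIFFs fine, but the R writer only
#   stores [0,1]-scaled integers, so a minimal uncompressed float32 TIFF
#   writer (single- and multi-page) lives here.
# - MRC2014 (modes 0/1/2/6) reader and mode-2 (float32) writer.
# - Raw (uncompressed) AVI: RIFF container with 8-bit palettised DIB
#   frames, bottom-up rows padded to 4 bytes. Bit-exact round trips.

w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
w_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4, endian = "little")
w_tag <- function(con, tag) writeChar(tag, con, nchars = 4, eos = NULL)

# ---- float32 TIFF writer -------------------------------------------------

# frames: list of numeric matrices (same shape). Little-endian, one strip
# per page, SampleFormat = IEEE float.
write_tiff_float32 <- function(frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  nbytes <- H * W * 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2A, 0x00)), con)  # "II", 42
  n <- length(frames)
  data_off <- 8
  ifd_off <- data_off + n * nbytes
  w_u32(con, ifd_off)  # offset of first IFD
  for (f in frames) w_f32(con, as.numeric(t(f)))  # row-major strips
  ntags <- 10
  entry <- function(tag, type, count, value) {
    w_u16(con, tag); w_u16(con, type); w_u32(con, count)
    if (type == 3) { w_u16(con, value); w_u16(con, 0) } else w_u32(con, value)
  }
  for (i in seq_len(n)) {
    entry_off <- ifd_off + (i - 1) * (2 + ntags * 12 + 4)
    stopifnot(seek(con, where = NA) == entry_off)
    w_u16(con, ntags)
    entry(256, 4, 1, W)                      # ImageWidth
    entry(257, 4, 1, H)                      # ImageLength
    entry(258, 3, 1, 32)                     # BitsPerSample
    entry(259, 3, 1, 1)                      # Compression: none
    entry(262, 3, 1, 1)                      # Photometric: black is zero
    entry(273, 4, 1, data_off + (i - 1) * nbytes)  # StripOffsets
    entry(277, 3, 1, 1)                      # SamplesPerPixel
    entry(278, 4, 1, H)                      # RowsPerStrip
    entry(279, 4, 1, nbytes)                 # StripByteCounts
    entry(339, 3, 1, 3)                      # SampleFormat: IEEE float
    next_off <- if (i < n) entry_off + 2 + ntags * 12 + 4 else 0
    w_u32(con, next_off)
  }
  invisible(path)
}

# ---- MRC2014 -------------------------------------------------------------

# pixel size is stored in the header cell dimensions, in Angstrom per the
# format convention; 0 means unset.
write_mrc <- function(frames, path, pixel_size_ang = 0) {
  if (!is.list(frames)) frames <- list(frames)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  nz <- length(frames)
  all_px <- unlist(lapply(frames, function(f) as.numeric(t(f))))
  con <- file(path, "wb")
  on.exit(close(con))
  w_u32(con, c(W, H, nz))                    # nx ny nz
  w_u32(con, 2)                              # mode 2 = float32
  w_u32(con, c(0, 0, 0))                     # nxstart..
  w_u32(con, c(W, H, nz))                    # mx my mz
  w_f32(con, c(W, H, nz) * pixel_size_ang)   # cella (Angstrom)
  w_f32(con, c(90, 90, 90))                  # cellb
  w_u32(con, c(1, 2, 3))                     # mapc mapr maps
  w_f32(con, c(min(all_px), max(all_px), mean(all_px)))
  w_u32(con, 0)                              # ispg
  w_u32(con, 0)                              # nsymbt
  writeBin(raw(100), con)                    # extra
  w_f32(con, c(0, 0, 0))                     # origin
  w_tag(con, "MAP ")
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  w_f32(con, stats::sd(all_px))              # rms
  w_u32(con, 0)                              # nlabl
  writeBin(raw(800), con)                    # labels
  w_f32(con, all_px)
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (any(dims <= 0) || !(mode %in% c(0, 1, 2, 6)))
    mg_stop("mg_corrupt_file",
            sprintf("unsupported or corrupt MRC header in %s (mode %d)",
                    path, mode))
  seek(con, 7 * 4)
  mx <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  W <- dims[1]; H <- dims[2]; nz <- dims[3]
  npx <- W * H
  read_frame <- function() {
    px <- switch(as.character(mode),
      "0" = readBin(con, "integer", npx, size = 1, signed = TRUE),
      "1" = readBin(con, "integer", npx, size = 2, signed = TRUE,
                    endian = "little"),
      "2" = readBin(con, "numeric", npx, size = 4, endian = "little"),
      "6" = readBin(con, "integer", npx, size = 2, signed = FALSE,
                    endian = "little"))
    if (length(px) < npx)
      mg_stop("mg_corrupt_file", sprintf("truncated MRC data in %s", path))
    t(matrix(as.numeric(px), W, H))  # stored x-fastest -> transpose
  }
  frames <- lapply(seq_len(nz), function(i) read_frame())
  ps_ang <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else NA_real_
  list(frames = frames, pixel_size_ang = ps_ang)
}

is_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 216)
  length(hdr) >= 212 && rawToChar(hdr[209:212]) == "MAP "
}

is_tiff <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  length(magic) == 4 &&
    (all(magic == as.raw(c(0x49, 0x49, 0x2A, 0x00))) ||
     all(magic == as.raw(c(0x4D, 0x4D, 0x00, 0x2A))))
}

is_riff_avi <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 12)
  length(hdr) == 12 && rawToChar(hdr[1:4]) == "RIFF" &&
    rawToChar(hdr[9:12]) == "AVI "
}

is_jpeg <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  length(magic) == 2 && all(magic == as.raw(c(0xFF, 0xD8)))
}

# ---- raw AVI -------------------------------------------------------------

# frames: list of 8-bit matrices. 8 bpp grayscale palette, '00db' chunks.
write_avi_raw <- function(frames, path, fps = 10) {
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  n <- length(frames)
  rowsize <- 4 * ceiling(W / 4)
  framesize <- rowsize * H
  frame_raw <- lapply(frames, function(f) {
    rows <- lapply(rev(seq_len(H)), function(i) {  # bottom-up rows
      r <- as.raw(f[i, ])
      if (rowsize > W) r <- c(r, raw(rowsize - W))
      r
    })
    do.call(c, rows)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  chunk <- function(tag, body) {
    w_tag(con, tag); w_u32(con, length(body)); writeBin(body, con)
    if (length(body) %% 2 == 1) writeBin(raw(1), con)
  }
  bin_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                  endian = "little")
  bin_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
  avih <- c(bin_u32(round(1e6 / fps)), bin_u32(framesize * fps),
            bin_u32(0), bin_u32(0x10), bin_u32(n), bin_u32(0), bin_u32(1),
            bin_u32(framesize), bin_u32(W), bin_u32(H),
            bin_u32(c(0, 0, 0, 0)))
  scale <- 1000
  strh <- c(charToRaw("vids"), charToRaw("DIB "), bin_u32(0), bin_u16(0),
            bin_u16(0), bin_u32(0), bin_u32(scale),
            bin_u32(round(fps * scale)), bin_u32(0), bin_u32(n),
            bin_u32(framesize), bin_u32(-1), bin_u32(0),
            bin_u16(c(0, 0, W, H)))
  pal <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))))
  strf <- c(bin_u32(40), bin_u32(W), bin_u32(H), bin_u16(1), bin_u16(8),
            bin_u32(0), bin_u32(framesize), bin_u32(0), bin_u32(0),
            bin_u32(256), bin_u32(0), pal)
  list_body_len <- function(...) sum(vapply(list(...), length, integer(1)))
  strl_len <- 4 + (8 + length(strh)) + (8 + length(strf))
  hdrl_len <- 4 + (8 + length(avih)) + (8 + strl_len)
  movi_len <- 4 + n * (8 + framesize + (framesize %% 2))
  idx_len <- n * 16
  riff_len <- 4 + (8 + hdrl_len) + (8 + movi_len) + (8 + idx_len)
  w_tag(con, "RIFF"); w_u32(con, riff_len); w_tag(con, "AVI ")
  w_tag(con, "LIST"); w_u32(con, hdrl_len); w_tag(con, "hdrl")
  chunk("avih", avih)
  w_tag(con, "LIST"); w_u32(con, strl_len); w_tag(con, "strl")
  chunk("strh", strh)
  chunk("strf", strf)
  w_tag(con, "LIST"); w_u32(con, movi_len); w_tag(con, "movi")
  offsets <- integer(n)
  off <- 4  # relative to 'movi' fourcc
  for (i in seq_len(n)) {
    offsets[i] <- off
    chunk("00db", frame_raw[[i]])
    off <- off + 8 + framesize + (framesize %% 2)
  }
  w_tag(con, "idx1"); w_u32(con, idx_len)
  for (i in seq_len(n)) {
    w_tag(con, "00db"); w_u32(con, 0x10)  # keyframe flag
    w_u32(con, offsets[i]); w_u32(con, framesize)
  }
  invisible(path)
}

read_avi_raw <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  r_tag <- function() rawToChar(readBin(con, "raw", 4))
  if (r_tag() != "RIFF") mg_stop("mg_corrupt_file", "not a RIFF file")
  r_u32()
  if (r_tag() != "AVI ") mg_stop("mg_corrupt_file", "not an AVI file")
  W <- H <- bits <- NULL; fps <- NA_real_
  frames <- list()
  # walk chunks recursively; LIST chunks contain sub-chunks
  walk <- function(end) {
    while (seek(con, where = NA) < end) {
      tag <- r_tag(); len <- r_u32()
      start <- seek(con, where = NA)
      if (tag == "LIST") {
        r_tag()  # list type
        walk(start + len)
      } else if (tag == "strh") {
        body <- readBin(con, "raw", len)
        if (rawToChar(body[1:4]) == "vids") {
          scale <- readBin(body[21:24], "integer", 1, size = 4,
                           endian = "little")
          rate <- readBin(body[25:28], "integer", 1, size = 4,
                          endian = "little")
          if (scale > 0) fps <<- rate / scale
        }
      } else if (tag == "strf") {
        body <- readBin(body_raw <- readBin(con, "raw", len), "integer",
                        10, size = 4, endian = "little")
        W <<- body[2]; H <<- body[3]
        bits <<- readBin(body_raw[15:16], "integer", 1, size = 2,
                         endian = "little")
      } else if (tag %in% c("00db", "00dc")) {
        frames[[length(frames) + 1]] <<- readBin(con, "raw", len)
      }
      seek(con, start + len + (len %% 2))
    }
  }
  walk(sz)
  if (is.null(W) || length(frames) == 0)
    mg_stop("mg_corrupt_file", sprintf("no video stream found in %s", path))
  if (!identical(bits, 8L))
    mg_stop("mg_format_error",
            "only 8-bit uncompressed (DIB) AVI streams are supported")
  rowsize <- 4 * ceiling(W / 4)
  decode <- function(rawf) {
    px <- matrix(0, H, W)
    for (i in seq_len(H)) {
      row <- rawf[(i - 1) * rowsize + seq_len(W)]
      px[H + 1 - i, ] <- as.integer(row)  # bottom-up storage
    }
    px
  }
  list(frames = lapply(frames, decode), fps = if (is.na(fps)) 10 else fps)
}
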