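# Scale-bar annotation. Rendering is fully deterministic: a bundled 5x7
# bitmap font, integer-scaled, burned into the pixel array at 0 or 255.

# 5x7 glyphs, rows top to bottom, '#' = set. Covers everything a scale-bar
# label can contain: digits, decimal point, and the unit names nm / um
# (with the micro sign) / Angstrom / px.
.mg_font <- local({
  g <- list(
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11111","00010","00100","00010","00001","10001","01110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("00110","01000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00010","01100"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    " " = c("00000","00000","00000","00000","00000","00000","00000"),
    "n" = c("00000","00000","10110","11001","10001","10001","10001"),
    "m" = c("00000","00000","11010","10101","10101","10101","10101"),
    "p" = c("00000","00000","11110","10001","11110","10000","10000"),
    "x" = c("00000","00000","10001","01010","00100","01010","10001"),
    "μ" = c("00000","00000","10010","10010","10010","11101","10000"),
    "Å" = c("00100","01010","01110","10001","11111","10001","10001")
  )
  lapply(g, function(rows)
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]] == "1"))))
})

render_text_mask <- function(text, scale = 1) {
  chars <- strsplit(text, "")[[1]]
  glyphs <- lapply(chars, function(ch) {
    gl <- .mg_font[[ch]]
    if (is.null(gl)) gl <- .mg_font[[" "]]
    cbind(gl, 0)  # 1-column spacing
  })
  mask <- do.call(cbind, glyphs)
  mask <- mask[, -ncol(mask), drop = FALSE]  # drop trailing space
  if (scale > 1)
    mask <- mask[rep(seq_len(nrow(mask)), each = scale),
                 rep(seq_len(ncol(mask)), each = scale), drop = FALSE]
  mask
}

# largest "nice" value {1,2,5} * 10^k, in the image's unit, whose pixel
# length fits in f * width
nice_bar_length <- function(pixel_size, width, f) {
  best <- NA_real_
  for (k in -12:12) for (m in c(1, 2, 5)) {
    L <- m * 10^k
    px <- round(L / pixel_size)
    if (px >= 1 && px <= f * width && (is.na(best) || L > best)) best <- L
  }
  if (is.na(best))
    mg_stop("mg_invalid_scale",
            "no scale-bar length fits; image too small for fraction f")
  best
}

# promote the label to the most readable unit (1000 nm -> 1 um etc.)
format_bar_label <- function(L, unit) {
  if (unit == "px") return(list(value = L, unit = "px"))
  nm <- L * unit_in_nm[[unit]]
  if (nm >= 1000) { value <- nm / 1000; u <- "um" }
  else if (nm >= 1) { value <- nm; u <- "nm" }
  else { value <- nm * 10; u <- "A" }
  list(value = value, unit = u)
}

#' Choose scale-bar geometry for an image
#'
#' Picks the largest "nice" physical length (1, 2 or 5 times a power of
#' ten, in the image's unit) whose pixel length does not exceed
#' `f * width`, and decides the bar colour: white when the bar region is
#' significantly darker than the image (region mean below image mean minus
#' 0.1 of the intensity range), black otherwise.
#'
#' @param m a [micrograph()] with `pixel_size` set.
#' @param f target bar length as a fraction of image width (default 0.25).
#' @return a `scalebar_layout` list: physical length `L` and `unit`, pixel
#'   length `bar_px`, bar height/margin, label text, colour, and the
#'   0-based bounding boxes of bar and text.
#' @export
choose_bar <- function(m, f = 0.25) {
  stopifnot(inherits(m, "micrograph"))
  if (is.na(m$pixel_size))
    mg_stop("mg_invalid_scale",
            "pixel_size unset: load with pixel_size= or use set_scale()")
  px <- m$pixels
  H <- nrow(px); W <- ncol(px)
  L <- nice_bar_length(m$pixel_size, W, f)
  bar_px <- round(L / m$pixel_size)
  lab <- format_bar_label(L, m$unit)
  label <- paste0(format(lab$value, trim = TRUE), " ", unit_label(lab$unit))
  margin <- max(1, round(0.02 * W))
  bar_h <- max(1, round(0.015 * H))
  tscale <- max(1, round(0.03 * H / 7))
  tmask <- render_text_mask(label, tscale)
  # stack: text above bar, both left-anchored at the margin, bottom-left
  bar_r1 <- H - margin                     # 1-based inclusive rows
  bar_r0 <- bar_r1 - bar_h + 1
  txt_r1 <- bar_r0 - max(1, tscale)
  txt_r0 <- txt_r1 - nrow(tmask) + 1
  region_r0 <- max(1, txt_r0); region_r1 <- bar_r1
  region_c0 <- margin + 1
  region_c1 <- min(W, margin + max(bar_px, ncol(tmask)))
  region <- px[region_r0:region_r1, region_c0:region_c1, drop = FALSE]
  colour <- if (mean(region) < mean(px) - 0.1 * (max(px) - min(px)))
    "white" else "black"
  structure(list(L = L, unit = m$unit, bar_px = bar_px, bar_h = bar_h,
                 margin = margin, label = label, colour = colour,
                 text_scale = tscale,
                 bar_box = c(bar_r0, margin + 1, bar_r1, margin + bar_px) - 1,
                 text_box = c(txt_r0, margin + 1, txt_r1,
                              margin + ncol(tmask)) - 1),
            class = "scalebar_layout")
}

#' Burn a scale bar into an image
#'
#' Draws the bar and its label into the bottom-left region of an 8-bit
#' image (at intensity 0 or 255); every pixel outside the bar/text
#' bounding boxes is untouched. Returns a copy.
#'
#' @param m an 8-bit [micrograph()] with `pixel_size` set.
#' @param f bar length fraction of image width.
#' @param colour `"black"`, `"white"`, or `NULL` for the automatic choice.
#' @return a new annotated `micrograph`.
#' @export
add_scalebar <- function(m, f = 0.25, colour = NULL) {
  stopifnot(inherits(m, "micrograph"))
  if (!is_8bit(m$pixels))
    mg_stop("mg_range_error",
            "add_scalebar needs an 8-bit image; apply to_8bit() or clip_contrast() first")
  layout <- choose_bar(m, f)
  if (!is.null(colour)) layout$colour <- match.arg(colour, c("black", "white"))
  val <- if (layout$colour == "black") 0 else 255
  px <- m$pixels
  bb <- layout$bar_box + 1  # back to 1-based
  px[bb[1]:bb[3], bb[2]:bb[4]] <- val
  tb <- layout$text_box + 1
  tmask <- render_text_mask(layout$label, layout$text_scale)
  rr <- tb[1]:tb[3]; cc <- tb[2]:tb[4]
  keep <- rr >= 1 & rr <= nrow(px)
  ckeep <- cc >= 1 & cc <= ncol(px)
  sub <- px[rr[keep], cc[ckeep], drop = FALSE]
  sub[tmask[keep, ckeep, drop = FALSE] == 1] <- val
  px[rr[keep], cc[ckeep]] <- sub
  mg_with_pixels(m, px)
}

#' Set or convert the physical pixel size
#'
#' `set_scale` attaches a pixel size; `convert_scale_unit` converts an
#' existing one between nm, Angstrom and microns (other units need an
#' explicit factor). Pixels are never touched.
#'
#' @param m a [micrograph()] or [micro_video()].
#' @param pixel_size physical length per pixel edge.
#' @param unit unit of `pixel_size`.
#' @return the object with updated scale.
#' @export
set_scale <- function(m, pixel_size, unit) {
  stopifnot(inherits(m, "micrograph") || inherits(m, "microvideo"))
  unit <- match.arg(unit, mg_units)
  m$pixel_size <- as.numeric(pixel_size)
  m$unit <- unit
  m
}

#' @rdname set_scale
#' @param to_unit target unit.
#' @param factor explicit conversion factor (target = current * factor)
#'   for unit pairs the package does not know.
#' @export
convert_scale_unit <- function(m, to_unit, factor = NULL) {
  stopifnot(inherits(m, "micrograph") || inherits(m, "microvideo"))
  if (is.na(m$pixel_size))
    mg_stop("mg_invalid_scale", "pixel_size unset; use set_scale() first")
  if (is.null(factor)) {
    if (!(m$unit %in% names(unit_in_nm)) || !(to_unit %in% names(unit_in_nm)))
      mg_stop("mg_invalid_scale",
              sprintf("no built-in factor for %s -> %s; supply factor=",
                      m$unit, to_unit))
    factor <- unit_in_nm[[m$unit]] / unit_in_nm[[to_unit]]
  }
  m$pixel_size <- m$pixel_size * factor
  m$unit <- if (to_unit %in% mg_units) to_unit else to_unit
  m
}
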