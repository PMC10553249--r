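# Contact-sheet documents: a responsive HTML + CSS pair, or a paginated
# PDF. Output is deterministic for fixed inputs (no timestamps).

#' Describe one contact-sheet item
#'
#' @param path media file (image, or MP4 for the HTML sheet).
#' @param caption caption text (default: the file name).
#' @param note optional per-item note.
#' @param kind `"image"` or `"video"`; guessed from the extension when
#'   missing.
#' @return an object of class `sheet_item`.
#' @export
sheet_item <- function(path, caption = basename(path), note = NULL,
                       kind = NULL) {
  if (is.null(kind))
    kind <- if (grepl("\\.(mp4|avi|mov)$", path, ignore.case = TRUE))
      "video" else "image"
  structure(list(path = path, caption = caption, note = note,
                 kind = match.arg(kind, c("image", "video"))),
            class = "sheet_item")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# path of `target` relative to directory `base` (falls back to basename)
relative_to <- function(target, base) {
  t <- normalizePath(target, winslash = "/", mustWork = TRUE)
  b <- normalizePath(base, winslash = "/", mustWork = TRUE)
  if (startsWith(t, paste0(b, "/"))) substring(t, nchar(b) + 2)
  else basename(t)
}

sheet_css <- paste(
  "body { font-family: sans-serif; margin: 2em; background: #fafafa; }",
  "h1 { margin-bottom: 0.2em; }",
  ".notes { color: #444; margin-bottom: 1.5em; }",
  ".sheet { display: grid;",
  "  grid-template-columns: repeat(auto-fill, minmax(300px, 1fr));",
  "  gap: 1em; }",
  ".tile { background: #fff; border: 1px solid #ddd; padding: 0.5em; }",
  ".tile img, .tile video { width: 100%; display: block; }",
  ".caption { font-size: 0.9em; margin-top: 0.4em; color: #222; }",
  ".note { font-size: 0.8em; color: #666; }",
  sep = "\n")

#' Build an HTML contact sheet
#'
#' Writes a standalone HTML file plus its CSS stylesheet into `out_dir`.
#' Media are referenced by paths relative to `out_dir`, so the sheet stays
#' portable together with its folder; videos are embedded as MP4 `<video>`
#' elements. Byte-identical output for identical inputs.
#'
#' @param items non-empty list of [sheet_item()]s; every media file must
#'   exist.
#' @param title document title (HTML-escaped).
#' @param notes experimental notes shown under the title.
#' @param out_dir output directory (created if needed).
#' @param name base name for the output files.
#' @return character vector: paths of the HTML and CSS files.
#' @export
build_html <- function(items, title = "Contact sheet", notes = "",
                       out_dir = ".", name = "contact_sheet") {
  if (length(items) == 0)
    mg_stop("mg_invalid_spec", "no items to lay out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (it in items)
    if (!file.exists(it$path))
      mg_stop("mg_missing_file", sprintf("media missing: %s", it$path))
  tiles <- vapply(items, function(it) {
    rel <- relative_to(it$path, out_dir)
    media <- if (it$kind == "video")
      sprintf('<video controls src="%s" type="video/mp4"></video>',
              html_escape(rel))
    else
      sprintf('<img src="%s" alt="%s"/>', html_escape(rel),
              html_escape(it$caption))
    note <- if (is.null(it$note)) "" else
      sprintf('\n    <div class="note">%s</div>', html_escape(it$note))
    sprintf('  <div class="tile">\n    %s\n    <div class="caption">%s</div>%s\n  </div>',
            media, html_escape(it$caption), note)
  }, character(1))
  css_file <- paste0(name, ".css")
  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", html_escape(title)),
    sprintf('<link rel="stylesheet" href="%s"/>', css_file),
    "</head>",
    "<body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    if (nzchar(notes))
      sprintf('<div class="notes">%s</div>', html_escape(notes)),
    '<div class="sheet">',
    tiles,
    "</div>",
    "</body>",
    "</html>")
  html_path <- file.path(out_dir, paste0(name, ".html"))
  css_path <- file.path(out_dir, css_file)
  writeLines(html, html_path)
  writeLines(sheet_css, css_path)
  c(html_path, css_path)
}

read_any_image <- function(path) {
  if (is_jpeg(path)) {
    px <- jpeg::readJPEG(path)
  } else if (is_tiff(path)) {
    px <- tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    mg_stop("mg_format_error", "png preview input is not supported")
  } else {
    mg_stop("mg_format_error",
            sprintf("cannot embed %s in a PDF; convert to JPEG/TIFF", path))
  }
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  px
}

#' Build a PDF contact sheet
#'
#' Image items only (represent a video by a pre-rendered preview frame,
#' e.g. its average frame). Images flow through a fixed grid, captions
#' underneath; page count is `ceiling(n / (per_page[1]*per_page[2]))`.
#'
#' @param items list of image [sheet_item()]s.
#' @param title,notes shown on the first page.
#' @param out_path output PDF path.
#' @param per_page `c(rows, cols)` grid per A4 page (default 2 x 2).
#' @return `out_path`, invisibly.
#' @export
build_pdf <- function(items, title = "Contact sheet", notes = "",
                      out_path = "contact_sheet.pdf", per_page = c(2, 2)) {
  if (length(items) == 0)
    mg_stop("mg_invalid_spec", "no items to lay out")
  for (it in items) {
    if (it$kind != "image")
      mg_stop("mg_invalid_spec",
              sprintf("video item %s needs a pre-rendered preview frame for PDF",
                      it$path))
    if (!file.exists(it$path))
      mg_stop("mg_missing_file", sprintf("media missing: %s", it$path))
  }
  npp <- per_page[1] * per_page[2]
  grDevices::pdf(out_path, width = 8.27, height = 11.69,
                 onefile = TRUE, useDingbats = FALSE)
  on.exit(grDevices::dev.off())
  pages <- split(seq_along(items), (seq_along(items) - 1) %/% npp)
  first <- TRUE
  for (pg in pages) {
    graphics::par(mfrow = per_page, mar = c(2.5, 1, 2.5, 1),
                  oma = c(0, 0, if (first) 4 else 1, 0))
    for (i in pg) {
      px <- read_any_image(items[[i]]$path)
      graphics::plot.new()
      graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = NA)
      graphics::rasterImage(px / max(max(px), 1), 0, 0, 1, 1)
      graphics::mtext(items[[i]]$caption, side = 1, line = 1, cex = 0.8)
    }
    if (first) {
      graphics::mtext(title, outer = TRUE, cex = 1.4, line = 2)
      if (nzchar(notes))
        graphics::mtext(notes, outer = TRUE, cex = 0.9, line = 0.5)
      first <- FALSE
    }
  }
  invisible(out_path)
}
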