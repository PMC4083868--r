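#' Export a rendered canvas to an image file
#'
#' Writes the canvas as a bitmapped image (PNG, JPEG, TIFF) or as scalable
#' vector graphics (SVG, PDF). Raster formats write the canvas pixels
#' directly (optionally integer-upscaled), so PNG output is byte-identical
#' across runs for identical inputs; vector formats replay the cell
#' display list as rectangle primitives and draw identifier/"P"/"M" labels
#' where present. A sub-region of the haplotype grid (subject/group rows x
#' variants) may be exported instead of the full canvas.
#'
#' @param canvas a `hap_canvas` from [render_matrix()].
#' @param path output file path.
#' @param format one of `"png"`, `"jpeg"`, `"tiff"`, `"svg"`, `"pdf"`
#'   (default: from the file extension).
#' @param scale integer pixel-upscaling factor for raster formats (>= 1);
#'   raster output is `scale * width` x `scale * height` pixels.
#' @param region optional list with integer vectors `rows` (display rows)
#'   and/or `variants` (variant indices); only the bounding window of the
#'   selected grid cells is exported (annotation panels are cropped away).
#' @return `path`, invisibly.
#' @export
export_image <- function(canvas, path, format = NULL, scale = 1L,
                         region = NULL) {
  stopifnot(inherits(canvas, "hap_canvas"))
  formats <- c("png", "jpeg", "tiff", "svg", "pdf")
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format == "jpg") format <- "jpeg"
  }
  format <- tolower(format)
  if (!format %in% formats) {
    stop("unsupported format '", format, "': supported formats are ",
         paste(toupper(formats), collapse = ", "), call. = FALSE)
  }
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be a positive integer", call. = FALSE)

  win <- region_window(canvas, region)
  if (format %in% c("png", "jpeg", "tiff")) {
    r <- canvas$raster[win$y0:win$y1, win$x0:win$x1, , drop = FALSE]
    if (scale > 1L) {
      r <- r[rep(seq_len(nrow(r)), each = scale),
             rep(seq_len(ncol(r)), each = scale), , drop = FALSE]
    }
    switch(format,
      png = png::writePNG(r, target = path),
      tiff = tiff::writeTIFF(r, where = path),
      jpeg = write_jpeg_raster(r, path))
  } else {
    write_vector_rects(canvas, path, format, win)
  }
  invisible(path)
}

# pixel window (inclusive bounds) of a rows x variants sub-region, or the
# full canvas when region is NULL
region_window <- function(canvas, region) {
  if (is.null(region)) {
    return(list(x0 = 1L, y0 = 1L, x1 = canvas$width, y1 = canvas$height,
                cropped = FALSE))
  }
  L <- canvas$layout
  rows <- region$rows %||% seq_len(L$n_rows)
  variants <- region$variants %||% seq_len(L$n_variants)
  if (!length(rows) || !length(variants) ||
      min(rows) < 1L || max(rows) > L$n_rows ||
      min(variants) < 1L || max(variants) > L$n_variants) {
    stop("region indices out of range", call. = FALSE)
  }
  cols <- range((range(variants) - 1L) * L$p_disp + c(1L, L$p_disp))
  list(
    x0 = as.integer(L$left_margin + (min(cols) - 1L) * L$cell_w + 1L),
    x1 = as.integer(L$left_margin + max(cols) * L$cell_w),
    y0 = as.integer(L$top_margin + (min(rows) - 1L) * L$cell_h + 1L),
    y1 = as.integer(L$top_margin + max(rows) * L$cell_h),
    cropped = TRUE)
}

write_jpeg_raster <- function(r, path) {
  h <- dim(r)[1L]; w <- dim(r)[2L]
  grDevices::jpeg(path, width = w, height = h, units = "px", quality = 95)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
  graphics::rasterImage(grDevices::as.raster(r), 0, 0, 1, 1,
                        interpolate = FALSE)
}

# replay the display list on a vector device; user coordinates are canvas
# pixels with y growing downward
write_vector_rects <- function(canvas, path, format, win) {
  w <- win$x1 - win$x0 + 1L
  h <- win$y1 - win$y0 + 1L
  if (format == "svg") {
    grDevices::svg(path, width = w / 72, height = h / 72)
  } else {
    grDevices::pdf(path, width = w / 72, height = h / 72)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(win$x0 - 1L, win$x1),
                        ylim = c(win$y1, win$y0 - 1L))
  rects <- canvas$rects
  if (win$cropped) {
    keep <- rects$x0 >= win$x0 - 1L & rects$x0 + rects$w <= win$x1 &
      rects$y0 >= win$y0 - 1L & rects$y0 + rects$h <= win$y1
    rects <- rects[keep, , drop = FALSE]
  } else {
    graphics::rect(win$x0 - 1L, win$y0 - 1L, win$x1, win$y1,
                   col = canvas$opts$palette$background, border = NA)
  }
  body <- rects[!rects$frame, , drop = FALSE]
  if (nrow(body)) {
    graphics::rect(body$x0, body$y0, body$x0 + body$w, body$y0 + body$h,
                   col = body$col, border = NA)
  }
  frames <- rects[rects$frame, , drop = FALSE]
  if (nrow(frames)) {
    graphics::rect(frames$x0, frames$y0, frames$x0 + frames$w,
                   frames$y0 + frames$h, col = NA, border = frames$col)
  }
  if (!win$cropped && nrow(canvas$texts)) {
    for (srt in unique(canvas$texts$srt)) {
      tx <- canvas$texts[canvas$texts$srt == srt, , drop = FALSE]
      graphics::text(tx$x, tx$y, tx$label, srt = srt, cex = 0.5,
                     adj = if (srt == 0) c(1, 0.5) else c(0, 0.5))
    }
  }
  invisible(path)
}
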