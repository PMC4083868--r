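#' Rendering options
#'
#' Collects every tunable of the static renderer. Default colors follow the
#' tool's conventions — nucleotide encoding: A green, C blue, T red,
#' G yellow, missing white; reference encoding: equal-to-reference blue,
#' different yellow; genotype encoding: both-reference green, heterozygous
#' yellow, homozygous-alternate red — with concrete RGB values taken from
#' ColorBrewer-style qualitative sets.
#'
#' @param encoding `"nucleotide"`, `"reference"` or `"genotype"`. The first
#'   two draw one display column per allele column (two per SNV for phased
#'   data); the genotype encoding collapses each SNV to a single column.
#' @param cell_w,cell_h cell size in pixels (>= 1).
#' @param aggregate_mode `"saturation"` (cell saturation scales with the
#'   consensus frequency) or `"bar"` (bottom-anchored bar of height
#'   `round(frequency * cell_h)`).
#' @param rarity_bars logical; in bar mode draw `1 - frequency` instead
#'   (bar height represents rarity, for minimum-method views).
#' @param palette named list of colors; see Details.
#' @param saturation_floor minimum saturation multiplier in saturation mode
#'   (the multiplier is `floor + (1 - floor) * frequency`, so cells with a
#'   weak consensus stay visible).
#' @param gradient length-2 vector of colors for numerical annotations
#'   (low, high; linear interpolation).
#' @param category_colors colors cycled over categorical annotation labels
#'   in first-seen order.
#' @param selection_color outline color for selected rows/columns.
#' @param show_ids logical; reserve label margins and emit row/column
#'   identifier text (drawn in vector exports).
#' @param gap pixel gap between the haplotype grid and annotation panels.
#'
#' @details `palette` entries: `nucleotide` (named A/C/G/T), `missing`,
#' `ref_match`, `ref_diff`, `geno_ref`, `geno_het`, `geno_hom`, `pm`
#' (length-2: paternal, maternal column marker), `background`.
#'
#' @return a list of class `render_options`.
#' @export
render_options <- function(encoding = c("nucleotide", "reference", "genotype"),
                           cell_w = 12L, cell_h = 12L,
                           aggregate_mode = c("saturation", "bar"),
                           rarity_bars = FALSE,
                           palette = NULL,
                           saturation_floor = 0.15,
                           gradient = c("#F7FBFF", "#08306B"),
                           category_colors = c(
                             "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
                             "#FF7F00", "#A65628", "#F781BF", "#999999",
                             "#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3",
                             "#A6D854", "#FFD92F"),
                           selection_color = "#000000",
                           show_ids = FALSE,
                           gap = 2L) {
  encoding <- match.arg(encoding)
  aggregate_mode <- match.arg(aggregate_mode)
  default_palette <- list(
    nucleotide = c(A = "#4DAF4A", C = "#377EB8", G = "#FFD92F",
                   T = "#E41A1C"),
    missing = "#FFFFFF",
    ref_match = "#377EB8",
    ref_diff = "#FFD92F",
    geno_ref = "#4DAF4A",
    geno_het = "#FFD92F",
    geno_hom = "#E41A1C",
    pm = c("#CCCCCC", "#666666"),
    background = "#FFFFFF")
  if (!is.null(palette)) {
    for (nm in names(palette)) default_palette[[nm]] <- palette[[nm]]
  }
  cell_w <- as.integer(cell_w); cell_h <- as.integer(cell_h)
  if (cell_w < 1L || cell_h < 1L) {
    stop("cell_w and cell_h must be >= 1 pixel", call. = FALSE)
  }
  if (saturation_floor < 0 || saturation_floor > 1) {
    stop("saturation_floor must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    encoding = encoding, cell_w = cell_w, cell_h = cell_h,
    aggregate_mode = aggregate_mode, rarity_bars = isTRUE(rarity_bars),
    palette = default_palette, saturation_floor = saturation_floor,
    gradient = gradient, category_colors = category_colors,
    selection_color = selection_color, show_ids = isTRUE(show_ids),
    gap = as.integer(gap)), class = "render_options")
}

#' Load rendering options from a YAML file
#'
#' Any field of [render_options()] may be set in the file; unset fields
#' keep their defaults. Palette entries are merged with the default
#' palette.
#'
#' @param path YAML file.
#' @return a `render_options` list.
#' @export
render_options_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(render_options))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown render option(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$palette)) {
    cfg$palette <- lapply(cfg$palette, function(x)
      if (length(x) > 1L) unlist(x) else x)
    if (!is.null(cfg$palette$nucleotide)) {
      cfg$palette$nucleotide <- unlist(cfg$palette$nucleotide)
    }
  }
  do.call(render_options, cfg)
}

## ---- per-cell color rules --------------------------------------------

#' Nucleotide color encoding
#'
#' Each base has its own color (defaults: A green, C blue, G yellow,
#' T red); a missing call is white.
#'
#' @param a character vector of calls (`NA` = missing).
#' @param palette named base-color vector plus missing color, as in
#'   [render_options()]'s `palette` (defaults used when omitted).
#' @param missing color for missing calls.
#' @return character vector of colors.
#' @export
cell_color_nucleotide <- function(a, palette = NULL, missing = NULL) {
  opts <- render_options()
  pal <- if (is.null(palette)) opts$palette$nucleotide else palette
  miss <- if (is.null(missing)) opts$palette$missing else missing
  out <- unname(pal[a])
  out[is.na(a)] <- miss
  if (anyNA(out)) stop("palette does not cover all bases", call. = FALSE)
  out
}

#' Reference-based color encoding
#'
#' An allele equal to the variant's reference base is blue, a differing
#' allele yellow, a missing call white.
#'
#' @param a character vector of calls.
#' @param ref reference base(s), recycled along `a`.
#' @param match_color,diff_color,missing_color override the defaults.
#' @return character vector of colors.
#' @export
cell_color_reference <- function(a, ref, match_color = NULL,
                                 diff_color = NULL, missing_color = NULL) {
  pal <- render_options()$palette
  mc <- if (is.null(match_color)) pal$ref_match else match_color
  dc <- if (is.null(diff_color)) pal$ref_diff else diff_color
  wc <- if (is.null(missing_color)) pal$missing else missing_color
  if (any(is.na(ref))) stop("reference base must be non-missing",
                            call. = FALSE)
  out <- ifelse(a == ref, mc, dc)
  out[is.na(a)] <- wc
  out
}

#' Genotype (unphased) color encoding
#'
#' One column per SNV: both alleles equal to the reference is green, a
#' heterozygous call yellow, a homozygous non-reference call red; any
#' missing allele gives white.
#'
#' @param a0,a1 the two allele calls (vectors).
#' @param ref reference base(s).
#' @param ref_color,het_color,hom_color,missing_color override the defaults.
#' @return character vector of colors.
#' @export
cell_color_genotype <- function(a0, a1, ref, ref_color = NULL,
                                het_color = NULL, hom_color = NULL,
                                missing_color = NULL) {
  pal <- render_options()$palette
  rc <- if (is.null(ref_color)) pal$geno_ref else ref_color
  yc <- if (is.null(het_color)) pal$geno_het else het_color
  hc <- if (is.null(hom_color)) pal$geno_hom else hom_color
  wc <- if (is.null(missing_color)) pal$missing else missing_color
  if (any(is.na(ref))) stop("reference base must be non-missing",
                            call. = FALSE)
  out <- ifelse(a0 == a1, ifelse(a0 == ref, rc, hc), yc)
  out[is.na(a0) | is.na(a1)] <- wc
  out
}

#' Color for an annotation value
#'
#' Numerical values are mapped by linear interpolation onto a two-color
#' gradient over the column's value range; categorical labels get a stable
#' color in first-seen order from a qualitative palette. Absent values are
#' white.
#'
#' @param values vector of annotation values.
#' @param kind `"numerical"` or `"categorical"`.
#' @param opts a [render_options()] list (supplies gradient and palette).
#' @param domain for numerical columns, the `c(min, max)` of the full
#'   column (default: range of `values`).
#' @param categories for categorical columns, the labels in first-seen
#'   order of the full column (default: first-seen order of `values`).
#' @return character vector of colors.
#' @export
meta_color <- function(values, kind = c("numerical", "categorical"),
                       opts = render_options(), domain = NULL,
                       categories = NULL) {
  kind <- match.arg(kind)
  miss <- opts$palette$missing
  if (kind == "numerical") {
    values <- as.numeric(values)
    if (is.null(domain)) domain <- range(values, na.rm = TRUE)
    if (!any(is.finite(domain))) return(rep(miss, length(values)))
    span <- domain[2L] - domain[1L]
    t <- if (span == 0) rep(0, length(values))
         else pmin(1, pmax(0, (values - domain[1L]) / span))
    ramp <- grDevices::colorRamp(opts$gradient)
    out <- rep(miss, length(values))
    ok <- !is.na(t)
    if (any(ok)) {
      rgbm <- ramp(t[ok])
      out[ok] <- grDevices::rgb(rgbm[, 1L], rgbm[, 2L], rgbm[, 3L],
                                maxColorValue = 255)
    }
    out
  } else {
    values <- as.character(values)
    if (is.null(categories)) categories <- unique(values[!is.na(values)])
    pal <- rep_len(opts$category_colors, max(1L, length(categories)))
    out <- pal[match(values, categories)]
    out[is.na(out)] <- miss
    out
  }
}

# scale a color's HSV saturation by floor + (1 - floor) * f
saturate_color <- function(color, f, floor = 0.15) {
  hsv_m <- grDevices::rgb2hsv(grDevices::col2rgb(color))
  mult <- floor + (1 - floor) * pmin(1, pmax(0, f))
  grDevices::hsv(hsv_m[1L, ], hsv_m[2L, ] * mult, hsv_m[3L, ])
}

## ---- canvas assembly --------------------------------------------------

#' Render a haplotype or aggregated matrix to a pixel canvas
#'
#' Produces a deterministic in-memory canvas: a heatmap-style grid of
#' `n_rows x (n_variants x allele columns)` cells (one column per SNV for
#' the genotype encoding), a "P/M" marker row under the grid for phased
#' data, subject annotation columns to the right of the grid and variant
#' annotation rows below it. For an [aggregate_rows()] result each cell
#' shows the consensus base in the chosen encoding, displayed either with
#' frequency-scaled saturation or as a bottom-anchored bar of height
#' `round(frequency * cell_h)`; rows are labelled with their `AGN` group
#' labels. Canvas dimensions are exact affine functions of the matrix
#' shape and cell sizes (see the `layout` element).
#'
#' @param x a [hap_matrix] or an `agg_matrix` from [aggregate_rows()].
#' @param subject_meta,variant_meta optional [meta_table]s; for aggregated
#'   input, subject annotations are summarized per group (mode for
#'   categorical columns, mean for numerical).
#' @param opts a [render_options()] list.
#' @param selection optional list with integer vectors `rows` and/or
#'   `cols` (display rows / variant indices) to outline in the selection
#'   color.
#' @return an object of class `hap_canvas`: list with `raster`
#'   (height x width x 3 array in `[0,1]`), `width`, `height`, `layout`,
#'   `rects`, `texts`, `opts`.
#' @export
render_matrix <- function(x, subject_meta = NULL, variant_meta = NULL,
                          opts = render_options(), selection = NULL) {
  stopifnot(inherits(opts, "render_options"))
  is_agg <- inherits(x, "agg_matrix")
  if (!is_agg && !inherits(x, "hap_matrix")) {
    stop("x must be a hap_matrix or agg_matrix", call. = FALSE)
  }
  if (is_agg && opts$encoding == "genotype") {
    stop("the genotype encoding is per subject and cannot display ",
         "aggregated consensus cells; use nucleotide or reference",
         call. = FALSE)
  }
  m <- nrow(x$variants)
  p <- x$n_allele_columns
  n_rows <- if (is_agg) nrow(x$groups) else x$n_subjects
  p_disp <- if (opts$encoding == "genotype") 1L else p
  n_cols <- m * p_disp
  if (n_rows == 0L || n_cols == 0L) {
    stop("cannot render a zero-size matrix (", n_rows, " rows x ",
         n_cols, " display columns)", call. = FALSE)
  }
  cw <- opts$cell_w; ch <- opts$cell_h; gap <- opts$gap
  pm_row <- x$phased && p_disp == 2L
  n_smeta <- n_meta(subject_meta)
  n_vmeta <- n_meta(variant_meta)
  row_ids <- if (is_agg) x$groups$label else x$subject_ids

  left_margin <- if (opts$show_ids) {
    as.integer(6L * max(nchar(row_ids)) + 6L)
  } else 0L
  top_margin <- if (opts$show_ids) {
    as.integer(6L * max(nchar(x$variants$id)) + 6L)
  } else 0L

  grid_w <- n_cols * cw
  grid_h <- n_rows * ch
  width <- left_margin + grid_w +
    (if (n_smeta > 0L) gap + n_smeta * cw else 0L)
  height <- top_margin + grid_h +
    (if (pm_row) gap + ch else 0L) +
    (if (n_vmeta > 0L) gap + n_vmeta * ch else 0L)

  rects <- new_rect_list()
  texts <- data.frame(x = numeric(0), y = numeric(0),
                      label = character(0), srt = numeric(0))

  gx <- function(col) left_margin + (col - 1L) * cw  # left px of display col
  gy <- function(row) top_margin + (row - 1L) * ch   # top px of display row

  ## -- haplotype grid cells
  if (is_agg) {
    base_color <- array("", dim = c(n_rows, m, p))
    for (k in seq_len(p)) {
      cons_k <- x$consensus[, , k, drop = FALSE]
      dim(cons_k) <- c(n_rows, m)
      base_color[, , k] <- switch(
        opts$encoding,
        nucleotide = cell_color_nucleotide(
          cons_k, opts$palette$nucleotide, opts$palette$missing),
        reference = cell_color_reference(
          cons_k, rep(x$variants$ref, each = n_rows),
          opts$palette$ref_match, opts$palette$ref_diff,
          opts$palette$missing))
    }
    for (r in seq_len(n_rows)) for (j in seq_len(m)) for (k in seq_len(p)) {
      col_ix <- (j - 1L) * p + k
      f <- x$frequency[r, j, k]
      colr <- base_color[r, j, k]
      x0 <- gx(col_ix); y0 <- gy(r)
      if (is.na(f)) {           # all-missing cell
        rects <- add_rect(rects, x0, y0, cw, ch, opts$palette$missing)
      } else if (opts$aggregate_mode == "saturation") {
        rects <- add_rect(rects, x0, y0, cw, ch,
                          saturate_color(colr, f, opts$saturation_floor))
      } else {
        fh <- if (opts$rarity_bars) 1 - f else f
        bh <- as.integer(round(fh * ch))
        rects <- add_rect(rects, x0, y0, cw, ch, opts$palette$background)
        if (bh > 0L) {
          rects <- add_rect(rects, x0, y0 + ch - bh, cw, bh, colr)
        }
      }
    }
  } else {
    calls <- hap_calls(x)
    if (opts$encoding == "genotype") {
      a0 <- calls[, , 1L]
      a1 <- if (p >= 2L) calls[, , 2L] else calls[, , 1L]
      colors <- cell_color_genotype(
        a0, a1, rep(x$variants$ref, each = n_rows),
        opts$palette$geno_ref, opts$palette$geno_het,
        opts$palette$geno_hom, opts$palette$missing)
      colors <- matrix(colors, n_rows, m)
      for (r in seq_len(n_rows)) for (j in seq_len(m)) {
        rects <- add_rect(rects, gx(j), gy(r), cw, ch, colors[r, j])
      }
    } else {
      for (k in seq_len(p)) {
        a <- calls[, , k]
        colors <- switch(
          opts$encoding,
          nucleotide = cell_color_nucleotide(
            a, opts$palette$nucleotide, opts$palette$missing),
          reference = cell_color_reference(
            a, rep(x$variants$ref, each = n_rows),
            opts$palette$ref_match, opts$palette$ref_diff,
            opts$palette$missing))
        colors <- matrix(colors, n_rows, m)
        for (r in seq_len(n_rows)) for (j in seq_len(m)) {
          rects <- add_rect(rects, gx((j - 1L) * p + k), gy(r), cw, ch,
                            colors[r, j])
        }
      }
    }
  }

  ## -- P/M marker row
  pm_y <- top_margin + grid_h + gap
  if (pm_row) {
    for (j in seq_len(m)) for (k in 1:2) {
      x0 <- gx((j - 1L) * 2L + k)
      rects <- add_rect(rects, x0, pm_y, cw, ch, opts$palette$pm[k])
      texts <- rbind(texts, data.frame(
        x = x0 + cw / 2, y = pm_y + ch / 2,
        label = c("P", "M")[k], srt = 0))
    }
  }

  ## -- variant annotation rows (below grid / P-M row)
  vmeta_y0 <- top_margin + grid_h + (if (pm_row) gap + ch else 0L) + gap
  if (n_vmeta > 0L) {
    for (mi in seq_len(n_vmeta)) {
      colname <- names(variant_meta$data)[mi]
      kind <- variant_meta$kinds[mi]
      all_vals <- variant_meta$data[[mi]]
      vals <- meta_values(variant_meta, colname, x$variants$id)
      colors <- if (kind == "numerical") {
        meta_color(vals, "numerical", opts,
                   domain = suppressWarnings(range(all_vals, na.rm = TRUE)))
      } else {
        meta_color(vals, "categorical", opts,
                   categories = unique(all_vals[!is.na(all_vals)]))
      }
      y0 <- vmeta_y0 + (mi - 1L) * ch
      for (j in seq_len(m)) {
        rects <- add_rect(rects, gx((j - 1L) * p_disp + 1L), y0,
                          cw * p_disp, ch, colors[j])
      }
    }
  }

  ## -- subject annotation columns (right of grid)
  smeta_x0 <- left_margin + grid_w + gap
  if (n_smeta > 0L) {
    for (mi in seq_len(n_smeta)) {
      colname <- names(subject_meta$data)[mi]
      kind <- subject_meta$kinds[mi]
      all_vals <- subject_meta$data[[mi]]
      vals <- if (is_agg) {
        vapply(x$members, function(ids) {
          v <- meta_values(subject_meta, colname, ids)
          if (kind == "numerical") {
            aggregate_meta_column(v, "numerical", "mean")
          } else {
            as.vector(aggregate_meta_column(v, "categorical", "mode"))
          }
        }, if (kind == "numerical") numeric(1L) else character(1L))
      } else {
        meta_values(subject_meta, colname, x$subject_ids)
      }
      colors <- if (kind == "numerical") {
        meta_color(vals, "numerical", opts,
                   domain = suppressWarnings(range(all_vals, na.rm = TRUE)))
      } else {
        meta_color(vals, "categorical", opts,
                   categories = unique(all_vals[!is.na(all_vals)]))
      }
      x0 <- smeta_x0 + (mi - 1L) * cw
      for (r in seq_len(n_rows)) {
        rects <- add_rect(rects, x0, gy(r), cw, ch, colors[r])
      }
    }
  }

  ## -- selection outlines (whole-row / whole-column bands)
  if (!is.null(selection)) {
    for (r in selection$rows %||% integer(0)) {
      rects <- add_frame(rects, left_margin, gy(r), grid_w, ch,
                         opts$selection_color)
    }
    for (j in selection$cols %||% integer(0)) {
      rects <- add_frame(rects, gx((j - 1L) * p_disp + 1L), top_margin,
                         cw * p_disp, grid_h, opts$selection_color)
    }
  }

  ## -- identifier labels
  if (opts$show_ids) {
    texts <- rbind(texts,
      data.frame(x = left_margin - 3, y = gy(seq_len(n_rows)) + ch / 2,
                 label = row_ids, srt = 0),
      data.frame(x = gx((seq_len(m) - 1L) * p_disp + 1L) + p_disp * cw / 2,
                 y = top_margin - 3, label = x$variants$id, srt = 90))
  }

  rects_df <- finish_rect_list(rects)
  raster <- rasterize_rects(rects_df, width, height,
                            opts$palette$background)
  structure(list(
    raster = raster, width = width, height = height,
    layout = list(
      cell_w = cw, cell_h = ch, gap = gap,
      n_rows = n_rows, n_cols = n_cols, n_variants = m, p_disp = p_disp,
      left_margin = left_margin, top_margin = top_margin,
      grid_w = grid_w, grid_h = grid_h,
      pm_row = pm_row, n_subject_meta = n_smeta, n_variant_meta = n_vmeta,
      row_ids = row_ids, variant_ids = x$variants$id),
    rects = rects_df, texts = texts, opts = opts),
    class = "hap_canvas")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_rect_list <- function() {
  list(x0 = list(), y0 = list(), w = list(), h = list(), col = list(),
       frame = list())
}

add_rect <- function(r, x0, y0, w, h, col, frame = FALSE) {
  i <- length(r$x0) + 1L
  r$x0[[i]] <- x0; r$y0[[i]] <- y0; r$w[[i]] <- w; r$h[[i]] <- h
  r$col[[i]] <- col; r$frame[[i]] <- frame
  r
}

add_frame <- function(r, x0, y0, w, h, col) {
  add_rect(r, x0, y0, w, h, col, frame = TRUE)
}

finish_rect_list <- function(r) {
  data.frame(x0 = unlist(r$x0), y0 = unlist(r$y0),
             w = unlist(r$w), h = unlist(r$h),
             col = unlist(r$col), frame = unlist(r$frame),
             stringsAsFactors = FALSE)
}

# paint the rect display list into a height x width x 3 array in [0,1];
# y grows downward, rect (x0, y0) is the top-left corner in pixel units
rasterize_rects <- function(rects, width, height, background) {
  raster <- array(0, dim = c(height, width, 3L))
  bg <- grDevices::col2rgb(background) / 255
  for (ch in 1:3) raster[, , ch] <- bg[ch]
  if (!nrow(rects)) return(raster)
  rgb_m <- grDevices::col2rgb(rects$col) / 255
  for (i in seq_len(nrow(rects))) {
    xs <- (rects$x0[i] + 1L):(rects$x0[i] + rects$w[i])
    ys <- (rects$y0[i] + 1L):(rects$y0[i] + rects$h[i])
    if (rects$frame[i]) {
      edge_x <- c(xs[1L], xs[length(xs)])
      edge_y <- c(ys[1L], ys[length(ys)])
      for (ch in 1:3) {
        raster[ys, edge_x, ch] <- rgb_m[ch, i]
        raster[edge_y, xs, ch] <- rgb_m[ch, i]
      }
    } else {
      for (ch in 1:3) raster[ys, xs, ch] <- rgb_m[ch, i]
    }
  }
  raster
}

#' @export
print.hap_canvas <- function(x, ...) {
  cat(sprintf("hap_canvas: %d x %d px, %d cell rect(s), encoding %s\n",
              x$width, x$height, nrow(x$rects), x$opts$encoding))
  invisible(x)
}

## ---- canvas probing ---------------------------------------------------

#' Pixel color at a canvas coordinate
#'
#' @param canvas a `hap_canvas`.
#' @param x,y pixel coordinates, 1-based from the top-left corner.
#' @return hex color string.
#' @export
canvas_pixel <- function(canvas, x, y) {
  stopifnot(inherits(canvas, "hap_canvas"))
  if (x < 1L || x > canvas$width || y < 1L || y > canvas$height) {
    stop("pixel coordinate out of canvas", call. = FALSE)
  }
  grDevices::rgb(canvas$raster[y, x, 1L], canvas$raster[y, x, 2L],
                 canvas$raster[y, x, 3L])
}

#' Pixel coordinates of a grid cell's center
#'
#' @param canvas a `hap_canvas`.
#' @param row display row index.
#' @param variant variant index.
#' @param allele_column allele-column index (ignored for the genotype
#'   encoding, which has one display column per SNV).
#' @return integer vector `c(x, y)`.
#' @export
cell_center <- function(canvas, row, variant, allele_column = 1L) {
  stopifnot(inherits(canvas, "hap_canvas"))
  L <- canvas$layout
  k <- if (L$p_disp == 1L) 1L else allele_column
  col <- (variant - 1L) * L$p_disp + k
  if (row < 1L || row > L$n_rows || col < 1L || col > L$n_cols) {
    stop("cell index out of range", call. = FALSE)
  }
  c(x = as.integer(L$left_margin + (col - 1L) * L$cell_w +
                     ceiling(L$cell_w / 2)),
    y = as.integer(L$top_margin + (row - 1L) * L$cell_h +
                     ceiling(L$cell_h / 2)))
}
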