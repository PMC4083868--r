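# A 3-subject x 5-SNV handcrafted matrix with known calls per cell,
# used by the pixel-probe checks.
probe_fixture <- function() {
  calls <- array(NA_character_, dim = c(3L, 5L, 2L))
  #              s1        s2        s3          (per variant, cols P/M)
  calls[, 1, 1] <- c("C", "C", "G"); calls[, 1, 2] <- c("G", "C", "G")
  calls[, 2, 1] <- c("A", "T", "A"); calls[, 2, 2] <- c("A", "A", "T")
  calls[, 3, 1] <- c("T", "T", "T"); calls[, 3, 2] <- c("T", "T", "T")
  calls[, 4, 1] <- c(NA, "G", "A"); calls[, 4, 2] <- c(NA, NA, "A")
  calls[, 5, 1] <- c("C", "C", "C"); calls[, 5, 2] <- c("C", "G", "C")
  v <- data.frame(id = paste0("rs", 1:5), chrom = "9",
                  pos = seq(10L, 50L, by = 10L),
                  ref = c("C", "A", "T", "A", "C"),
                  alt = c("G", "T", "A", "G", "G"),
                  stringsAsFactors = FALSE)
  hap_matrix(calls, c("s1", "s2", "s3"), v, phased = TRUE)
}

test_that("the three color encodings follow their rules", {
  pal <- render_options()$palette
  # nucleotide: fixed base colors, missing white
  expect_identical(cell_color_nucleotide(c("A", "C", "G", "T")),
                   unname(pal$nucleotide[c("A", "C", "G", "T")]))
  expect_identical(cell_color_nucleotide(NA_character_), pal$missing)
  custom <- c(A = "#111111", C = "#222222", G = "#333333", T = "#444444")
  expect_identical(cell_color_nucleotide("G", palette = custom), "#333333")
  # reference: equal blue, different yellow, missing white
  expect_identical(cell_color_reference("G", "C"), pal$ref_diff)
  expect_identical(cell_color_reference("C", "C"), pal$ref_match)
  expect_identical(cell_color_reference(NA_character_, "C"), pal$missing)
  # genotype: both-ref green, hom-alt red, het yellow, missing white
  expect_identical(cell_color_genotype("C", "C", "C"), pal$geno_ref)
  expect_identical(cell_color_genotype("G", "G", "C"), pal$geno_hom)
  expect_identical(cell_color_genotype("C", "G", "C"), pal$geno_het)
  expect_identical(cell_color_genotype("C", NA, "C"), pal$missing)
})

test_that("annotation colors interpolate and assign stably", {
  opts <- render_options()
  # numerical: endpoints hit the gradient ends
  cols <- meta_color(c(0, 5, 10), "numerical", opts, domain = c(0, 10))
  expect_identical(cols[1], toupper(opts$gradient[1]))
  expect_identical(cols[3], toupper(opts$gradient[2]))
  expect_identical(meta_color(NA_real_, "numerical", opts,
                              domain = c(0, 1)), opts$palette$missing)
  # categorical: equal labels equal colors, first-seen order
  labs <- c("CEU", "YRI", "CEU", "TSI", "YRI")
  cols <- meta_color(labs, "categorical", opts)
  expect_identical(cols[1], cols[3])
  expect_identical(cols[2], cols[5])
  expect_identical(cols[1:2], opts$category_colors[1:2])
  expect_identical(cols, meta_color(labs, "categorical", opts,
                                    categories = c("CEU", "YRI", "TSI")))
})

test_that("canvas layout is an exact affine function of the shape", {
  M <- probe_fixture()
  smeta <- make_pop_meta(M)
  vmeta <- meta_table(M$variants$id,
                      data.frame(Gene = rep("G1", 5)),
                      kinds = "categorical", axis = "variant")
  opts <- render_options(cell_w = 10L, cell_h = 8L, gap = 2L)
  cv <- render_matrix(M, smeta, vmeta, opts)
  # width = grid (5 SNVs x 2 columns) + gap + 1 subject meta column
  expect_identical(cv$width, 5L * 2L * 10L + 2L + 10L)
  # height = 3 rows + gap + P/M row + gap + 1 variant meta row
  expect_identical(cv$height, 3L * 8L + 2L + 8L + 2L + 8L)
  expect_identical(dim(cv$raster), c(cv$height, cv$width, 3L))
  # genotype encoding collapses to one column per SNV, no P/M row
  cvg <- render_matrix(M, opts = render_options(encoding = "genotype",
                                                cell_w = 10L, cell_h = 8L))
  expect_identical(cvg$width, 5L * 10L)
  expect_identical(cvg$height, 3L * 8L)
  expect_error(render_matrix(hap_slice(M, variants = integer(0))),
               "zero-size")
})

test_that("pixel probes confirm all three encodings on the raster", {
  M <- probe_fixture()
  calls <- hap_calls(M)
  pal <- render_options()$palette
  # nucleotide
  cvn <- render_matrix(M, opts = render_options(encoding = "nucleotide"))
  for (i in 1:3) for (j in 1:5) for (k in 1:2) {
    a <- calls[i, j, k]
    want <- if (is.na(a)) pal$missing else unname(pal$nucleotide[a])
    expect_identical(hex_at(cvn, i, j, k), want)
  }
  # reference
  cvr <- render_matrix(M, opts = render_options(encoding = "reference"))
  for (i in 1:3) for (j in 1:5) for (k in 1:2) {
    a <- calls[i, j, k]
    want <- if (is.na(a)) pal$missing
            else if (a == M$variants$ref[j]) pal$ref_match else pal$ref_diff
    expect_identical(hex_at(cvr, i, j, k), want)
  }
  # genotype
  cvg <- render_matrix(M, opts = render_options(encoding = "genotype"))
  for (i in 1:3) for (j in 1:5) {
    a0 <- calls[i, j, 1]; a1 <- calls[i, j, 2]; ref <- M$variants$ref[j]
    want <- if (is.na(a0) || is.na(a1)) pal$missing
            else if (a0 == a1 && a0 == ref) pal$geno_ref
            else if (a0 == a1) pal$geno_hom else pal$geno_het
    expect_identical(hex_at(cvg, i, j), want)
  }
  # P/M marker row sits below the grid with its two colors
  L <- cvn$layout
  expect_true(L$pm_row)
  y <- L$grid_h + L$gap + 1L + L$cell_h %/% 2L
  expect_identical(canvas_pixel(cvn, L$cell_w %/% 2L, y), pal$pm[1])
  expect_identical(canvas_pixel(cvn, L$cell_w + L$cell_w %/% 2L, y),
                   pal$pm[2])
})

test_that("aggregate bar heights equal round(frequency x cell height)", {
  set.seed(21)
  # 10 members with a controlled base mix at one site
  mk_freq_matrix <- function(n_alt) {
    calls <- array("C", dim = c(10L, 1L, 2L))
    if (n_alt > 0) calls[seq_len(n_alt), 1, 1] <- "G"
    hap_matrix(calls, paste0("s", 1:10),
               data.frame(id = "v", chrom = "1", pos = 1L,
                          ref = "C", alt = "G"))
  }
  ch <- 12L
  pal <- render_options()$palette
  for (n_alt in c(0L, 3L, 5L, 9L)) {
    M <- mk_freq_matrix(n_alt)
    A <- aggregate_rows(M, list(all = 1:10), "maximum")
    f <- A$frequency[1, 1, 1]
    expect_equal(f, max(n_alt, 10 - n_alt) / 10)
    cv <- render_matrix(
      A, opts = render_options(encoding = "nucleotide",
                               aggregate_mode = "bar", cell_h = ch))
    # count colored (non-background) pixels down the first cell's column
    x <- cell_center(cv, 1, 1, 1)["x"]
    col_px <- vapply(seq_len(ch), function(y) canvas_pixel(cv, x, y),
                     character(1))
    bar <- sum(col_px != pal$background)
    expect_identical(bar, as.integer(round(f * ch)))
    # bottom-anchored: colored pixels are the lowest ones
    if (bar > 0) {
      expect_true(all(col_px[(ch - bar + 1):ch] != pal$background))
    }
    # rarity inversion flips the height
    cvr <- render_matrix(
      A, opts = render_options(encoding = "nucleotide",
                               aggregate_mode = "bar", rarity_bars = TRUE,
                               cell_h = ch))
    col_px_r <- vapply(seq_len(ch), function(y) canvas_pixel(cvr, x, y),
                       character(1))
    expect_identical(sum(col_px_r != pal$background),
                     as.integer(round((1 - f) * ch)))
  }
})

test_that("saturation mode is monotone in the consensus frequency", {
  sat_of <- function(hex) {
    unname(grDevices::rgb2hsv(grDevices::col2rgb(hex))[2, 1])
  }
  # consensus C at increasing frequency; remaining calls spread over other
  # bases so C stays the most frequent base
  mixes <- list(c("C", 4, "G", 3, "T", 2, "A", 1),
                c("C", 6, "G", 2, "T", 1, "A", 1),
                c("C", 8, "G", 1, "T", 1),
                c("C", 10))
  sats <- vapply(mixes, function(mix) {
    bases <- rep(mix[c(TRUE, FALSE)], times = as.integer(mix[c(FALSE, TRUE)]))
    calls <- array("C", dim = c(10L, 1L, 2L))
    calls[, 1, 1] <- bases
    M <- hap_matrix(calls, paste0("s", 1:10),
                    data.frame(id = "v", chrom = "1", pos = 1L,
                               ref = "C", alt = "G"))
    A <- aggregate_rows(M, list(all = 1:10), "maximum")
    expect_identical(A$consensus[1, 1, 1], "C")
    cv <- render_matrix(A, opts = render_options(
      encoding = "nucleotide", aggregate_mode = "saturation"))
    sat_of(hex_at(cv, 1, 1, 1))
  }, numeric(1))
  expect_true(all(diff(sats) > 0))
  # full agreement renders the pure base color
  expect_equal(sats[4],
               sat_of(render_options()$palette$nucleotide[["C"]]),
               tolerance = 1e-6)
})

test_that("rendering is deterministic and exports to all five formats", {
  M <- probe_fixture()
  smeta <- make_pop_meta(M)
  opts <- render_options(encoding = "nucleotide")
  cv1 <- render_matrix(M, smeta, opts = opts)
  cv2 <- render_matrix(M, smeta, opts = opts)
  expect_identical(cv1$raster, cv2$raster)
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  export_image(cv1, p1); export_image(cv2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # PNG reopens with the canvas dimensions (and scales up exactly)
  img <- png::readPNG(p1)
  expect_identical(dim(img)[1:2], c(cv1$height, cv1$width))
  p3 <- tempfile(fileext = ".png")
  export_image(cv1, p3, scale = 3L)
  expect_identical(dim(png::readPNG(p3))[1:2],
                   c(cv1$height * 3L, cv1$width * 3L))
  # all five formats yield nonempty files
  for (fmt in c("png", "jpeg", "tiff", "svg", "pdf")) {
    fp <- tempfile(fileext = paste0(".", fmt))
    export_image(cv1, fp, fmt)
    expect_gt(file.size(fp), 0)
  }
  expect_error(export_image(cv1, tempfile(), "bmp"), "SVG")
})

test_that("sub-region export windows scale with the selection", {
  M <- probe_fixture()
  cv <- render_matrix(M, opts = render_options(encoding = "nucleotide",
                                               cell_w = 10L, cell_h = 10L))
  f2 <- tempfile(fileext = ".png"); f4 <- tempfile(fileext = ".png")
  export_image(cv, f2, region = list(rows = 1:2, variants = 1:2))
  export_image(cv, f4, region = list(rows = 1:2, variants = 1:4))
  d2 <- dim(png::readPNG(f2)); d4 <- dim(png::readPNG(f4))
  expect_identical(d2[1:2], c(2L * 10L, 2L * 2L * 10L))
  expect_identical(d4[2] / d2[2], 2)  # width doubles with variant count
  # vector sub-region export also works
  fs <- tempfile(fileext = ".svg")
  export_image(cv, fs, region = list(rows = 1:2, variants = 1:2))
  expect_gt(file.size(fs), 0)
  expect_error(export_image(cv, tempfile(fileext = ".png"),
                            region = list(rows = 0:1)), "out of range")
})

test_that("selection outlines and YAML-configured options are honored", {
  M <- probe_fixture()
  opts <- render_options(encoding = "nucleotide", cell_w = 8L, cell_h = 8L)
  cv <- render_matrix(M, opts = opts, selection = list(rows = 2L))
  # default selection color is black: top-left corner pixel of row 2's band
  expect_identical(canvas_pixel(cv, 1L, 8L + 1L), "#000000")
  # YAML round trip of options
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("encoding: reference", "cell_w: 5", "cell_h: 7",
               "aggregate_mode: bar",
               "palette:", "  ref_diff: '#ABCDEF'"), yml)
  o <- render_options_from_yaml(yml)
  expect_identical(o$encoding, "reference")
  expect_identical(o$cell_w, 5L)
  expect_identical(o$palette$ref_diff, "#ABCDEF")
  expect_identical(o$palette$ref_match, render_options()$palette$ref_match)
  writeLines("no_such_option: 1", yml)
  expect_error(render_options_from_yaml(yml), "unknown render option")
})
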