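#' Read an IMPUTE2 hap/legend/sample triple
#'
#' The IMPUTE2 haplotype text format stores one variant per hap-file row as
#' space-separated 0/1 tokens, two columns per subject (haplotype columns
#' `2s` and `2s+1` become subject `s`'s allele columns 1 and 2); the legend
#' file (header `id position a0 a1`) gives the variant identity; the sample
#' file lists subject identifiers. Token `0` maps to the `a0` allele, `1`
#' to `a1`, and `?` to a missing call. The result is always phased.
#'
#' @param hap_path haplotype file (0/1 tokens; plain or gzip).
#' @param legend_path legend file with header `id position a0 a1`.
#' @param sample_path sample file; the first column of each data line is
#'   used as the subject identifier (an IMPUTE2-style two-header `ID_1`
#'   file has its `0 0 0` type line skipped automatically).
#' @param chrom chromosome label to assign to all variants (the legend
#'   format does not carry one). Default `"1"`.
#' @return a [hap_matrix], phased.
#' @export
read_impute2 <- function(hap_path, legend_path, sample_path, chrom = "1") {
  legend_lines <- read_lines_maybe_gz(legend_path)
  legend_lines <- legend_lines[nzchar(trimws(legend_lines))]
  if (length(legend_lines) < 1L) {
    stop("legend file is empty: ", legend_path, call. = FALSE)
  }
  hdr <- strsplit(trimws(legend_lines[1L]), "[ \t]+")[[1L]]
  if (!all(c("id", "position", "a0", "a1") %in% tolower(hdr))) {
    stop("legend header must contain: id position a0 a1", call. = FALSE)
  }
  cols <- match(c("id", "position", "a0", "a1"), tolower(hdr))
  leg <- do.call(rbind, strsplit(trimws(legend_lines[-1L]), "[ \t]+"))
  if (is.null(leg)) leg <- matrix(character(0), ncol = length(hdr))
  leg <- matrix(leg[, cols], ncol = 4L)

  subj <- read_impute2_samples(sample_path)

  hap_lines <- read_lines_maybe_gz(hap_path)
  hap_lines <- hap_lines[nzchar(trimws(hap_lines))]
  if (length(hap_lines) != nrow(leg)) {
    stop("hap file has ", length(hap_lines), " rows but legend has ",
         nrow(leg), " data rows", call. = FALSE)
  }
  toks <- strsplit(trimws(hap_lines), "[ \t]+")
  n_hap_cols <- if (length(toks)) length(toks[[1L]]) else 2L * length(subj)
  if (any(lengths(toks) != n_hap_cols)) {
    stop("ragged hap file: rows differ in column count", call. = FALSE)
  }
  if (n_hap_cols != 2L * length(subj)) {
    stop("hap file has ", n_hap_cols, " haplotype columns but sample file ",
         "lists ", length(subj), " subjects (expected ",
         2L * length(subj), " columns)", call. = FALSE)
  }

  nv <- length(toks); ns <- length(subj)
  tok <- matrix(unlist(toks), nrow = n_hap_cols)       # hap col x variant
  bad <- !tok %in% c("0", "1", "?")
  if (any(bad)) {
    stop("invalid hap token '", tok[bad][1L],
         "' (expected 0, 1 or ?)", call. = FALSE)
  }
  a0 <- leg[, 3L]; a1 <- leg[, 4L]
  vj <- rep(seq_len(nv), each = n_hap_cols)
  vals <- rep(NA_character_, length(tok))
  vals[tok == "0"] <- a0[vj][tok == "0"]
  vals[tok == "1"] <- a1[vj][tok == "1"]
  # tok matrix is (hap col, variant); reshape to subject x variant x 2
  arr <- array(vals, dim = c(2L, ns, nv))
  calls <- aperm(arr, c(2L, 3L, 1L))
  variants <- data.frame(
    id = leg[, 1L], chrom = chrom, pos = as.integer(leg[, 2L]),
    ref = a0, alt = a1, stringsAsFactors = FALSE)
  hap_matrix(calls, subj, variants, phased = TRUE)
}

read_impute2_samples <- function(sample_path) {
  lines <- read_lines_maybe_gz(sample_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) {
    stop("sample file is empty: ", sample_path, call. = FALSE)
  }
  first <- vapply(strsplit(trimws(lines), "[ \t]+"), `[`, character(1L), 1L)
  if (tolower(first[1L]) %in% c("id_1", "id", "sample")) {
    first <- first[-1L]
    if (length(first) && first[1L] == "0") first <- first[-1L]  # type line
  }
  if (!length(first)) stop("sample file lists no subjects", call. = FALSE)
  first
}

#' Write a haplotype matrix as an IMPUTE2 triple
#'
#' Inverse of [read_impute2()] for phased two-column matrices: the legend's
#' `a0`/`a1` are the matrix `ref`/`alt`, hap tokens are 0 (ref), 1 (alt) or
#' `?` (missing).
#'
#' @param M a phased [hap_matrix] with two allele columns.
#' @param hap_path,legend_path,sample_path output file paths.
#' @return invisibly, a named list of the three paths.
#' @export
write_impute2 <- function(M, hap_path, legend_path, sample_path) {
  stopifnot(inherits(M, "hap_matrix"))
  if (M$n_allele_columns != 2L) {
    stop("IMPUTE2 output requires two allele columns", call. = FALSE)
  }
  v <- M$variants
  writeLines(c("id position a0 a1",
               paste(v$id, v$pos, v$ref, v$alt)), legend_path)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(M$subject_ids, M$subject_ids, "0")), sample_path)
  rows <- character(M$n_variants)
  if (M$n_variants > 0L) {
    calls <- hap_calls(M)
    for (j in seq_len(M$n_variants)) {
      tok <- character(2L * M$n_subjects)
      for (i in seq_len(M$n_subjects)) {
        for (k in 1:2) {
          a <- calls[i, j, k]
          tok[2L * (i - 1L) + k] <-
            if (is.na(a)) "?" else if (a == v$ref[j]) "0" else "1"
        }
      }
      rows[j] <- paste(tok, collapse = " ")
    }
  }
  writeLines(rows, hap_path)
  invisible(list(hap = hap_path, legend = legend_path, sample = sample_path))
}
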