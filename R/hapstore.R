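#' @title Compressed haplotype matrix
#'
#' @description
#' A `hap_matrix` holds the allele calls of `n_subjects` subjects at
#' `n_variants` single-nucleotide variants, with one or two allele columns
#' per variant (two for phased or diploid data: the left/paternal and
#' right/maternal allele; one for a haploid view). Calls are stored packed
#' at two bits per allele in a raw-byte payload, plus a one-bit-per-call
#' missingness mask, so a diploid call costs four payload bits — an
#' eight-fold saving over the naive two-bytes-per-character representation.
#'
#' The object is immutable: all transformations ([hap_slice()], the filters,
#' the sorts) return new objects. Decompression is lazy — [hap_calls()] and
#' [get_allele()] decode only the requested cells; no global decompressed
#' copy is ever materialized by the package itself.
#'
#' Linear cell order is subject-major: allele column fastest, then variant,
#' then subject.
#'
#' @param calls three-dimensional character array
#'   (subjects x variants x allele columns) with entries `"A"`, `"C"`,
#'   `"G"`, `"T"` or `NA` (missing).
#' @param subject_ids character vector of unique subject identifiers,
#'   length `dim(calls)[1]`.
#' @param variants data frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per variant; `ref`/`alt` non-missing bases,
#'   `ref != alt`, `pos >= 1`, unique `id`).
#' @param phased logical; `TRUE` requires two allele columns.
#'
#' @details Variants are kept sorted by `(chrom, pos)` (ties broken by id)
#' at construction; `calls` columns are reordered accordingly.
#'
#' @return an object of class `hap_matrix`.
#' @examples
#' calls <- array(c("C", "G"), dim = c(1, 1, 2))
#' v <- data.frame(id = "rs1", chrom = "2", pos = 100, ref = "C", alt = "G")
#' m <- hap_matrix(calls, "S1", v, phased = TRUE)
#' get_allele(m, 1, 1, 2)
#' @export
hap_matrix <- function(calls, subject_ids, variants, phased = TRUE) {
  stopifnot(is.array(calls), length(dim(calls)) == 3L)
  d <- dim(calls)
  n <- d[1L]; m <- d[2L]; p <- d[3L]
  if (length(subject_ids) != n) {
    stop("length(subject_ids) must equal dim(calls)[1]", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique", call. = FALSE)
  }
  variants <- validate_variants(variants, m)
  if (phased && p != 2L) {
    stop("phased data requires exactly 2 allele columns", call. = FALSE)
  }
  if (!p %in% c(1L, 2L)) {
    stop("n_allele_columns must be 1 or 2", call. = FALSE)
  }

  ord <- order(variants$chrom, variants$pos, variants$id, method = "radix")
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  calls <- calls[, ord, , drop = FALSE]

  bad <- !is.na(calls) & !calls %in% ALLELE_BASES
  if (any(bad)) {
    stop("invalid allele symbol(s): ",
         paste(unique(calls[bad]), collapse = ", "), call. = FALSE)
  }

  flat <- aperm(calls, c(3L, 2L, 1L))   # allele col fastest, then variant, subject
  miss <- is.na(flat)
  codes <- integer(length(flat))
  codes[!miss] <- allele_to_code(flat[!miss])

  structure(
    list(
      subject_ids = as.character(subject_ids),
      variants = variants,
      n_subjects = n,
      n_variants = m,
      n_allele_columns = p,
      phased = isTRUE(phased),
      payload = pack_codes(codes),
      missing_mask = pack_mask(as.logical(miss))
    ),
    class = "hap_matrix"
  )
}

validate_variants <- function(variants, m) {
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!is.data.frame(variants) || !all(need %in% names(variants))) {
    stop("variants must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(variants) != m) {
    stop("nrow(variants) must equal dim(calls)[2]", call. = FALSE)
  }
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (m == 0L) return(variants[, need])
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  if (any(is.na(variants$pos)) || any(variants$pos < 1L)) {
    stop("variant positions must be integers >= 1 (1-based)", call. = FALSE)
  }
  if (!all(is_valid_base(variants$ref)) || !all(is_valid_base(variants$alt))) {
    stop("ref and alt must be non-missing bases (A/C/G/T)", call. = FALSE)
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt must differ for every variant", call. = FALSE)
  }
  variants[, need]
}

## ---- bit packing ------------------------------------------------------

# codes: integer vector in 0..3, element s stored at bits 2s, 2s+1 of the
# payload (little-endian within a byte, four codes per byte)
pack_codes <- function(codes) {
  n <- length(codes)
  if (n == 0L) return(raw(0))
  pad <- (4L - n %% 4L) %% 4L
  x <- matrix(c(codes, integer(pad)), nrow = 4L)
  as.raw(x[1L, ] + x[2L, ] * 4L + x[3L, ] * 16L + x[4L, ] * 64L)
}

unpack_codes <- function(payload, idx) {
  byte <- as.integer(payload[(idx - 1L) %/% 4L + 1L])
  off <- (idx - 1L) %% 4L
  (byte %/% 4L^off) %% 4L
}

pack_mask <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(raw(0))
  pad <- (8L - n %% 8L) %% 8L
  packBits(c(bits, logical(pad)), type = "raw")
}

unpack_mask <- function(mask, idx) {
  byte <- as.integer(mask[(idx - 1L) %/% 8L + 1L])
  off <- (idx - 1L) %% 8L
  (byte %/% 2L^off) %% 2L == 1L
}

# linear cell index for (subject i, variant j, allele column k), all 1-based
cell_index <- function(M, i, j, k) {
  ((i - 1L) * M$n_variants + (j - 1L)) * M$n_allele_columns + k
}

## ---- size accounting --------------------------------------------------

#' Payload size of the two-bit haplotype store
#'
#' Number of bits needed to store all allele calls at two bits per call:
#' `n_subjects * n_variants * n_allele_columns * 2`. For a diploid cohort of
#' 1000 subjects and four million variants this is 2 GByte of payload —
#' eight times less than [naive_size_bytes()] at two bytes per character.
#' The one-bit missingness mask is accounted separately (see
#' [mask_size_bits()]); the payload figure covers the allele codes alone.
#'
#' @param n_subjects,n_variants,n_allele_columns non-negative integers.
#' @return payload size in bits (numeric, to allow genome-scale products).
#' @examples
#' payload_size_bits(1e3, 4e6, 2) / 8 / 2^30  # GByte for a 1000-genomes-scale cohort
#' @export
payload_size_bits <- function(n_subjects, n_variants, n_allele_columns) {
  check_nonneg(n_subjects, n_variants, n_allele_columns)
  as.numeric(n_subjects) * as.numeric(n_variants) *
    as.numeric(n_allele_columns) * 2
}

#' Missingness-mask size in bits
#'
#' One bit per (subject, variant, allele column) cell.
#'
#' @inheritParams payload_size_bits
#' @return mask size in bits (numeric).
#' @export
mask_size_bits <- function(n_subjects, n_variants, n_allele_columns) {
  check_nonneg(n_subjects, n_variants, n_allele_columns)
  as.numeric(n_subjects) * as.numeric(n_variants) * as.numeric(n_allele_columns)
}

#' Naive character-store size
#'
#' Size in bytes of the uncompressed representation that stores every allele
#' call as a character primitive (two bytes per character by default, as in
#' UTF-16 character storage). Used only to report the compression ratio of
#' the packed store, which is exactly 8 for the default `bytes_per_char`.
#'
#' @inheritParams payload_size_bits
#' @param bytes_per_char bytes per stored character (default 2).
#' @return size in bytes (numeric).
#' @examples
#' naive_size_bytes(1e3, 4e6, 2) / 2^30  # GByte, naive storage
#' @export
naive_size_bytes <- function(n_subjects, n_variants, n_allele_columns,
                             bytes_per_char = 2) {
  check_nonneg(n_subjects, n_variants, n_allele_columns, bytes_per_char)
  as.numeric(n_subjects) * as.numeric(n_variants) *
    as.numeric(n_allele_columns) * as.numeric(bytes_per_char)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (a in args) {
    if (length(a) != 1L || is.na(a) || a < 0) {
      stop("size arguments must be single non-negative numbers", call. = FALSE)
    }
  }
  invisible(NULL)
}

## ---- access -----------------------------------------------------------

#' Read one allele call
#'
#' Decodes a single cell of the packed store. Returns `NA` iff the
#' missingness bit is set, otherwise the decoded base. Pure read.
#'
#' @param M a [hap_matrix].
#' @param i subject index (1-based).
#' @param j variant index (1-based).
#' @param k allele-column index (1-based; 1 = left/paternal, 2 = right/maternal).
#' @return a single base character or `NA`.
#' @export
get_allele <- function(M, i, j, k) {
  stopifnot(inherits(M, "hap_matrix"))
  for (v in list(i = i, j = j, k = k)) {
    if (length(v) != 1L || is.na(v) || v != as.integer(v)) {
      stop("indices must be single integers", call. = FALSE)
    }
  }
  if (i < 1L || i > M$n_subjects || j < 1L || j > M$n_variants ||
      k < 1L || k > M$n_allele_columns) {
    stop("index out of range", call. = FALSE)
  }
  idx <- cell_index(M, as.integer(i), as.integer(j), as.integer(k))
  if (unpack_mask(M$missing_mask, idx)) return(NA_character_)
  code_to_allele(unpack_codes(M$payload, idx))
}

#' Decode a block of allele calls
#'
#' Decompresses the requested (subject x variant) sub-block into a dense
#' character array with `NA` for missing calls. Only the selected cells are
#' decoded.
#'
#' @param M a [hap_matrix].
#' @param subjects,variants integer index vectors (default: all, in order).
#' @return character array `length(subjects) x length(variants) x n_allele_columns`.
#' @export
hap_calls <- function(M, subjects = seq_len(M$n_subjects),
                      variants = seq_len(M$n_variants)) {
  stopifnot(inherits(M, "hap_matrix"))
  subjects <- check_indices(subjects, M$n_subjects, "subject",
                            allow_dup = TRUE)
  variants <- check_indices(variants, M$n_variants, "variant",
                            allow_dup = TRUE)
  p <- M$n_allele_columns
  ns <- length(subjects); nv <- length(variants)
  if (ns == 0L || nv == 0L || p == 0L) {
    return(array(NA_character_, dim = c(ns, nv, p)))
  }
  # linear indices, allele-column fastest
  base <- outer((variants - 1L) * p,
                (subjects - 1L) * (M$n_variants * p), `+`)  # nv x ns
  idx <- rep(as.vector(base), each = p) + seq_len(p)        # p, nv, ns order
  vals <- code_to_allele(unpack_codes(M$payload, idx))
  vals[unpack_mask(M$missing_mask, idx)] <- NA_character_
  aperm(array(vals, dim = c(p, nv, ns)), c(3L, 2L, 1L))
}

check_indices <- function(idx, n, what, allow_dup = FALSE) {
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n)) {
    stop(what, " index out of range", call. = FALSE)
  }
  if (!allow_dup && anyDuplicated(idx)) {
    stop("duplicate ", what, " indices are not allowed", call. = FALSE)
  }
  idx
}

#' Subset a haplotype matrix
#'
#' Returns a new `hap_matrix` with the selected subjects and variants in
#' the given order; the source matrix is unchanged. Duplicate indices are
#' forbidden (a slice is a sub-matrix, not a replication).
#'
#' @param M a [hap_matrix].
#' @param subjects,variants integer index vectors (default: keep all).
#' @return a new [hap_matrix].
#' @export
hap_slice <- function(M, subjects = seq_len(M$n_subjects),
                      variants = seq_len(M$n_variants)) {
  stopifnot(inherits(M, "hap_matrix"))
  subjects <- check_indices(subjects, M$n_subjects, "subject")
  variants <- check_indices(variants, M$n_variants, "variant")
  calls <- hap_calls(M, subjects, variants)
  flat <- aperm(calls, c(3L, 2L, 1L))
  miss <- is.na(flat)
  codes <- integer(length(flat))
  if (any(!miss)) codes[!miss] <- allele_to_code(flat[!miss])
  out <- M
  out$subject_ids <- M$subject_ids[subjects]
  out$variants <- M$variants[variants, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$n_subjects <- length(subjects)
  out$n_variants <- length(variants)
  out$payload <- pack_codes(codes)
  out$missing_mask <- pack_mask(as.logical(miss))
  out
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf(
    "hap_matrix: %d subjects x %d SNVs x %d allele column(s), %s\n",
    x$n_subjects, x$n_variants, x$n_allele_columns,
    if (x$phased) "phased" else "unphased"))
  cat(sprintf("  payload: %s bits packed in %d bytes; mask: %d bytes\n",
              format(payload_size_bits(x$n_subjects, x$n_variants,
                                       x$n_allele_columns), big.mark = ","),
              length(x$payload), length(x$missing_mask)))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) {
  c(x$n_subjects, x$n_variants, x$n_allele_columns)
}
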