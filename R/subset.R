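#' @title SNV filters and stable metadata-driven sorting
#'
#' @description
#' Filters operate on the variant axis only and return a new [hap_matrix]
#' whose surviving variants keep their original order and allele data
#' (every filter is implemented through [hap_slice()], so the packed bits
#' at surviving variants are identical to the source). The sorts reorder
#' subjects or variants by an annotation column using a stable sort, so
#' consecutive sorts by several columns behave like a single compound-key
#' sort.
#'
#' @name subsetting
NULL

#' Keep variants inside a chromosomal region
#'
#' Region coordinates are 1-based and inclusive on both ends, matching VCF
#' positions.
#'
#' @param M a [hap_matrix].
#' @param chrom chromosome label (or a region string `"chrom:start-end"`,
#'   in which case `start`/`end` are taken from it).
#' @param start,end integer bounds, `start <= end`.
#' @return a filtered [hap_matrix] (possibly with zero variants).
#' @examples
#' \dontrun{filter_region(M, "2", 73600000, 73700000)}
#' @export
filter_region <- function(M, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(M, "hap_matrix"))
  if (is.null(start) && grepl(":", chrom, fixed = TRUE)) {
    q <- parse_region(chrom)
    chrom <- q$chrom; start <- q$start; end <- q$end
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || is.na(start) || is.na(end) || start > end ||
      start < 1) {
    stop("invalid region: need chrom and 1 <= start <= end", call. = FALSE)
  }
  keep <- which(M$variants$chrom == chrom &
                  M$variants$pos >= start & M$variants$pos <= end)
  hap_slice(M, variants = keep)
}

#' Parse a region string `chrom:start-end`
#' @param x region string, e.g. `"2:100-200"`.
#' @return list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 4L) {
    stop("cannot parse region '", x, "' (expected chrom:start-end)",
         call. = FALSE)
  }
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Keep variants whose identifier is in a given list
#'
#' Exactly the intersection of the list with the matrix's variant ids is
#' kept, in matrix order; ids in the list but absent from the matrix are
#' ignored (their count is reported in a message).
#'
#' @param M a [hap_matrix].
#' @param ids character vector of variant identifiers.
#' @return a filtered [hap_matrix].
#' @export
filter_id_list <- function(M, ids) {
  stopifnot(inherits(M, "hap_matrix"))
  ids <- as.character(ids)
  n_unknown <- length(setdiff(ids, M$variants$id))
  if (n_unknown > 0L) {
    message("filter_id_list: ", n_unknown,
            " id(s) not present in the matrix were ignored")
  }
  hap_slice(M, variants = which(M$variants$id %in% ids))
}

#' Keep variants whose identifier matches a regular expression
#'
#' Full-match semantics: the pattern must match the entire identifier
#' (it is anchored internally), which makes id filters predictable —
#' `"rs7.*"` keeps `rs743616` but `"rs7"` alone does not.
#'
#' @param M a [hap_matrix].
#' @param pattern a regular expression (ERE as used by [grepl()]).
#' @return a filtered [hap_matrix].
#' @export
filter_id_regex <- function(M, pattern) {
  stopifnot(inherits(M, "hap_matrix"))
  ok <- tryCatch(suppressWarnings(grepl(paste0("^(?:", pattern, ")$"),
                                        M$variants$id, perl = TRUE)),
                 error = function(e) {
                   stop("invalid regular expression '", pattern, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  hap_slice(M, variants = which(ok))
}

#' Non-reference allele frequency of each variant
#'
#' The frequency of a variant is the number of allele calls equal to its
#' alternate base divided by the number of non-missing allele calls, counted
#' across all subjects and allele columns. This per-allele reading of
#' "genotype frequency" is the one consistent with applying a percent
#' threshold across all individuals of a phased cohort; a subject-level
#' alternative (`per = "subject"`: fraction of subjects carrying at least
#' one alternate allele among subjects with at least one non-missing call)
#' is available behind a flag.
#'
#' @param M a [hap_matrix].
#' @param variants variant indices (default all).
#' @param per `"allele"` (default) or `"subject"`.
#' @return numeric vector of frequencies in `[0, 1]`; `NaN` for variants
#'   whose calls are all missing.
#' @export
alt_allele_frequency <- function(M, variants = seq_len(M$n_variants),
                                 per = c("allele", "subject")) {
  stopifnot(inherits(M, "hap_matrix"))
  per <- match.arg(per)
  variants <- check_indices(variants, M$n_variants, "variant",
                            allow_dup = TRUE)
  if (!length(variants)) return(numeric(0))
  calls <- hap_calls(M, variants = variants)
  alt <- M$variants$alt[variants]
  is_alt <- sweep_equal(calls, alt)
  if (per == "allele") {
    n_alt <- apply(is_alt, 2L, sum, na.rm = TRUE)
    n_inf <- apply(!is.na(calls), 2L, sum)
    out <- n_alt / n_inf
  } else {
    carrier <- apply(is_alt, c(1L, 2L), function(x) any(x, na.rm = TRUE))
    informative <- apply(!is.na(calls), c(1L, 2L), any)
    out <- colSums(carrier & informative) / colSums(informative)
  }
  unname(out)
}

# elementwise calls[i,j,k] == per_variant[j], NA-preserving
sweep_equal <- function(calls, per_variant) {
  d <- dim(calls)
  cmp <- rep(rep(per_variant, each = d[1L]), times = d[3L])
  array(calls == cmp, dim = d)
}

#' Filter variants by non-reference allele frequency
#'
#' Keeps variants whose [alt_allele_frequency()] is strictly above
#' (`mode = "above"`) or strictly below (`mode = "below"`) the threshold,
#' matching the strict `> 0.5\%` / `< 0.5\%` convention for separating
#' common from rare variants. Variants whose calls are all missing have no
#' defined frequency and are dropped (their count is reported).
#'
#' @param M a [hap_matrix].
#' @param threshold frequency threshold in `[0, 1]`.
#' @param mode `"above"` or `"below"`.
#' @param per passed to [alt_allele_frequency()].
#' @return a filtered [hap_matrix].
#' @export
filter_frequency <- function(M, threshold, mode = c("above", "below"),
                             per = c("allele", "subject")) {
  stopifnot(inherits(M, "hap_matrix"))
  mode <- match.arg(mode)
  per <- match.arg(per)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  f <- alt_allele_frequency(M, per = per)
  undefined <- is.nan(f)
  if (any(undefined)) {
    message("filter_frequency: dropped ", sum(undefined),
            " all-missing variant(s) with undefined frequency")
  }
  keep <- if (mode == "above") f > threshold else f < threshold
  hap_slice(M, variants = which(keep & !undefined))
}

## ---- stable sorting ---------------------------------------------------

# Stable order of values by an annotation column: categorical labels sort
# lexicographically (C locale), numerical ascending; ids absent from the
# meta table or with absent values sort last, prior order preserved.
stable_meta_order <- function(ids, meta, column) {
  vals <- meta_values(meta, column, ids)
  if (meta_kind(meta, column) == "categorical") {
    vals <- as.character(vals)
  }
  order(is.na(vals), vals, method = "radix", na.last = TRUE)
}

#' Sort subjects by a subject annotation column
#'
#' Stable: subjects with equal keys keep their prior relative order, so
#' sorting by column B and then by column A is the same as one sort by the
#' compound key (A, B). Subjects without a value (or absent from the meta
#' table) sort last in their prior order.
#'
#' @param M a [hap_matrix].
#' @param meta a subject-axis [meta_table].
#' @param column annotation column name.
#' @return a [hap_matrix] with subjects reordered.
#' @export
sort_rows_by_meta <- function(M, meta, column) {
  stopifnot(inherits(M, "hap_matrix"), inherits(meta, "meta_table"))
  ord <- stable_meta_order(M$subject_ids, meta, column)
  hap_slice(M, subjects = ord)
}

#' Sort variants by a variant annotation column
#'
#' Same contract as [sort_rows_by_meta()], applied to the variant axis
#' (annotation rows below the haplotype grid).
#'
#' @param M a [hap_matrix].
#' @param meta a variant-axis [meta_table].
#' @param column annotation column (meta-information row) name.
#' @return a [hap_matrix] with variants reordered.
#' @export
sort_columns_by_meta <- function(M, meta, column) {
  stopifnot(inherits(M, "hap_matrix"), inherits(meta, "meta_table"))
  ord <- stable_meta_order(M$variants$id, meta, column)
  hap_slice(M, variants = ord)
}
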