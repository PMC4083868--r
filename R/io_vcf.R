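#' Read a phased or unphased VCF into a haplotype matrix
#'
#' Loads a VCF (v4.x, plain or gzip) via the \pkg{vcfR} parser and converts
#' the per-sample GT fields into a [hap_matrix]. Only biallelic SNV records
#' are kept: multi-allelic records, INDELs and symbolic alleles are skipped
#' with a message giving the count. Only CHROM, POS, ID, REF, ALT and
#' FORMAT/GT are consulted.
#'
#' GT parsing: `"a|b"` is a phased call with allele column 1 = left of the
#' pipe (displayed as "P") and column 2 = right ("M"); `"a/b"` is unphased;
#' `"."` or a missing sub-field gives a missing call; a ploidy-1 call such
#' as `"0"` (for example male X) fills column 2 with missing. If any record
#' carries an unphased separator the whole matrix is flagged unphased with
#' a warning.
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`).
#' @return a list with elements `matrix` (a [hap_matrix]) and
#'   `variant_meta` (a [meta_table] stub on the variant axis holding the
#'   reference and alternate base of each kept SNV).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (!"FORMAT" %in% colnames(vcf@gt)) {
    stop("VCF has no FORMAT column: ", path, call. = FALSE)
  }
  if (!any(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("VCF FORMAT lacks the GT field: ", path, call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(vcf@gt)[-1L]
  if (length(samples) < 1L) stop("VCF has no samples: ", path, call. = FALSE)

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) &
    ref %in% ALLELE_BASES & alt %in% ALLELE_BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNV record(s) (multi-allelic, INDEL or symbolic)")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "." | id == ""
  id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  variants <- data.frame(
    id = id, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)

  parsed <- parse_gt_matrix(gt, variants$ref, variants$alt)
  calls <- parsed$calls                      # variant x sample x 2
  calls <- aperm(calls, c(2L, 1L, 3L))       # subject x variant x 2
  phased <- parsed$phased
  if (!phased && parsed$mixed) {
    warning("VCF mixes phased and unphased GT separators; ",
            "matrix flagged unphased", call. = FALSE)
  }
  M <- hap_matrix(calls, samples, variants, phased = phased)
  vm <- meta_table(M$variants$id,
                   data.frame(Ref = M$variants$ref, Alt = M$variants$alt,
                              stringsAsFactors = FALSE),
                   kinds = c("categorical", "categorical"),
                   axis = "variant")
  list(matrix = M, variant_meta = vm)
}

# gt: variant x sample matrix of GT strings (NA allowed); returns calls
# array (variant x sample x 2), phased flag, and whether separators mixed
parse_gt_matrix <- function(gt, ref, alt) {
  nv <- nrow(gt); ns <- ncol(gt)
  calls <- array(NA_character_, dim = c(nv, ns, 2L))
  g <- as.vector(gt)
  g[is.na(g)] <- "."
  has_pipe <- grepl("|", g, fixed = TRUE)
  has_slash <- grepl("/", g, fixed = TRUE)
  left <- rep(NA_character_, length(g))
  right <- rep(NA_character_, length(g))
  sep <- has_pipe | has_slash
  parts <- strsplit(g[sep], "[|/]")
  left[sep] <- vapply(parts, `[`, character(1L), 1L)
  right[sep] <- vapply(parts, function(x)
    if (length(x) >= 2L) x[2L] else ".", character(1L))
  left[!sep] <- g[!sep]     # ploidy-1 call: right allele stays missing
  decode <- function(tok, vi) {
    tok[is.na(tok)] <- "."
    out <- rep(NA_character_, length(tok))
    out[tok == "0"] <- ref[vi][tok == "0"]
    out[tok == "1"] <- alt[vi][tok == "1"]
    bad <- !tok %in% c("0", "1", ".", "", NA)
    if (any(bad)) {
      stop("unsupported GT allele index '", tok[bad][1L],
           "' (only biallelic 0/1 calls are supported)", call. = FALSE)
    }
    out
  }
  vi <- rep(seq_len(nv), times = ns)
  calls[, , 1L] <- decode(left, vi)
  calls[, , 2L] <- decode(right, vi)
  informative <- sep
  list(calls = calls,
       phased = !any(has_slash[informative]) ,
       mixed = any(has_slash) && any(has_pipe))
}

#' Write a haplotype matrix as a VCF file
#'
#' Emits a minimal VCF v4.2 with CHROM, POS, ID, REF, ALT and per-sample GT
#' fields; phased matrices use the `|` separator, unphased `/`. Missing
#' alleles are written as `.`; a call whose second allele column is missing
#' while the first is present is written as a ploidy-1 GT. Reading the file
#' back with [read_vcf()] reproduces the matrix.
#'
#' @param M a [hap_matrix].
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(M, path) {
  stopifnot(inherits(M, "hap_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplopaint",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", M$subject_ids), collapse = "\t"))
  sep <- if (M$phased) "|" else "/"
  rows <- character(M$n_variants)
  if (M$n_variants > 0L) {
    calls <- hap_calls(M)
    v <- M$variants
    for (j in seq_len(M$n_variants)) {
      gt <- vapply(seq_len(M$n_subjects), function(i) {
        a1 <- calls[i, j, 1L]
        a2 <- if (M$n_allele_columns >= 2L) calls[i, j, 2L] else NA
        t1 <- allele_token(a1, v$ref[j], v$alt[j])
        if (M$n_allele_columns == 1L) return(t1)
        t2 <- allele_token(a2, v$ref[j], v$alt[j])
        if (t2 == "." && t1 != ".") t1 else paste(t1, t2, sep = sep)
      }, character(1L))
      rows[j] <- paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                         ".", "PASS", ".", "GT", gt), collapse = "\t")
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

allele_token <- function(a, ref, alt) {
  if (is.na(a)) "." else if (a == ref) "0" else if (a == alt) "1"
  else stop("call '", a, "' matches neither ref nor alt", call. = FALSE)
}
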