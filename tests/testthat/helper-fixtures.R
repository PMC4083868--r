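# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no binary files.

BASES <- c("A", "C", "G", "T")

# random call array + matching variant frame -> hap_matrix (+ the raw array)
make_test_matrix <- function(n = 5L, m = 20L, p = 2L, seed = 1L,
                             missing_rate = 0.1, chrom = "1") {
  set.seed(seed)
  ref_ix <- sample.int(4L, m, replace = TRUE)
  alt_ix <- (ref_ix + sample.int(3L, m, replace = TRUE) - 1L) %% 4L + 1L
  variants <- data.frame(
    id = sprintf("rs%03d", seq_len(m)), chrom = chrom,
    pos = seq(100L, by = 50L, length.out = m),
    ref = BASES[ref_ix], alt = BASES[alt_ix], stringsAsFactors = FALSE)
  # calls restricted to ref/alt so VCF round trips are defined
  pick_alt <- array(stats::runif(n * m * p) < 0.3, dim = c(n, m, p))
  calls <- array("", dim = c(n, m, p))
  for (k in seq_len(p)) {
    calls[, , k] <- ifelse(pick_alt[, , k],
                           matrix(variants$alt, n, m, byrow = TRUE),
                           matrix(variants$ref, n, m, byrow = TRUE))
  }
  if (missing_rate > 0) {
    calls[array(stats::runif(n * m * p) < missing_rate,
                dim = c(n, m, p))] <- NA_character_
  }
  M <- hap_matrix(calls, sprintf("S%02d", seq_len(n)), variants,
                  phased = (p == 2L))
  list(M = M, calls = calls, variants = variants)
}

# two-population subject meta for a matrix's subjects
make_pop_meta <- function(M, pops = c("AFR", "EUR")) {
  labels <- rep_len(rep(pops, each = ceiling(M$n_subjects / length(pops))),
                    M$n_subjects)
  meta_table(M$subject_ids,
             data.frame(Population = labels, stringsAsFactors = FALSE),
             kinds = "categorical", axis = "subject")
}

# handcrafted 3-sample x 5-record VCF exercising phased, missing, half and
# skipped records; returns path + the manually decoded expectation
write_handcrafted_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "HG01", "HG02", "HG03"), collapse = "\t"),
    "7\t100\trs100\tC\tG\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "7\t200\trs200\tA\tT\t.\tPASS\t.\tGT\t.|.\t0|.\t1|0",
    "7\t300\trs300\tG\tA\t.\tPASS\t.\tGT\t0\t1\t0|1",
    "7\t400\trsINDEL\tGA\tG\t.\tPASS\t.\tGT\t0|0\t0|0\t0|0",
    "7\t500\trsMULTI\tA\tC,T\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0")
  writeLines(lines, path)
  # manual decode of the three kept SNVs (rs100, rs200, rs300)
  expected <- array(NA_character_, dim = c(3L, 3L, 2L))
  expected[, 1L, 1L] <- c("C", "G", "C"); expected[, 1L, 2L] <- c("G", "G", "C")
  expected[, 2L, 1L] <- c(NA, "A", "T"); expected[, 2L, 2L] <- c(NA, NA, "A")
  expected[, 3L, 1L] <- c("G", "A", "G"); expected[, 3L, 2L] <- c(NA, NA, "A")
  list(path = path, expected = expected,
       samples = c("HG01", "HG02", "HG03"),
       kept_ids = c("rs100", "rs200", "rs300"))
}

# write a small two-header meta TSV and return its path
write_meta_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

hex_at <- function(canvas, row, variant, k = 1L) {
  cc <- cell_center(canvas, row, variant, k)
  canvas_pixel(canvas, cc["x"], cc["y"])
}
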