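test_that("region filter keeps 1-based inclusive coordinates", {
  fx <- make_test_matrix(n = 2L, m = 3L, p = 2L, missing_rate = 0)
  M <- fx$M
  M$variants$pos <- c(50L, 100L, 150L)  # ids rs001..rs003 in order
  expect_identical(filter_region(M, "1", 60, 140)$variants$pos, 100L)
  expect_identical(filter_region(M, "1", 1, 1e6)$variants$id,
                   M$variants$id)
  expect_identical(filter_region(M, "2", 1, 1e6)$n_variants, 0L)
  expect_identical(filter_region(M, "1:60-140")$variants$pos, 100L)
  expect_error(filter_region(M, "1", 200, 100), "start <= end")
  expect_error(parse_region("chr1:5"), "chrom:start-end")
})

test_that("filters agree with brute-force linear-scan oracles", {
  fx <- make_test_matrix(n = 10L, m = 200L, p = 2L, seed = 77L,
                         missing_rate = 0.05)
  M <- fx$M
  v <- M$variants

  # region
  kept <- filter_region(M, "1", 2000, 6000)$variants$id
  oracle <- v$id[vapply(seq_len(nrow(v)), function(j)
    v$chrom[j] == "1" && v$pos[j] >= 2000 && v$pos[j] <= 6000,
    logical(1))]
  expect_identical(kept, oracle)

  # id list (with unknown ids ignored)
  set.seed(1)
  ids <- c(sample(v$id, 50L), "rs_not_there")
  expect_message(Mi <- filter_id_list(M, ids), "1 id\\(s\\) not present")
  expect_identical(Mi$variants$id, v$id[v$id %in% ids])

  # regex, full-match semantics
  kept_rx <- filter_id_regex(M, "rs0[0-4].")$variants$id
  oracle_rx <- v$id[vapply(v$id, function(id)
    grepl("^rs0[0-4].$", id), logical(1))]
  expect_identical(kept_rx, oracle_rx)

  # frequency vs counting oracle
  f <- alt_allele_frequency(M)
  oracle_f <- vapply(seq_len(M$n_variants), function(j) {
    cc <- hap_calls(M, variants = j)
    sum(cc == v$alt[j], na.rm = TRUE) / sum(!is.na(cc))
  }, numeric(1))
  expect_equal(f, oracle_f, tolerance = 1e-12)
  thr <- stats::median(f)
  expect_identical(filter_frequency(M, thr, "above")$variants$id,
                   v$id[f > thr])
  expect_identical(filter_frequency(M, thr, "below")$variants$id,
                   v$id[f < thr])
})

test_that("id filters behave on edge inputs", {
  fx <- make_test_matrix(m = 10L)
  expect_identical(filter_id_list(fx$M, character(0))$n_variants, 0L)
  expect_identical(filter_id_regex(fx$M, ".*")$variants$id,
                   fx$M$variants$id)
  # full-match: a prefix alone does not match
  expect_identical(filter_id_regex(fx$M, "rs0")$n_variants, 0L)
  expect_error(filter_id_regex(fx$M, "("), "invalid regular expression")
})

test_that("frequency computes the documented per-allele ratio", {
  # 4 phased subjects at a C->G site: one G among 8 calls -> 0.125
  calls <- array("C", dim = c(4L, 2L, 2L))
  calls[2, 1, 2] <- "G"
  v <- data.frame(id = c("a", "b"), chrom = "1", pos = 1:2,
                  ref = "C", alt = "G")
  M <- hap_matrix(calls, paste0("s", 1:4), v)
  expect_equal(alt_allele_frequency(M), c(0.125, 0))
  # subject-level alternative: 1 carrier of 4
  expect_equal(alt_allele_frequency(M, per = "subject"), c(0.25, 0))
  # all-missing variant: undefined frequency, dropped with a message
  calls[, 2, ] <- NA_character_
  M2 <- hap_matrix(calls, paste0("s", 1:4), v)
  expect_true(is.nan(alt_allele_frequency(M2)[2]))
  expect_message(Mf <- filter_frequency(M2, 0.5, "below"), "all-missing")
  expect_identical(Mf$variants$id, "a")
})

test_that("strict thresholds partition the variants", {
  fx <- make_test_matrix(n = 8L, m = 60L, seed = 13L, missing_rate = 0)
  f <- alt_allele_frequency(fx$M)
  thr <- f[17]  # a threshold hit exactly by at least one variant
  above <- filter_frequency(fx$M, thr, "above")$variants$id
  below <- filter_frequency(fx$M, thr, "below")$variants$id
  at <- fx$M$variants$id[f == thr]
  expect_gte(length(at), 1L)
  expect_identical(sort(c(above, below, at)), sort(fx$M$variants$id))
  expect_length(intersect(above, below), 0L)
})

test_that("filters are subset operations that commute", {
  fx <- make_test_matrix(n = 6L, m = 80L, seed = 31L, missing_rate = 0.1)
  M <- fx$M
  a <- filter_frequency(filter_region(M, "1", 500, 3000), 0.2, "above")
  b <- filter_region(filter_frequency(M, 0.2, "above"), "1", 500, 3000)
  expect_identical(hap_calls(a), hap_calls(b))
  expect_identical(a$variants, b$variants)
  # subject axis untouched; surviving allele data bit-identical
  expect_identical(a$subject_ids, M$subject_ids)
  jmap <- match(a$variants$id, M$variants$id)
  expect_identical(hap_calls(a), hap_calls(M, variants = jmap))
})

test_that("meta sorts are stable and compose into compound keys", {
  fx <- make_test_matrix(n = 12L, m = 8L, seed = 9L)
  M <- fx$M
  set.seed(4)
  meta <- meta_table(
    M$subject_ids,
    data.frame(A = sample(c("x", "y"), 12, TRUE),
               B = sample(c("p", "q", "r"), 12, TRUE),
               N = sample(c(1:3, NA), 12, TRUE) / 2,
               stringsAsFactors = FALSE),
    kinds = c("categorical", "categorical", "numerical"),
    axis = "subject")

  # two-population fixture sorts into contiguous blocks
  pop <- make_pop_meta(M)
  Ms <- sort_rows_by_meta(M, pop, "Population")
  labs <- meta_values(pop, "Population", Ms$subject_ids)
  expect_identical(labs, sort(labs))
  # sorting a sorted matrix changes nothing (stability)
  expect_identical(sort_rows_by_meta(Ms, pop, "Population")$subject_ids,
                   Ms$subject_ids)

  # defining stable-sort law: sort by B then by A == compound sort by (A, B)
  M_ba <- sort_rows_by_meta(sort_rows_by_meta(M, meta, "B"), meta, "A")
  a <- meta_values(meta, "A", M$subject_ids)
  b <- meta_values(meta, "B", M$subject_ids)
  compound <- M$subject_ids[order(a, b, method = "radix")]
  expect_identical(M_ba$subject_ids, compound)

  # numerical keys sort ascending with missing last, prior order kept
  Mn <- sort_rows_by_meta(M, meta, "N")
  vals <- meta_values(meta, "N", Mn$subject_ids)
  expect_false(is.unsorted(vals[!is.na(vals)]))
  miss_ids <- M$subject_ids[is.na(meta_values(meta, "N", M$subject_ids))]
  expect_identical(Mn$subject_ids[is.na(vals)], miss_ids)

  # sorting is a permutation and idempotent
  expect_setequal(Mn$subject_ids, M$subject_ids)
  expect_identical(sort_rows_by_meta(Mn, meta, "N")$subject_ids,
                   Mn$subject_ids)
  expect_error(sort_rows_by_meta(M, meta, "nope"), "unknown meta column")
})

test_that("variant sorts mirror the subject sort contract", {
  fx <- make_test_matrix(n = 3L, m = 9L, seed = 2L)
  M <- fx$M
  vmeta <- meta_table(
    M$variants$id,
    data.frame(Gene = rep(c("G2", "G1", "G3"), each = 3L),
               stringsAsFactors = FALSE),
    kinds = "categorical", axis = "variant")
  Ms <- sort_columns_by_meta(M, vmeta, "Gene")
  genes <- meta_values(vmeta, "Gene", Ms$variants$id)
  expect_identical(genes, sort(genes))
  # stability: equal keys keep prior (positional) order
  expect_identical(Ms$variants$id[genes == "G1"],
                   M$variants$id[4:6])
  expect_identical(
    sort_columns_by_meta(Ms, vmeta, "Gene")$variants$id,
    Ms$variants$id)
})

test_that("stable-sort law holds over many random meta tables", {
  set.seed(123)
  fx <- make_test_matrix(n = 15L, m = 4L, seed = 6L)
  M <- fx$M
  for (rep in 1:25) {
    meta <- meta_table(
      M$subject_ids,
      data.frame(A = sample(letters[1:3], 15, TRUE),
                 B = sample(letters[1:4], 15, TRUE),
                 stringsAsFactors = FALSE),
      kinds = c("categorical", "categorical"), axis = "subject")
    got <- sort_rows_by_meta(sort_rows_by_meta(M, meta, "B"),
                             meta, "A")$subject_ids
    a <- meta_values(meta, "A", M$subject_ids)
    b <- meta_values(meta, "B", M$subject_ids)
    expect_identical(got, M$subject_ids[order(a, b, method = "radix")])
  }
})
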