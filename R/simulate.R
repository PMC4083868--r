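#' Specification of a synthetic multi-population cohort
#'
#' Describes a phased cohort with population structure for exercising the
#' full load/filter/sort/aggregate/render path without external downloads.
#' The default layout mirrors a 1000-genomes-style design in miniature:
#' 14 populations in 4 super-populations, with a mix of common variants and
#' rare variants (per-population alternate-allele frequency below the 0.5%
#' rare threshold).
#'
#' Alleles are drawn independently per haplotype (no linkage-disequilibrium
#' model): at variant `j`, each allele column of a subject from population
#' `p` is the alternate base with probability `F[p, j]`, otherwise the
#' reference base.
#'
#' @param populations data frame with columns `label`, `super_label`,
#'   `n_subjects` (default: the 14-population / 4-super-population layout,
#'   3 subjects each).
#' @param n_variants number of SNVs.
#' @param chrom chromosome label for all variants.
#' @param pos_start,pos_step genomic position layout (1-based).
#' @param rare_fraction fraction of variants that are rare in every
#'   population.
#' @param rare_threshold per-population frequency bound defining "rare"
#'   (default 0.005, i.e. 0.5%).
#' @param common_range frequency range from which common-variant
#'   population frequencies are drawn.
#' @param missing_rate per-call probability of a missing allele.
#' @param F optional populations x variants frequency matrix in `[0, 1]`;
#'   overrides the rare/common draw (rows = populations in order).
#' @param n_genes number of gene labels cycled over consecutive variants
#'   (variant annotation row).
#' @param seed integer seed fixing every draw.
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(populations = default_populations(),
                        n_variants = 100L,
                        chrom = "2",
                        pos_start = 73600000L,
                        pos_step = 997L,
                        rare_fraction = 0.3,
                        rare_threshold = 0.005,
                        common_range = c(0.05, 0.6),
                        missing_rate = 0,
                        F = NULL,
                        n_genes = 3L,
                        seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("label", "super_label", "n_subjects") %in%
                  names(populations)))
  if (any(populations$n_subjects < 1L)) {
    stop("every population needs at least one subject", call. = FALSE)
  }
  if (anyDuplicated(populations$label)) {
    stop("population labels must be unique", call. = FALSE)
  }
  n_variants <- as.integer(n_variants)
  if (n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  if (rare_fraction < 0 || rare_fraction > 1) {
    stop("rare_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (rare_threshold <= 0 || rare_threshold >= 1) {
    stop("rare_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(F)) {
    F <- as.matrix(F)
    if (nrow(F) != nrow(populations) || ncol(F) != n_variants ||
        any(F < 0) || any(F > 1)) {
      stop("F must be a populations x variants matrix with entries in ",
           "[0, 1]", call. = FALSE)
    }
  }
  structure(list(populations = populations, n_variants = n_variants,
                 chrom = as.character(chrom),
                 pos_start = as.integer(pos_start),
                 pos_step = as.integer(pos_step),
                 rare_fraction = rare_fraction,
                 rare_threshold = rare_threshold,
                 common_range = common_range,
                 missing_rate = missing_rate, F = F,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default population layout: 14 populations, 4 super-populations
#'
#' Labels follow the continental cohort naming widely used for human
#' resequencing panels (AFR, AMR, ASN, EUR super-populations).
#'
#' @param n_subjects subjects per population (recycled; default 3).
#' @return data frame with `label`, `super_label`, `n_subjects`.
#' @export
default_populations <- function(n_subjects = 3L) {
  labels <- c("ASW", "LWK", "YRI",
              "CLM", "MXL", "PUR",
              "CHB", "CHS", "JPT",
              "CEU", "FIN", "GBR", "IBS", "TSI")
  super <- c(rep("AFR", 3L), rep("AMR", 3L), rep("ASN", 3L),
             rep("EUR", 5L))
  data.frame(label = labels, super_label = super,
             n_subjects = rep_len(as.integer(n_subjects), length(labels)),
             stringsAsFactors = FALSE)
}

#' Simulate a phased multi-population cohort
#'
#' Draws a phased [hap_matrix] plus subject and variant annotation tables
#' from a [cohort_spec()]. Deterministic under the spec's seed.
#'
#' Per-variant reference/alternate bases are drawn uniformly from the
#' ordered pairs of distinct bases. A `rare_fraction` share of variants is
#' rare: their per-population alternate-allele frequencies are drawn
#' uniformly from `(0, rare_threshold)`; common variants draw a shared base
#' frequency from `common_range` with independent per-population
#' perturbation. Subject annotations carry `Population` and
#' `SuperPopulation` (categorical); variant annotations carry a cyclic
#' `Gene` label (categorical) and the genomic `Position` (numerical).
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (phased [hap_matrix]), `subject_meta`,
#'   `variant_meta`, `F` (the population x variant frequency matrix used),
#'   `rare` (logical vector marking rare variants) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pops <- spec$populations
  n_pop <- nrow(pops)
  m <- spec$n_variants
  n <- sum(pops$n_subjects)

  ## variant identities
  pos <- spec$pos_start + (seq_len(m) - 1L) * spec$pos_step
  ref_ix <- sample.int(4L, m, replace = TRUE)
  alt_off <- sample.int(3L, m, replace = TRUE)
  alt_ix <- (ref_ix - 1L + alt_off) %% 4L + 1L
  variants <- data.frame(
    id = sprintf("rs%d", 100000L + seq_len(m)),
    chrom = spec$chrom, pos = pos,
    ref = ALLELE_BASES[ref_ix], alt = ALLELE_BASES[alt_ix],
    stringsAsFactors = FALSE)

  ## population frequency matrix
  rare <- logical(m)
  n_rare <- round(spec$rare_fraction * m)
  if (n_rare > 0L) rare[sample.int(m, n_rare)] <- TRUE
  if (!is.null(spec$F)) {
    F <- spec$F
    rare <- apply(F < spec$rare_threshold, 2L, all)
  } else {
    F <- matrix(0, n_pop, m)
    if (any(rare)) {
      F[, rare] <- stats::runif(n_pop * sum(rare), 0, spec$rare_threshold)
    }
    if (any(!rare)) {
      base <- stats::runif(sum(!rare), spec$common_range[1L],
                           spec$common_range[2L])
      jitter <- matrix(stats::runif(n_pop * sum(!rare), -0.05, 0.05),
                       n_pop)
      F[, !rare] <- pmin(1, pmax(
        spec$rare_threshold * 2,
        matrix(base, n_pop, sum(!rare), byrow = TRUE) + jitter))
    }
  }
  rownames(F) <- pops$label

  ## subjects and their calls
  pop_of <- rep(seq_len(n_pop), times = pops$n_subjects)
  subject_ids <- sprintf("%s%03d", pops$label[pop_of],
                         unlist(lapply(pops$n_subjects, seq_len)))
  calls <- array(NA_character_, dim = c(n, m, 2L))
  prob <- F[pop_of, , drop = FALSE]            # n x m
  for (k in 1:2) {
    is_alt <- matrix(stats::runif(n * m), n, m) < prob
    calls[, , k] <- ifelse(is_alt,
                           matrix(variants$alt, n, m, byrow = TRUE),
                           matrix(variants$ref, n, m, byrow = TRUE))
  }
  if (spec$missing_rate > 0) {
    drop <- stats::runif(length(calls)) < spec$missing_rate
    calls[drop] <- NA_character_
  }

  M <- hap_matrix(calls, subject_ids, variants, phased = TRUE)
  smeta <- meta_table(
    subject_ids,
    data.frame(Population = pops$label[pop_of],
               SuperPopulation = pops$super_label[pop_of],
               stringsAsFactors = FALSE),
    kinds = c("categorical", "categorical"), axis = "subject")
  gene <- sprintf("GENE%d", rep_len(rep(seq_len(spec$n_genes),
                                        each = ceiling(m / spec$n_genes)),
                                    m))
  vmeta <- meta_table(
    M$variants$id,
    data.frame(Gene = gene, Position = as.numeric(M$variants$pos),
               stringsAsFactors = FALSE),
    kinds = c("categorical", "numerical"), axis = "variant")
  list(matrix = M, subject_meta = smeta, variant_meta = vmeta,
       F = F, rare = rare, spec = spec)
}

#' Write a simulated cohort to standard files
#'
#' Writes the haplotype matrix in VCF and/or IMPUTE2 form plus the two
#' annotation TSVs; reading the files back reproduces the matrix.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("vcf", "impute2")`.
#' @param gzip write the VCF gzip-compressed.
#' @return named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, formats = c("vcf", "impute2"),
                         gzip = FALSE) {
  stopifnot(is.list(cohort), inherits(cohort$matrix, "hap_matrix"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if ("vcf" %in% formats) {
    paths$vcf <- file.path(dir, if (gzip) "cohort.vcf.gz" else "cohort.vcf")
    write_vcf(cohort$matrix, paths$vcf)
  }
  if ("impute2" %in% formats) {
    paths$hap <- file.path(dir, "cohort.hap")
    paths$legend <- file.path(dir, "cohort.legend")
    paths$sample <- file.path(dir, "cohort.sample")
    write_impute2(cohort$matrix, paths$hap, paths$legend, paths$sample)
  }
  paths$subject_meta <- file.path(dir, "subjects.tsv")
  write_meta(cohort$subject_meta, paths$subject_meta, id_name = "Subject")
  paths$variant_meta <- file.path(dir, "variants.tsv")
  write_meta(cohort$variant_meta, paths$variant_meta, id_name = "SNV")
  invisible(paths)
}
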