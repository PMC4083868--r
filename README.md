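# haplopaint

Scriptable exploration and static visualization of **phased haplotype** and
unphased genotype matrices from population-scale resequencing studies.

Genotype matrices answer *which* variants an individual carries; phase
information additionally assigns each allele to its chromosome of origin,
which is what makes haplotype patterns — population-specific substitution
blocks, parent-of-origin signals, rare-variant clustering — visible at all.
`haplopaint` re-creates, as a library plus command-line tool, the
computational core such a viewer needs:

* **Compressed storage.** Calls over the alphabet Σ = {A, C, G, T} are
  packed at 2 bits per allele, so one diploid call (paternal + maternal
  allele of one SNV for one subject) costs 4 payload bits. For n subjects,
  m SNVs and p allele columns the payload is exactly `n·m·p·2` bits:
  a 1000-subject × 4·10⁶-SNV diploid cohort needs 2 GByte of payload versus
  16 GByte at two bytes per character — an 8-fold reduction. Missing calls
  (e.g. the absent second allele of male X genotypes) live in a separate
  1-bit mask, and only requested sub-blocks are ever decompressed.
* **Input formats.** Phased/unphased VCF 4.x (GT fields, `|` or `/`
  separators, plain or gzip), IMPUTE2 hap/legend/sample triples, and a
  two-header-line tab-delimited annotation dialect (column names on line 1,
  `CATEGORICAL`/`NUMERICAL` declarations on line 2) for subject and SNV
  meta-information.
* **Filters and sorting.** SNV filters by chromosomal region, identifier
  list, identifier regular expression (full-match), and non-reference
  allele frequency — strictly above or strictly below a threshold, e.g.
  the 0.5% bound separating common from rare variants. Subjects and
  variants sort by annotation columns with a *stable* sort, so consecutive
  sorts compose into compound keys.
* **Aggregation.** Subject groups (typically populations) collapse into
  consensus rows: per variant and allele column the most frequent base
  (`maximum` method) or the least frequent observed base (`minimum`) is
  stored with its relative frequency f = count/informative calls, ties
  broken A < C < G < T. Aggregated rows are labelled `AGN<k>` where k is
  the number of aggregated individuals; paternal and maternal columns
  aggregate independently.
* **Rendering and export.** Heatmap-style figures with three color
  encodings — per-nucleotide (A green, C blue, G yellow, T red), reference
  (match blue / mismatch yellow), and genotype (reference green /
  heterozygous yellow / homozygous-alternate red; one column per SNV) —
  plus a P/M marker row, annotation side panels, and aggregate cells drawn
  either with frequency-scaled saturation or as bars of height
  `round(f · cell_h)`. Export to PNG, JPEG, TIFF, SVG or PDF.
* **Cohort simulator.** A seeded generator of multi-population phased
  cohorts (default: 14 populations in 4 super-populations) with
  controllable common/rare variant structure, used throughout the test
  suite.

## Worked example

A miniature phased cohort ships with the package (3 subjects, 5 SNVs on
chromosome 22 around the arylsulfatase-A locus, with missing and
half-calls):

```r
library(haplopaint)

vcf  <- system.file("extdata", "example.vcf", package = "haplopaint")
meta <- system.file("extdata", "example_subjects.tsv", package = "haplopaint")

res   <- read_vcf(vcf)
M     <- res$matrix
smeta <- read_meta(meta, "subject")
M
#> hap_matrix: 3 subjects x 5 SNVs x 2 allele column(s), phased
#>   payload: 60 bits packed in 8 bytes; mask: 4 bytes

summarize_dataset(M, smeta, res$variant_meta)
#> 3 subjects, 5 SNVs, phased, 3 MI columns, 2 MI rows

round(alt_allele_frequency(M), 3)
#> [1] 0.500 0.167 0.250 0.167 0.250
```

The first SNV, rs743616 (a C→G substitution), carries the alternate allele
on 3 of its 6 calls. Aggregating by population and probing
that site:

```r
g <- group_by_meta(M, smeta, "Population")
A <- aggregate_rows(M, g, "maximum")
A
#> agg_matrix: 2 group(s) x 5 SNVs x 2 allele column(s), method maximum
#>   CEU (AGN2)
#>   YRI (AGN1)

j <- match("rs743616", A$variants$id)
A$consensus[1, j, ]; A$frequency[1, j, ]
#> [1] "C" "G"
#> [1] 0.5 1.0
```

Both CEU subjects carry G on the right-hand ("maternal") column, so its
consensus frequency is 1.0, while the left column splits C/G — exactly the
kind of allele-column asymmetry phased displays exist to show. Render and
export:

```r
cv <- render_matrix(A, smeta, res$variant_meta,
                    render_options(encoding = "reference",
                                   aggregate_mode = "bar"))
cv
#> hap_canvas: 158 x 64 px, 63 cell rect(s), encoding reference
export_image(cv, "example.png")          # also .svg/.pdf/.jpeg/.tiff
```

The same run from a shell:

```sh
exec/haplopaint view --vcf example.vcf --subject-meta subjects.tsv \
    --freq-above 0.005 --sort-rows Population \
    --aggregate-by Population --method maximum \
    --encoding reference --out view.png --log view.log
```

`view.log` records every transformation with before/after dimensions.

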