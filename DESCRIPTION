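Package: haplopaint
Title: Bit-Packed Storage, Filtering, Aggregation and Visualization of
    Phased Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scriptable toolkit for exploring phased haplotype and unphased
    genotype matrices from population-scale resequencing studies. Haplotype
    calls are held in a compressed two-bit-per-allele store with a separate
    missingness mask, loaded from phased VCF or IMPUTE2 hap/legend/sample
    files together with tab-delimited subject and variant annotations.
    Variants can be filtered by genomic region, identifier list, identifier
    regular expression or non-reference allele frequency; subjects and
    variants can be reordered by stable metadata-driven sorts. Subject
    groups (for example populations) are collapsed into consensus rows
    carrying the consensus base and its frequency, and matrices are rendered
    as static heatmap-style figures with nucleotide, reference-based or
    genotype color encodings, saturation or bar-height aggregate displays,
    and PNG, JPEG, TIFF, SVG or PDF export. A seeded cohort simulator
    generates multi-population fixtures with controllable common and rare
    variant structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    png,
    stats,
    tiff,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
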