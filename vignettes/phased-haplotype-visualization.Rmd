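---
title: "Models and methods behind haplopaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplopaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopaint)
```

`haplopaint` turns phased haplotype or unphased genotype matrices into
static, reproducible figures, with the data-reduction steps (filtering,
stable sorting, consensus aggregation) exposed as ordinary R functions.
This vignette explains the underlying models, the parameters that matter,
the numerical choices, and what the package deliberately does not do.

## The data model

A cohort is a matrix of allele calls over the nucleotide alphabet
Σ = {A, C, G, T}: `n` subjects × `m` single-nucleotide variants × `p`
allele columns. Phased diploid data has `p = 2` — the left ("P") and right
("M") allele of each VCF `a|b` genotype — so every SNV occupies two display
columns and chromosome-of-origin patterns stay visible. Unphased data keeps
the same layout but is flagged, and the genotype color encoding collapses
each SNV to one column.

### Two-bit packing

Each base is coded in two bits (A = 0, C = 1, G = 2, T = 3; the mapping is
an arbitrary fixed bijection, chosen alphabetical). One diploid call
therefore costs 4 payload bits, and the payload of an `n × m × p` matrix is
exactly `n·m·p·2` bits: 2 GByte (decimal, 10⁹ bytes) for 1000 subjects and
4·10⁶ SNVs, against 16 GByte when every character is stored as a two-byte
primitive — a factor of exactly 8.

Missingness cannot fit the two-bit code (five states in four codes), so it
is a **separate one-bit mask**; `payload_size_bits()` and
`mask_size_bits()` report the two components separately rather than
folding the mask into the headline payload figure. A masked cell's payload
bits are defined (zeros) but never interpreted.

Access is lazy: `hap_calls()` and `get_allele()` decode only the requested
cells, and no operation materializes a global decompressed copy. The matrix
is immutable — filters, sorts and slices return new objects — which makes
every pipeline step trivially replayable and testable; the in-place update
model of an interactive GUI is out of scope here.

Variants are kept sorted by `(chrom, pos)` at construction, with ties
broken by identifier, so genomic region queries and figure layouts are
well-defined regardless of input file order.

## Input formats

* **VCF 4.x** (plain or gzip) via the `vcfR` parser. Only CHROM, POS, ID,
  REF, ALT and FORMAT/GT are consulted. Multi-allelic records, INDELs and
  symbolic alleles are skipped with a reported count: the display model is
  built around biallelic SNVs, and indel encodings would need their own
  visual vocabulary. `"a|b"` calls are phased with the left allele in
  column 1; which physical parent that is cannot be inferred from a VCF, so
  the labels "P"/"M" are display conventions, not pedigree claims. A
  ploidy-1 call (`"0"`, e.g. male X) leaves column 2 missing; any `/`
  separator flags the whole matrix unphased (mixed files warn).
* **IMPUTE2 hap/legend/sample**: hap tokens 0/1 map to the legend's
  `a0`/`a1` alleles, `?` to missing; haplotype columns 2s−1, 2s become
  subject s's two allele columns. Always phased.
* **Annotation TSVs** use two header lines — names, then `CATEGORICAL` or
  `NUMERICAL` per column (case-insensitive) — with identifiers in the first
  column. Empty cells and `NA` are absent values; both conventions appear
  in the wild and the dialect does not fix one.

Writers (`write_vcf()`, `write_impute2()`, `write_meta()`) are exact
inverses of the readers on the supported subset, which the suite checks by
round-tripping simulated cohorts through both formats.

## Filters and frequency

All filters act on the variant axis and preserve variant order and allele
bits. The frequency filter needs a definition of "the" frequency of a
variant: `haplopaint` uses the **non-reference allele frequency over
non-missing allele calls**, counted across all subjects and both allele
columns. On phased data this is the only reading under which a single
percentage threshold "across all individuals" is well-defined per variant;
a subject-level alternative (fraction of carriers) is available via
`alt_allele_frequency(per = "subject")` for users who want genotype-level
semantics. Thresholds are **strict** (`> t` above, `< t` below), matching
the usual "> 0.5%" / "< 0.5%" phrasing for separating common from rare
variants; variants whose calls are all missing have no defined frequency
and are dropped by the filter with a reported count.

Identifier regular expressions use **full-match** semantics (the pattern is
anchored internally): `rs7.*` matches `rs743616`, but a bare prefix like
`rs7` matches nothing, which keeps id filters predictable.

## Stable sorting

`sort_rows_by_meta()` / `sort_columns_by_meta()` use a stable (radix)
sort: equal keys keep their prior relative order, so sorting by column B
and then by column A is identical to one compound-key (A, B) sort — the
property that makes consecutive interactive sorts meaningful, and the one
the test suite asserts over randomized annotation tables. Categorical
labels sort lexicographically (C locale), numerical values ascending;
subjects or variants without a value sort last in prior order. The choice
of lexicographic categorical order is a convention — any fixed order works,
this one needs no configuration.

## Consensus aggregation

For a group G of subjects, a variant j and an allele column k, the member
calls are tallied with missing calls excluded. The `maximum` method picks
the most frequent base (the consensus in the usual sense), `minimum` the
least frequent *observed* base — useful when rare alleles are the object of
study. The stored frequency is always `count(picked base) / n_informative`
and `n_informative` is kept per cell so renderings of sparse groups stay
honest. Ties break by the fixed base order A < C < G < T, making results
deterministic across runs. A `mean` of categorical base data is undefined,
so for haplotype cells only `maximum`/`minimum` are offered; `mean` (plus
`minimum`/`maximum`/`mode`) applies to annotation columns through
`aggregate_meta_column()`.

Group rows are labelled `AGN<k>` with k the member count. Allele columns
aggregate independently, so a signal confined to one chromosome of origin
(e.g. a mostly-maternal allele) survives aggregation. The frequency `f`
itself is stored even for minimum-method views; the renderer's
`rarity_bars` flag draws `1 − f` when bar height should express rarity
rather than agreement — storing the raw quantity and letting the display
invert keeps the stored matrix method-agnostic.

## Rendering

The renderer produces a deterministic pixel raster plus a rectangle/text
display list, so raster exports are byte-reproducible (no fonts touch the
pixels; text labels exist only in vector exports) and pixel-probe tests can
assert color rules exactly.

Color defaults follow the conventional qualitative assignments — nucleotide
view A green, C blue, G yellow, T red, missing white; reference view
match blue / mismatch yellow; genotype view both-reference green /
heterozygous yellow / homozygous-alternate red — with concrete RGB values
taken from ColorBrewer-style palettes, since only the hues, not exact RGB
coordinates, are fixed by convention. Every color is overridable via
`render_options()` or a YAML file.

Aggregate cells are drawn in one of two modes:

* **saturation** — the cell's HSV saturation is scaled by
  `0.15 + 0.85·f`. Monotonicity in f is the requirement; the linear form
  with a 0.15 floor is our choice, the floor keeping weak-consensus cells
  visible against white.
* **bar** — a bottom-anchored bar of height `round(f · cell_h)` pixels in
  the consensus base's color. Rounding half-up to whole pixels is asserted
  in the tests.

Layout is pure arithmetic: grid width is `m · p_disp · cell_w`, with the
P/M marker row and variant annotation rows below and subject annotation
columns to the right, separated by a fixed pixel gap — so canvas dimensions
are exact affine functions of the matrix shape, which the suite asserts.
Zooming is simply `cell_w`/`cell_h`; selections are drawn as black row or
column outlines. Numerical annotation gradients interpolate linearly over
the full column's range (not the displayed subset's), so colors remain
comparable across filtered views; categorical colors are assigned in
first-seen order of the full column for the same reason.

`export_image()` writes PNG/TIFF pixels directly, JPEG through a device at
exact pixel size, and SVG/PDF by replaying the display list as vector
rectangles. Sub-region export crops to the bounding window of the selected
rows × variants (cell-aligned, annotation panels excluded).

## The cohort simulator

`simulate_cohort()` exists so every code path — rare/common frequency
filters, multi-population aggregation, P/M asymmetries, missing calls, both
file formats — can be exercised without external downloads. Its default
mirrors the population structure of large human resequencing panels in
miniature: 14 populations in 4 super-populations (3 subjects each by
default), one chromosome, and a 0.5% rare-variant threshold. Alleles are
drawn i.i.d. per haplotype: subject in population p is alternate at variant
j with probability `F[p, j]`, independently per allele column. Rare
variants draw `F` from `(0, rare_threshold)` per population; common
variants share a base frequency from `common_range` (default 0.05–0.6,
a realistic common-variant band) with ±0.05 per-population jitter to give
populations distinguishable profiles. All draws are fixed by a single seed.

What the simulator does **not** emulate: linkage disequilibrium,
recombination, demography and genotyping error correlation. Passing tests
therefore demonstrate algorithmic correctness of storage, filtering,
aggregation and rendering — not that biological LD structure would be
displayed faithfully; on real data the same code paths run unchanged, but
patterns driven by LD will look different from i.i.d. fixtures.

## Problem sizes and determinism

The test and acceptance workloads are sized for a desk-scale run: codec
round trips over ~10⁴ random calls, filter oracles on a simulated
504-subject × 2000-variant cohort, aggregation oracles over 14 × 60 × 2
cells, 100 randomized sort-law tables, and a 42 × 50 end-to-end render.
These sizes exercise every branch while keeping the whole suite under a
minute; the size *laws* are checked analytically up to the
1000 × 4·10⁶ cohort shape. All randomness flows from explicit seeds, and
renders of identical inputs are byte-identical.

## Known limitations

* Biallelic SNVs only; multi-allelic records and INDELs are skipped on
  import (reported, not silently dropped).
* `p ≤ 2` allele columns; polyploid display would need a wider layout.
* No interactive features: navigation, live re-sorting, tooltips and
  selection-by-mouse are replaced by function arguments and re-rendering.
* Subject-axis filtering by annotation values is intentionally absent
  (subjects are selected by slicing or grouping); filters are variant-axis
  operations.
* The frequency filter's per-allele definition can differ from tools that
  count per-genotype; use `per = "subject"` to compare.
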