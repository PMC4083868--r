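#' Allele alphabet and two-bit codes
#'
#' Haplotype calls are drawn from the four-letter nucleotide alphabet
#' {A, C, G, T}; a missing call (for example the absent second allele of a
#' male X chromosome) is represented as `NA`. Each base is assigned a fixed
#' two-bit code so that a full call fits in two bits of the packed payload;
#' missingness is tracked in a separate one-bit mask because five states do
#' not fit two bits.
#'
#' The code assignment is alphabetical: A = 0, C = 1, G = 2, T = 3.
#'
#' @name alleles
NULL

#: fixed bijection base <-> 2-bit code; order also serves as the
#: deterministic tie-break order for consensus calls (A < C < G < T)
ALLELE_BASES <- c("A", "C", "G", "T")

#' Convert a base to its two-bit code
#'
#' @param a character vector of bases, each one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return integer vector of codes in 0..3.
#' @examples
#' allele_to_code(c("A", "T"))
#' @export
allele_to_code <- function(a) {
  if (any(is.na(a))) {
    stop("missing alleles have no code: missingness is stored in the mask, ",
         "not in the two-bit payload", call. = FALSE)
  }
  code <- match(a, ALLELE_BASES) - 1L
  if (anyNA(code)) {
    stop("invalid allele(s): ", paste(unique(a[is.na(code)]), collapse = ", "),
         " (expected A, C, G or T)", call. = FALSE)
  }
  code
}

#' Convert a two-bit code back to its base
#'
#' @param code integer vector with values in 0..3.
#' @return character vector of bases.
#' @examples
#' code_to_allele(0:3)
#' @export
code_to_allele <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 3L)) {
    stop("allele codes must be integers in 0..3", call. = FALSE)
  }
  ALLELE_BASES[code + 1L]
}

is_valid_base <- function(a) !is.na(a) & a %in% ALLELE_BASES
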