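## The 96-category substitution space: 6 pyrimidine-referenced substitution
## types x 16 trinucleotide contexts. Ordering is fixed package-wide
## (substitution-major, then 5' flank, then 3' flank) so that catalog rows
## always align with signature-matrix rows.

SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution categories
#'
#' Returns the fixed, ordered vector of category labels, e.g. `"A[C>A]A"`.
#' The ordering is lexicographic by substitution type, then 5' flanking
#' base, then 3' flanking base; every catalog and signature matrix in the
#' package uses this row order.
#'
#' @return Character vector of length 96.
#' @export
mut_category_levels <- function() {
  grid <- expand.grid(context3 = DNA_BASES, context5 = DNA_BASES,
                      substitution = SUBSTITUTION_TYPES,
                      stringsAsFactors = FALSE)
  ## expand.grid varies its first factor fastest; we want substitution
  ## slowest, context5 next, context3 fastest
  sprintf("%s[%s]%s", grid$context5, grid$substitution, grid$context3)
}

#' Classify a substitution into its strand-collapsed category
#'
#' Maps a single-base substitution with its two flanking reference bases
#' onto one of the 96 pyrimidine-referenced categories. Mutations reported
#' with a purine reference (A or G) are reverse-complemented — substitution
#' and both flanks — so that the returned category always has a C or T
#' reference. All arguments are vectorized.
#'
#' @param ref,alt Reference and alternate alleles (single bases, A/C/G/T).
#' @param context5,context3 Reference bases immediately 5' and 3' of the
#'   mutated position, on the plus strand.
#' @return A data.frame with columns `substitution` (one of the 6 types),
#'   `context5`, `context3` (collapsed flanks), `label` (e.g. `"T[C>A]G"`)
#'   and `index` (1-based position in [mut_category_levels()]).
#' @examples
#' classify_substitution("G", "T", "T", "T")  # collapses to A[C>A]A
#' @export
classify_substitution <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  ok <- .is_base(ref) & .is_base(alt) & .is_base(context5) & .is_base(context3)
  if (!all(ok)) {
    stop("non-ACGT base in substitution input (first offender at position ",
         which(!ok)[1], ")")
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ")
  }
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .complement(ref), ref)
  a <- ifelse(flip, .complement(alt), alt)
  c5 <- ifelse(flip, .complement(context3), context5)
  c3 <- ifelse(flip, .complement(context5), context3)
  label <- sprintf("%s[%s>%s]%s", c5, r, a, c3)
  idx <- match(label, mut_category_levels())
  data.frame(substitution = paste0(r, ">", a),
             context5 = c5, context3 = c3,
             label = label, index = idx,
             stringsAsFactors = FALSE)
}

## Strand on which the mutated pyrimidine sits, given the plus-strand ref
## allele of the record: C/T ref -> "+", A/G ref -> "-".
pyrimidine_strand <- function(ref) {
  ifelse(ref %in% c("C", "T"), "+", "-")
}
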