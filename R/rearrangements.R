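## Structural-variant filtering, breakpoint clustering and the 38-category
## classification (type x size bin x clustered status, plus the two
## translocation categories).

SV_TYPES_INTRA <- c("del", "dup", "inv")
SV_SIZE_BREAKS <- c(0, 1e3, 1e4, 1e5, 1e6, 1e7, Inf)
SV_SIZE_LABELS <- c("<1kb", "1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")

#' The 38 structural-variant categories
#'
#' Deletions, tandem duplications and inversions in six size bins, each
#' split by clustered status (36 labels), plus clustered and non-clustered
#' interchromosomal translocations. Size bins are half-open on the left
#' boundary convention `[low, high)`: a 1 kb event falls in "1-10kb" and a
#' 1 Mb event in "1-10Mb".
#'
#' @return Character vector of 38 labels, the fixed row order of SV
#'   catalogs.
#' @export
sv_category_levels <- function() {
  intra <- as.vector(outer(SV_SIZE_LABELS, SV_TYPES_INTRA,
                           function(sz, ty) paste(ty, sz, sep = ":")))
  intra <- as.vector(t(outer(intra, c("clustered", "non-clustered"), paste, sep = ":")))
  c(intra, "trans:clustered", "trans:non-clustered")
}

#' Filter structural variants on read evidence
#'
#' Keeps SVs supported by at least `min_reads` reads; inversions and
#' interchromosomal translocations must additionally be supported by at
#' least `min_fraction` of reads. Records with missing evidence fields are
#' rejected with reason `"missing-evidence"`. Filtering is idempotent.
#'
#' @param svs SV table (see [read_sv_table()]).
#' @param min_reads Minimum supporting reads, all types (default 15).
#' @param min_fraction Minimum supporting read fraction for inversions and
#'   translocations (default 0.10).
#' @return List with `retained` (SV table) and `rejected` (SV table with a
#'   `reason` column).
#' @export
filter_svs <- function(svs, min_reads = 15, min_fraction = 0.10) {
  frac_needed <- svs$sv_type %in% c("inv", "trans")
  missing_ev <- is.na(svs$supporting_reads) | (frac_needed & is.na(svs$read_fraction))
  low_reads <- !missing_ev & svs$supporting_reads < min_reads
  low_frac <- !missing_ev & !low_reads & frac_needed & svs$read_fraction < min_fraction
  keep <- !(missing_ev | low_reads | low_frac)
  rejected <- svs[!keep, , drop = FALSE]
  rejected$reason <- ifelse(missing_ev[!keep], "missing-evidence",
                            ifelse(low_reads[!keep], "low-read-support",
                                   "low-read-fraction"))
  list(retained = svs[keep, , drop = FALSE], rejected = rejected)
}

## Core clustering rule on one sorted-or-not position vector: position i is
## clustered iff some window of length `window` contains it together with
## >= min_breakpoints positions. Two-pointer scan over the sorted vector.
flag_clustered_positions <- function(pos, window = 1e6, min_breakpoints = 10) {
  n <- length(pos)
  if (n < min_breakpoints) return(rep(FALSE, n))
  o <- order(pos)
  p <- pos[o]
  flag <- rep(FALSE, n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && p[j + 1L] - p[i] <= window) j <- j + 1L
    if (j - i + 1L >= min_breakpoints) flag[i:j] <- TRUE
  }
  out <- logical(n)
  out[o] <- flag
  out
}

#' Flag clustered structural variants
#'
#' A breakpoint is clustered when it lies in some 1 Mb window containing
#' at least 10 breakpoints of the same sample (windows are continuously
#' placed, not tiled); an SV is clustered when any of its breakpoints is.
#' Intra-chromosomal events contribute both breakpoints on their
#' chromosome; translocations contribute one breakpoint per partner
#' chromosome.
#'
#' @param svs SV table.
#' @param window Window size in bases (default 1e6).
#' @param min_breakpoints Breakpoint count threshold (default 10).
#' @return `svs` with a logical `clustered` column.
#' @export
detect_clusters <- function(svs, window = 1e6, min_breakpoints = 10) {
  n <- nrow(svs)
  bp <- data.frame(sv = rep(seq_len(n), 2L),
                   sample = rep(as.character(svs$sample_id), 2L),
                   chrom = c(as.character(svs$chrom1), as.character(svs$chrom2)),
                   pos = c(svs$pos1, svs$pos2),
                   stringsAsFactors = FALSE)
  bp$clustered <- FALSE
  for (key in unique(paste(bp$sample, bp$chrom))) {
    sel <- paste(bp$sample, bp$chrom) == key
    bp$clustered[sel] <- flag_clustered_positions(bp$pos[sel], window, min_breakpoints)
  }
  per_sv <- tapply(bp$clustered, bp$sv, any)
  svs$clustered <- unname(as.logical(per_sv[as.character(seq_len(n))]))
  if (n == 0) svs$clustered <- logical(0)
  svs
}

#' Classify structural variants into the 38 categories
#'
#' @param svs SV table with the `clustered` flag set (see
#'   [detect_clusters()]).
#' @return `svs` with added `size` (NA for translocations) and `category`
#'   columns.
#' @export
classify_sv <- function(svs) {
  if (is.null(svs$clustered)) stop("run detect_clusters() before classify_sv()")
  intra <- svs$sv_type %in% SV_TYPES_INTRA
  size <- ifelse(intra, abs(svs$pos2 - svs$pos1), NA_real_)
  if (any(intra & (is.na(size) | size <= 0))) {
    stop("intra-chromosomal SV with non-positive size")
  }
  status <- ifelse(svs$clustered, "clustered", "non-clustered")
  bin <- SV_SIZE_LABELS[findInterval(size, SV_SIZE_BREAKS, rightmost.closed = FALSE)]
  category <- ifelse(intra,
                     paste(svs$sv_type, bin, status, sep = ":"),
                     paste("trans", status, sep = ":"))
  if (!all(category[!is.na(category)] %in% sv_category_levels())) {
    stop("unknown SV type encountered")
  }
  svs$size <- size
  svs$category <- category
  svs
}

#' Build the 38-category rearrangement catalog
#'
#' One event contributes one count in its category; column sums equal the
#' number of classified SVs per sample.
#'
#' @param svs Classified SV table (see [classify_sv()]).
#' @return Integer 38 x n_samples matrix.
#' @export
build_sv_catalog <- function(svs) {
  samples <- sort(unique(as.character(svs$sample_id)))
  tab <- table(factor(svs$category, levels = sv_category_levels()),
               factor(as.character(svs$sample_id), levels = samples))
  matrix(as.integer(tab), nrow = 38,
         dimnames = list(sv_category_levels(), samples))
}

#' Call rearrangement phenotypes from SV signature exposures
#'
#' A sample carries a rearrangement phenotype when at least `min_events`
#' rearrangements are attributed to the corresponding signature.
#'
#' @param exposures Signature x sample exposure matrix (count units), e.g.
#'   `fit$counts` from [fit_exposures()] on a 38-row catalog or
#'   `fit$exposures` from [extract_denovo()].
#' @param min_events Attribution threshold (default 50).
#' @return Logical samples x signatures matrix of phenotype flags.
#' @export
call_phenotypes <- function(exposures, min_events = 50) {
  t(as.matrix(exposures) >= min_events)
}
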