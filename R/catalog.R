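## Building the 96 x samples mutation catalog from somatic mutation records.
##
## A mutation table is a plain data.frame with at least the columns
## sample_id, chrom, pos (1-based), ref, alt and optionally
## alt_reads_tumor / total_reads_tumor. The reference genome is a named
## character vector of chromosome sequences (see read_genome_fasta()).

#' Derive the mutation class of each record
#'
#' @param ref,alt Allele strings (VCF conventions: indels carry a shared
#'   anchor base).
#' @return Character vector with values `"SNV"`, `"INS"` or `"DEL"`.
#' @export
mutation_class <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV", ifelse(la > lr, "INS", "DEL"))
}

#' Build the 96-category mutation catalog
#'
#' Counts the SNVs of each sample in each of the 96 strand-collapsed
#' trinucleotide categories (the mutation matrix M, with entry the number
#' of mutations of a category in a sample). Indels are excluded from the
#' matrix; route them through [summarize_indels()]. SNVs whose flanking
#' bases are unavailable or whose reported reference allele disagrees with
#' the genome are skipped, counted, and reported via a warning and the
#' `"n_skipped"` attribute.
#'
#' @param mutations Mutation table (see above). `mut_class` is derived from
#'   the alleles if absent.
#' @param genome Named character vector of chromosome sequences.
#' @return Integer matrix, 96 x n_samples, rownames the category labels,
#'   colnames the sorted sample ids, with attribute `n_skipped`.
#' @export
build_catalog <- function(mutations, genome) {
  samples <- sort(unique(as.character(mutations$sample_id)))
  levels96 <- mut_category_levels()
  out <- matrix(0L, nrow = 96, ncol = length(samples),
                dimnames = list(levels96, samples))
  cls <- mutation_class(mutations$ref, mutations$alt)
  snv <- mutations[cls == "SNV", , drop = FALSE]
  n_skipped <- 0L
  if (nrow(snv) > 0) {
    chrom <- as.character(snv$chrom)
    pos <- as.integer(snv$pos)
    len <- nchar(genome)[chrom]
    inside <- !is.na(len) & pos >= 2L & pos <= len - 1L
    c5 <- c3 <- refg <- rep(NA_character_, nrow(snv))
    idx <- which(inside)
    if (length(idx)) {
      tri <- substr(genome[chrom[idx]], pos[idx] - 1L, pos[idx] + 1L)
      c5[idx] <- substr(tri, 1L, 1L)
      refg[idx] <- substr(tri, 2L, 2L)
      c3[idx] <- substr(tri, 3L, 3L)
    }
    usable <- inside & refg == snv$ref &
      .is_base(c5) & .is_base(c3) & .is_base(snv$ref) & .is_base(snv$alt)
    usable[is.na(usable)] <- FALSE
    n_skipped <- sum(!usable)
    if (n_skipped > 0) {
      warning(sprintf("skipped %d SNV(s) with unavailable context or reference mismatch",
                      n_skipped))
    }
    if (any(usable)) {
      cat_df <- classify_substitution(snv$ref[usable], snv$alt[usable],
                                      c5[usable], c3[usable])
      tab <- table(factor(cat_df$label, levels = levels96),
                   factor(as.character(snv$sample_id)[usable], levels = samples))
      out <- out + matrix(as.integer(tab), nrow = 96,
                          dimnames = list(levels96, samples))
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Flag indels occurring at polynucleotide repeats
#'
#' An insertion or deletion is considered to lie in a polynucleotide repeat
#' when the event's unit occurs in at least 2 exact tandem copies at the
#' site: concretely, the reference sequence immediately following the event
#' begins with at least one further full copy of the inserted/deleted unit
#' (the event's own unit provides the other copy).
#'
#' @param mutations Mutation table; non-indel rows get `NA`.
#' @param genome Named character vector of chromosome sequences.
#' @return Logical vector `at_repeat`, aligned with the rows of `mutations`.
#' @export
annotate_indel_repeats <- function(mutations, genome) {
  cls <- mutation_class(mutations$ref, mutations$alt)
  out <- rep(NA, nrow(mutations))
  for (i in which(cls != "SNV")) {
    ref <- as.character(mutations$ref[i])
    alt <- as.character(mutations$alt[i])
    unit <- if (cls[i] == "DEL") substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
    chrom <- as.character(mutations$chrom[i])
    ## reference position just after the event (after the deleted bases for
    ## a deletion, after the anchor base for an insertion)
    after <- as.integer(mutations$pos[i]) + nchar(ref)
    seqc <- genome[[chrom]]
    if (is.null(seqc) || is.na(seqc)) next
    flank <- substr(seqc, after, min(nchar(seqc), after + nchar(unit) - 1L))
    out[i] <- nchar(unit) > 0 && identical(flank, unit)
  }
  out
}

#' Summarize indels by type, size class and gene-expression bin
#'
#' Cross-tabulates insertions and deletions by size class (1, 2-5, >5
#' bases — the 2-5 class isolates the short-deletion excess seen in very
#' highly expressed genes) and by the expression bin of the containing
#' gene; indels outside any gene count as `"intergenic"`.
#'
#' @param mutations Mutation table with a `gene` column (`NA` when
#'   intergenic).
#' @param gene_bins Named character vector mapping gene id to expression
#'   bin label (see [expression_bins()]).
#' @return A 3-way contingency table `indel_type x size_class x bin`.
#' @export
summarize_indels <- function(mutations, gene_bins) {
  cls <- mutation_class(mutations$ref, mutations$alt)
  ind <- mutations[cls != "SNV", , drop = FALSE]
  type <- cls[cls != "SNV"]
  size <- abs(nchar(ind$ref) - nchar(ind$alt))
  size_class <- cut(size, breaks = c(0, 1, 5, Inf),
                    labels = c("1", "2-5", ">5"))
  bin_levels <- unique(c(as.character(gene_bins), "intergenic"))
  gene <- if ("gene" %in% names(ind)) as.character(ind$gene) else rep(NA, nrow(ind))
  bin <- ifelse(is.na(gene) | is.na(gene_bins[gene]), "intergenic",
                as.character(gene_bins[gene]))
  table(indel_type = factor(type, levels = c("INS", "DEL")),
        size_class = size_class,
        bin = factor(bin, levels = bin_levels))
}
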