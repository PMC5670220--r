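## Readers and writers for the tab-delimited interchange formats used at
## the package boundary. Coordinates in mutation/segment tables are
## 1-based inclusive (VCF convention); bedGraph input is 0-based
## half-open and converted on read.

#' Read a mutation table from a tab-delimited file
#'
#' Expects columns sample_id, chrom, pos, ref, alt and optionally
#' alt_reads_tumor, total_reads_tumor (a header line is required).
#'
#' @param path File path.
#' @return data.frame of mutation records.
#' @export
read_mutations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (all(c("alt_reads_tumor", "total_reads_tumor") %in% names(df))) {
    bad <- df$alt_reads_tumor > df$total_reads_tumor
    if (any(bad, na.rm = TRUE)) stop("alt reads exceed total reads in mutation table")
  }
  df
}

#' Read somatic mutations from a VCF file
#'
#' Thin wrapper around \pkg{vcfR}: extracts position, alleles and the
#' tumor-sample AD field (alt/total read counts). Multi-allelic records
#' are skipped with a warning, as are records without usable depth.
#'
#' @param path VCF path (4.x, plain or gzipped).
#' @param sample Name of the tumor sample column; defaults to the first.
#' @return data.frame of mutation records as in [read_mutations_tsv()].
#' @export
read_mutations_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", sum(multi)))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  adv <- ad[, sample]
  parts <- strsplit(adv, ",", fixed = TRUE)
  refd <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
  altd <- suppressWarnings(as.integer(vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_, character(1))))
  keep <- !multi & !is.na(refd) & !is.na(altd)
  data.frame(sample_id = sample,
             chrom = fix$CHROM[keep],
             pos = as.integer(fix$POS[keep]),
             ref = fix$REF[keep],
             alt = fix$ALT[keep],
             alt_reads_tumor = altd[keep],
             total_reads_tumor = refd[keep] + altd[keep],
             stringsAsFactors = FALSE)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a signature probability matrix from TSV
#'
#' Expects 96 rows labelled with the trinucleotide category labels of
#' [mut_category_levels()] (first column) and one column per signature.
#' Rows are reordered to the package's fixed category order; each column
#' must sum to 1 within 1e-6.
#'
#' @param path File path.
#' @return Numeric 96 x S matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  lv <- mut_category_levels()
  if (!setequal(rownames(df), lv)) {
    stop("signature matrix rows do not match the 96 category labels")
  }
  P <- as.matrix(df[lv, , drop = FALSE])
  sums <- colSums(P)
  if (any(abs(sums - 1) > 1e-6) || any(P < 0)) {
    stop("signature columns must be non-negative and sum to 1")
  }
  P
}

#' Write a catalog (or any category x sample matrix) to TSV
#'
#' @param catalog Matrix with category rownames.
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(data.frame(category = rownames(catalog), catalog,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read allele-specific copy-number segments (Battenberg-like TSV)
#'
#' Expects columns sample_id, chrom, start, end, major, minor; total
#' tumor copy number is derived as major + minor.
#'
#' @param path File path.
#' @return data.frame of segments with an added `n_tumor` column.
#' @export
read_cn_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "major", "minor")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("segment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$minor > df$major)) stop("minor allele copy number exceeds major")
  df$n_tumor <- df$major + df$minor
  df
}

#' Read a BEDPE-like structural-variant table
#'
#' Expects columns sample_id, chrom1, pos1, chrom2, pos2, sv_type
#' (del/dup/inv/trans), supporting_reads, read_fraction.
#'
#' @param path File path.
#' @return data.frame of SV records.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom1", "pos1", "chrom2", "pos2", "sv_type",
            "supporting_reads", "read_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("SV table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a bedGraph replication-timing track
#'
#' bedGraph is 0-based half-open; intervals are kept in that convention
#' internally (a 1-based position p falls in a bin iff start < p <= end).
#'
#' @param path File path (4 columns: chrom, start, end, value; no header).
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  df
}

#' Read gene models from BED6
#'
#' @param path File path (chrom, start, end, name, score, strand).
#' @return data.frame with 1-based inclusive start/end, gene id and strand.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene = df[[4]], chrom = df[[1]],
             start = df[[2]] + 1L, end = df[[3]],
             strand = df[[6]], stringsAsFactors = FALSE)
}

#' Read a two-column gene/FPKM expression table
#'
#' @param path File path with header columns gene, fpkm.
#' @return Named numeric vector of FPKM values.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$fpkm), df$gene)
}
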