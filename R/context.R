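## Replication- and transcription-context analyses: timing deciles,
## leading/lagging fork strands, expression bins, mutation rates per
## informative megabase, strand asymmetries, TSS profiles and the
## transcription-coupled damage/repair slopes.

## ---- replication timing ----------------------------------------------

.local_extrema <- function(values, starts, ends) {
  r <- rle(values)
  nruns <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  mid <- (starts[run_start] + ends[run_end]) / 2
  type <- rep(NA_character_, nruns)
  for (i in seq_len(nruns)) {
    left <- if (i > 1) r$values[i - 1] else -Inf
    right <- if (i < nruns) r$values[i + 1] else -Inf
    if (r$values[i] > left && r$values[i] > right) type[i] <- "peak"
    left <- if (i > 1) r$values[i - 1] else Inf
    right <- if (i < nruns) r$values[i + 1] else Inf
    if (r$values[i] < left && r$values[i] < right) type[i] <- "valley"
  }
  keep <- !is.na(type)
  data.frame(pos = mid[keep], type = type[keep])
}

#' Annotate a replication-timing track with deciles and fork direction
#'
#' Timing deciles partition the covered genome into 10 classes of equal
#' informative size by signal quantile (decile 1 = lowest signal, i.e.
#' latest replication; 10 = earliest). Signal peaks mark replication
#' initiation and valleys termination; bins between an adjacent
#' peak/valley pair are assigned the direction of the fork travelling
#' from the peak towards the valley, but only where the peak-to-valley
#' distance is at least `min_peak_valley` (500 kb by default) — closer
#' pairs stay `"unassigned"`.
#'
#' @param signal bedGraph-style data.frame (chrom, start, end, value;
#'   0-based half-open), sorted by position within chromosome.
#' @param min_peak_valley Minimum peak-to-valley distance in bases.
#' @return List with `bins` (the signal with added `decile` and `fork`
#'   columns, fork in right/left/unassigned), `extrema`, and `degenerate`
#'   (TRUE when the signal is constant and deciles collapse to one class).
#' @export
replication_annotation <- function(signal, min_peak_valley = 5e5) {
  width <- signal$end - signal$start
  degenerate <- diff(range(signal$value)) == 0
  if (degenerate) {
    decile <- rep(1L, nrow(signal))
    warning("constant replication signal: deciles collapse to a single class")
  } else {
    ord <- order(signal$value)
    cum_mid <- cumsum(width[ord]) - width[ord] / 2
    d <- pmin(pmax(ceiling(10 * cum_mid / sum(width)), 1L), 10L)
    decile <- integer(nrow(signal))
    decile[ord] <- d
  }
  signal$decile <- decile
  signal$fork <- "unassigned"
  extrema <- list()
  for (ch in unique(signal$chrom)) {
    sel <- which(signal$chrom == ch)
    ex <- .local_extrema(signal$value[sel], signal$start[sel], signal$end[sel])
    if (nrow(ex)) ex$chrom <- ch
    extrema[[ch]] <- ex
    if (nrow(ex) < 2) next
    for (i in seq_len(nrow(ex) - 1L)) {
      if (ex$type[i] == ex$type[i + 1L]) next
      if (ex$pos[i + 1L] - ex$pos[i] < min_peak_valley) next
      dir <- if (ex$type[i] == "peak") "right" else "left"
      mid <- (signal$start[sel] + signal$end[sel]) / 2
      between <- mid >= ex$pos[i] & mid <= ex$pos[i + 1L]
      signal$fork[sel[between]] <- dir
    }
  }
  list(bins = signal, extrema = do.call(rbind, extrema), degenerate = degenerate)
}

#' Map mutation positions onto a replication annotation
#'
#' @param positions data.frame with chrom and pos (1-based).
#' @param annotation Output of [replication_annotation()].
#' @return data.frame with `decile` and `fork` per position; positions off
#'   the track get NA/unassigned with one summarizing warning.
#' @export
assign_replication_context <- function(positions, annotation) {
  bins <- annotation$bins
  decile <- rep(NA_integer_, nrow(positions))
  fork <- rep("unassigned", nrow(positions))
  for (ch in unique(as.character(positions$chrom))) {
    mi <- which(positions$chrom == ch)
    bi <- which(bins$chrom == ch)
    if (!length(bi)) next
    bo <- bi[order(bins$start[bi])]
    k <- findInterval(positions$pos[mi] - 1L, bins$start[bo])
    hit <- k >= 1 & positions$pos[mi] - 1L < bins$end[bo][pmax(k, 1L)]
    decile[mi[hit]] <- bins$decile[bo][k[hit]]
    fork[mi[hit]] <- bins$fork[bo][k[hit]]
  }
  if (anyNA(decile)) {
    warning(sprintf("%d position(s) outside the replication track", sum(is.na(decile))))
  }
  data.frame(decile = decile, fork = fork, stringsAsFactors = FALSE)
}

#' Leading/lagging strand of a mutation
#'
#' Package convention (a single switch, `plus_is_lagging_for_right_fork`):
#' for a rightward-moving fork the reference plus strand is the
#' lagging-strand template. The mutation sits on the strand carrying its
#' mutated pyrimidine.
#'
#' @param fork Fork direction per mutation (right/left/unassigned).
#' @param pyr_strand Strand of the mutated pyrimidine ("+"/"-"), see
#'   [pyrimidine_strand()].
#' @param plus_is_lagging_for_right_fork Flip to invert the convention.
#' @return Character vector leading/lagging/unassigned.
#' @export
replication_strand <- function(fork, pyr_strand,
                               plus_is_lagging_for_right_fork = TRUE) {
  base <- ifelse(fork == "right", "lagging",
                 ifelse(fork == "left", "leading", "unassigned"))
  flip <- (pyr_strand == "-") != (!plus_is_lagging_for_right_fork)
  ifelse(base == "unassigned", base,
         ifelse(flip, ifelse(base == "lagging", "leading", "lagging"), base))
}

## ---- rates and asymmetry ---------------------------------------------

#' Mutation rate per informative megabase
#'
#' @param n_mutations Mutation count.
#' @param informative_bp Informative region size in bases (excluding 'N'
#'   bases); zero size yields NA with a warning.
#' @return Mutations per Mb.
#' @export
mutation_rate <- function(n_mutations, informative_bp) {
  out <- ifelse(informative_bp > 0, n_mutations / (informative_bp / 1e6), NA_real_)
  if (anyNA(out)) warning("zero informative size: rate undefined")
  out
}

#' Select mutations attributed to a single signature
#'
#' The signature-wise analyses use only mutations attributed to one
#' signature with probability at least `min_prob` (default 0.7).
#'
#' @param attributions n x S matrix from [mutation_probabilities()].
#' @param signature Signature id or column index.
#' @param min_prob Attribution threshold.
#' @return Logical vector of length n.
#' @export
signature_filtered <- function(attributions, signature, min_prob = 0.7) {
  p <- attributions[, signature]
  !is.na(p) & p >= min_prob
}

#' Strand asymmetry of mutation counts
#'
#' Counts mutations per class on two strands and tests each class for
#' departure from 1:1 with an exact binomial test. Mutations on other
#' strands (e.g. "unassigned") are excluded and tallied in attribute
#' `n_excluded`.
#'
#' @param strand Strand label per mutation.
#' @param class Grouping label per mutation (e.g. timing decile or
#'   expression bin); single group by default.
#' @param strands Length-2 character: the two strands to compare (ratio is
#'   first / second).
#' @return data.frame per class: counts, ratio (NA when a denominator is
#'   empty) and p-value.
#' @export
strand_asymmetry <- function(strand, class = rep("all", length(strand)),
                             strands = c("leading", "lagging")) {
  keep <- strand %in% strands
  n_excluded <- sum(!keep)
  strand <- strand[keep]; class <- class[keep]
  lev <- unique(class)
  out <- do.call(rbind, lapply(lev, function(cl) {
    n1 <- sum(class == cl & strand == strands[1])
    n2 <- sum(class == cl & strand == strands[2])
    p <- if (n1 + n2 > 0) stats::binom.test(n1, n1 + n2, 0.5)$p.value else NA_real_
    data.frame(class = cl, n1 = n1, n2 = n2,
               ratio = if (n2 > 0) n1 / n2 else NA_real_, p = p,
               stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- strands
  attr(out, "n_excluded") <- n_excluded
  out
}

## ---- expression bins and gene assignment ------------------------------

#' Bin genes by expression level
#'
#' Unexpressed genes (FPKM 0) form their own class, very highly expressed
#' genes (FPKM >= 100) another; the rest are split into five quintiles of
#' equal gene counts (within 1).
#'
#' @param fpkm Named numeric vector of per-gene FPKM values (one value per
#'   gene, e.g. the median across expression samples).
#' @return Named factor with levels FPKM0, Q1..Q5, VeryHigh.
#' @export
expression_bins <- function(fpkm) {
  lev <- c("FPKM0", paste0("Q", 1:5), "VeryHigh")
  bin <- rep(NA_character_, length(fpkm))
  bin[fpkm <= 0] <- "FPKM0"
  bin[fpkm >= 100] <- "VeryHigh"
  mid <- which(is.na(bin))
  if (length(mid)) {
    r <- rank(fpkm[mid], ties.method = "first")
    bin[mid] <- paste0("Q", ceiling(5 * r / length(mid)))
  }
  stats::setNames(factor(bin, levels = lev), names(fpkm))
}

#' Assign mutations to genes and transcriptional strand
#'
#' Maps each mutation to the gene containing it. Positions covered by
#' overlapping genes on opposite strands are strand-ambiguous and excluded
#' (gene set to NA, `ambiguous` TRUE). The transcriptional class follows
#' the strand of the mutated pyrimidine: pyrimidine on the gene's coding
#' strand = `"non_transcribed"`, on the template strand = `"transcribed"`.
#'
#' @param mutations Mutation table (chrom, pos, ref).
#' @param genes Gene table (gene, chrom, start, end, strand; 1-based
#'   inclusive).
#' @return data.frame with gene, gene_strand, tx_class ("transcribed",
#'   "non_transcribed" or NA) and ambiguous flag.
#' @export
assign_genes <- function(mutations, genes) {
  n <- nrow(mutations)
  gene <- rep(NA_character_, n)
  gstrand <- rep(NA_character_, n)
  nhit <- integer(n)
  ambiguous <- rep(FALSE, n)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- which(mutations$chrom == g$chrom &
                   mutations$pos >= g$start & mutations$pos <= g$end)
    if (!length(sel)) next
    newly <- nhit[sel] == 0L
    ambiguous[sel][!newly] <- ambiguous[sel][!newly] |
      (gstrand[sel][!newly] != g$strand)
    gene[sel[newly]] <- g$gene
    gstrand[sel[newly]] <- g$strand
    nhit[sel] <- nhit[sel] + 1L
  }
  gene[ambiguous] <- NA_character_
  gstrand[ambiguous] <- NA_character_
  pyr <- pyrimidine_strand(mutations$ref)
  tx_class <- ifelse(is.na(gstrand), NA_character_,
                     ifelse(pyr == gstrand, "non_transcribed", "transcribed"))
  data.frame(gene = gene, gene_strand = gstrand, tx_class = tx_class,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Mutation rate in intergenic regions
#'
#' The normalization reference of the TSS profiles: all genome outside
#' gene bodies extended by `flank` on each side.
#'
#' @param mutations Mutation table.
#' @param genes Gene table.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param flank Flank excluded around genes (default 10 kb).
#' @return Rate in mutations per Mb (attribute `bp` carries the region
#'   size).
#' @export
intergenic_rate <- function(mutations, genes, chrom_lengths, flank = 1e4) {
  total_bp <- 0
  n_mut <- 0
  for (ch in names(chrom_lengths)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    L <- chrom_lengths[[ch]]
    s <- pmax(g$start - flank, 1)
    e <- pmin(g$end + flank, L)
    o <- order(s)
    s <- s[o]; e <- e[o]
    merged_s <- c(); merged_e <- c()
    for (i in seq_along(s)) {
      if (length(merged_e) && s[i] <= merged_e[length(merged_e)] + 1) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], e[i])
      } else {
        merged_s <- c(merged_s, s[i]); merged_e <- c(merged_e, e[i])
      }
    }
    total_bp <- total_bp + L - sum(merged_e - merged_s + 1)
    mpos <- mutations$pos[mutations$chrom == ch]
    if (length(merged_s)) {
      k <- findInterval(mpos, merged_s)
      inside <- k >= 1 & mpos <= merged_e[pmax(k, 1)]
    } else inside <- rep(FALSE, length(mpos))
    n_mut <- n_mut + sum(!inside)
  }
  out <- mutation_rate(n_mut, total_bp)
  attr(out, "bp") <- total_bp
  attr(out, "n_mutations") <- n_mut
  out
}

#' Stranded mutation-rate profile around transcription start sites
#'
#' Groups mutations into 1 kb bins from 50 kb upstream to 100 kb
#' downstream of each TSS (gene-strand oriented), split by
#' transcriptional strand class, and normalizes rates against the
#' per-strand intergenic reference (half the pooled intergenic rate,
#' since each mutation lands on one of the two strand classes). Genes
#' shorter than the downstream window contribute truncated exposure
#' downstream.
#'
#' @param mutations Mutation table.
#' @param genes Gene table.
#' @param chrom_lengths Named chromosome lengths (for the intergenic
#'   reference).
#' @param binsize,upstream,downstream Window geometry in bases.
#' @return data.frame per (bin, tx_class): bin start relative to TSS,
#'   count, exposure bp, rate and normalized rate. Empty gene sets yield
#'   an empty profile.
#' @export
tss_profile <- function(mutations, genes, chrom_lengths,
                        binsize = 1e3, upstream = 5e4, downstream = 1e5) {
  bins <- seq(-upstream / binsize, downstream / binsize - 1)
  classes <- c("transcribed", "non_transcribed")
  if (nrow(genes) == 0) {
    return(data.frame(bin = integer(), tx_class = character(),
                      count = integer(), exposure_bp = numeric(),
                      rate = numeric(), norm_rate = numeric()))
  }
  counts <- matrix(0L, length(bins), 2, dimnames = list(bins, classes))
  exposure <- stats::setNames(numeric(length(bins)), bins)
  pyr <- pyrimidine_strand(mutations$ref)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    glen <- g$end - g$start + 1
    tss <- if (g$strand == "+") g$start else g$end
    dir <- if (g$strand == "+") 1 else -1
    ## exposure: full bins upstream, truncated at gene end downstream
    up <- bins < 0
    exposure[up] <- exposure[up] + binsize
    dn <- bins[!up]
    exposure[!up] <- exposure[!up] + pmin(pmax(glen - dn * binsize, 0), binsize)
    sel <- which(mutations$chrom == g$chrom)
    if (!length(sel)) next
    rel <- (mutations$pos[sel] - tss) * dir
    keep <- rel >= -upstream & rel < downstream &
      !(rel >= 0 & rel >= glen)  # downstream of gene end: truncated away
    if (!any(keep)) next
    b <- floor(rel[keep] / binsize)
    cls <- ifelse(pyr[sel[keep]] == g$strand, "non_transcribed", "transcribed")
    tab <- table(factor(b, levels = bins), factor(cls, levels = classes))
    counts <- counts + matrix(as.integer(tab), length(bins), 2)
  }
  ref <- intergenic_rate(mutations, genes, chrom_lengths)
  ref_per_strand <- as.numeric(ref) / 2
  out <- do.call(rbind, lapply(classes, function(cl) {
    rate <- ifelse(exposure > 0, counts[, cl] / (exposure / 1e6), NA_real_)
    data.frame(bin = bins * binsize, tx_class = cl,
               count = counts[, cl], exposure_bp = unname(exposure),
               rate = unname(rate),
               norm_rate = unname(rate) / ref_per_strand,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## ---- transcription-coupled damage and repair --------------------------

.is_a_to_g <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "T" & alt == "C")
}

#' Quantify transcription-coupled damage and repair per sample
#'
#' For A>G mutations (the T>C category seen from the purine), rates per
#' expression quintile are computed separately for mutations whose adenine
#' lies on the non-transcribed (coding) strand and on the transcribed
#' (template) strand, normalized against the unexpressed-gene (FPKM0)
#' per-strand rate when available. TCD is the non-transcribed-strand slope
#' `rate(Q5) - rate(Q1)` (damage scales with expression); TCR is the
#' transcribed-strand slope (repair makes it negative).
#'
#' @param mutations Mutation table (sample_id, chrom, pos, ref, alt).
#' @param genes Gene table.
#' @param bins Named factor from [expression_bins()] over the genes.
#' @return data.frame per sample: tcd, tcr, `normalized` (FALSE when no
#'   FPKM0 reference existed and raw per-Mb rates were differenced), and
#'   `flag` naming an empty endpoint quintile if any (tcd/tcr NA then).
#' @export
quantify_tcd_tcr <- function(mutations, genes, bins) {
  ag <- mutations[.is_a_to_g(mutations$ref, mutations$alt), , drop = FALSE]
  asg <- assign_genes(ag, genes)
  gene_len <- stats::setNames(genes$end - genes$start + 1, genes$gene)
  size_mb <- tapply(gene_len[names(bins)], bins, sum) / 1e6
  size_mb[is.na(size_mb)] <- 0
  in_gene <- !is.na(asg$gene)
  ag <- ag[in_gene, , drop = FALSE]
  asg <- asg[in_gene, , drop = FALSE]
  mut_bin <- bins[asg$gene]
  ## adenine strand: opposite of the pyrimidine strand; on the coding
  ## strand = non-transcribed
  a_strand <- ifelse(pyrimidine_strand(ag$ref) == "+", "-", "+")
  a_class <- ifelse(a_strand == asg$gene_strand, "non_transcribed", "transcribed")
  samples <- sort(unique(as.character(ag$sample_id)))
  out <- do.call(rbind, lapply(samples, function(sm) {
    sel <- ag$sample_id == sm
    rate_q <- function(q, cl) {
      cnt <- sum(sel & mut_bin == q & a_class == cl)
      if (size_mb[[q]] > 0) cnt / size_mb[[q]] else NA_real_
    }
    ref0 <- if (size_mb[["FPKM0"]] > 0)
      sum(sel & mut_bin == "FPKM0") / (2 * size_mb[["FPKM0"]]) else NA_real_
    normalized <- !is.na(ref0) && ref0 > 0
    norm <- function(r) if (normalized) r / ref0 else r
    r_q1_nt <- rate_q("Q1", "non_transcribed"); r_q5_nt <- rate_q("Q5", "non_transcribed")
    r_q1_t <- rate_q("Q1", "transcribed"); r_q5_t <- rate_q("Q5", "transcribed")
    flag <- if (size_mb[["Q1"]] == 0 || size_mb[["Q5"]] == 0) "empty-quintile" else ""
    data.frame(sample_id = sm,
               tcd = norm(r_q5_nt) - norm(r_q1_nt),
               tcr = norm(r_q5_t) - norm(r_q1_t),
               normalized = normalized, flag = flag,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), tcd = numeric(), tcr = numeric(),
                      normalized = logical(), flag = character())
  }
  out
}
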