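## Seeded synthetic-tumor generators. Every generator draws from an
## explicit forward model with recorded ground truth, so each pipeline
## stage has a closed-loop test: catalogs from known signature mixtures,
## read counts from known purity/copy-number/CCF, SV sets from known
## category mixtures, duplications placed at known molecular times, and
## gene/replication annotations with known geometry.

#' Default simulation configuration
#'
#' Central defaults for the generators: mean sequencing depth 92x (the
#' coverage scale of deep tumor whole genomes) with a floor of 6 reads,
#' diploid normal, purity 1.
#'
#' @param ... Overrides merged into the default list.
#' @return Named list.
#' @export
simulation_config <- function(...) {
  cfg <- list(depth = 92, min_depth = 6, purity = 1, n_normal = 2,
              genome_length = 1e6, gc = 0.41)
  utils::modifyList(cfg, list(...))
}

#' Simulate a random reference genome
#'
#' Independent draws with a configurable GC content (default 0.41,
#' the human genome-wide value).
#'
#' @param lengths Named vector of chromosome lengths.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
simulate_genome <- function(lengths = c(sim1 = 1e6), gc = 0.41, seed = NULL) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    vapply(lengths, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
}

## index of genome positions by strand-collapsed center trinucleotide
.trinuc_index <- function(genome) {
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < 3) next
    tri <- substring(s, 1:(L - 2), 3:L)
    center <- substr(tri, 2, 2)
    rc <- paste0(.complement(substr(tri, 3, 3)),
                 .complement(center),
                 .complement(substr(tri, 1, 1)))
    collapsed <- ifelse(center %in% c("C", "T"), tri, rc)
    valid <- !grepl("[^ACGT]", tri)
    pos <- which(valid) + 1L
    grp <- split(pos, collapsed[valid])
    for (k in names(grp)) {
      out[[k]] <- rbind(out[[k]], cbind(chrom = ch, pos = grp[[k]]))
    }
  }
  out
}

#' Simulate mutation catalogs from known signature mixtures
#'
#' Per sample, each mutation's generating signature is drawn from the
#' exposure mixture and its category from that signature's profile, so
#' category counts are multinomial from `P %*% (e / sum(e))` and the true
#' generating signature of every mutation is recorded. With a reference
#' genome, each mutation is placed at a position whose strand-collapsed
#' trinucleotide matches its category (ref/alt follow the plus strand).
#'
#' @param P Signature matrix 96 x S.
#' @param exposures True exposure matrix S x n_samples (counts), or a
#'   vector for one sample.
#' @param genome Optional named character vector of sequences.
#' @param seed Integer seed (fixed seed gives identical output).
#' @return List with `mutations` (data.frame incl. `category_index`,
#'   `true_signature`), `catalog` (96 x n_samples), `exposures`.
#' @export
simulate_catalog <- function(P, exposures, genome = NULL, seed = NULL) {
  P <- as.matrix(P)
  if (is.null(dim(exposures))) exposures <- matrix(exposures, ncol = 1)
  stopifnot(nrow(exposures) == ncol(P))
  samples <- colnames(exposures) %||% sprintf("sim%02d", seq_len(ncol(exposures)))
  colnames(exposures) <- samples
  sig_ids <- colnames(P) %||% paste0("S", seq_len(ncol(P)))
  levels96 <- mut_category_levels()
  tri_idx <- if (!is.null(genome)) .trinuc_index(genome) else NULL
  with_seed(seed, {
    muts <- list()
    for (j in seq_len(ncol(exposures))) {
      n <- round(sum(exposures[, j]))
      if (n == 0) next
      sig <- sample(seq_len(ncol(P)), n, replace = TRUE,
                    prob = exposures[, j] / sum(exposures[, j]))
      cat_i <- integer(n)
      for (s in unique(sig)) {
        k <- which(sig == s)
        cat_i[k] <- sample(96L, length(k), replace = TRUE, prob = P[, s])
      }
      lab <- levels96[cat_i]
      tri <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
      alt_pyr <- substr(lab, 5, 5)
      ref_pyr <- substr(lab, 3, 3)
      if (is.null(tri_idx)) {
        chrom <- rep("sim", n); pos <- seq_len(n)
        ref <- ref_pyr; alt <- alt_pyr
      } else {
        chrom <- character(n); pos <- integer(n)
        ref <- character(n); alt <- character(n)
        for (tk in unique(tri)) {
          k <- which(tri == tk)
          cand <- tri_idx[[tk]]
          if (is.null(cand)) {
            stop("reference genome lacks trinucleotide context ", tk)
          }
          pick <- sample(nrow(cand), length(k), replace = TRUE)
          chrom[k] <- cand[pick, "chrom"]
          pos[k] <- as.integer(cand[pick, "pos"])
          center <- substr(genome[chrom[k]], pos[k], pos[k])
          flip <- center %in% c("A", "G")
          ref[k] <- center
          alt[k] <- ifelse(flip, .complement(alt_pyr[k]), alt_pyr[k])
        }
      }
      muts[[j]] <- data.frame(sample_id = samples[j], chrom = chrom, pos = pos,
                              ref = ref, alt = alt, category = lab,
                              category_index = cat_i,
                              true_signature = sig_ids[sig],
                              stringsAsFactors = FALSE)
    }
    mutations <- do.call(rbind, muts)
    catalog <- matrix(0L, 96, length(samples), dimnames = list(levels96, samples))
    tab <- table(factor(mutations$category, levels = levels96),
                 factor(mutations$sample_id, levels = samples))
    catalog <- catalog + matrix(as.integer(tab), 96,
                                dimnames = list(levels96, samples))
    list(mutations = mutations, catalog = catalog, exposures = exposures)
  })
}

#' Simulate alt/total read counts for mutations
#'
#' Expected VAF follows the CCF model,
#' `VAF = CCF * rho * n_chr / (rho*N_t + (1-rho)*N_n)`; total depth is
#' Poisson around the configured mean with a floor, and alt reads are
#' binomial at the expected VAF.
#'
#' @param n Number of mutations.
#' @param ccf,purity,n_tumor,n_normal,n_chr Model parameters (recycled).
#' @param depth Mean sequencing depth (default 92).
#' @param min_depth Depth floor (default 6).
#' @param seed Integer seed.
#' @return data.frame with alt_reads_tumor, total_reads_tumor,
#'   vaf_expected.
#' @export
simulate_reads <- function(n, ccf = 1, purity = 1, n_tumor = 2, n_normal = 2,
                           n_chr = 1, depth = 92, min_depth = 6, seed = NULL) {
  vaf <- rep_len(ccf, n) * rep_len(purity, n) * rep_len(n_chr, n) /
    (rep_len(purity, n) * rep_len(n_tumor, n) +
       (1 - rep_len(purity, n)) * rep_len(n_normal, n))
  if (any(vaf > 1 + 1e-12)) stop("configuration implies expected VAF > 1")
  with_seed(seed, {
    tot <- pmax(stats::rpois(n, depth), min_depth)
    alt <- stats::rbinom(n, tot, pmin(vaf, 1))
    data.frame(alt_reads_tumor = alt, total_reads_tumor = tot,
               vaf_expected = vaf)
  })
}

## duplicated-mutation fraction implied by a gain at molecular time t.
## single_parent: mechanistic model (uniform accrual on 2 copies before
## the gain, N_t after; pre-gain mutations on the duplicated copy are
## duplicated) -- exact for N_t = 3 and identical to inverting the timing
## formula in general. both_parents: inversion of the timing formula.
.dup_fraction <- function(t_star, n_tumor, mode) {
  cc <- (3 + n_tumor) / 2
  if (mode == "single_parent") {
    t_star / (100 * cc - t_star * (cc - 2))
  } else {
    t_star / (50 * cc - t_star * (cc / 2 - 1))
  }
}

#' Simulate the mutation record of a timed chromosome duplication
#'
#' Draws `n_mutations` clonal mutations on a duplicated segment whose gain
#' happened at molecular time `t_star` (pmt in (0, 100]). Each mutation is
#' duplicated (multiplicity = major copy number) with the probability
#' implied by the forward accrual model, and non-duplicated (multiplicity
#' 1) otherwise.
#'
#' @param t_star True gain time in pmt.
#' @param n_mutations Mutations on the segment (default 300).
#' @param n_tumor Total copy number after the gain (default 3).
#' @param mode `"single_parent"` or `"both_parents"`.
#' @param seed Integer seed.
#' @return List with `mutations` (multiplicity, duplicated), `major`,
#'   `minor`, `t_star`, `mode`.
#' @export
simulate_duplication_history <- function(t_star, n_mutations = 300,
                                         n_tumor = 3,
                                         mode = c("single_parent", "both_parents"),
                                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(t_star >= 0, t_star <= 100)
  if (mode == "both_parents" && n_tumor %% 2 != 0) {
    stop("both-parents duplication requires an even total copy number")
  }
  major <- if (mode == "single_parent") n_tumor - 1L else n_tumor / 2L
  minor <- n_tumor - major
  p <- .dup_fraction(t_star, n_tumor, mode)
  with_seed(seed, {
    dup <- stats::runif(n_mutations) < p
    list(mutations = data.frame(multiplicity = ifelse(dup, major, 1L),
                                duplicated = dup),
         major = major, minor = minor, t_star = t_star, mode = mode)
  })
}

#' Simulate structural variants from known category mixtures
#'
#' Event counts per sample follow the exposure mixture over SV signatures,
#' each signature being a probability vector over the 38 categories. Sizes
#' are drawn log-uniformly within the category's size bin; events meant to
#' be clustered are laid down in groups of ten first breakpoints within a
#' 300 kb span (>= 10 breakpoints per 1 Mb window); support fields pass
#' the read filters unless failure fractions are requested.
#'
#' @param sig_probs 38 x K matrix of category probabilities (rows in
#'   [sv_category_levels()] order).
#' @param exposures K x n_samples matrix of event counts (vector for one
#'   sample).
#' @param chrom_lengths Named chromosome lengths (at least 2 chromosomes
#'   for translocations).
#' @param fail_reads_frac,fail_fraction_frac Fractions of events given
#'   sub-threshold read support / read fraction, to exercise the filters.
#' @param seed Integer seed.
#' @return data.frame of SV records with true_category, true_signature and
#'   true_clustered columns.
#' @export
simulate_svs <- function(sig_probs, exposures,
                         chrom_lengths = c(sv1 = 8e7, sv2 = 8e7),
                         fail_reads_frac = 0, fail_fraction_frac = 0,
                         seed = NULL) {
  sig_probs <- as.matrix(sig_probs)
  stopifnot(nrow(sig_probs) == 38)
  if (is.null(rownames(sig_probs))) rownames(sig_probs) <- sv_category_levels()
  if (is.null(dim(exposures))) exposures <- matrix(exposures, ncol = 1)
  samples <- colnames(exposures) %||% sprintf("svsim%02d", seq_len(ncol(exposures)))
  sig_ids <- colnames(sig_probs) %||% paste0("RS", seq_len(ncol(sig_probs)))
  bin_lo <- c("<1kb" = 50, "1-10kb" = 1e3, "10-100kb" = 1e4,
              "100kb-1Mb" = 1e5, "1-10Mb" = 1e6, ">10Mb" = 1e7)
  bin_hi <- c("<1kb" = 1e3, "1-10kb" = 1e4, "10-100kb" = 1e5,
              "100kb-1Mb" = 1e6, "1-10Mb" = 1e7, ">10Mb" = 3e7)
  with_seed(seed, {
    rows <- list()
    for (j in seq_len(ncol(exposures))) {
      n_k <- round(exposures[, j])
      if (sum(n_k) == 0) next
      sig <- rep(seq_along(n_k), n_k)
      cat_i <- integer(length(sig))
      for (s in unique(sig)) {
        k <- which(sig == s)
        cat_i[k] <- sample(38L, length(k), replace = TRUE, prob = sig_probs[, s])
      }
      lab <- sv_category_levels()[cat_i]
      parts <- strsplit(lab, ":", fixed = TRUE)
      type <- vapply(parts, `[`, character(1), 1)
      status <- vapply(parts, function(x) x[length(x)], character(1))
      szbin <- ifelse(type == "trans", NA_character_,
                      vapply(parts, `[`, character(1), 2))
      n <- length(lab)
      size <- rep(NA_real_, n)
      intra <- type != "trans"
      if (any(intra)) {
        lo <- bin_lo[szbin[intra]]; hi <- bin_hi[szbin[intra]]
        size[intra] <- floor(exp(stats::runif(sum(intra), log(lo), log(hi - 1))))
      }
      chrom1 <- sample(names(chrom_lengths), n, replace = TRUE)
      ## intra events must fit on their chromosome
      for (i in which(intra)) {
        fits <- chrom_lengths > size[i] + 2
        chrom1[i] <- sample(names(chrom_lengths)[fits], 1)
      }
      chrom2 <- chrom1
      for (i in which(!intra)) {
        chrom2[i] <- sample(setdiff(names(chrom_lengths), chrom1[i]), 1)
      }
      clustered <- status == "clustered"
      pos1 <- numeric(n)
      idx_cl <- which(clustered)
      if (length(idx_cl)) {
        n_groups <- max(1L, floor(length(idx_cl) / 10))
        grp <- rep(seq_len(n_groups), length.out = length(idx_cl))
        for (g in seq_len(n_groups)) {
          members <- idx_cl[grp == g]
          ch <- names(which.max(chrom_lengths))
          chrom1[members] <- ch
          chrom2[members[!intra[members]]] <- sample(setdiff(names(chrom_lengths), ch), 1)
          chrom2[members[intra[members]]] <- ch
          center <- stats::runif(1, 1e6, chrom_lengths[[ch]] -
                                   max(size[members], 0, na.rm = TRUE) - 1e6)
          pos1[members] <- round(center + stats::runif(length(members), 0, 3e5))
        }
      }
      idx_nc <- which(!clustered)
      pos1[idx_nc] <- vapply(idx_nc, function(i) {
        lim <- chrom_lengths[[chrom1[i]]] - (if (intra[i]) size[i] else 0) - 1
        round(stats::runif(1, 1, lim))
      }, numeric(1))
      pos2 <- ifelse(intra, pos1 + size,
                     round(stats::runif(n, 1, chrom_lengths[chrom2] - 1)))
      reads <- 15L + stats::rpois(n, 25)
      frac <- stats::runif(n, 0.15, 0.9)
      if (fail_reads_frac > 0) {
        bad <- stats::runif(n) < fail_reads_frac
        reads[bad] <- sample(6:14, sum(bad), replace = TRUE)
      }
      if (fail_fraction_frac > 0) {
        bad <- stats::runif(n) < fail_fraction_frac
        frac[bad] <- stats::runif(sum(bad), 0.01, 0.09)
      }
      rows[[j]] <- data.frame(sample_id = samples[j],
                              chrom1 = chrom1, pos1 = pos1,
                              chrom2 = chrom2, pos2 = pos2,
                              sv_type = type,
                              supporting_reads = reads, read_fraction = frac,
                              true_category = lab,
                              true_signature = sig_ids[sig],
                              true_clustered = clustered,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(sample_id = character(), chrom1 = character(),
                        pos1 = numeric(), chrom2 = character(), pos2 = numeric(),
                        sv_type = character(), supporting_reads = integer(),
                        read_fraction = numeric(), true_category = character(),
                        true_signature = character(), true_clustered = logical())
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate gene models, expression and a replication-timing track
#'
#' Places non-overlapping genes with random strands along one chromosome,
#' assigns FPKM values spanning all expression bins (zeros, a (0,100)
#' range filling the five quintiles, and a very-high class >= 100), and
#' builds a piecewise-linear (triangle-wave) replication signal whose
#' peak-to-valley distance is configurable — set it below 500 kb to
#' exercise the unassigned-strand rule.
#'
#' @param n_genes Total genes (default 60).
#' @param gene_length,spacing Gene size and intergenic gap in bases.
#' @param frac_zero,frac_veryhigh Fractions of unexpressed / very highly
#'   expressed genes.
#' @param peak_valley_distance Half-period of the replication signal in
#'   bases (default 1 Mb).
#' @param signal_binsize Replication track bin size (default 10 kb).
#' @param seed Integer seed.
#' @return List with `genes`, `fpkm`, `bins` (expression bins), `signal`,
#'   `chrom_lengths`.
#' @export
simulate_annotation <- function(n_genes = 60, gene_length = 2e4, spacing = 5e4,
                                frac_zero = 1 / 6, frac_veryhigh = 1 / 6,
                                peak_valley_distance = 1e6,
                                signal_binsize = 1e4, seed = NULL) {
  stopifnot(spacing > 2e4)  # keep intergenic space outside 10 kb flanks
  chrom <- "simchr"
  L <- n_genes * (gene_length + spacing) + spacing
  with_seed(seed, {
    start <- spacing + (seq_len(n_genes) - 1L) * (gene_length + spacing) + 1L
    genes <- data.frame(gene = sprintf("g%03d", seq_len(n_genes)),
                        chrom = chrom, start = start,
                        end = start + gene_length - 1L,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    n0 <- max(1L, round(frac_zero * n_genes))
    nvh <- max(1L, round(frac_veryhigh * n_genes))
    nq <- n_genes - n0 - nvh
    fpkm <- c(rep(0, n0),
              exp(stats::runif(nq, log(0.1), log(99))),
              stats::runif(nvh, 100, 1000))
    fpkm <- sample(fpkm)  # shuffle over gene positions
    names(fpkm) <- genes$gene
    starts <- seq(0, L - signal_binsize, by = signal_binsize)
    mids <- starts + signal_binsize / 2
    phase <- (mids %% (2 * peak_valley_distance)) / peak_valley_distance
    value <- 100 * ifelse(phase <= 1, 1 - phase, phase - 1)
    signal <- data.frame(chrom = chrom, start = starts,
                         end = starts + signal_binsize, value = value)
    list(genes = genes, fpkm = fpkm, bins = expression_bins(fpkm),
         signal = signal, chrom_lengths = stats::setNames(L, chrom))
  })
}

#' Simulate A>G mutations with an expression-dependent strand bias
#'
#' Draws `n` A>G mutations across the genes, with expected counts per
#' (gene, adenine-strand) cell proportional to gene length times a linear
#' expression trend: the non-transcribed-strand rate scales as
#' `1 + tcd * (q-1)/4` across quintiles q (very-high genes behave as Q5)
#' and the transcribed-strand rate as `1 + tcr * (q-1)/4`; unexpressed
#' genes stay at baseline. [quantify_tcd_tcr()] recovers `tcd`/`tcr` in
#' normalized units.
#'
#' @param genes,bins Gene table and expression bins.
#' @param n Total mutations (default 5000).
#' @param tcd,tcr Injected slopes (0 = flat null).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Mutation data.frame (sample_id, chrom, pos, ref, alt).
#' @export
simulate_tcd_mutations <- function(genes, bins, n = 5000, tcd = 0, tcr = 0,
                                   sample_id = "sim01", seed = NULL) {
  q <- match(as.character(bins[genes$gene]), paste0("Q", 1:5))
  q[as.character(bins[genes$gene]) == "VeryHigh"] <- 5L
  trend <- ifelse(is.na(q), 0, (q - 1) / 4)
  len <- genes$end - genes$start + 1
  w_nt <- len * (1 + tcd * trend)
  w_t <- len * (1 + tcr * trend)
  if (any(c(w_nt, w_t) < 0)) stop("injected slope implies a negative rate")
  cells <- c(w_nt, w_t)
  with_seed(seed, {
    pick <- sample(length(cells), n, replace = TRUE, prob = cells)
    gi <- ((pick - 1L) %% nrow(genes)) + 1L
    on_nt <- pick <= nrow(genes)
    pos <- genes$start[gi] + floor(stats::runif(n) * len[gi])
    gstrand <- genes$strand[gi]
    ## adenine on the coding (gene) strand for NT-class mutations
    a_plus <- ifelse(on_nt, gstrand == "+", gstrand == "-")
    data.frame(sample_id = sample_id, chrom = genes$chrom[gi], pos = pos,
               ref = ifelse(a_plus, "A", "T"),
               alt = ifelse(a_plus, "G", "C"),
               stringsAsFactors = FALSE)
  })
}
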