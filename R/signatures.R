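## Exposure fitting of known signatures and per-mutation attribution.
##
## With the signature matrix P known (96 x S, columns sum to 1), the
## exposure of each sample is the non-negative vector e minimizing
## ||m - P e||_2; signatures contributing less than a minimum fraction of
## the sample's mutations are discarded one at a time and the remaining
## set refitted, then exposures are rescaled to count units.

#' Identifiers of the 10 liver-cancer signatures in the bundled catalog
#'
#' The subset of the 30-column reference catalog used by default for
#' liver tumors (signatures 1, 4, 5, 6, 12, 16, 17, 22, 23 and 24).
#' @return Character vector of 10 signature ids.
#' @export
liver_signature_ids <- function() {
  paste0("Signature.", c(1, 4, 5, 6, 12, 16, 17, 22, 23, 24))
}

#' Load the bundled reference signature catalog
#'
#' Loads the synthetic stand-in for the COSMIC v2 catalog shipped with the
#' package (`signatures_cosmic_v2_synthetic.tsv`): 30 signature profiles
#' over the 96 categories with the same structure (non-negative columns
#' summing to 1) as the public catalog, generated once from seeded sparse
#' Dirichlet draws. It is synthetic — profiles do not reproduce the
#' empirical COSMIC patterns — and exists so that the full pipeline can be
#' exercised and tested without network access.
#'
#' @param subset `"liver"` for the 10-signature liver set,
#'   `"all"` for all 30 columns, or a character vector of signature ids.
#' @return Numeric 96 x S matrix.
#' @export
reference_signatures <- function(subset = c("liver", "all")) {
  P <- read_signature_matrix(system.file("extdata",
                                         "signatures_cosmic_v2_synthetic.tsv",
                                         package = "mutproc", mustWork = TRUE))
  if (is.character(subset) && length(subset) == 1 && subset[1] %in% c("liver", "all")) {
    subset <- match.arg(subset)
    if (subset == "liver") P <- P[, liver_signature_ids(), drop = FALSE]
  } else {
    P <- P[, subset, drop = FALSE]
  }
  P
}

.check_alignment <- function(M, P) {
  if (nrow(M) != nrow(P)) {
    stop("catalog and signature matrix have different numbers of categories")
  }
  if (!is.null(rownames(M)) && !is.null(rownames(P)) &&
      !identical(rownames(M), rownames(P))) {
    if (setequal(rownames(M), rownames(P))) {
      stop("catalog and signature rows are ordered differently; reorder before fitting")
    }
    stop("catalog and signature row names disagree")
  }
  invisible(NULL)
}

#' Fit signature exposures to a mutation catalog
#'
#' Per-sample non-negative least squares against a fixed signature matrix,
#' followed by the minimum-contribution discard rule: while any signature
#' with nonzero exposure contributes less than `min_contribution` of the
#' sample's fitted mutations, the lowest such signature is removed and the
#' remaining set refitted. Final exposures are rescaled so each column
#' sums to the sample's observed mutation count.
#'
#' @param M Catalog matrix, 96 x n_samples (rows aligned with `P`).
#' @param P Signature matrix, 96 x S.
#' @param min_contribution Minimum relative contribution below which a
#'   signature is discarded (default 0.06, i.e. <6% of the tumor genome).
#' @return Object of class `exposure_fit`: list with `counts` (S x
#'   n_samples exposures in mutation units), `relative` (per-sample
#'   proportions), `n_mutations`, and `residual` (per-sample Frobenius
#'   residual of the pre-rescale fit).
#' @export
fit_exposures <- function(M, P, min_contribution = 0.06) {
  .check_alignment(M, P)
  M <- as.matrix(M)
  P <- as.matrix(P)
  S <- ncol(P)
  n <- ncol(M)
  sig_ids <- colnames(P)
  counts <- matrix(0, S, n, dimnames = list(sig_ids, colnames(M)))
  residual <- numeric(n)
  for (j in seq_len(n)) {
    m <- M[, j]
    tot <- sum(m)
    if (tot == 0) {
      warning(sprintf("sample %s has an all-zero catalog column; exposures set to 0",
                      colnames(M)[j] %||% j))
      next
    }
    active <- seq_len(S)
    repeat {
      fit <- pracma::lsqnonneg(P[, active, drop = FALSE], m)
      e <- fit$x
      if (sum(e) == 0) break
      rel <- e / sum(e)
      low <- which(rel > 0 & rel < min_contribution)
      if (!length(low) || length(active) == 1) break
      drop_i <- low[which.min(rel[low])]
      active <- active[-drop_i]
    }
    if (sum(e) > 0) {
      counts[active, j] <- e / sum(e) * tot
      residual[j] <- sqrt(sum((m - P[, active, drop = FALSE] %*% e)^2))
    }
  }
  rel <- sweep(counts, 2, pmax(colSums(counts), .Machine$double.eps), "/")
  structure(list(counts = counts, relative = rel,
                 n_mutations = colSums(M), residual = residual,
                 min_contribution = min_contribution),
            class = "exposure_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("exposure_fit: %d signatures x %d samples (min contribution %.0f%%)\n",
              nrow(x$counts), ncol(x$counts), 100 * x$min_contribution))
  cat("mean active signatures per sample:",
      round(mean(colSums(x$counts > 0)), 2), "\n")
  invisible(x)
}

#' Fit exposures independently for clonal and subclonal mutations
#'
#' Fits the two catalogs separately with [fit_exposures()] and reports the
#' per-sample change in signature proportions (subclonal minus clonal) for
#' samples present in both catalogs. Samples present in only one catalog
#' are reported, not fatal.
#'
#' @param M_clonal,M_subclonal 96 x samples catalogs of clonal and
#'   subclonal mutations (column names identify samples).
#' @inheritParams fit_exposures
#' @return List with `clonal` and `subclonal` (`exposure_fit`), `delta`
#'   (S x shared-samples matrix of proportion differences) and
#'   `unshared_samples`.
#' @export
split_clonal_subclonal_exposures <- function(M_clonal, M_subclonal, P,
                                             min_contribution = 0.06) {
  fc <- fit_exposures(M_clonal, P, min_contribution)
  fs <- fit_exposures(M_subclonal, P, min_contribution)
  shared <- intersect(colnames(M_clonal), colnames(M_subclonal))
  unshared <- setdiff(union(colnames(M_clonal), colnames(M_subclonal)), shared)
  if (length(unshared)) {
    message("samples in only one catalog: ", paste(unshared, collapse = ", "))
  }
  delta <- fs$relative[, shared, drop = FALSE] - fc$relative[, shared, drop = FALSE]
  list(clonal = fc, subclonal = fs, delta = delta, unshared_samples = unshared)
}

#' Per-mutation signature attribution probabilities
#'
#' For a mutation of category c in a tumor with exposures e, the
#' probability that signature s caused it is
#' `p[c, s] * e[s] / sum_s' p[c, s'] * e[s']` — the signature's share of
#' the expected mutations of that category.
#'
#' @param categories Category labels or 1-based indices of the mutations.
#' @param P Signature matrix, 96 x S.
#' @param exposures Exposure vector for the tumor (length S, count or
#'   proportion units; scale cancels).
#' @return n x S matrix of probabilities, each row summing to 1; rows for
#'   categories impossible under all active signatures are `NA` and their
#'   count is in attribute `n_undefined`.
#' @export
mutation_probabilities <- function(categories, P, exposures) {
  P <- as.matrix(P)
  stopifnot(length(exposures) == ncol(P))
  if (is.character(categories)) {
    idx <- match(categories, rownames(P) %||% mut_category_levels())
    if (anyNA(idx)) stop("unknown category label")
  } else {
    idx <- as.integer(categories)
    stopifnot(all(idx >= 1 & idx <= nrow(P)))
  }
  raw <- P[idx, , drop = FALSE] * rep(exposures, each = length(idx))
  denom <- rowSums(raw)
  out <- raw / denom
  undef <- denom == 0
  out[undef, ] <- NA_real_
  dimnames(out) <- list(NULL, colnames(P))
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Cumulative signature contribution to a set of mutations
#'
#' Sums per-mutation attribution probabilities over the mutations of a
#' gene (or any set) G: the expected number of mutations in G caused by
#' each signature. The result sums to the number of attributed mutations.
#'
#' @param attributions n x S attribution matrix from
#'   [mutation_probabilities()].
#' @param members Logical or integer index selecting the mutations of G.
#' @return Named numeric vector over signatures.
#' @export
gene_contribution <- function(attributions, members = seq_len(nrow(attributions))) {
  sub <- attributions[members, , drop = FALSE]
  colSums(sub, na.rm = FALSE)
}

#' Test genes for enrichment of signature attributions
#'
#' For each gene x signature pair, compares the distribution of
#' per-mutation attribution probabilities in the gene against a
#' background — all other mutations, or all other mutations in samples
#' carrying a mutation of that gene — with a two-sided Wilcoxon rank-sum
#' test, followed by Benjamini-Hochberg correction across all tested
#' pairs.
#'
#' @param attributions n x S attribution matrix.
#' @param mutation_gene Character vector (length n) of containing gene ids
#'   (`NA` for intergenic mutations).
#' @param mutation_sample Character vector (length n) of sample ids.
#' @param genes Genes to test.
#' @param background `"all"` or `"mutated_samples"`.
#' @return data.frame with one row per (gene, signature): group sizes,
#'   Wilcoxon statistic `W`, `p`, BH-adjusted `q`, and `degenerate` flag
#'   set when all pooled values are tied (p forced to 1).
#' @export
test_gene_enrichment <- function(attributions, mutation_gene, mutation_sample,
                                 genes, background = c("all", "mutated_samples")) {
  background <- match.arg(background)
  sigs <- colnames(attributions) %||% paste0("S", seq_len(ncol(attributions)))
  res <- list()
  for (g in genes) {
    in_g <- !is.na(mutation_gene) & mutation_gene == g
    if (!any(in_g)) next
    bg <- !in_g
    if (background == "mutated_samples") {
      bg <- bg & mutation_sample %in% unique(mutation_sample[in_g])
    }
    for (k in seq_along(sigs)) {
      x <- attributions[in_g, k]
      y <- attributions[bg, k]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      degenerate <- length(unique(c(x, y))) == 1L
      if (degenerate) {
        w <- length(x) * length(y) / 2
        p <- 1
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
        w <- unname(ht$statistic)
        p <- ht$p.value
      }
      res[[length(res) + 1L]] <- data.frame(gene = g, signature = sigs[k],
                                            n_gene = length(x), n_background = length(y),
                                            W = w, p = p, degenerate = degenerate,
                                            stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(gene = character(), signature = character(),
                      n_gene = integer(), n_background = integer(),
                      W = numeric(), p = numeric(), degenerate = logical(),
                      q = numeric()))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Match extracted signatures to a reference catalog
#'
#' Computes cosine similarities of each query profile against every
#' reference profile and flags a query as "known" when its best match
#' reaches the similarity threshold.
#'
#' @param W 96 x K matrix of query signature profiles.
#' @param reference 96 x R reference matrix.
#' @param threshold Similarity above which a query counts as a known
#'   signature (default 0.75).
#' @return data.frame with best match, similarity and `known` flag per
#'   query, carrying the full similarity matrix as attribute `"similarity"`.
#' @export
match_signatures <- function(W, reference, threshold = 0.75) {
  W <- as.matrix(W); reference <- as.matrix(reference)
  sim <- matrix(NA_real_, ncol(W), ncol(reference),
                dimnames = list(colnames(W), colnames(reference)))
  for (i in seq_len(ncol(W))) {
    for (j in seq_len(ncol(reference))) {
      sim[i, j] <- cosine_similarity(W[, i], reference[, j])
    }
  }
  best <- max.col(sim)
  out <- data.frame(query = colnames(W) %||% paste0("denovo", seq_len(ncol(W))),
                    best_match = colnames(reference)[best],
                    similarity = sim[cbind(seq_len(nrow(sim)), best)],
                    stringsAsFactors = FALSE)
  out$known <- out$similarity >= threshold
  attr(out, "similarity") <- sim
  out
}
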