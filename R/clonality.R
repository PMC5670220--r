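## Cancer cell fraction, multiplicity and clonality from read counts,
## tumor purity and allele-specific copy number.
##
## CCF = VAF * (rho*N_t + (1-rho)*N_n) / (rho * n_chr), with rho the tumor
## cell content, N_t/N_n the tumor/normal copy numbers at the locus and
## n_chr the number of tumor chromosome copies carrying the mutation.

#' Estimate mutation multiplicity
#'
#' The number of chromosome copies carrying a mutation, set to the integer
#' closest to `max(1, VAF * (rho*N_t + (1-rho)*N_n) / rho)` and clamped to
#' `[1, major]`. Ties at .5 round half away from zero.
#'
#' @param vaf Variant allele fraction.
#' @param purity Tumor cell content rho, in (0, 1].
#' @param n_tumor Total tumor copy number N_t at the locus.
#' @param n_normal Normal copy number N_n (2 for autosomes; 1 for X/Y in
#'   males).
#' @param major Major allele copy number, the upper clamp (defaults to
#'   `n_tumor`).
#' @return Integer vector of multiplicities.
#' @export
estimate_multiplicity <- function(vaf, purity, n_tumor, n_normal = 2,
                                  major = n_tumor) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  raw <- pmax(1, vaf * (purity * n_tumor + (1 - purity) * n_normal) / purity)
  n <- floor(raw + 0.5)  # round half away from zero (raw > 0)
  as.integer(pmin(pmax(n, 1), pmax(major, 1)))
}

#' Cancer cell fraction with exact binomial confidence interval
#'
#' Computes the CCF of each mutation and its 95% confidence interval,
#' obtained by applying the same affine transform to the two-sided exact
#' (Clopper-Pearson) binomial interval of the VAF. The reported `ccf` is
#' clamped to 1 (sampling noise pushes clonal VAFs above expectation);
#' `ccf_raw` keeps the unclamped value, which is the one to use when
#' measuring estimator bias. Status is `"subclonal"` iff the CI upper
#' bound is strictly below `clonal_cutoff`.
#'
#' @param alt_reads,total_reads Read counts (vectors).
#' @param purity,n_tumor,n_normal,n_chr Model parameters per mutation
#'   (recycled).
#' @param conf_level CI level (default 0.95).
#' @param clonal_cutoff Subclonality cutoff on the CI upper bound
#'   (default 0.95).
#' @return data.frame with vaf, n_chr, ccf, ccf_raw, ccf_lower, ccf_upper
#'   and status; rows with zero total reads are NA with status
#'   `"undefined"`.
#' @export
compute_ccf <- function(alt_reads, total_reads, purity, n_tumor, n_normal = 2,
                        n_chr = 1, conf_level = 0.95, clonal_cutoff = 0.95) {
  n <- length(alt_reads)
  df <- data.frame(alt = alt_reads, tot = total_reads,
                   purity = rep_len(purity, n), n_tumor = rep_len(n_tumor, n),
                   n_normal = rep_len(n_normal, n), n_chr = rep_len(n_chr, n))
  fac <- (df$purity * df$n_tumor + (1 - df$purity) * df$n_normal) /
    (df$purity * df$n_chr)
  vaf <- ifelse(df$tot > 0, df$alt / df$tot, NA_real_)
  lo <- hi <- rep(NA_real_, n)
  ok <- which(df$tot > 0)
  for (i in ok) {
    ci <- stats::binom.test(df$alt[i], df$tot[i], conf.level = conf_level)$conf.int
    lo[i] <- ci[1]; hi[i] <- ci[2]
  }
  ccf_raw <- vaf * fac
  out <- data.frame(vaf = vaf, n_chr = df$n_chr,
                    ccf = pmin(ccf_raw, 1), ccf_raw = ccf_raw,
                    ccf_lower = lo * fac, ccf_upper = hi * fac)
  out$status <- ifelse(is.na(out$ccf_upper), "undefined",
                       call_clonality(out$ccf_upper, clonal_cutoff))
  out
}

#' Clonal/subclonal call from the CCF confidence interval
#'
#' A mutation is subclonal when the upper boundary of its 95% CCF
#' confidence interval is strictly below the cutoff, and clonal otherwise
#' (an upper bound of exactly 0.95 is clonal).
#'
#' @param ccf_upper Upper CI bound(s).
#' @param clonal_cutoff Cutoff (default 0.95).
#' @return Character vector `"clonal"` / `"subclonal"`.
#' @export
call_clonality <- function(ccf_upper, clonal_cutoff = 0.95) {
  ifelse(ccf_upper < clonal_cutoff, "subclonal", "clonal")
}

#' Per-mutation clonality calls against a copy-number model
#'
#' Joins mutations to their allele-specific copy-number segment (same
#' sample and chromosome, position within [start, end]), estimates
#' multiplicity, and computes CCF with confidence interval and
#' clonal/subclonal status. Mutations falling outside every segment are
#' returned with NA model fields and status `"no-segment"`.
#'
#' @param mutations Mutation table with read counts (`alt_reads_tumor`,
#'   `total_reads_tumor`).
#' @param segments Segment table from [read_cn_segments()] (optionally
#'   with a logical `subclonal_cn` column; such segments are flagged so
#'   duplication timing can exclude them).
#' @param purity Named vector of tumor purities by sample id.
#' @param n_normal Normal copy number (scalar or named-by-sample vector
#'   for sex-chromosome handling).
#' @return `mutations` with appended model and clonality columns.
#' @export
clonality_calls <- function(mutations, segments, purity, n_normal = 2) {
  n <- nrow(mutations)
  idx <- rep(NA_integer_, n)
  for (s in unique(as.character(mutations$sample_id))) {
    for (ch in unique(as.character(mutations$chrom[mutations$sample_id == s]))) {
      mi <- which(mutations$sample_id == s & mutations$chrom == ch)
      si <- which(segments$sample_id == s & segments$chrom == ch)
      if (!length(si)) next
      so <- si[order(segments$start[si])]
      k <- findInterval(mutations$pos[mi], segments$start[so])
      hit <- k >= 1 & mutations$pos[mi] <= segments$end[so][pmax(k, 1)]
      idx[mi[hit]] <- so[k[hit]]
    }
  }
  rho <- purity[as.character(mutations$sample_id)]
  nn <- if (length(n_normal) > 1) n_normal[as.character(mutations$sample_id)] else rep(n_normal, n)
  out <- mutations
  out$n_tumor <- segments$n_tumor[idx]
  out$major <- segments$major[idx]
  out$minor <- segments$minor[idx]
  out$subclonal_cn <- if ("subclonal_cn" %in% names(segments))
    segments$subclonal_cn[idx] else rep(FALSE, n)
  has <- !is.na(idx) & out$n_tumor >= 1
  vaf <- out$alt_reads_tumor / out$total_reads_tumor
  out$multiplicity <- NA_integer_
  out$multiplicity[has] <- estimate_multiplicity(vaf[has], rho[has],
                                                 out$n_tumor[has], nn[has],
                                                 major = out$major[has])
  cc <- data.frame(vaf = vaf, n_chr = NA_real_, ccf = NA_real_,
                   ccf_raw = NA_real_, ccf_lower = NA_real_,
                   ccf_upper = NA_real_, status = "no-segment",
                   stringsAsFactors = FALSE)
  if (any(has)) {
    cc[has, ] <- compute_ccf(out$alt_reads_tumor[has], out$total_reads_tumor[has],
                             rho[has], out$n_tumor[has], nn[has],
                             out$multiplicity[has])
  }
  cbind(out, cc[, c("ccf", "ccf_raw", "ccf_lower", "ccf_upper", "status")])
}
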