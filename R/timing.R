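## Molecular timing of chromosome duplications on the point-mutation-time
## (pmt) scale: 0 = no clonal mutations yet acquired, 100 = all acquired.
## Mutations present on the duplicated copy before the gain are themselves
## duplicated (multiplicity = major copy number); the balance of
## duplicated vs non-duplicated mutation counts dates the gain.

#' Count duplicated and non-duplicated mutations on a segment
#'
#' `n_dup` counts clonal mutations at the maximal multiplicity (the major
#' allele copy number); `n_ndup` counts mutations at intermediate levels
#' of multiplicity or non-duplicated. A timing is informative only when
#' the segment carries at least `min_mutations` mutations in total.
#'
#' @param multiplicities Integer multiplicities of the clonal mutations on
#'   the segment.
#' @param n_max Maximal multiplicity (major allele copy number).
#' @param min_mutations Informativeness threshold (default 30).
#' @return List with `n_dup`, `n_ndup`, `informative`.
#' @export
count_duplicated <- function(multiplicities, n_max, min_mutations = 30) {
  m <- multiplicities[!is.na(multiplicities)]
  list(n_dup = sum(m == n_max),
       n_ndup = sum(m < n_max),
       informative = length(m) >= min_mutations)
}

#' Time a chromosome duplication from mutation counts
#'
#' For a single-parent gain the molecular time is
#' `T = n_dup / (n_dup + (n_ndup - n_dup) / c) * 100` with
#' `c = (3 + N_t)/2` (which reduces to the 3-copy form
#' `n_dup / (n_dup + (n_ndup - n_dup)/3) * 100` at N_t = 3; for N_t >= 4
#' it times the first duplication event). When both parental copies were
#' duplicated (e.g. N_t = 4 as 2+2, including whole-genome doubling),
#' `T = (n_dup/2) / (n_dup/2 + n_ndup / c) * 100`. The result is clamped
#' to [0, 100].
#'
#' @param n_dup,n_ndup Duplicated / non-duplicated mutation counts.
#' @param n_tumor Total tumor copy number N_t of the segment.
#' @param mode `"single_parent"` or `"both_parents"`.
#' @return Timing T in pmt units, `NA` when both counts are zero.
#' @export
time_duplication <- function(n_dup, n_ndup, n_tumor,
                             mode = c("single_parent", "both_parents")) {
  mode <- match.arg(mode)
  if (n_dup + n_ndup == 0) return(NA_real_)
  cc <- (3 + n_tumor) / 2
  t <- if (mode == "single_parent") {
    n_dup / (n_dup + (n_ndup - n_dup) / cc) * 100
  } else {
    (n_dup / 2) / (n_dup / 2 + n_ndup / cc) * 100
  }
  min(max(t, 0), 100)
}

#' Select the timing mode of a duplicated segment
#'
#' Both-parents mode when major == minor >= 2 (e.g. 2+2 after whole-genome
#' doubling); single-parent mode when major >= 2 otherwise; segments
#' without a duplicated allele (major < 2) are not timed.
#'
#' @param major,minor Allele-specific copy numbers.
#' @return `"single_parent"`, `"both_parents"` or `NA` (not timeable).
#' @export
select_timing_mode <- function(major, minor) {
  ifelse(major >= 2 & minor >= 2 & major == minor, "both_parents",
         ifelse(major >= 2, "single_parent", NA_character_))
}

#' Time every duplicated segment of a sample set
#'
#' Applies [count_duplicated()] and [time_duplication()] to each clonal
#' duplicated segment, using only clonal mutations (and skipping segments
#' flagged as subclonal copy number, whose formulas assume clonal CN).
#'
#' @param calls Output of [clonality_calls()] (needs multiplicity, major,
#'   minor, n_tumor, subclonal_cn, status, plus segment assignment via
#'   sample/chrom/pos).
#' @param segments Segment table used for the calls.
#' @param min_mutations Informativeness threshold (default 30).
#' @return data.frame, one row per timeable segment: identifiers, mode,
#'   n_dup, n_ndup, informative flag and timing `T` (NA when not
#'   informative).
#' @export
time_segments <- function(calls, segments, min_mutations = 30) {
  res <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    mode <- select_timing_mode(seg$major, seg$minor)
    if (is.na(mode)) next
    if (isTRUE(seg$subclonal_cn)) next
    sel <- calls$sample_id == seg$sample_id & calls$chrom == seg$chrom &
      calls$pos >= seg$start & calls$pos <= seg$end & calls$status == "clonal"
    cnt <- count_duplicated(calls$multiplicity[sel], n_max = seg$major,
                            min_mutations = min_mutations)
    res[[length(res) + 1L]] <- data.frame(
      sample_id = seg$sample_id, chrom = seg$chrom,
      start = seg$start, end = seg$end, n_tumor = seg$n_tumor,
      mode = mode, n_dup = cnt$n_dup, n_ndup = cnt$n_ndup,
      informative = cnt$informative,
      T = if (cnt$informative)
        time_duplication(cnt$n_dup, cnt$n_ndup, seg$n_tumor, mode)
      else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_tumor = numeric(),
                      mode = character(), n_dup = integer(), n_ndup = integer(),
                      informative = logical(), T = numeric()))
  }
  do.call(rbind, res)
}

#' Classify the chromosome-gain pattern of a sample
#'
#' `"synchronous"` when some set of at least `min_events` duplications
#' falls within a window narrower than `window` pmt (checked exactly on
#' the sorted timings), `"WGD"` when a genome-wide doubling is present,
#' `"scattered"` otherwise.
#'
#' @param timings Informative duplication timings (pmt) of one sample.
#' @param wgd Logical: whole-genome doubling present.
#' @param min_events Minimum co-occurring duplications (default 4).
#' @param window Maximal pmt span counted as synchronous (default 30,
#'   strict inequality).
#' @return One of `"WGD"`, `"synchronous"`, `"scattered"`.
#' @export
classify_gain_pattern <- function(timings, wgd = FALSE, min_events = 4,
                                  window = 30) {
  if (isTRUE(wgd)) return("WGD")
  t <- sort(timings[!is.na(timings)])
  if (length(t) >= min_events) {
    span <- t[seq_len(length(t) - min_events + 1L) + min_events - 1L] -
      t[seq_len(length(t) - min_events + 1L)]
    if (any(span < window)) return("synchronous")
  }
  "scattered"
}
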