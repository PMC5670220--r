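---
title: "Methods: signature fitting, clonality and duplication timing in mutproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature fitting, clonality and duplication timing in mutproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mutproc implements the computational core of a whole-genome tumor analysis:
mutational-signature exposures and per-mutation attribution, rearrangement
signatures, clonality from read counts and copy number, molecular timing of
chromosome duplications, and replication/transcription context analyses.
This vignette explains the models, the tunable parameters, the synthetic
generators used for closed-loop testing, and the numerical choices made
where the design was open.

## The 96-category catalog

Every somatic SNV is collapsed onto a pyrimidine-referenced trinucleotide
category: 6 substitution types (C>A, C>G, C>T, T>A, T>C, T>G) times 16
flanking-base contexts. Mutations reported with a purine reference are
reverse-complemented together with both flanks, so `classify_substitution()`
is an involution under strand flips. The row order of every catalog and
signature matrix is fixed package-wide: lexicographic by substitution type,
then 5' flank, then 3' flank. Mutation records use 1-based VCF coordinates;
interval tracks (bedGraph) stay 0-based half-open internally, with
conversion only at the read boundary. Multi-allelic VCF records are skipped
with a warning, as are SNVs whose reference base disagrees with the genome
or whose flanks are unavailable; `build_catalog()` reports the skip count so
catalog totals always reconcile with the input.

Indels never enter the 96-category matrix (the reference signature model is
SNV-only); they are summarized by type, size class (1, 2–5, >5 bp — the 2–5
class isolates the short-deletion excess of very highly expressed genes) and
the expression bin of the containing gene. An indel lies in a
polynucleotide repeat when its unit occurs in at least two exact tandem
copies at the site; operationally, the reference sequence immediately after
the event must begin with one further full copy of the unit. This is a
deliberately sharp, testable reading of "occurring at polynucleotide
repeats".

## Exposure fitting and the 6% rule

With a known signature matrix $P$ (96 × S, columns sum to 1), the exposure
vector $e$ of a sample with catalog column $m$ minimizes
$\lVert m - P e \rVert_2$ subject to $e \ge 0$. This per-sample
non-negative least squares problem is the exact subproblem of NMF with $P$
fixed, and unlike a joint multiplicative-update fit it is deterministic and
restart-free; `pracma::lsqnonneg` (Lawson–Hanson) is the solver. Signatures
contributing less than `min_contribution` (default 0.06, i.e. <6% of the
tumor's mutations) are then discarded to avoid overfitting. The discard
procedure is greedy and reproducible: drop the single lowest sub-threshold
signature, refit on the remaining set, repeat until every nonzero
contribution clears the threshold. Exposures are finally rescaled so each
column sums to the sample's observed mutation count — exposures are in
mutation units, not proportions. Whether discarded-signature mutations
should be redistributed before per-mutation attribution is not prescribed
anywhere; mutproc refits after discard, so attribution always uses the
final exposure vector.

De novo extraction (`extract_denovo`) is a standard Frobenius NMF with
Lee–Seung multiplicative updates, 50 random restarts per rank (seeded, RNG
state restored), and an elbow rule on the residual for rank selection (the
largest rank whose step still cuts the residual by >5%). It serves the
exploratory role that Bayesian NMF variants play in larger studies; matching
extracted profiles to the bundled reference uses cosine similarity with the
conventional 0.75 "known signature" threshold.

The bundled reference (`reference_signatures()`) is a **synthetic** 30-column
catalog with the structure of the public COSMIC v2 matrix (96 rows, columns
sum to 1, sparse peaked profiles; generated once from seeded sparse
Dirichlet draws). It exists so the pipeline runs and tests without network
access; its profiles do not reproduce the empirical COSMIC patterns, and
any application to real data should substitute the real catalog via
`read_signature_matrix()`. The "liver" subset selects the ten columns
(1, 4, 5, 6, 12, 16, 17, 22, 23, 24) used by default.

## Per-mutation attribution and gene enrichment

For a mutation of category $c$ in a tumor with exposures $e$, the expected
count of category $c$ decomposes as $m^c = \sum_s p_s^c e^s$, and the
probability that signature $s$ generated the mutation is
$P(m,s) = p_s^c e^s / \sum_{s'} p_{s'}^c e^{s'}$. Summing $P(m,s)$ over the
mutations of a gene gives that gene's cumulative signature contribution
$P(G,s)$. Summing over *all* mutations of a sample reproduces the fitted
exposures only up to the NNLS residual: the leakage is about 0.5–1% of the
sample total at 5,000 mutations (it shrinks as $1/\sqrt{n}$), which is why
context analyses that need high-confidence assignments use only mutations
attributed to a single signature with probability ≥ 0.7.

Gene × signature enrichment uses two-sided Wilcoxon rank-sum tests
comparing $P(m,s)$ inside the gene against either all other mutations or
all other mutations of samples that carry a mutation in the gene, with
Benjamini–Hochberg correction across the tested grid. Fully tied inputs are
flagged degenerate with p = 1 rather than passed to `wilcox.test`.

## Rearrangement signatures

Structural variants are first filtered on read evidence: at least 15
supporting reads for every type, plus at least 10% of reads for inversions
and translocations (the fraction rule deliberately does not apply to
deletions and duplications). Breakpoints are then scanned for clustering: a
breakpoint is clustered when some continuously-placed 1 Mb window contains
it together with ≥ 10 breakpoints of the same sample. The scan is a sorted
two-pointer pass, verified against a quadratic sliding-window oracle in the
tests; translocations contribute one breakpoint to each partner chromosome,
because the rule counts breakpoints, not events. Classification yields 38
categories: {del, dup, inv} × six size bins × {clustered, non-clustered},
plus the two translocation categories. Size bins are half-open `[low, high)`
so exactly 1 kb falls in "1–10 kb" and exactly 1 Mb in "1–10 Mb". One event
contributes one count to the 38-row catalog (events, not breakpoints, are
tallied). The same NMF machinery extracts rearrangement signatures from
this catalog, and a sample carries a rearrangement phenotype when ≥ 50
events are attributed to one signature.

## Clonality

For a mutation with variant allele fraction VAF on a segment with tumor
copy number $N_t$, normal copy number $N_n$, and tumor purity $\rho$:

$$\mathrm{CCF} = \mathrm{VAF}\,\frac{\rho N_t + (1-\rho)N_n}{\rho\, n_\mathrm{chr}},
\qquad
n_\mathrm{chr} = \mathrm{round}\!\left(\max\!\left(1, \mathrm{VAF}\,\frac{\rho N_t + (1-\rho)N_n}{\rho}\right)\right)$$

with $n_\mathrm{chr}$ clamped to the major allele copy number. Rounding
ties (x.5) round half away from zero — the convention had to be fixed
somewhere and R's banker's rounding would be surprising here. The 95%
confidence interval of the VAF is the exact two-sided Clopper–Pearson
interval ("binomial test" admits several readings; the exact interval is
conservative and standard), mapped through the same affine transform to a
CCF interval. A mutation is subclonal iff the CI upper bound is strictly
below 0.95 — an upper bound of exactly 0.95 is clonal. Reported CCFs are
clamped to 1 (sampling noise pushes clonal VAFs above expectation) but the
raw value is retained; bias measurements must use the raw value, since
clamping alone introduces a ~0.04 downward bias at depth 100 while the raw
mean is unbiased. Normal copy number defaults to 2 and is overridable per
sample for sex chromosomes. Mutations on segments flagged as subclonal copy
number are excluded from duplication timing, whose formulas assume clonal
copy number.

## Timing chromosome duplications

Mutations acquired on a chromosome copy before its duplication are
themselves duplicated, so late gains carry many duplicated mutations and
early gains few. With $N_\mathrm{dup}$ mutations at maximal multiplicity
and $N_\mathrm{ndup}$ at intermediate or single multiplicity, the gain time
on the point-mutation-time scale (0 = no clonal mutations yet, 100 = all
acquired) is

$$T = \frac{N_\mathrm{dup}}{N_\mathrm{dup} + \dfrac{N_\mathrm{ndup}-N_\mathrm{dup}}{(3+N_t)/2}} \times 100$$

which reduces to the familiar denominator 3 at $N_t = 3$; when both
parental copies were duplicated (2+2, including whole-genome doubling) the
numerator halves and the denominator uses $N_\mathrm{ndup}/((3+N_t)/2)$.
$T$ is clamped to [0, 100]. Only clonal duplications with ≥ 30 mutations on
the segment are timed; for $N_t \ge 4$ single-parent gains only the first
duplication is timed (later gains on the same segment are reported
untimed). A sample's gain pattern is "synchronous" when ≥ 4 informative
timings fall within a window narrower than 30 pmt (the sorted-window scan
is exactly equivalent to the exhaustive subset check), "WGD" when a doubling
is present, "scattered" otherwise.

The generator inverts this model. For 2→3 gains it is mechanistic —
mutations accrue uniformly in pmt on 2 copies before the gain and 3 after,
and pre-gain mutations on the duplicated copy get multiplicity 2 — under
which the $N_t=3$ formula is exact in expectation. For $N_t\ge4$ and
both-parents modes the extrapolated formulas are not exact under the same
mechanistic accrual, so the generator draws the duplicated fraction from
the inverted formula itself; the closed loop then tests the estimator, not
the extrapolation. Note the estimator's sampling noise: with 300
informative mutations the delta-method standard deviation of $\hat T$ is
4–5 pmt, so individual timings should be read with roughly that
uncertainty.

## Replication and transcription context

Replication timing deciles partition the covered genome into ten classes
of equal informative size by signal quantile (decile 1 = lowest signal).
Fork direction is assigned between adjacent signal peaks (initiation) and
valleys (termination), from peak towards valley, and only where the
peak-to-valley distance is ≥ 500 kb; closer pairs stay unassigned, and a
constant signal collapses the deciles with an explicit flag. The
leading/lagging convention is a single documented switch: for a rightward
fork the reference plus strand is the lagging-strand template. Mutation
rates divide counts by informative sizes (excluding N bases) in mutations
per Mb; strand asymmetries are tested against 1:1 with exact binomial
tests.

A mutation sits "on" the strand carrying its mutated pyrimidine; its
transcriptional class compares that strand with the gene's coding strand.
Genes get a single FPKM (median across expression samples) and one bin:
FPKM 0, five equal-count quintiles on (0, 100), or the very-high class
(FPKM ≥ 100). Regions where genes on opposite strands overlap are
strand-ambiguous and excluded (tallied). TSS profiles bin mutations from
50 kb upstream to 100 kb downstream of each TSS in 1 kb bins, truncate
exposure at gene ends, and normalize against the intergenic reference (the
genome outside gene bodies ± 10 kb, halved for per-strand rates since each
mutation lands in one strand class); samples are pooled by default with a
per-sample option, since per-sample profiles are noisy at realistic
mutation loads.

Transcription-coupled damage and repair are quantified on A>G mutations
(the T>C category seen from the purine), classified by the strand carrying
the adenine: TCD is the slope of the non-transcribed-strand rate between
the lowest and highest expression quintiles, TCR the transcribed-strand
slope, both in rates normalized to the unexpressed-gene baseline. The
generator injects a linear trend across quintiles so that the injected
slope equals the recovered normalized slope exactly in expectation.

## Synthetic cohorts and what they do (and do not) show

All generators are deterministic under a seed and emit the same plain
formats the readers consume. Defaults mirror deep tumor whole-genome
sequencing: mean depth 92× (Poisson, floored at 6 reads), purity 1, diploid
normal, a random genome with GC 0.41. The synthetic genome has realistic
base composition but no repeat structure, no mutation hotspots, and no
caller artifacts; the SV generator places clusters explicitly rather than
through a replication-based mechanism; expression and replication tracks
are idealized geometry. Passing closed-loop tests therefore demonstrates
that the estimators invert their own forward models at realistic noise
levels — not that the models capture every property of real tumors.

Problem sizes used in the checked examples (chosen to exercise the
estimators at realistic scale while keeping the full suite to a few
minutes): 10 samples × 5,000 mutations for exposure recovery (per-sample
true-vs-fitted cosine ≥ 0.95), 300-mutation segments × 100 replicates per
true time for duplication timing, 1,000 mutations for CCF calibration at
depth 100, and 5,000 A>G mutations for TCD/TCR recovery within 20%.

## Known limitations

* The reference signature catalog is synthetic (see above); results on real
  data require the real catalog file.
* Exposure fitting assumes the provided signatures are the true dictionary;
  misspecified dictionaries bias exposures silently.
* Duplication timing for $N_t \ge 4$ uses the extrapolated first-gain
  formula; sequential-gain histories are not modeled.
* The two-level clonal/subclonal split does not reconstruct subclonal
  phylogenies; CCF confidence intervals ignore purity and copy-number
  uncertainty.
* TSS profiles and TCD/TCR assume one dominant isoform per gene (single
  TSS, single FPKM).
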