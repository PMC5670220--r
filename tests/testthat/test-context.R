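test_that("replication deciles partition the covered genome evenly", {
  ann <- simulate_annotation(peak_valley_distance = 1e6, seed = 81)
  ra <- replication_annotation(ann$signal)
  width <- ra$bins$end - ra$bins$start
  sizes <- tapply(width, ra$bins$decile, sum)
  expect_equal(length(sizes), 10)
  expect_lt((max(sizes) - min(sizes)) / mean(sizes), 0.05)
})

test_that("fork direction runs from peaks to valleys when they are far enough", {
  # triangular signal: peak at 10 Mb, valley at 11.2 Mb
  starts <- seq(9.0e6, 12.4e6 - 1e4, by = 1e4)
  mids <- starts + 5e3
  v <- ifelse(mids <= 1e7, (mids - 9e6) / 1e6,
              ifelse(mids <= 11.2e6, (11.2e6 - mids) / 1.2e6,
                     (mids - 11.2e6) / 1.2e6))
  sig <- data.frame(chrom = "c1", start = starts, end = starts + 1e4, value = v)
  ra <- replication_annotation(sig)
  ctx <- assign_replication_context(
    data.frame(chrom = "c1", pos = c(10.5e6, 11.0e6)), ra)
  expect_equal(ctx$fork, c("right", "right"))
  # a 400 kb peak-to-valley pair stays unassigned
  starts2 <- seq(0, 8e5 - 1e4, by = 1e4)
  mids2 <- starts2 + 5e3
  v2 <- ifelse(mids2 <= 4e5, mids2, 8e5 - mids2)
  sig2 <- data.frame(chrom = "c1", start = starts2, end = starts2 + 1e4, value = v2)
  ra2 <- replication_annotation(sig2)
  expect_true(all(ra2$bins$fork == "unassigned"))
})

test_that("constant signals collapse deciles with a warning and off-track positions warn", {
  sig <- data.frame(chrom = "c1", start = seq(0, 9e5, 1e5),
                    end = seq(1e5, 1e6, 1e5), value = 1)
  expect_warning(ra <- replication_annotation(sig), "constant")
  expect_true(ra$degenerate)
  expect_equal(unique(ra$bins$decile), 1L)
  expect_warning(ctx <- assign_replication_context(
    data.frame(chrom = "c1", pos = 5e6), ra), "outside")
  expect_true(is.na(ctx$decile))
})

test_that("leading/lagging assignment follows the documented strand convention", {
  # rightward fork: plus strand is the lagging template
  expect_equal(replication_strand("right", "+"), "lagging")
  expect_equal(replication_strand("right", "-"), "leading")
  expect_equal(replication_strand("left", "+"), "leading")
  expect_equal(replication_strand("unassigned", "+"), "unassigned")
  # the convention switch flips every assignment
  expect_equal(replication_strand("right", "+", plus_is_lagging_for_right_fork = FALSE),
               "leading")
})

test_that("mutation rates use informative sizes and the 0.7 attribution rule", {
  expect_equal(mutation_rate(100, 1e6), 100)
  # 2 Mb of which 1 Mb is N: the informative size is what counts
  expect_equal(mutation_rate(100, 2e6 - 1e6), 100)
  expect_warning(r0 <- mutation_rate(5, 0), "undefined")
  expect_true(is.na(r0))
  A <- rbind(c(0.65, 0.35), c(0.72, 0.28), c(0.5, 0.5))
  colnames(A) <- c("s1", "s2")
  expect_identical(signature_filtered(A, "s1"), c(FALSE, TRUE, FALSE))
})

test_that("strand asymmetry is quiet under symmetry and loud under constructed bias", {
  set.seed(82)
  strands <- sample(c("leading", "lagging"), 2000, replace = TRUE)
  sym <- strand_asymmetry(strands)
  expect_gt(sym$p, 0.01)
  expect_lt(abs(sym$ratio - 1), 0.15)
  # all T>C purines on one strand: extreme ratio in the expected direction
  biased <- strand_asymmetry(rep(c("transcribed", "non_transcribed"), c(30, 270)),
                             strands = c("non_transcribed", "transcribed"))
  expect_gt(biased$ratio, 5)
  expect_lt(biased$p, 1e-10)
  # empty class: ratio undefined, excluded strands tallied
  empty <- strand_asymmetry(c("leading", "other"), strands = c("leading", "lagging"))
  expect_true(is.na(empty$ratio))
  expect_equal(attr(empty, "n_excluded"), 1)
})

test_that("expression bins partition genes with balanced quintiles", {
  set.seed(83)
  fpkm <- c(rep(0, 7), exp(stats::runif(52, log(0.1), log(99))),
            stats::runif(9, 100, 500))
  names(fpkm) <- paste0("g", seq_along(fpkm))
  bins <- expression_bins(fpkm)
  expect_equal(sum(is.na(bins)), 0)
  expect_equal(unname(table(bins)[["FPKM0"]]), 7)
  expect_equal(unname(table(bins)[["VeryHigh"]]), 9)
  qn <- table(bins)[paste0("Q", 1:5)]
  expect_lte(max(qn) - min(qn), 1)
  expect_true(all(fpkm[bins == "VeryHigh"] >= 100))
})

test_that("gene assignment resolves strand class and excludes ambiguous overlaps", {
  genes <- data.frame(gene = c("gP", "gM", "gX", "gY"),
                      chrom = "c1",
                      start = c(1e3, 5e3, 9e3, 9.5e3),
                      end = c(2e3, 6e3, 10e3, 10.5e3),
                      strand = c("+", "-", "+", "-"),
                      stringsAsFactors = FALSE)
  mut <- data.frame(chrom = "c1", pos = c(1500, 5500, 9700, 300),
                    ref = c("C", "C", "C", "C"), alt = "T",
                    stringsAsFactors = FALSE)
  asg <- assign_genes(mut, genes)
  # pyrimidine on the coding strand of gP -> non-transcribed
  expect_equal(asg$tx_class[1], "non_transcribed")
  # pyrimidine on plus, gene on minus -> transcribed
  expect_equal(asg$tx_class[2], "transcribed")
  # overlapping genes on opposite strands -> excluded
  expect_true(asg$ambiguous[3])
  expect_true(is.na(asg$gene[3]))
  # intergenic
  expect_true(is.na(asg$gene[4]) && !asg$ambiguous[4])
  # conservation: stranded classes plus exclusions account for all gene hits
  n_in_genes <- sum(!is.na(asg$gene)) + sum(asg$ambiguous)
  expect_equal(sum(asg$tx_class %in% c("transcribed", "non_transcribed")) +
                 sum(asg$ambiguous), n_in_genes)
})

test_that("TSS profiles are flat under uniform mutations and step under injected bias", {
  ann <- simulate_annotation(n_genes = 40, gene_length = 6e4, spacing = 1.3e5,
                             seed = 84)
  L <- ann$chrom_lengths[[1]]
  set.seed(85)
  n <- 60000
  mut <- data.frame(chrom = "simchr", pos = sample(L, n, replace = TRUE),
                    ref = sample(c("C", "T", "A", "G"), n, replace = TRUE),
                    alt = "X", stringsAsFactors = FALSE)
  mut$alt <- c(C = "T", T = "C", A = "G", G = "A")[mut$ref]
  prof <- tss_profile(mut, ann$genes, ann$chrom_lengths,
                      binsize = 1e4, upstream = 3e4, downstream = 6e4)
  expect_true(all(abs(prof$norm_rate - 1) < 0.45))
  expect_equal(nrow(prof), 2 * 9)
  # inject a non-transcribed-strand excess inside gene bodies: T>C with the
  # pyrimidine always on the coding strand (the package's strand convention)
  glen <- ann$genes$end - ann$genes$start + 1
  set.seed(87)
  gpick <- sample(nrow(ann$genes), 8000, replace = TRUE)
  pos2 <- ann$genes$start[gpick] + floor(stats::runif(length(gpick)) * glen[gpick])
  pyr_plus <- ann$genes$strand[gpick] == "+"
  mut2 <- data.frame(chrom = "simchr", pos = pos2,
                     ref = ifelse(pyr_plus, "T", "A"),
                     alt = ifelse(pyr_plus, "C", "G"), stringsAsFactors = FALSE)
  prof2 <- tss_profile(rbind(mut, mut2), ann$genes, ann$chrom_lengths,
                       binsize = 1e4, upstream = 3e4, downstream = 6e4)
  dn_nt <- prof2$norm_rate[prof2$tx_class == "non_transcribed" & prof2$bin >= 0]
  up_nt <- prof2$norm_rate[prof2$tx_class == "non_transcribed" & prof2$bin < 0]
  expect_gt(mean(dn_nt), mean(up_nt) + 0.5)
  # empty gene set: empty, error-free profile
  expect_equal(nrow(tss_profile(mut, ann$genes[0, ], ann$chrom_lengths)), 0)
})

test_that("TCD/TCR slopes are null without injection and recover injected bias", {
  ann <- simulate_annotation(n_genes = 60, seed = 88)
  flat <- simulate_tcd_mutations(ann$genes, ann$bins, n = 5000, tcd = 0, tcr = 0,
                                 seed = 89)
  q0 <- quantify_tcd_tcr(flat, ann$genes, ann$bins)
  expect_lt(abs(q0$tcd), 0.35)
  expect_lt(abs(q0$tcr), 0.35)
  inj <- simulate_tcd_mutations(ann$genes, ann$bins, n = 5000, tcd = 1, tcr = -0.5,
                                seed = 90)
  qi <- quantify_tcd_tcr(inj, ann$genes, ann$bins)
  expect_lt(abs(qi$tcd - 1), 0.2)
  expect_lt(qi$tcr, 0)  # transcribed-strand depletion
  expect_true(qi$normalized)
})
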