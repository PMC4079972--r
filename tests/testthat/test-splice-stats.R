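# Hand evaluation of the single-stratum CMH chi-squared (no correction):
# (a - r1*c1/n)^2 / (r1*r2*c1*c2 / (n^2*(n-1)))
hand_cmh <- function(tabs) {
  a <- ea <- va <- 0
  for (k in seq_len(dim(tabs)[3])) {
    t <- tabs[, , k]
    n <- sum(t)
    r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
    c1 <- sum(t[, 1]); c2 <- sum(t[, 2])
    if (min(r1, r2, c1, c2) == 0) next
    a <- a + t[1, 1]
    ea <- ea + r1 * c1 / n
    va <- va + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  (a - ea)^2 / va
}

test_that("splicing efficiency is the bounded proportion with NA at zero depth", {
  expect_equal(splicing_efficiency(0, 7), 0)
  expect_equal(splicing_efficiency(5, 0), 1)
  expect_equal(splicing_efficiency(30, 10), 0.75)
  expect_true(is.na(splicing_efficiency(0, 0)))
  expect_error(splicing_efficiency(-1, 2), "non-negative")
  # complementarity when both counts are positive
  set.seed(4)
  jr <- sample(1:50, 10); ei <- sample(1:50, 10)
  expect_equal(splicing_efficiency(jr, ei) + splicing_efficiency(ei, jr),
               rep(1, 10))
  # raw ratio behind the flag
  expect_equal(splicing_efficiency(30, 10, ratio = TRUE), 3)
})

test_that("CMH statistic matches the hand formula and mantelhaen.test", {
  t1 <- array(c(20, 10, 5, 25), dim = c(2, 2, 1))
  got <- cmh_test(t1)
  expect_equal(got$statistic, hand_cmh(t1))
  # single stratum: CMH equals (n-1)/n times the Pearson chi-squared
  x2 <- stats::chisq.test(t1[, , 1], correct = FALSE)$statistic
  expect_equal(got$statistic, unname(x2) * 59 / 60)
  # two identical strata
  t2 <- array(c(20, 10, 5, 25, 20, 10, 5, 25), dim = c(2, 2, 2))
  got2 <- cmh_test(t2)
  expect_equal(got2$statistic, hand_cmh(t2))
  expect_equal(got2$statistic,
               unname(stats::mantelhaen.test(t2, correct = FALSE)$statistic))
  # identical column distributions: no association
  t0 <- array(c(12, 8, 12, 8), dim = c(2, 2, 1))
  expect_equal(cmh_test(t0)$statistic, 0)
})

test_that("CMH is invariant to stratum order and to all-zero strata", {
  set.seed(14)
  tabs <- array(rpois(2 * 2 * 3, 15), dim = c(2, 2, 3))
  s1 <- cmh_test(tabs)$statistic
  s2 <- cmh_test(tabs[, , c(3, 1, 2)])$statistic
  expect_equal(s1, s2)
  with_zero <- array(c(tabs, matrix(0, 2, 2)), dim = c(2, 2, 4))
  expect_equal(cmh_test(with_zero)$statistic, s1)
  expect_warning(res <- cmh_test(matrix(0, 2, 2)), "degenerate")
  expect_true(is.na(res$statistic))
  # continuity correction reduces the statistic
  expect_lt(cmh_test(tabs, correct = TRUE)$statistic, s1)
})

test_that("q-values reproduce hand computations and stay monotone", {
  # BH by hand: q_i = min_k>=i (m * p_k / k)
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(qvalues(rep(1, 5), method = "storey"), rep(1, 5))
  expect_equal(qvalues(rep(1, 5), method = "bh"), rep(1, 5))
  # with pi0 fixed at 1 (small m), Storey reduces to BH exactly
  p <- c(0.001, 0.02, 0.2, 0.4, 0.9)
  expect_equal(qvalues(p, method = "storey"), qvalues(p, method = "bh"))
  set.seed(15)
  p2 <- runif(200)
  for (m in c("storey", "bh")) {
    q <- qvalues(p2, method = m)
    expect_true(all(q <= 1 & q >= 0))
    expect_true(all(diff(q[order(p2)]) >= -1e-12))
  }
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("RPKM follows the scaled formula with the epsilon floor", {
  expect_equal(rpkm(100, 1e7, 1000), 10 + 1e-5)
  expect_equal(rpkm(0, 1e7, 1000), 1e-5)
  expect_equal(rpkm(200, 1e7, 1000) - 1e-5,
               2 * (rpkm(100, 1e7, 1000) - 1e-5))
  expect_error(rpkm(1, 0, 10), "> 0")
  expect_error(rpkm(1, 10, 0), "> 0")
})

test_that("diagnostic JR/EI counting respects boundaries and strand", {
  genome <- toy_genome()
  tm <- toy_transcripts()
  introns <- derive_introns(tm, genome)
  rl <- 20L
  jdb <- build_junction_db(tm, genome, rl, min_overlap = 6L)
  # tA intron 1: genomic (101,150) on "+": upstream exon ends at 100
  ei_read <- substr(genome[["chr1"]], 91, 110)       # 10/10 straddle
  exon_read <- substr(genome[["chr1"]], 41, 60)      # inside an exon
  down_read <- substr(genome[["chr1"]], 141, 160)    # intron/downstream-exon
  jrec <- jdb[jdb$junction_id == "tA.J1-2", ]
  jr_read <- substr(jrec$sequence, jrec$boundary_index - 9,
                    jrec$boundary_index + 10)
  # tB intron (on "-"): genomic (101,150), upstream exon starts at 151;
  # a sense transcript read is the reverse complement of the genome slice
  eiB_read <- extract_sequence(genome, "chr2", 141, 160, "-")
  reads <- c(a = ei_read, b = exon_read, c = down_read, d = jr_read,
             e = eiB_read)
  cls <- classify_reads(reads, genome_refs = genome,
                        junction_refs = setNames(jdb$sequence,
                                                 jdb$junction_id),
                        genome_mm = 0L)
  counts <- count_diagnostic_reads(cls$genome_hits, cls$junction_hits,
                                   reads, introns, jdb, min_overlap = 6L)
  expect_equal(counts[counts$intron_id == "tA.I1", ]$EI, 1L)  # only 'a'
  expect_equal(counts[counts$intron_id == "tA.I1", ]$JR, 1L)  # only 'd'
  expect_equal(counts[counts$intron_id == "tA.I2", ]$EI, 0L)
  expect_equal(counts[counts$intron_id == "tB.I1", ]$EI, 1L)  # only 'e'
})

test_that("differential splicing recovers introns with halved splicing in B", {
  sim <- simulate_splice_counts(n_introns = 300L, n_replicates = 2L,
                                mean_depth = 60, frac_affected = 0.1,
                                seed = 19L)
  res <- splice_table(sim$counts)
  hits <- res[res$q.value < 0.05 & !is.na(res$q.value), ]$intron_id
  n_aff <- length(sim$affected)
  # affected introns are strongly enriched among discoveries
  tp <- sum(hits %in% sim$affected)
  expect_gt(tp / n_aff, 0.5)                  # decent power
  fp <- sum(!hits %in% sim$affected)
  expect_lt(fp / max(1, length(hits)), 0.2)   # FDR roughly controlled
  ft <- stats::fisher.test(table(factor(res$intron_id %in% sim$affected,
                                        c(FALSE, TRUE)),
                                 factor(res$intron_id %in% hits,
                                        c(FALSE, TRUE))))
  expect_lt(ft$p.value, 1e-6)
})
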