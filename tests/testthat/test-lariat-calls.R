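test_that("a single well-supported observation becomes the primary call", {
  calls <- cluster_branch_points(obs_fixture(25L, 5L))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$primary_offset, 25L)
  expect_equal(calls$primary_reads, 5L)
  expect_equal(calls$n_alternates, 0L)
})

test_that("neighbouring branch points differing by <10 reads pick the 3'-most", {
  # 20 and 15 reads, one base apart: difference 5 < 10 -> 3'-most wins
  calls <- cluster_branch_points(obs_fixture(c(30L, 31L), c(20L, 15L)))
  expect_equal(calls$primary_offset, 31L)
  expect_equal(calls$primary_reads, 35L)  # cluster support pools both
  expect_equal(sort(calls$cluster_members[[1]]), c(30L, 31L))
  # difference >= 10: the better-supported one wins regardless of side
  calls2 <- cluster_branch_points(obs_fixture(c(30L, 31L), c(25L, 10L)))
  expect_equal(calls2$primary_offset, 30L)
})

test_that("branch points more than one base apart are reported separately", {
  calls <- cluster_branch_points(obs_fixture(c(20L, 25L), c(12L, 8L)))
  expect_equal(calls$primary_offset, 20L)
  expect_equal(calls$n_alternates, 1L)
  expect_equal(calls$alternates[[1]]$offset, 25L)
  expect_equal(calls$alternates[[1]]$reads, 8L)
})

test_that("fewer than three supporting reads yields no call", {
  expect_equal(nrow(cluster_branch_points(obs_fixture(10L, 2L))), 0L)
  # cluster support is pooled across chained neighbours by default
  expect_equal(nrow(cluster_branch_points(obs_fixture(c(10L, 11L),
                                                      c(2L, 1L)))), 1L)
  # strict per-offset thresholding is available
  expect_equal(nrow(cluster_branch_points(obs_fixture(c(10L, 11L),
                                                      c(2L, 1L)),
                                          per_offset_threshold = TRUE)), 0L)
  expect_equal(nrow(cluster_branch_points(obs_fixture(integer(0),
                                                      integer(0)))), 0L)
})

test_that("no reads are created or lost by clustering", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    offsets <- sort(sample(10:60, n))
    counts <- sample(1:30, n, replace = TRUE)
    obs <- obs_fixture(offsets, counts)
    calls <- cluster_branch_points(obs, min_reads = 1L)
    total_called <- calls$primary_reads +
      sum(calls$alternates[[1]]$reads)
    expect_equal(total_called, sum(counts))
  }
})

test_that("min_reads is monotone and cluster_gap controls splitting", {
  set.seed(32)
  obs <- obs_fixture(c(10L, 11L, 14L, 20L), c(4L, 3L, 5L, 2L))
  n_calls <- vapply(1:15, function(mr) {
    nrow(cluster_branch_points(obs, min_reads = mr))
  }, integer(1))
  expect_true(all(diff(n_calls) <= 0))
  # smaller gap -> more, never fewer, reported branch points
  n_gap1 <- nrow(cluster_branch_points(obs, min_reads = 1L, cluster_gap = 1L))
  n_gap5 <- nrow(cluster_branch_points(obs, min_reads = 1L, cluster_gap = 5L))
  expect_gte(n_gap1, n_gap5)
})

test_that("stringent filtering removes the right hits", {
  hits <- data.table::data.table(
    read_id = paste0("r", 1:5),
    signature_id = "s",
    orientation = c("sense", "antisense", "sense", "sense", "sense"),
    n_mismatches = c(0L, 0L, 1L, 1L, 0L),
    mismatch_at_bp = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    overlap_5prime = c(20L, 20L, 20L, 20L, 9L),
    overlap_3prime = c(29L, 29L, 29L, 29L, 40L))
  kept <- filter_hits_stringent(hits, min_junction_overlap = 10L)
  # r2 antisense, r4 mismatch off the branch point, r5 9-base overlap
  expect_setequal(kept$read_id, c("r1", "r3"))
  # the 10/39 boundary case is kept
  hits2 <- data.table::copy(hits[5])
  hits2$overlap_5prime <- 10L
  hits2$overlap_3prime <- 39L
  expect_equal(nrow(filter_hits_stringent(hits2,
                                          min_junction_overlap = 10L)), 1L)
})

test_that("distance statistics use L minus the primary offset", {
  introns <- data.table::data.table(
    intron_id = c("a", "b", "c"), length = c(50L, 80L, 120L),
    sequence = c(random_seq(50), random_seq(80), random_seq(120)))
  calls <- data.table::data.table(
    event_id = c("a", "b"), intron_id = c("a", "b"), kind = "canonical",
    primary_offset = c(38L, 68L), primary_base = "A",
    primary_reads = c(10L, 5L), cluster_members = list(38L, 68L),
    alternates = list(data.table::data.table(offset = integer(),
                                             reads = integer()),
                      data.table::data.table(offset = integer(),
                                             reads = integer())),
    n_alternates = 0L)
  st <- bp_distance_stats(calls, introns)
  expect_equal(sort(st$per_call$distance_to_3prime), c(12L, 12L))
  expect_equal(st$median_distance_3prime, 12)
  expect_equal(st$n_detected, 2L)
  bad <- data.table::copy(calls)
  bad$intron_id <- c("a", "zzz")
  expect_error(bp_distance_stats(bad, introns), "unknown intron")
})

test_that("consensus matrix columns are probabilities with sane information content", {
  # 20 single-base 'introns' would clip; build introns with the branch
  # point centred so the full window survives
  set.seed(33)
  n <- 20
  introns <- data.table::data.table(
    intron_id = paste0("i", 1:n),
    sequence = vapply(1:n, function(i) random_seq(30), character(1)),
    length = 30L)
  calls <- data.table::data.table(
    event_id = introns$intron_id, intron_id = introns$intron_id,
    kind = "canonical", primary_offset = 15L, primary_base = "A",
    primary_reads = 5L)
  cm <- consensus_matrix(calls, introns, flank = 3L)
  expect_equal(unname(colSums(cm$prob)), rep(1, 7))
  expect_equal(cm$n, n)
  # a single sequence gives an indicator matrix
  cm1 <- consensus_matrix(calls[1], introns, flank = 3L)
  expect_true(all(apply(cm1$prob, 2, max) == 1))
  # a column matching the background exactly has zero information content
  introns_bg <- data.table::data.table(
    intron_id = paste0("b", 1:20),
    sequence = paste0(strrep("G", 3),
                      c(rep("A", 7), rep("T", 7), rep("C", 3), rep("G", 3)),
                      strrep("G", 3)),
    length = 7L)
  calls_bg <- data.table::data.table(
    event_id = introns_bg$intron_id, intron_id = introns_bg$intron_id,
    kind = "canonical", primary_offset = 4L, primary_base = "A",
    primary_reads = 3L)
  cm_bg <- consensus_matrix(calls_bg, introns_bg, flank = 0L,
                            background_gc = 0.30)
  expect_equal(unname(cm_bg$bits), 0, tolerance = 1e-12)
  # windows clipped at intron bounds are excluded
  expect_error(consensus_matrix(calls_bg, introns_bg, flank = 4L), "usable")
})

test_that("skipping calls are labelled when they reuse the canonical branch point", {
  calls <- data.table::data.table(
    event_id = c("t.I2", "t.I1-I2", "t.I1-I3"),
    intron_id = c("t.I2", "t.I2", "t.I3"),
    kind = c("canonical", "skipping", "skipping"),
    primary_offset = c(40L, 40L, 22L), primary_base = "A",
    primary_reads = c(30L, 4L, 3L))
  lab <- label_shared_branch_points(calls)
  expect_true(lab[lab$event_id == "t.I1-I2", ]$bp_shared_with_canonical)
  expect_true(is.na(lab[lab$event_id == "t.I1-I3", ]$bp_shared_with_canonical))
  expect_true(is.na(lab[lab$kind == "canonical", ]$bp_shared_with_canonical))
})
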