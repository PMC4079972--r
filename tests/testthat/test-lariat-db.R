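toy_intron <- function(seq, id = "t.I1", tx = "t", idx = 1L) {
  list(intron_id = id, transcript_id = tx, index = idx, sequence = seq)
}

# Independent re-derivation of one signature by direct string slicing.
slice_signature <- function(intron_seq, p, read_length) {
  w <- read_length - 1L
  five <- substr(intron_seq, max(1L, p - w), p - 1L)
  paste0(five, substr(intron_seq, p, p),
         substr(intron_seq, 1L, min(w, nchar(intron_seq))))
}

test_that("canonical signatures match the worked slicing example", {
  sig <- build_canonical_signatures(
    toy_intron("GTATGTTTACTAACTTTTAG"), 6L, "all_bases")
  expect_equal(nrow(sig), 20L)  # one per intronic base
  s13 <- sig[sig$bp_offset == 13L, ]
  expect_equal(s13$bp_base, "A")
  expect_equal(s13$sequence, "TACTAAGTATG")
  expect_equal(s13$bp_index_in_sequence, 5L)
  # candidates iterate from the 3' end toward position 1
  expect_equal(sig$bp_offset, 20:1)
  # BP at position 1 has an empty 5' segment and is flagged
  expect_true(sig[sig$bp_offset == 1L, ]$degenerate)
  expect_false(any(sig[sig$bp_offset > 1L, ]$degenerate))
})

test_that("adenine-only mode keeps only adenine branch points", {
  expect_equal(nrow(build_canonical_signatures(
    toy_intron("CCGCC"), 4L, "adenine_only")), 0L)
  seq <- "GTAAGCATTAG"
  sig <- build_canonical_signatures(toy_intron(seq), 5L, "adenine_only")
  a_pos <- which(strsplit(seq, "")[[1]] == "A")
  expect_equal(sort(sig$bp_offset), a_pos)
  expect_true(all(sig$bp_base == "A"))
})

test_that("signature construction agrees with independent slicing on random introns", {
  set.seed(202)
  for (i in 1:60) {
    L <- sample(5:120, 1)
    rl <- sample(4:50, 1)
    seq <- random_seq(L)
    mode <- sample(c("all_bases", "adenine_only"), 1)
    sig <- build_canonical_signatures(toy_intron(seq), rl, mode)
    n_expected <- if (mode == "all_bases") L else {
      sum(strsplit(seq, "")[[1]] == "A")
    }
    expect_equal(nrow(sig), n_expected)
    if (nrow(sig) == 0) next
    redone <- vapply(sig$bp_offset, slice_signature, character(1),
                     intron_seq = seq, read_length = rl)
    expect_equal(sig$sequence, unname(redone))
    # maximum length 2*rl-1, attained only deep inside long introns
    expect_true(all(nchar(sig$sequence) <= 2L * rl - 1L))
    expect_equal(nchar(sig$sequence) == 2L * rl - 1L,
                 sig$bp_offset > rl - 1L & L >= rl - 1L)
  }
})

test_that("skipping signatures follow the intron-concatenation construction", {
  it <- data.table::data.table(
    intron_id = c("t.I1", "t.I2"), transcript_id = "t", index = 1:2,
    sequence = c("GTAAGCCTAG", "GTTTACAAAG"))
  sk <- build_skipping_signatures(it, 5L, "all_bases")
  # BP candidates iterate over the downstream intron only
  expect_equal(nrow(sk), 10L)
  expect_true(all(sk$upstream_intron_index == 1L))
  expect_true(all(sk$downstream_intron_index == 2L))
  s6 <- sk[sk$bp_offset == 6L, ]
  expect_equal(s6$sequence, "TTTACGTAA")  # hand concatenation and slicing
  # 3' segment is always the upstream intron's 5' end
  expect_true(all(substr(sk$sequence, sk$bp_index_in_sequence + 2L,
                         nchar(sk$sequence)) ==
                  substr("GTAAGCCTAG", 1L, 4L)))
  # 5' segment extends into the upstream intron near the 5' end of I2:
  # upstream of BP position 2 of I2 in "GTAAGCCTAGGTTTACAAAG" is "TAGG"
  s1 <- sk[sk$bp_offset == 2L, ]
  expect_equal(s1$sequence, paste0("TAGG", "T", "GTAA"))
})

test_that("skipping pair enumeration matches brute force", {
  expect_equal(enumerate_skipping_pairs(2L), 1L)
  expect_equal(enumerate_skipping_pairs(1L), 0L)
  expect_equal(enumerate_skipping_pairs(0L), 0L)
  for (I in 2:8) {
    pairs <- 0L
    for (i in seq_len(I - 1)) for (j in (i + 1):I) pairs <- pairs + 1L
    expect_equal(enumerate_skipping_pairs(I), pairs)
  }
  expect_error(enumerate_skipping_pairs(-1L))
  # a transcript with I introns produces signatures for exactly S_n pairs
  set.seed(9)
  it <- data.table::data.table(
    intron_id = paste0("t.I", 1:4), transcript_id = "t", index = 1:4,
    sequence = replicate(4, random_seq(12)))
  sk <- build_skipping_signatures(it, 5L, "all_bases")
  pairs_seen <- unique(sk[, c("upstream_intron_index",
                              "downstream_intron_index")])
  expect_equal(nrow(pairs_seen), enumerate_skipping_pairs(4L))
  expect_equal(nrow(build_skipping_signatures(it[1], 5L, "all_bases")), 0L)
})

test_that("FASTA database round-trips and collapses duplicates", {
  set.seed(77)
  it <- data.table::data.table(
    intron_id = paste0("t.I", 1:3), transcript_id = "t", index = 1:3,
    sequence = c("GTACGTATAG", "GTACGTATAG", "GTACGTATAG"))
  db <- build_lariat_db(it, 5L, "all_bases")
  path <- withr::local_tempfile(fileext = ".fa")
  write_lariat_fasta(db, path)
  back <- read_lariat_fasta(path)
  # identical introns: skipping pairs (1,2), (1,3), (2,3) produce duplicate
  # sequences that collapse on disk but re-expand on read
  recs <- Biostrings::readDNAStringSet(path)
  expect_lt(length(recs), nrow(db))
  expect_true(any(grepl(";", names(recs), fixed = TRUE)))
  expect_setequal(back$signature_id, db$signature_id)
  m <- merge(as.data.frame(back), as.data.frame(db), by = "signature_id")
  expect_equal(m$sequence.x, m$sequence.y)
  expect_equal(m$bp_offset.x, m$bp_offset.y)
  expect_equal(m$bp_index_in_sequence.x, m$bp_index_in_sequence.y)
  expect_equal(m$kind.x, m$kind.y)
})

test_that("chunked output splits into files of at most chunk_size records", {
  it <- data.table::data.table(
    intron_id = "t.I1", transcript_id = "t", index = 1L,
    sequence = "GTAAGTTCATAG")
  db <- build_canonical_signatures(it, 5L, "all_bases")  # 12 signatures
  stem <- withr::local_tempfile(fileext = ".fa")
  files <- write_lariat_fasta(db, stem, chunk_size = 5L)
  expect_length(files, 3L)
  sizes <- vapply(files, function(f) length(Biostrings::readDNAStringSet(f)),
                  integer(1))
  expect_equal(unname(sizes), c(5L, 5L, 2L))
  back <- read_lariat_fasta(files)
  expect_setequal(back$signature_id, db$signature_id)
})

test_that("degenerate inputs error clearly", {
  expect_error(build_canonical_signatures(toy_intron("ACGT"), 1L), ">= 2")
  expect_error(build_canonical_signatures(toy_intron(""), 5L), "empty")
})
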