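# Independent oracles and shared fixtures for the test suite.

# Brute-force ungapped Hamming matcher: scans every fully-contained
# placement, comparing integer-coded characters position by position.
# Deliberately independent of the package's seed-index implementation.
bf_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

bf_match <- function(read, refs, max_mm, policy = "sense_only") {
  out <- list()
  queries <- list(sense = read)
  if (policy == "both") queries$antisense <- bf_revcomp(read)
  nN <- utf8ToInt("N")
  for (ori in names(queries)) {
    q <- utf8ToInt(queries[[ori]])
    L <- length(q)
    for (ri in seq_along(refs)) {
      r <- utf8ToInt(refs[[ri]])
      if (length(r) < L) next
      for (off in 0:(length(r) - L)) {
        seg <- r[(off + 1):(off + L)]
        mm <- which(seg != q | seg == nN | q == nN)
        if (length(mm) <= max_mm) {
          out[[length(out) + 1]] <- data.frame(
            ref_id = names(refs)[ri], offset = off, orientation = ori,
            n_mismatches = length(mm), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(), offset = integer(),
                      orientation = character(), n_mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Branch-point observation table for one event.
obs_fixture <- function(offsets, counts, id = "t.I1",
                        bases = rep("A", length(offsets))) {
  data.table::data.table(event_id = id, intron_id = id, kind = "canonical",
                         bp_offset = offsets, bp_base = bases,
                         read_count = counts)
}

# Two-gene toy annotation on a small genome, one gene per strand.
toy_genome <- function() {
  set.seed(42)
  c(chr1 = random_seq(600), chr2 = random_seq(400))
}

toy_transcripts <- function() {
  transcript_models(data.frame(
    transcript_id = c("tA", "tA", "tA", "tB", "tB"),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "+", "-", "-"),
    start = c(1, 151, 301, 151, 21),
    end = c(100, 250, 400, 250, 100),
    stringsAsFactors = FALSE
  ))
}

# The 200-gene simulation used by the parameter-recovery and
# detection-bias checks; computed once per test run.
.sim_cache <- new.env(parent = emptyenv())
get_reference_simulation <- function() {
  if (is.null(.sim_cache$res)) {
    cfg <- sim_config()
    sim <- generate_genome(cfg, seed = 11L)
    reads <- generate_reads(sim, cfg, seed = 11L)
    res <- run_pipeline(sim$genome, sim$transcripts, reads$reads,
                        run_config(seed = 11L))
    .sim_cache$res <- list(cfg = cfg, sim = sim, reads = reads, res = res)
  }
  .sim_cache$res
}
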