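# Mismatch-tolerant ungapped matching of short reads against a set of
# reference sequences. The contract is brute-force Hamming semantics over
# every fully-contained placement; a pigeonhole seed index (any placement
# with <= m mismatches must contain an exact match of one of m+1 disjoint
# read pieces) prunes the candidate placements, and every candidate is then
# verified explicitly. N never matches anything, including another N.

# Hamming verification of candidate placements, vectorised by read length.
# cand: data.table(read_id, sequence, ref_id, offset) with `sequence` the
# (possibly reverse-complemented) read as aligned. Returns cand plus
# n_mismatches and mismatch_positions (0-based read indices, list column).
verify_candidates <- function(cand, refs, max_mismatches) {
  if (nrow(cand) == 0L) {
    cand[, `:=`(n_mismatches = integer(), mismatch_positions = list())]
    return(cand)
  }
  cand[, read_len := nchar(sequence)]
  out <- lapply(split(cand, cand$read_len), function(sub) {
    L <- sub$read_len[1L]
    refsub <- substr(refs[sub$ref_id], sub$offset + 1L, sub$offset + L)
    a <- matrix(unlist(strsplit(sub$sequence, "", fixed = TRUE),
                       use.names = FALSE), nrow = L)
    b <- matrix(unlist(strsplit(refsub, "", fixed = TRUE),
                       use.names = FALSE), nrow = L)
    mm <- (a != b) | a == "N" | b == "N"
    nmm <- .colSums(mm, L, ncol(mm))
    keep <- which(nmm <= max_mismatches)
    sub <- sub[keep]
    sub[, n_mismatches := as.integer(nmm[keep])]
    sub[, mismatch_positions := lapply(keep, function(j) which(mm[, j]) - 1L)]
    sub
  })
  rbindlist(out)
}

# Candidate placements from the pigeonhole seed index. reads_dt columns:
# read_id, sequence (as aligned). Returns data.table(read_id, sequence,
# ref_id, offset) of deduplicated fully-contained placements to verify.
seed_candidates <- function(reads_dt, refs, max_mismatches, min_seed = 6L) {
  rl <- nchar(reads_dt$sequence)
  k <- as.integer(min(rl)) %/% (max_mismatches + 1L)
  reflen <- nchar(refs)
  if (k < min_seed) {
    # degenerate case: enumerate every placement outright
    cand <- rbindlist(lapply(seq_along(refs), function(ri) {
      n_off <- reflen[ri] - rl + 1L
      ok <- which(n_off >= 1L)
      if (length(ok) == 0L) return(NULL)
      data.table(read_id = rep(reads_dt$read_id[ok], n_off[ok]),
                 sequence = rep(reads_dt$sequence[ok], n_off[ok]),
                 ref_id = names(refs)[ri],
                 offset = sequence(n_off[ok]) - 1L)
    }))
    if (is.null(cand) || nrow(cand) == 0L) {
      return(data.table(read_id = character(), sequence = character(),
                        ref_id = character(), offset = integer()))
    }
    return(cand)
  }
  m1 <- max_mismatches + 1L
  # read seeds: first k bases of each of the m+1 equal pieces
  piece_starts <- function(L) vapply(0:(m1 - 1L), function(i) {
    as.integer(i * (L %/% m1)) + 1L
  }, integer(1))
  seeds <- rbindlist(lapply(seq_len(nrow(reads_dt)), function(i) {
    st <- piece_starts(rl[i])
    data.table(read_id = reads_dt$read_id[i], sequence = reads_dt$sequence[i],
               seed = substring(reads_dt$sequence[i], st, st + k - 1L),
               piece = st)
  }))
  seed_set <- unique(seeds$seed)
  # reference k-mers, filtered by membership in the read seed set before any
  # join, to keep the big intermediate small
  usable <- which(reflen >= k)
  refk <- NULL
  if (length(usable) > 0L) {
    n_pos <- reflen[usable] - k + 1L
    ref_rep <- rep(usable, n_pos)          # pointer copies, cheap
    starts <- sequence(n_pos)
    km <- substring(refs[ref_rep], starts, starts + k - 1L)
    hitp <- which(km %chin% seed_set)
    if (length(hitp) > 0L) {
      refk <- data.table(ref_id = names(refs)[ref_rep[hitp]],
                         pos = starts[hitp], seed = km[hitp])
    }
  }
  if (is.null(refk) || nrow(refk) == 0L) {
    return(data.table(read_id = character(), sequence = character(),
                      ref_id = character(), offset = integer()))
  }
  cand <- merge(seeds, refk, by = "seed", allow.cartesian = TRUE)
  cand[, offset := pos - piece]               # 0-based placement offset
  cand <- cand[offset >= 0L &
                 offset + nchar(sequence) <= nchar(refs[ref_id])]
  unique(cand[, .(read_id, sequence, ref_id, offset)])
}

#' Match reads against reference sequences, tolerating mismatches
#'
#' Reports every ungapped, fully-contained placement of each read within a
#' reference at Hamming distance at most `max_mismatches`. `N` counts as a
#' mismatch against every base, including `N`. Antisense placements (the
#' reverse complement of the read matching the reference) are searched only
#' under `orientation_policy = "both"`.
#'
#' @param reads named character vector of read sequences, or a data.frame
#'   with columns `read_id` and `sequence`.
#' @param refs named character vector of reference sequences.
#' @param max_mismatches maximum Hamming distance (0--3).
#' @param orientation_policy `"sense_only"` or `"both"`.
#' @return data.table with one row per placement: `read_id`, `ref_id`,
#'   `offset` (0-based start of the read within the reference),
#'   `orientation` (`"sense"`/`"antisense"`), `n_mismatches`,
#'   `mismatch_positions` (list column of 0-based indices into the aligned
#'   read, i.e. the reverse complement for antisense placements).
#' @export
match_reads <- function(reads, refs, max_mismatches = 1L,
                        orientation_policy = c("sense_only", "both")) {
  orientation_policy <- match.arg(orientation_policy)
  if (!max_mismatches %in% 0:3) {
    stop("max_mismatches must be 0, 1, 2 or 3", call. = FALSE)
  }
  rd <- if (is.data.frame(reads)) {
    data.table(read_id = as.character(reads$read_id),
               sequence = toupper(as.character(reads$sequence)))
  } else {
    if (is.null(names(reads))) stop("reads must be named", call. = FALSE)
    data.table(read_id = names(reads), sequence = toupper(as.character(reads)))
  }
  if (nrow(rd) == 0L) return(empty_hit_table())
  if (any(is.na(rd$sequence) | nchar(rd$sequence) == 0L)) {
    stop("empty read sequence", call. = FALSE)
  }
  refs <- toupper(refs)
  if (length(refs) == 0L || is.null(names(refs))) {
    stop("refs must be a non-empty named character vector", call. = FALSE)
  }
  queries <- list(sense = rd)
  if (orientation_policy == "both") {
    anti <- copy(rd)[, sequence := revcomp(sequence)]
    queries$antisense <- anti
  }
  hits <- rbindlist(lapply(names(queries), function(ori) {
    cand <- seed_candidates(queries[[ori]], refs, max_mismatches)
    h <- verify_candidates(cand, refs, max_mismatches)
    if (nrow(h) == 0L) return(NULL)
    h[, orientation := ori]
    h
  }))
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hit_table())
  hits[, c("sequence", "read_len") := NULL]
  setcolorder(hits, c("read_id", "ref_id", "offset", "orientation",
                      "n_mismatches", "mismatch_positions"))
  setorder(hits, read_id, ref_id, offset)
  hits[]
}

#' Match a single read (see [match_reads()])
#'
#' @param read read sequence (single string).
#' @param refs named character vector of reference sequences.
#' @param max_mismatches maximum Hamming distance (0--3).
#' @param orientation_policy `"sense_only"` or `"both"`.
#' @param read_id identifier used in the hit table.
#' @return hit data.table as in [match_reads()].
#' @export
match_read <- function(read, refs, max_mismatches = 1L,
                       orientation_policy = c("sense_only", "both"),
                       read_id = "read1") {
  if (length(read) != 1L || is.na(read) || nchar(read) == 0L) {
    stop("read must be a single non-empty string", call. = FALSE)
  }
  match_reads(setNames(read, read_id), refs, max_mismatches,
              orientation_policy)
}

empty_hit_table <- function() {
  data.table(read_id = character(), ref_id = character(), offset = integer(),
             orientation = character(), n_mismatches = integer(),
             mismatch_positions = list())
}

# Per read: keep the best placement within each reference (fewest
# mismatches, then smallest offset, sense before antisense), then label the
# read ambiguous when acceptable placements remain in more than one
# *distinct reference sequence* (identical duplicated references do not
# make a read ambiguous). Returns list(unique = hits, ambiguous_reads).
resolve_hits <- function(hits, refs) {
  if (nrow(hits) == 0L) {
    return(list(unique = hits, ambiguous_reads = character(0)))
  }
  h <- copy(hits)
  h[, seq_ := unname(refs[ref_id])]
  setorder(h, read_id, n_mismatches, offset)
  best <- h[, .SD[1L], by = .(read_id, ref_id)]
  nseq <- best[, .(n_refs = data.table::uniqueN(seq_)), by = read_id]
  ambiguous <- nseq[n_refs > 1L, read_id]
  uniq <- best[!read_id %in% ambiguous]
  setorder(uniq, read_id, n_mismatches, offset)
  uniq <- uniq[, .SD[1L], by = read_id]
  uniq[, seq_ := NULL]
  list(unique = uniq, ambiguous_reads = ambiguous)
}
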