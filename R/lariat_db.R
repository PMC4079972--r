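#' Number of exon-skipping event classes for a transcript
#'
#' A transcript with I introns admits one skipping lariat class per ordered
#' intron pair (i, j), i < j: the 5' splice donor of intron i joins the
#' branch point of intron j, skipping the exon(s) in between. Hence
#' S = (I - 1) * I / 2.
#'
#' @param I number of introns (non-negative integer).
#' @return integer count of skipping event classes.
#' @export
#' @examples
#' enumerate_skipping_pairs(2) # 1
#' enumerate_skipping_pairs(5) # 10
enumerate_skipping_pairs <- function(I) {
  if (length(I) != 1L || is.na(I) || I < 0 || I != as.integer(I)) {
    stop("I must be a single non-negative integer", call. = FALSE)
  }
  as.integer((I - 1L) * I / 2L)
}

# Core signature constructor shared by the canonical and skipping builders.
# `input` is the sequence iterated for branch-point candidates laid 5'->3';
# candidate positions are 1-based offsets into the *donor intron* (the last
# `donor_len` bases of `input`). `threeprime_src` supplies the 3' segment.
build_signatures_core <- function(input, donor_len, threeprime_src,
                                  read_length, mode) {
  stopifnot(read_length >= 2L)
  w <- read_length - 1L
  three_seg <- substr(threeprime_src, 1L, min(w, nchar(threeprime_src)))
  donor_start <- nchar(input) - donor_len + 1L  # donor intron begins here
  # candidate BP offsets within the donor intron, 3' end toward position 1
  cand <- donor_len:1L
  bases <- substring(input, donor_start + cand - 1L, donor_start + cand - 1L)
  if (mode == "adenine_only") {
    keep <- bases == "A"
    cand <- cand[keep]
    bases <- bases[keep]
  }
  if (length(cand) == 0L) {
    return(data.table(bp_offset = integer(), bp_base = character(),
                      sequence = character(), bp_index_in_sequence = integer(),
                      degenerate = logical()))
  }
  bp_abs <- donor_start + cand - 1L            # position in `input`
  five_start <- pmax(1L, bp_abs - w)
  five_seg <- substring(input, five_start, bp_abs - 1L)
  five_seg[bp_abs == 1L] <- ""                 # BP at very first base
  data.table(
    bp_offset = cand,
    bp_base = bases,
    sequence = paste0(five_seg, bases, three_seg),
    bp_index_in_sequence = nchar(five_seg),    # 0-based index of BP base
    degenerate = nchar(five_seg) == 0L
  )
}

#' Build canonical lariat signatures for one intron
#'
#' A canonical lariat joins the intron's own 5' end to a branch point
#' within the same intron. Each candidate branch-point position p yields
#' one diagnostic signature: the last `read_length - 1` bases upstream of p
#' (the 5'-lariat segment), the branch-point base itself, then the first
#' `read_length - 1` bases of the intron (the 3'-lariat segment). Candidates
#' run from the intron 3' end toward the first intronic base; in
#' `adenine_only` mode only adenine positions are considered.
#'
#' @param intron one-row intron record (from [derive_introns()]) or a list
#'   with at least `intron_id`, `transcript_id`, `index`, `sequence`.
#' @param read_length sequencing read length (>= 2).
#' @param mode `"all_bases"` (every position is a candidate) or
#'   `"adenine_only"`.
#' @return data.table of signatures with columns `signature_id`,
#'   `transcript_id`, `upstream_intron_index`, `downstream_intron_index`
#'   (equal for canonical), `bp_offset` (1-based position in the donor
#'   intron), `bp_base`, `sequence`, `bp_index_in_sequence` (0-based index
#'   of the branch-point base within `sequence`), `kind`, `degenerate`
#'   (TRUE when the 5' segment is empty, i.e. BP at intron position 1).
#' @export
build_canonical_signatures <- function(intron, read_length,
                                       mode = c("all_bases", "adenine_only")) {
  mode <- match.arg(mode)
  if (read_length < 2L) stop("read_length must be >= 2", call. = FALSE)
  sq <- toupper(intron$sequence[[1L]])
  if (is.na(sq) || nchar(sq) == 0L) stop("empty intron sequence", call. = FALSE)
  sig <- build_signatures_core(sq, nchar(sq), sq, read_length, mode)
  if (nrow(sig) == 0L) return(empty_signature_table())
  sig[, `:=`(
    transcript_id = intron$transcript_id[[1L]],
    upstream_intron_index = as.integer(intron$index[[1L]]),
    downstream_intron_index = as.integer(intron$index[[1L]]),
    kind = "canonical"
  )]
  sig[, signature_id := sprintf("%s.I%d.bp%d", transcript_id,
                                upstream_intron_index, bp_offset)]
  setcolorder(sig, signature_columns())
  sig[]
}

#' Build exon-skipping lariat signatures for a transcript's introns
#'
#' For every ordered intron pair (i, j) with i < j the skipping lariat
#' joins intron i's 5' splice donor to a branch point inside intron j. The
#' construction concatenates intron i and intron j and iterates branch-point
#' candidates over intron j only; the 5' segment is taken from the
#' concatenated sequence upstream of the branch point (it extends into
#' intron i when the branch point lies near intron j's 5' end), while the
#' 3' segment is always the 5' end of intron i.
#'
#' @param introns intron table for one transcript, index-ordered.
#' @param read_length sequencing read length (>= 2).
#' @param mode `"all_bases"` or `"adenine_only"`.
#' @param intervening_exons if TRUE, place the true intervening exon (and
#'   intron) sequence between the paired introns instead of concatenating
#'   them directly; the default (FALSE) is the direct concatenation of the
#'   paired introns.
#' @param transcripts transcript models (only needed when
#'   `intervening_exons = TRUE`).
#' @param genome genome sequences (only needed when
#'   `intervening_exons = TRUE`).
#' @return signature data.table as in [build_canonical_signatures()], with
#'   `kind = "skipping"` and `upstream_intron_index < downstream_intron_index`.
#'   Fewer than two introns yield an empty table.
#' @export
build_skipping_signatures <- function(introns, read_length,
                                      mode = c("all_bases", "adenine_only"),
                                      intervening_exons = FALSE,
                                      transcripts = NULL, genome = NULL) {
  mode <- match.arg(mode)
  if (read_length < 2L) stop("read_length must be >= 2", call. = FALSE)
  it <- as.data.table(introns)
  if (length(unique(it$transcript_id)) > 1L) {
    stop("introns must come from a single transcript", call. = FALSE)
  }
  setorder(it, index)
  n <- nrow(it)
  if (n < 2L) return(empty_signature_table())
  out <- vector("list", enumerate_skipping_pairs(n))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      spacer <- ""
      if (intervening_exons) {
        spacer <- intervening_sequence(it, i, j, transcripts, genome)
      }
      input <- paste0(it$sequence[i], spacer, it$sequence[j])
      sig <- build_signatures_core(input, nchar(it$sequence[j]),
                                   it$sequence[i], read_length, mode)
      if (nrow(sig) == 0L) next
      k <- k + 1L
      sig[, `:=`(
        transcript_id = it$transcript_id[1L],
        upstream_intron_index = it$index[i],
        downstream_intron_index = it$index[j],
        kind = "skipping"
      )]
      sig[, signature_id := sprintf("%s.I%d-I%d.bp%d", transcript_id,
                                    upstream_intron_index,
                                    downstream_intron_index, bp_offset)]
      out[[k]] <- sig
    }
  }
  if (k == 0L) return(empty_signature_table())
  res <- rbindlist(out[seq_len(k)])
  setcolorder(res, signature_columns())
  res[]
}

# Exon (and intron) sequence lying between intron i and intron j of one
# transcript, in transcript orientation.
intervening_sequence <- function(it, i, j, transcripts, genome) {
  if (is.null(transcripts) || is.null(genome)) {
    stop("intervening_exons = TRUE requires transcripts and genome",
         call. = FALSE)
  }
  tm <- as.data.table(transcripts)[transcript_id == it$transcript_id[1L]]
  setorder(tm, exon_index)
  g <- as_genome(genome)
  # exons strictly between the two introns: exon k for i < k - ? exon e sits
  # after intron e-1 and before intron e -> exons i+1 .. j
  ex <- tm[exon_index >= i + 1L & exon_index <= j]
  segs <- vapply(seq_len(nrow(ex)), function(r) {
    extract_sequence(g, ex$chromosome[r], ex$start[r], ex$end[r], ex$strand[r])
  }, character(1))
  inner <- it[index > i & index < j]
  pieces <- character(0)
  # alternate exon / intron in transcript order: exon i+1, intron i+1, ...
  for (e in seq_len(nrow(ex))) {
    pieces <- c(pieces, segs[e])
    idx <- ex$exon_index[e]
    if (idx <= max(0L, j - 1L) && nrow(inner[index == idx]) == 1L) {
      pieces <- c(pieces, inner[index == idx, sequence])
    }
  }
  paste0(pieces, collapse = "")
}

signature_columns <- function() {
  c("signature_id", "transcript_id", "upstream_intron_index",
    "downstream_intron_index", "bp_offset", "bp_base", "sequence",
    "bp_index_in_sequence", "kind", "degenerate")
}

empty_signature_table <- function() {
  data.table(signature_id = character(), transcript_id = character(),
             upstream_intron_index = integer(),
             downstream_intron_index = integer(), bp_offset = integer(),
             bp_base = character(), sequence = character(),
             bp_index_in_sequence = integer(), kind = character(),
             degenerate = logical())
}

#' Build the full lariat signature database for an annotation
#'
#' Canonical signatures for every intron plus, optionally, skipping
#' signatures for every intron pair of every transcript.
#'
#' @param introns intron table from [derive_introns()].
#' @param read_length sequencing read length.
#' @param mode `"all_bases"` or `"adenine_only"`.
#' @param skipping include exon-skipping signatures (default TRUE).
#' @return signature data.table (see [build_canonical_signatures()]).
#' @export
build_lariat_db <- function(introns, read_length,
                            mode = c("all_bases", "adenine_only"),
                            skipping = TRUE) {
  mode <- match.arg(mode)
  it <- as.data.table(introns)
  if (nrow(it) == 0L) return(empty_signature_table())
  canon <- rbindlist(lapply(seq_len(nrow(it)), function(r) {
    build_canonical_signatures(it[r], read_length, mode)
  }))
  if (!skipping) return(canon)
  skip <- rbindlist(lapply(split(it, it$transcript_id), function(sub) {
    build_skipping_signatures(sub, read_length, mode)
  }))
  rbindlist(list(canon, skip))
}

#' Write lariat signatures as a FASTA database
#'
#' Headers are pipe-delimited:
#' `signature_id|transcript_id|up_idx|down_idx|bp_offset|bp_base|bp_index_in_sequence|kind`.
#' Records are ordered by transcript, intron pair, then descending
#' `bp_offset` (the candidate iteration order). Exact duplicate sequences
#' within one transcript are collapsed into a single record whose header
#' carries all provenance blocks separated by `;`. Optionally the database
#' is chunked into files of at most `chunk_size` records
#' (`<path>.NNN.fa`), allowing parallel alignment.
#'
#' @param signatures signature table.
#' @param path output FASTA path (used as a stem when chunking).
#' @param chunk_size maximum records per file; `Inf` (default) writes one
#'   file at `path`.
#' @return character vector of files written, invisibly.
#' @export
write_lariat_fasta <- function(signatures, path, chunk_size = Inf) {
  sig <- as.data.table(signatures)
  if (nrow(sig) == 0L) stop("no signatures to write", call. = FALSE)
  setorder(sig, transcript_id, upstream_intron_index, downstream_intron_index,
           -bp_offset)
  sig[, prov := sprintf("%s|%s|%d|%d|%d|%s|%d|%s", signature_id,
                        transcript_id, upstream_intron_index,
                        downstream_intron_index, bp_offset, bp_base,
                        bp_index_in_sequence, kind)]
  # collapse exact duplicate sequences within a transcript, keeping all
  # provenance blocks in the surviving header
  coll <- sig[, .(header = paste(prov, collapse = ";")),
              by = .(transcript_id, sequence)]
  setorder(coll, transcript_id)  # stable; within-transcript order preserved
  seqs <- setNames(coll$sequence, coll$header)
  if (!is.finite(chunk_size)) {
    write_fasta(seqs, path)
    return(invisible(path))
  }
  if (chunk_size < 1L) stop("chunk_size must be >= 1", call. = FALSE)
  n <- length(seqs)
  starts <- seq(1L, n, by = chunk_size)
  files <- character(length(starts))
  stem <- sub("\\.fa(sta)?$", "", path)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(n, starts[ci] + chunk_size - 1L)
    files[ci] <- sprintf("%s.%03d.fa", stem, ci)
    write_fasta(seqs[idx], files[ci])
  }
  invisible(files)
}

#' Read a lariat signature FASTA back into a signature table
#'
#' Inverse of [write_lariat_fasta()]; collapsed duplicate records are
#' expanded back into one row per provenance block (rows sharing the same
#' `sequence`).
#'
#' @param paths FASTA file(s).
#' @return signature data.table.
#' @export
read_lariat_fasta <- function(paths) {
  recs <- lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    data.table(header = names(ss), sequence = as.character(ss))
  })
  recs <- rbindlist(recs)
  out <- recs[, {
    blocks <- strsplit(header, ";", fixed = TRUE)[[1L]]
    f <- data.table::tstrsplit(blocks, "|", fixed = TRUE)
    .(signature_id = f[[1L]], transcript_id = f[[2L]],
      upstream_intron_index = as.integer(f[[3L]]),
      downstream_intron_index = as.integer(f[[4L]]),
      bp_offset = as.integer(f[[5L]]), bp_base = f[[6L]],
      bp_index_in_sequence = as.integer(f[[7L]]), kind = f[[8L]])
  }, by = sequence]
  out[, degenerate := bp_index_in_sequence == 0L]
  setcolorder(out, signature_columns())
  out[]
}
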