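#' Annotate lariat hits with signature provenance
#'
#' Joins lariat-stage hits to the signature table and derives the
#' quantities the downstream filters need: the target intron (the
#' branch-point donor; for skipping events the downstream intron of the
#' pair), the branch-point offset, how many read bases lie on each side of
#' the lariat junction (the boundary between the branch-point base and the
#' 3' segment; the 5' side includes the branch-point base), and whether a
#' mismatch falls exactly on the branch-point base.
#'
#' @param hits hit table from [classify_reads()] (`lariat_hits`) or
#'   [match_reads()] with `ref_id` equal to `signature_id`.
#' @param signatures signature table from [build_lariat_db()].
#' @param reads the read set that was matched (named vector or data.frame
#'   with `read_id`, `sequence`); used for read lengths.
#' @return hits with added columns `transcript_id`, `event_id` (intron id
#'   for canonical, pair id for skipping), `intron_id` (the branch-point
#'   donor intron), `kind`, `bp_offset`, `bp_base`, `overlap_5prime`,
#'   `overlap_3prime`, `mismatch_at_bp`.
#' @export
annotate_lariat_hits <- function(hits, signatures, reads) {
  rd <- if (is.data.frame(reads)) {
    data.table(read_id = as.character(reads$read_id),
               read_len = nchar(as.character(reads$sequence)))
  } else {
    data.table(read_id = names(reads), read_len = nchar(as.character(reads)))
  }
  sig <- as.data.table(signatures)
  h <- merge(as.data.table(hits), rd, by = "read_id")
  h <- merge(h, sig[, .(signature_id, transcript_id, upstream_intron_index,
                        downstream_intron_index, bp_offset, bp_base,
                        bp_index_in_sequence, kind)],
             by.x = "ref_id", by.y = "signature_id")
  h[, `:=`(
    overlap_5prime = pmax(0L, pmin(bp_index_in_sequence - offset + 1L,
                                   read_len)),
    intron_id = paste0(transcript_id, ".I", downstream_intron_index),
    event_id = ifelse(kind == "canonical",
                      paste0(transcript_id, ".I", downstream_intron_index),
                      sprintf("%s.I%d-I%d", transcript_id,
                              upstream_intron_index, downstream_intron_index))
  )]
  h[, overlap_3prime := read_len - overlap_5prime]
  h[, mismatch_at_bp := vapply(seq_len(.N), function(i) {
    length(mismatch_positions[[i]]) > 0L &&
      any(mismatch_positions[[i]] + offset[i] == bp_index_in_sequence[i])
  }, logical(1))]
  setnames(h, "ref_id", "signature_id")
  h[]
}

#' Filter lariat hits with the stringent (human-mode) criteria
#'
#' Removes antisense hits, hits whose mismatch (if any) is not located
#' exactly at the branch-point base, and hits that do not overlap the
#' lariat junction by at least `min_junction_overlap` bases on both sides.
#' Zero-mismatch hits satisfy the mismatch criterion. Multi-placed reads
#' are assumed already removed upstream (`unique_only` in
#' [classify_reads()]); `unique_only` here is accepted for interface
#' completeness and asserts that assumption.
#'
#' @param hits annotated hit table from [annotate_lariat_hits()].
#' @param unique_only retained for interface symmetry (multi-placed reads
#'   are dropped during classification).
#' @param sense_only remove antisense hits (default TRUE).
#' @param require_mismatch_at_bp require any mismatch to sit on the
#'   branch-point base (default TRUE).
#' @param min_junction_overlap minimum bases on each side of the lariat
#'   junction (default 10).
#' @return filtered hit table.
#' @export
filter_hits_stringent <- function(hits, unique_only = TRUE,
                                  sense_only = TRUE,
                                  require_mismatch_at_bp = TRUE,
                                  min_junction_overlap = 10L) {
  h <- as.data.table(hits)
  if (sense_only) h <- h[orientation == "sense"]
  if (require_mismatch_at_bp) h <- h[n_mismatches == 0L | mismatch_at_bp]
  h <- h[overlap_5prime >= min_junction_overlap &
           overlap_3prime >= min_junction_overlap]
  h[]
}

#' Aggregate lariat hits into branch-point observations
#'
#' One observation per (event, branch-point offset): the number of reads
#' supporting that branch-point position.
#'
#' @param hits annotated (and filtered) hit table.
#' @return data.table `event_id`, `intron_id`, `kind`, `bp_offset`,
#'   `bp_base`, `read_count`.
#' @export
hits_to_observations <- function(hits) {
  h <- as.data.table(hits)
  obs <- h[, .(read_count = .N),
           by = .(event_id, intron_id, kind, bp_offset, bp_base)]
  setorder(obs, event_id, bp_offset)
  obs[]
}

# Cluster the observations of a single event. Returns a one-row list or
# NULL when no cluster reaches min_reads.
cluster_one_event <- function(offsets, bases, counts, min_reads, tie_delta,
                              cluster_gap) {
  o <- order(offsets)
  offsets <- offsets[o]; bases <- bases[o]; counts <- counts[o]
  cl <- cumsum(c(1L, diff(offsets) > cluster_gap))
  reps <- lapply(split(seq_along(offsets), cl), function(ix) {
    co <- counts[ix]; of <- offsets[ix]; ba <- bases[ix]
    ord <- order(-co, -of)               # highest reads, 3'-most breaks ties
    top <- ord[1L]
    if (length(ix) >= 2L && abs(co[ord[1L]] - co[ord[2L]]) < tie_delta) {
      # neighbouring branch points with similar support: prefer the one
      # closer to the intron 3' end among the top two
      two <- ord[1:2]
      top <- two[which.max(of[two])]
    }
    list(offset = of[top], base = ba[top], support = sum(co),
         members = of, member_counts = co)
  })
  support <- vapply(reps, `[[`, numeric(1), "support")
  keep <- support >= min_reads
  if (!any(keep)) return(NULL)
  reps <- reps[keep]; support <- support[keep]
  rep_off <- vapply(reps, `[[`, numeric(1), "offset")
  prim <- order(-support, -rep_off)[1L]   # most reads; 3'-most on ties
  alt <- setdiff(seq_along(reps), prim)
  list(
    primary_offset = as.integer(reps[[prim]]$offset),
    primary_base = reps[[prim]]$base,
    primary_reads = as.integer(support[prim]),
    cluster_members = list(as.integer(reps[[prim]]$members)),
    alternates = list(data.table(
      offset = as.integer(rep_off[alt]),
      reads = as.integer(support[alt])
    ))
  )
}

#' Cluster branch-point observations into calls
#'
#' Reverse transcription scatters reads across offsets adjacent to the
#' true branch point (base mutation and base skipping), so observations at
#' most `cluster_gap` bases apart are chained into one cluster. Within a
#' cluster the representative is the member with the most reads, except
#' that when the two best-supported members differ by fewer than
#' `tie_delta` reads the one closer to the intron 3' end is chosen.
#' Clusters are discarded when their total support falls below
#' `min_reads`; the best-supported surviving cluster yields the primary
#' branch point, the rest are reported as alternates (necessarily more
#' than `cluster_gap` bases from the primary).
#'
#' @param observations observation table from [hits_to_observations()]
#'   (any subset of events).
#' @param min_reads minimum total reads per cluster (default 3).
#' @param tie_delta read-count difference below which the 3'-most of the
#'   two best members is preferred (default 10).
#' @param cluster_gap maximum offset gap chained into one cluster
#'   (default 1).
#' @param per_offset_threshold apply `min_reads` to single offsets rather
#'   than to cluster totals (default FALSE).
#' @return data.table of calls: `event_id`, `intron_id`, `kind`,
#'   `primary_offset`, `primary_base`, `primary_reads` (cluster support),
#'   `cluster_members` and `alternates` (list columns), `n_alternates`.
#' @export
cluster_branch_points <- function(observations, min_reads = 3L,
                                  tie_delta = 10L, cluster_gap = 1L,
                                  per_offset_threshold = FALSE) {
  obs <- as.data.table(observations)
  empty <- data.table(event_id = character(), intron_id = character(),
                      kind = character(), primary_offset = integer(),
                      primary_base = character(), primary_reads = integer(),
                      cluster_members = list(), alternates = list(),
                      n_alternates = integer())
  if (nrow(obs) == 0L) return(empty)
  if (per_offset_threshold) obs <- obs[read_count >= min_reads]
  if (nrow(obs) == 0L) return(empty)
  calls <- obs[, {
    r <- cluster_one_event(bp_offset, bp_base, read_count, min_reads,
                           tie_delta, cluster_gap)
    if (is.null(r)) NULL else r
  }, by = .(event_id, intron_id, kind)]
  if (nrow(calls) == 0L) return(empty)
  calls[, n_alternates := vapply(alternates, nrow, integer(1))]
  calls[]
}

#' Label skipping calls sharing the canonical branch point
#'
#' A skipping event usually uses the primary branch point of its
#' downstream intron; this adds `bp_shared_with_canonical` to skipping
#' calls by comparison with the canonical call for the same intron.
#'
#' @param calls call table from [cluster_branch_points()].
#' @return calls with logical `bp_shared_with_canonical` (NA for canonical
#'   calls and for skipping events whose intron has no canonical call).
#' @export
label_shared_branch_points <- function(calls) {
  cl <- as.data.table(calls)
  canon <- cl[kind == "canonical", .(intron_id, canon_offset = primary_offset)]
  cl <- merge(cl, canon, by = "intron_id", all.x = TRUE)
  cl[, bp_shared_with_canonical :=
       ifelse(kind == "skipping" & !is.na(canon_offset),
              primary_offset == canon_offset, NA)]
  cl[, canon_offset := NULL]
  cl[]
}

#' Branch-point positional statistics
#'
#' Distances from the primary branch point to the intron 3' and 5' ends
#' and intron-length-binned detection counts (the short-intron detection
#' bias shows up as depleted counts in bins below the read length).
#'
#' @param calls call table (canonical calls are used).
#' @param introns intron table from [derive_introns()].
#' @param length_breaks intron-length bin edges.
#' @return list with `per_call` (distances per call), `median_distance_3prime`,
#'   `median_distance_5prime`, and `by_length_bin` (introns detected /
#'   total per bin).
#' @export
bp_distance_stats <- function(calls, introns,
                              length_breaks = c(0, 50, 75, 100, 150, 250,
                                                500, Inf)) {
  cl <- as.data.table(calls)[kind == "canonical"]
  it <- as.data.table(introns)
  if (nrow(cl) > 0L && !all(cl$intron_id %in% it$intron_id)) {
    stop("call references unknown intron id", call. = FALSE)
  }
  per_call <- merge(cl[, .(intron_id, primary_offset, primary_reads)],
                    it[, .(intron_id, L = length)], by = "intron_id")
  per_call[, `:=`(distance_to_3prime = L - primary_offset,
                  distance_to_5prime = primary_offset - 1L)]
  it[, bin := cut(length, breaks = length_breaks, include.lowest = TRUE)]
  detected <- it$intron_id %in% cl$intron_id
  by_bin <- it[, .(n_introns = .N,
                   n_detected = sum(intron_id %in% cl$intron_id)), by = bin]
  setorder(by_bin, bin)
  by_bin[, detection_rate := n_detected / n_introns]
  list(per_call = per_call[],
       median_distance_3prime = if (nrow(per_call)) {
         median(per_call$distance_to_3prime)
       } else NA_real_,
       median_distance_5prime = if (nrow(per_call)) {
         median(per_call$distance_to_5prime)
       } else NA_real_,
       n_detected = sum(detected),
       by_length_bin = by_bin[])
}

#' Branch-site consensus matrix around the primary branch point
#'
#' Builds a position frequency matrix from the intronic sequence windows
#' `-flank..+flank` around each primary branch point (transcript
#' orientation) and the per-column information content against a
#' non-uniform background with the given GC content (default 30%:
#' q(A) = q(T) = 0.35, q(C) = q(G) = 0.15). Windows clipped at intron
#' bounds are excluded.
#'
#' @param calls call table (canonical calls are used).
#' @param introns intron table.
#' @param flank bases on each side of the branch point (default 5).
#' @param background_gc background GC fraction for the information content
#'   (default 0.30).
#' @return list with `prob` (4 x (2*flank+1) probability matrix, rows
#'   A,C,G,T, columns named by position relative to the branch point),
#'   `counts`, `bits` (per-column information content, in bits), and `n`
#'   (number of windows used).
#' @export
consensus_matrix <- function(calls, introns, flank = 5L,
                             background_gc = 0.30) {
  stopifnot(flank >= 0L)
  cl <- as.data.table(calls)[kind == "canonical"]
  it <- as.data.table(introns)
  m <- merge(cl[, .(intron_id, primary_offset)],
             it[, .(intron_id, sequence, L = length)], by = "intron_id")
  m <- m[primary_offset - flank >= 1L & primary_offset + flank <= L]
  if (nrow(m) == 0L) stop("no usable branch-point windows", call. = FALSE)
  win <- substr(m$sequence, m$primary_offset - flank, m$primary_offset + flank)
  chars <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                  nrow = 2L * flank + 1L)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(nrow(chars)), function(col) {
    tab <- table(factor(chars[col, ], levels = bases))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- bases
  colnames(counts) <- as.character(seq(-flank, flank))
  totals <- colSums(counts)
  prob <- sweep(counts, 2L, totals, "/")
  q <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
         G = background_gc / 2, T = (1 - background_gc) / 2)
  bits <- apply(prob, 2L, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[bases][nz]))
  })
  list(prob = prob, counts = counts, bits = bits, n = nrow(m))
}

#' Write branch-point calls as TSV and BED
#'
#' @param calls call table.
#' @param introns intron table (for genomic coordinates).
#' @param tsv_path,bed_path output files (either may be NULL to skip).
#' @return the flattened table, invisibly.
#' @export
write_branch_point_tables <- function(calls, introns, tsv_path = NULL,
                                      bed_path = NULL) {
  cl <- as.data.table(calls)
  it <- as.data.table(introns)[, .(intron_id, chromosome, start, end, strand,
                                   L = length)]
  flat <- merge(cl, it, by = "intron_id", all.x = TRUE)
  # genomic coordinate of the branch-point base
  flat[, genomic_pos := ifelse(strand == "+", start + primary_offset - 1L,
                               end - primary_offset + 1L)]
  flat[, alternates_txt := vapply(alternates, function(a) {
    if (is.null(a) || nrow(a) == 0L) "" else {
      paste(sprintf("%d:%d", a$offset, a$reads), collapse = ",")
    }
  }, character(1))]
  out <- flat[, .(event_id, intron_id, kind, chromosome, strand, genomic_pos,
                  primary_offset, primary_base, primary_reads,
                  distance_to_3prime = L - primary_offset,
                  alternates = alternates_txt)]
  if (!is.null(tsv_path)) fwrite(out, tsv_path, sep = "\t")
  if (!is.null(bed_path)) {
    bed <- flat[!is.na(genomic_pos),
                .(chromosome, genomic_pos - 1L, genomic_pos, event_id,
                  primary_reads, strand)]
    fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  invisible(out)
}
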