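#' Build the exon-exon junction database
#'
#' For each consecutive exon pair of each transcript the junction sequence
#' concatenates the last `window` bases of the upstream exon with the first
#' `window` bases of the downstream exon, where
#' `window = read_length - min_overlap` (whole exons are used when shorter
#' than the window). A read of `read_length` bases fully contained in such
#' a record therefore overlaps the junction boundary by at least
#' `min_overlap` bases on each side; with the default 49-base reads and
#' `min_overlap = 6` the windows are 43 bases.
#'
#' @param transcripts a `transcript_models` table.
#' @param genome named chromosome sequence vector (or `DNAStringSet`).
#' @param read_length sequencing read length.
#' @param min_overlap minimum bases a diagnostic read must overlap the
#'   junction on each side (default 6); must be `< read_length`.
#' @param include_skipping also build junctions bridging non-adjacent exon
#'   pairs (evidence for exon skipping); off by default.
#' @return data.table with `junction_id`, `transcript_id`, `up_exon`,
#'   `down_exon` (exon indices), `sequence` (transcript orientation),
#'   `boundary_index` (0-based index of the first downstream-exon base),
#'   `kind` in {adjacent, skipping}.
#' @export
build_junction_db <- function(transcripts, genome, read_length,
                              min_overlap = 6L, include_skipping = FALSE) {
  if (min_overlap < 1L || min_overlap >= read_length) {
    stop("need read_length > min_overlap >= 1", call. = FALSE)
  }
  window <- read_length - min_overlap
  g <- as_genome(genome)
  tm <- as.data.table(transcripts)
  setorder(tm, transcript_id, exon_index)
  tm[, seq_ := toupper(substr(g[chromosome], start, end))]
  tm[strand == "-", seq_ := revcomp(seq_)]
  out <- tm[, {
    n <- .N
    if (n < 2L) NULL else {
      pairs <- if (include_skipping) {
        idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
        data.table(up = idx[, "row"], down = idx[, "col"])
      } else {
        data.table(up = seq_len(n - 1L), down = seq_len(n - 1L) + 1L)
      }
      up_seq <- seq_[pairs$up]
      down_seq <- seq_[pairs$down]
      upw <- substr(up_seq, pmax(1L, nchar(up_seq) - window + 1L),
                    nchar(up_seq))
      dnw <- substr(down_seq, 1L, pmin(window, nchar(down_seq)))
      .(up_exon = pairs$up, down_exon = pairs$down,
        sequence = paste0(upw, dnw), boundary_index = nchar(upw),
        kind = ifelse(pairs$down - pairs$up == 1L, "adjacent", "skipping"))
    }
  }, by = transcript_id]
  if (nrow(out) == 0L) {
    return(data.table(junction_id = character(), transcript_id = character(),
                      up_exon = integer(), down_exon = integer(),
                      sequence = character(), boundary_index = integer(),
                      kind = character()))
  }
  out[, junction_id := sprintf("%s.J%d-%d", transcript_id, up_exon, down_exon)]
  setcolorder(out, c("junction_id", "transcript_id", "up_exon", "down_exon",
                     "sequence", "boundary_index", "kind"))
  out[]
}

#' Write the junction database as FASTA
#'
#' Headers are pipe-delimited:
#' `junction_id|transcript_id|up_exon|down_exon|boundary_index|kind`.
#'
#' @param junctions junction table from [build_junction_db()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_junction_fasta <- function(junctions, path) {
  hdr <- with(junctions, sprintf("%s|%s|%d|%d|%d|%s", junction_id,
                                 transcript_id, up_exon, down_exon,
                                 boundary_index, kind))
  write_fasta(setNames(junctions$sequence, hdr), path)
}
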