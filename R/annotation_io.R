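#' Build a validated transcript-model table
#'
#' A transcript model is the ordered list of exons of one transcript, held
#' in transcript (5'->3') orientation: for a "+" transcript genomic starts
#' ascend with `exon_index`; for a "-" transcript they descend. All
#' coordinates are 1-based inclusive.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `chromosome`, `strand` ("+"/"-"), `start`, `end` (1-based inclusive).
#'   An optional `exon_index` column gives the 5'->3' order; if absent it is
#'   derived from genomic coordinates and strand.
#' @return a `data.table` keyed by `transcript_id` with one row per exon and
#'   a canonical `exon_index`, class `transcript_models`.
#' @details Transcripts with overlapping exons are rejected with a warning
#'   (the record is dropped, not fatal); consecutive exons must be separated
#'   by at least one base, which is the putative intron.
#' @export
transcript_models <- function(exons) {
  need <- c("transcript_id", "gene_id", "chromosome", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss) > 0L) {
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tm <- as.data.table(exons)[, c(need, intersect("exon_index", names(exons))), with = FALSE]
  if (!all(tm$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(tm$end < tm$start)) stop("exon end < start", call. = FALSE)
  if (!"exon_index" %in% names(tm)) {
    tm[, exon_index := {
      o <- order(start)
      r <- integer(.N); r[o] <- seq_len(.N)
      if (strand[1L] == "-") r <- .N + 1L - r
      r
    }, by = transcript_id]
  }
  setorder(tm, transcript_id, exon_index)
  # reject transcripts whose exons overlap
  bad <- tm[, {
    o <- order(start)
    any(start[o][-1L] <= end[o][-length(o)])
  }, by = transcript_id][V1 == TRUE, transcript_id]
  if (length(bad) > 0L) {
    warning("dropping ", length(bad), " transcript(s) with overlapping exons: ",
            paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    tm <- tm[!transcript_id %in% bad]
  }
  setkey(tm, transcript_id)
  setattr(tm, "class", c("transcript_models", class(tm)))
  tm[]
}

#' Read transcript models from a GFF3 or GTF annotation
#'
#' Exon features are grouped into transcripts via the `transcript_id`
#' attribute (GTF) or the `Parent` attribute (GFF3) and ordered 5'->3'
#' along each transcript. An exon lacking a transcript grouping is a parse
#' error, never guessed.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.gtf`; format sniffed by
#'   [rtracklayer::import()] from the extension).
#' @param feature feature type(s) to treat as exons (default `"exon"`).
#' @return a `transcript_models` table (see [transcript_models()]).
#' @export
read_annotation <- function(path, feature = "exon") {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) %in% tolower(feature)]
  if (length(gr) == 0L) stop("no exon features found in ", path, call. = FALSE)
  md <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(md)) {
    as.character(md$transcript_id)
  } else if ("Parent" %in% names(md)) {
    p <- md$Parent
    if (any(lengths(p) != 1L)) {
      stop("exon with zero or multiple Parent attributes", call. = FALSE)
    }
    as.character(unlist(p))
  } else {
    stop("annotation exons carry neither transcript_id nor Parent attributes",
         call. = FALSE)
  }
  if (anyNA(tid) || any(tid == "")) {
    stop("exon without transcript grouping (empty transcript_id/Parent)",
         call. = FALSE)
  }
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tid
  transcript_models(data.frame(
    transcript_id = tid,
    gene_id       = gid,
    chromosome    = as.character(GenomeInfoDb::seqnames(gr)),
    strand        = as.character(BiocGenerics::strand(gr)),
    start         = BiocGenerics::start(gr),
    end           = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Extract a (possibly reverse-complemented) genomic subsequence
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` returns the slice as is; `"-"` returns its reverse
#'   complement.
#' @return uppercase nucleotide string of length `end - start + 1`.
#' @export
#' @examples
#' extract_sequence(c(chr = "ACGTACGT"), "chr", 2, 5, "+") # "CGTA"
#' extract_sequence(c(chr = "ACGTACGT"), "chr", 2, 5, "-") # "TACG"
extract_sequence <- function(genome, chromosome, start, end, strand = "+") {
  g <- as_genome(genome)
  if (!chromosome %in% names(g)) {
    stop("unknown chromosome: ", chromosome, call. = FALSE)
  }
  if (start < 1L || end > nchar(g[[chromosome]]) || end < start) {
    stop(sprintf("interval (%d,%d) out of bounds for chromosome %s (length %d)",
                 start, end, chromosome, nchar(g[[chromosome]])), call. = FALSE)
  }
  s <- substr(g[[chromosome]], start, end)
  check_alphabet(s, sprintf("%s:%d-%d", chromosome, start, end))
  if (strand == "-") revcomp(s) else s
}

#' Derive putative introns from transcript models
#'
#' The gap between two consecutive exons of a transcript is taken as a
#' putative intron. Introns are indexed 1..n along the transcript in
#' 5'->3' order and their sequences are transcript-oriented (reverse
#' complemented for "-" transcripts). Single-exon transcripts contribute
#' nothing.
#'
#' @param transcripts a `transcript_models` table.
#' @param genome named chromosome sequence vector (or `DNAStringSet`).
#' @return data.table with one row per intron: `intron_id`,
#'   `transcript_id`, `gene_id`, `index`, `chromosome`, `start`, `end`
#'   (genomic, 1-based inclusive), `strand`, `sequence`
#'   (transcript-oriented), `length`.
#' @export
derive_introns <- function(transcripts, genome) {
  g <- as_genome(genome)
  tm <- as.data.table(transcripts)
  unknown <- setdiff(unique(tm$chromosome), names(g))
  if (length(unknown) > 0L) {
    stop("annotation references unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  oob <- tm[end > nchar(g[chromosome]) | start < 1L]
  if (nrow(oob) > 0L) {
    stop("exon outside chromosome bounds for transcript ",
         oob$transcript_id[1L], call. = FALSE)
  }
  setorder(tm, transcript_id, exon_index)
  introns <- tm[, if (.N >= 2L) {
    gs <- pmin(head(start, -1L), tail(start, -1L))  # genomic layout
    ge <- pmax(head(end, -1L), tail(end, -1L))
    if (strand[1L] == "+") {
      .(index = seq_len(.N - 1L),
        chromosome = chromosome[1L], strand = strand[1L],
        start = head(end, -1L) + 1L, end = tail(start, -1L) - 1L)
    } else {
      .(index = seq_len(.N - 1L),
        chromosome = chromosome[1L], strand = strand[1L],
        start = tail(end, -1L) + 1L, end = head(start, -1L) - 1L)
    }
  }, by = .(transcript_id, gene_id)]
  if (nrow(introns) == 0L) {
    return(data.table(intron_id = character(), transcript_id = character(),
                      gene_id = character(), index = integer(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), length = integer()))
  }
  if (any(introns$end < introns$start)) {
    stop("consecutive exons are adjacent or out of order; no intron gap",
         call. = FALSE)
  }
  introns[, sequence := toupper(substr(g[chromosome], start, end))]
  introns[strand == "-", sequence := revcomp(sequence)]
  introns[, `:=`(length = end - start + 1L,
                 intron_id = paste0(transcript_id, ".I", index))]
  setcolorder(introns, c("intron_id", "transcript_id", "gene_id", "index",
                         "chromosome", "start", "end", "strand", "sequence",
                         "length"))
  setkey(introns, intron_id)
  introns[]
}

#' Export introns as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open.
#'
#' @param introns intron table from [derive_introns()].
#' @param path output file.
#' @param score column to place in the BED score field (default 0).
#' @return the path, invisibly.
#' @export
write_intron_bed <- function(introns, path, score = 0L) {
  bed <- data.table(
    chrom = introns$chromosome,
    chromStart = introns$start - 1L,
    chromEnd = introns$end,
    name = introns$intron_id,
    score = score,
    strand = introns$strand
  )
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
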