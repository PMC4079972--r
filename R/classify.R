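#' Classify reads through the staged lariat-detection workflow
#'
#' Reads are aligned stage by stage: (1) genome, (2) transcriptome /
#' exon-exon junction windows, (3) the lariat signature database. A read is
#' assigned to the first stage where it has at least one acceptable
#' placement; only reads unmapped after stages 1 and 2 are matched to the
#' lariat database. The genome stages tolerate `genome_mm` mismatches, the
#' lariat stage `lariat_mm` (reverse transcriptase frequently mutates the
#' branch-point base, so one mismatch is allowed there by default).
#'
#' Under `unique_only`, a read whose acceptable placements touch more than
#' one distinct reference *sequence* within its stage is kept in the
#' partition but flagged ambiguous and excluded from the per-stage hit
#' table (identical duplicated reference sequences do not count as
#' ambiguity). Within one reference, the best placement (fewest mismatches,
#' then smallest offset) is kept.
#'
#' @param reads named character vector of read sequences or data.frame
#'   with `read_id`, `sequence`.
#' @param genome_refs named character vector (chromosomes); `NULL` skips
#'   the stage.
#' @param junction_refs named character vector (transcript and/or junction
#'   window sequences, e.g. from [build_junction_db()]); `NULL` skips.
#' @param lariat_refs named character vector (lariat signature sequences,
#'   e.g. `setNames(db$sequence, db$signature_id)`); `NULL` skips.
#' @param genome_mm mismatches allowed at the genome/junction stages
#'   (default 3).
#' @param lariat_mm mismatches allowed at the lariat stage (default 1).
#' @param unique_only drop multi-placed reads from stage hit tables
#'   (default TRUE).
#' @param orientation_policy passed to [match_reads()]; use `"both"` for
#'   unstranded libraries. The genome stage always searches both strands
#'   (a sense transcript read from a "-" gene is antisense to the
#'   reference).
#' @return list with elements `partition` (data.table `read_id`, `stage`
#'   in {genome_mapped, junction_mapped, lariat_mapped, unmapped},
#'   `ambiguous`), per-stage hit tables `genome_hits`, `junction_hits`,
#'   `lariat_hits` (unique placements only), and `report` (per-stage
#'   assigned/unique/ambiguous counts).
#' @export
classify_reads <- function(reads, genome_refs = NULL, junction_refs = NULL,
                           lariat_refs = NULL, genome_mm = 3L, lariat_mm = 1L,
                           unique_only = TRUE,
                           orientation_policy = c("sense_only", "both")) {
  orientation_policy <- match.arg(orientation_policy)
  rd <- if (is.data.frame(reads)) {
    data.table(read_id = as.character(reads$read_id),
               sequence = toupper(as.character(reads$sequence)))
  } else {
    data.table(read_id = names(reads), sequence = toupper(as.character(reads)))
  }
  stages <- list(
    genome_mapped   = list(refs = genome_refs,   mm = genome_mm, ori = "both"),
    junction_mapped = list(refs = junction_refs, mm = genome_mm,
                           ori = orientation_policy),
    lariat_mapped   = list(refs = lariat_refs,   mm = lariat_mm,
                           ori = orientation_policy)
  )
  remaining <- rd
  partition <- data.table(read_id = rd$read_id, stage = "unmapped",
                          ambiguous = FALSE)
  setkey(partition, read_id)
  hit_tables <- list()
  report <- list()
  for (st in names(stages)) {
    spec_ <- stages[[st]]
    if (is.null(spec_$refs) || nrow(remaining) == 0L) {
      hit_tables[[st]] <- empty_hit_table()
      report[[st]] <- data.table(stage = st, n_assigned = 0L, n_unique = 0L,
                                 n_ambiguous = 0L)
      next
    }
    refs <- toupper(spec_$refs)
    hits <- match_reads(remaining, refs, spec_$mm, spec_$ori)
    assigned <- unique(hits$read_id)
    res <- resolve_hits(hits, refs)
    if (unique_only) {
      hit_tables[[st]] <- res$unique
      ambiguous <- res$ambiguous_reads
    } else {
      hit_tables[[st]] <- hits
      ambiguous <- character(0)
    }
    partition[assigned, stage := st]
    partition[ambiguous, ambiguous := TRUE]
    report[[st]] <- data.table(stage = st, n_assigned = length(assigned),
                               n_unique = length(assigned) - length(ambiguous),
                               n_ambiguous = length(ambiguous))
    remaining <- remaining[!read_id %in% assigned]
  }
  report <- rbindlist(report)
  report <- rbind(report,
                  data.table(stage = "unmapped", n_assigned = nrow(remaining),
                             n_unique = nrow(remaining), n_ambiguous = 0L))
  list(partition = partition[],
       genome_hits = hit_tables$genome_mapped,
       junction_hits = hit_tables$junction_mapped,
       lariat_hits = hit_tables$lariat_mapped,
       report = report)
}

#' Ingest external SAM alignments into the partition structure
#'
#' Supports reproducing the workflow with an external aligner: mapped /
#' unmapped flags and `NM` tags are converted into the same structures as
#' [classify_reads()] produces for one stage.
#'
#' @param sam_path path to a SAM (or BAM) file.
#' @param stage label for the stage these alignments represent.
#' @param unique_only drop reads with more than one mapped record.
#' @return list with `partition` (`read_id`, `stage`, `ambiguous`) and
#'   `hits` (`read_id`, `ref_id`, `offset` 0-based, `orientation`,
#'   `n_mismatches` -- `NA` with `nm_missing = TRUE` when the NM tag is
#'   absent).
#' @export
ingest_external_alignments <- function(sam_path, stage = "genome_mapped",
                                       unique_only = TRUE) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "flag"), tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  dt <- data.table(
    read_id = rec$qname,
    ref_id = as.character(rec$rname),
    pos = rec$pos,
    orientation = ifelse(as.character(rec$strand) == "-", "antisense", "sense"),
    mapped = !bitwAnd(rec$flag, 4L),
    n_mismatches = if (is.null(rec$tag$NM)) rep(NA_integer_, length(rec$qname))
                   else as.integer(rec$tag$NM)
  )
  dt[, nm_missing := mapped & is.na(n_mismatches)]
  if (any(dt$nm_missing)) {
    warning(sum(dt$nm_missing), " mapped record(s) lack the NM tag; ",
            "mismatch count unknown", call. = FALSE)
  }
  mapped_dt <- dt[mapped == TRUE]
  multi <- mapped_dt[, .N, by = read_id][N > 1L, read_id]
  hits <- mapped_dt
  ambiguous <- character(0)
  if (unique_only) {
    hits <- mapped_dt[!read_id %in% multi]
    ambiguous <- multi
  }
  hits <- hits[, .(read_id, ref_id, offset = pos - 1L, orientation,
                   n_mismatches, nm_missing)]
  partition <- unique(dt[, .(read_id)])
  partition[, stage := ifelse(read_id %in% mapped_dt$read_id, stage, "unmapped")]
  partition[, ambiguous := read_id %in% ambiguous]
  list(partition = partition[], hits = hits[])
}
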