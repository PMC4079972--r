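#' Pipeline run configuration
#'
#' Presets bundle the defaults used for the two reference settings:
#' `"pombe"` (strand-specific yeast-style libraries: all-bases lariat
#' database, 3 genome mismatches, 1 lariat mismatch, minimum lariat
#' junction overlap 1) and `"human"` (adenine-only database, stringent
#' filtering: sense-only, mismatch required at the branch point, minimum
#' junction overlap 10). Presets only set defaults; every value can be
#' overridden.
#'
#' @param preset `"pombe"` or `"human"`.
#' @param read_length read length; `NULL` means taken from the reads.
#' @param genome_mm,lariat_mm mismatch allowances per stage.
#' @param mode lariat database mode.
#' @param min_reads,tie_delta,cluster_gap branch-point clustering
#'   parameters.
#' @param min_junction_overlap minimum bases across the lariat junction.
#' @param min_jr_overlap minimum overlap for diagnostic JR/EI counting.
#' @param require_mismatch_at_bp restrict mismatches to the branch point.
#' @param orientation_policy `"sense_only"` or `"both"`.
#' @param unique_only drop multi-placed reads.
#' @param skipping build skipping signatures.
#' @param seed RNG seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = c("pombe", "human"), read_length = NULL,
                       genome_mm = 3L, lariat_mm = 1L, mode = NULL,
                       min_reads = 3L, tie_delta = 10L, cluster_gap = 1L,
                       min_junction_overlap = NULL, min_jr_overlap = 6L,
                       require_mismatch_at_bp = NULL,
                       orientation_policy = NULL, unique_only = TRUE,
                       skipping = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    pombe = list(mode = "all_bases", min_junction_overlap = 1L,
                 require_mismatch_at_bp = FALSE,
                 orientation_policy = "sense_only"),
    human = list(mode = "adenine_only", min_junction_overlap = 10L,
                 require_mismatch_at_bp = TRUE,
                 orientation_policy = "both"))
  cfg <- list(
    preset = preset, read_length = read_length, genome_mm = genome_mm,
    lariat_mm = lariat_mm,
    mode = if (is.null(mode)) defaults$mode else mode,
    min_reads = min_reads, tie_delta = tie_delta, cluster_gap = cluster_gap,
    min_junction_overlap = if (is.null(min_junction_overlap)) {
      defaults$min_junction_overlap
    } else min_junction_overlap,
    min_jr_overlap = min_jr_overlap,
    require_mismatch_at_bp = if (is.null(require_mismatch_at_bp)) {
      defaults$require_mismatch_at_bp
    } else require_mismatch_at_bp,
    orientation_policy = if (is.null(orientation_policy)) {
      defaults$orientation_policy
    } else orientation_policy,
    unique_only = unique_only, skipping = skipping, seed = seed
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the full lariat-detection workflow
#'
#' Builds the lariat and junction databases, classifies the reads through
#' the staged workflow, calls branch points, and computes per-intron
#' splicing diagnostics. Works from in-memory objects or file paths.
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @param annotation a `transcript_models` table or GFF3/GTF path.
#' @param reads data.frame (`read_id`, `sequence`), named vector, or
#'   FASTQ path.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, a deterministic
#'   layout is written: `db/` (signature and junction FASTA), `calls/`
#'   (branch-point TSV + BED), `stats/` (splice counts), `report.tsv`
#'   (per-stage read counts) and `manifest.txt` (parameters and input
#'   checksums).
#' @return list with `signatures`, `junctions`, `classification`,
#'   `hits` (annotated, filtered lariat hits), `observations`, `calls`,
#'   `bp_stats`, `splice_counts`, `report`.
#' @export
run_pipeline <- function(genome, annotation, reads, config = run_config(),
                         out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  genome <- as_genome(genome)
  if (is.character(annotation) && length(annotation) == 1L) {
    if (!file.exists(annotation)) {
      stop("annotation file not found: ", annotation, call. = FALSE)
    }
    annotation <- read_annotation(annotation)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- data.table(read_id = sub("\\s.*$", "", names(fq)),
                        sequence = as.character(fq))
  }
  rd <- if (is.data.frame(reads)) {
    data.table(read_id = as.character(reads$read_id),
               sequence = toupper(as.character(reads$sequence)))
  } else {
    data.table(read_id = names(reads), sequence = toupper(as.character(reads)))
  }
  cfg <- config
  rl <- if (is.null(cfg$read_length)) max(nchar(rd$sequence)) else cfg$read_length

  introns <- derive_introns(annotation, genome)
  signatures <- build_lariat_db(introns, rl, mode = cfg$mode,
                                skipping = cfg$skipping)
  junctions <- build_junction_db(annotation, genome, rl,
                                 min_overlap = cfg$min_jr_overlap)
  lariat_refs <- if (nrow(signatures) > 0L) {
    # collapse exact duplicate sequences so they do not render reads
    # ambiguous; provenance of the first record is kept
    sigs <- signatures[!duplicated(sequence)]
    setNames(sigs$sequence, sigs$signature_id)
  } else NULL
  junction_refs <- if (nrow(junctions) > 0L) {
    setNames(junctions$sequence, junctions$junction_id)
  } else NULL

  cls <- classify_reads(rd, genome_refs = genome,
                        junction_refs = junction_refs,
                        lariat_refs = lariat_refs,
                        genome_mm = cfg$genome_mm, lariat_mm = cfg$lariat_mm,
                        unique_only = cfg$unique_only,
                        orientation_policy = cfg$orientation_policy)

  hits <- annotate_lariat_hits(cls$lariat_hits, signatures, rd)
  hits <- filter_hits_stringent(
    hits, sense_only = cfg$orientation_policy == "sense_only" ||
      cfg$preset == "human",
    require_mismatch_at_bp = cfg$require_mismatch_at_bp,
    min_junction_overlap = cfg$min_junction_overlap)
  obs <- hits_to_observations(hits)
  calls <- cluster_branch_points(obs, min_reads = cfg$min_reads,
                                 tie_delta = cfg$tie_delta,
                                 cluster_gap = cfg$cluster_gap)
  calls <- label_shared_branch_points(calls)
  bp_stats <- bp_distance_stats(calls, introns)
  splice_counts <- count_diagnostic_reads(cls$genome_hits, cls$junction_hits,
                                          rd, introns, junctions,
                                          min_overlap = cfg$min_jr_overlap)
  splice_counts[, SE := splicing_efficiency(JR, EI)]

  res <- list(introns = introns, signatures = signatures,
              junctions = junctions, classification = cls, hits = hits,
              observations = obs, calls = calls, bp_stats = bp_stats,
              splice_counts = splice_counts, report = cls$report,
              config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, genome, rd, out_dir)
  res
}

write_pipeline_outputs <- function(res, genome, reads, out_dir) {
  for (d in c("db", "alignments", "calls", "stats")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  if (nrow(res$signatures) > 0L) {
    write_lariat_fasta(res$signatures, file.path(out_dir, "db", "lariats.fa"))
  }
  if (nrow(res$junctions) > 0L) {
    write_junction_fasta(res$junctions,
                         file.path(out_dir, "db", "junctions.fa"))
  }
  fwrite(res$classification$partition,
         file.path(out_dir, "alignments", "partition.tsv"), sep = "\t")
  hits_flat <- copy(res$hits)
  if (nrow(hits_flat) > 0L) {
    hits_flat[, mismatch_positions := vapply(mismatch_positions, paste,
                                             character(1), collapse = ",")]
  }
  fwrite(hits_flat, file.path(out_dir, "alignments", "lariat_hits.tsv"),
         sep = "\t")
  write_branch_point_tables(res$calls, res$introns,
                            tsv_path = file.path(out_dir, "calls", "branch_points.tsv"),
                            bed_path = file.path(out_dir, "calls", "branch_points.bed"))
  fwrite(res$splice_counts, file.path(out_dir, "stats", "splice_counts.tsv"),
         sep = "\t")
  fwrite(res$report, file.path(out_dir, "report.tsv"), sep = "\t")
  manifest <- c(
    sprintf("parameter\tvalue"),
    vapply(names(res$config), function(n) {
      sprintf("%s\t%s", n, paste(format(res$config[[n]]), collapse = ","))
    }, character(1)),
    sprintf("genome_md5\t%s",
            digest_string(paste(genome, collapse = ""))),
    sprintf("n_reads\t%d", nrow(reads))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

# md5 of a string via a temporary file (tools::md5sum is file-based)
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
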