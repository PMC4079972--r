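#' Simulation configuration
#'
#' Defaults emulate a compact fission-yeast-like setting: multi-exon genes
#' with short GT..AG introns (30--500 bases, so a sizeable minority is
#' shorter than the read length), a YURAY-like branch site planted with
#' its adenine at the true branch point placed near the intron 3' end
#' (distance to the 3' end = 5 + Poisson(7), median 12 bases), and
#' strand-specific single-end reads drawn from mRNA, pre-mRNA and lariat
#' junctions. Reverse transcription across the 2'-5' bond mutates the
#' branch-point base with probability `rt_mutation` (uniformly to one of
#' the other three bases) and skips it entirely (a one-base deletion) with
#' probability `rt_bp_skip`, which produces the +/-1 clustering fuzziness
#' seen around real primary branch points.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max), sampled uniformly.
#' @param exon_length_range exon length range in bases.
#' @param intron_length_range intron length range in bases.
#' @param bp_distance_min,bp_distance_lambda distance from the branch
#'   point to the intron 3' end is `bp_distance_min + Poisson(lambda)`,
#'   clipped to fit the intron.
#' @param read_length read length in bases.
#' @param depth total number of reads.
#' @param class_fractions named fractions for `mrna`, `premrna`, `lariat`
#'   reads (must sum to 1).
#' @param skipping_rate fraction of lariat reads drawn from exon-skipping
#'   lariats (rare by default, matching their scarcity in real libraries).
#' @param rt_mutation probability the branch-point base is substituted.
#' @param rt_bp_skip probability the branch-point base is skipped.
#' @param gc_content genome GC fraction.
#' @param intergenic_range spacer length range between genes.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       exons_per_gene = c(2L, 5L),
                       exon_length_range = c(80L, 300L),
                       intron_length_range = c(30L, 500L),
                       bp_distance_min = 5L,
                       bp_distance_lambda = 7,
                       read_length = 49L,
                       depth = 20000L,
                       class_fractions = c(mrna = 0.5, premrna = 0.3,
                                           lariat = 0.2),
                       skipping_rate = 0.0025,
                       rt_mutation = 0.2,
                       rt_bp_skip = 0.05,
                       gc_content = 0.36,
                       intergenic_range = c(100L, 300L)) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8,
            all(class_fractions >= 0),
            rt_mutation >= 0, rt_mutation <= 1,
            rt_bp_skip >= 0, rt_bp_skip <= 1,
            skipping_rate >= 0, skipping_rate <= 1,
            intron_length_range[1L] >= 20L)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Plant the YURAY-like branch site with its adenine at position bp (window
# bp-3..bp+1 of the intron): Y U R A Y, Y in {C,T}, R in {A,G}.
plant_branch_site <- function(intron, bp) {
  site <- paste0(sample(c("C", "T"), 1L), "T", sample(c("A", "G"), 1L), "A",
                 sample(c("C", "T"), 1L))
  paste0(substr(intron, 1L, bp - 4L), site,
         substr(intron, bp + 2L, nchar(intron)))
}

#' Generate a synthetic genome, annotation and branch-point truth
#'
#' Genes alternate with intergenic spacers along one chromosome; each
#' gene's introns begin GT, end AG and carry a planted YURAY-like branch
#' site. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genome` (named character), `transcripts`
#'   (`transcript_models`), `introns` (from [derive_introns()]), and
#'   `truth` (data.table `intron_id`, `true_bp_offset`, `L`,
#'   `distance_3prime`).
#' @export
generate_genome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  pieces <- character(0)
  exon_rows <- list()
  truth <- list()
  pos <- 1L
  for (gi in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", gi)
    tx_id <- paste0(gene_id, ".1")
    strand <- sample(c("+", "-"), 1L)
    n_exons <- sample(cfg$exons_per_gene[1L]:cfg$exons_per_gene[2L], 1L)
    exon_len <- sample(cfg$exon_length_range[1L]:cfg$exon_length_range[2L],
                       n_exons, replace = TRUE)
    n_int <- n_exons - 1L
    intron_len <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L],
                         n_int, replace = TRUE)
    spacer <- random_dna(sample(cfg$intergenic_range[1L]:cfg$intergenic_range[2L],
                                1L), cfg$gc_content)
    # build the gene in transcript orientation
    exon_seq <- vapply(exon_len, random_dna, character(1), gc = cfg$gc_content)
    intron_seq <- character(n_int)
    bp_off <- integer(n_int)
    for (ii in seq_len(n_int)) {
      L <- intron_len[ii]
      s <- random_dna(L, cfg$gc_content)
      s <- paste0("GT", substr(s, 3L, L - 2L), "AG")
      d <- cfg$bp_distance_min + stats::rpois(1L, cfg$bp_distance_lambda)
      d <- min(max(d, 3L), L - 6L)
      bp <- L - d
      s <- plant_branch_site(s, bp)
      intron_seq[ii] <- s
      bp_off[ii] <- bp
    }
    gene_tx <- paste0(rbind(exon_seq, c(intron_seq, ""))[seq_len(2L * n_exons - 1L)],
                      collapse = "")
    gene_seq <- if (strand == "+") gene_tx else revcomp(gene_tx)
    gene_start <- pos + nchar(spacer)
    pieces <- c(pieces, spacer, gene_seq)
    pos <- gene_start + nchar(gene_seq)
    # exon genomic coordinates (transcript order)
    cum <- cumsum(c(0L, head(rbind(exon_len, c(intron_len, 0L))[
      seq_len(2L * n_exons - 1L)], -1L)))
    tx_starts <- cum[seq(1L, by = 2L, length.out = n_exons)]  # 0-based in gene
    for (e in seq_len(n_exons)) {
      if (strand == "+") {
        st <- gene_start + tx_starts[e]
        en <- st + exon_len[e] - 1L
      } else {
        en <- gene_start + nchar(gene_seq) - 1L - tx_starts[e]
        st <- en - exon_len[e] + 1L
      }
      exon_rows[[length(exon_rows) + 1L]] <- data.table(
        transcript_id = tx_id, gene_id = gene_id, chromosome = "chrS",
        strand = strand, start = st, end = en, exon_index = e)
    }
    if (n_int > 0L) {
      truth[[length(truth) + 1L]] <- data.table(
        intron_id = paste0(tx_id, ".I", seq_len(n_int)),
        true_bp_offset = bp_off, L = intron_len,
        distance_3prime = intron_len - bp_off)
    }
  }
  genome <- c(chrS = paste(pieces, collapse = ""))
  tm <- transcript_models(rbindlist(exon_rows))
  introns <- derive_introns(tm, genome)
  truth <- rbindlist(truth)
  # construction check: derived intron sequences carry the planted sites
  stopifnot(identical(nrow(introns), nrow(truth)))
  list(genome = genome, transcripts = tm, introns = introns, truth = truth)
}

mutate_base <- function(base) sample(setdiff(c("A", "C", "G", "T"), base), 1L)

# Lariat junction window for one intron: up to read_length-1 bases ending
# at the branch point (5' side, including the BP base), then up to
# read_length-1 bases from the intron 5' end (3' side), mirroring the
# diagnostic signature construction. A read placement is junction-spanning
# when it covers the boundary with >= 1 base on each side; the number of
# such placements is what makes short lariats under-recovered (no
# insert-size model: containment alone).
lariat_window <- function(intron_seq, bp, read_length) {
  up <- substr(intron_seq, max(1L, bp - read_length + 2L), bp)
  down <- substr(intron_seq, 1L, min(read_length - 1L, nchar(intron_seq)))
  a <- nchar(up)                            # junction after index a
  n_span <- min(a, a + nchar(down) - read_length + 1L) -
    max(1L, a - read_length + 2L) + 1L
  list(up = up, down = down, a = a, n_span = max(0L, n_span))
}

# One junction-spanning read from a lariat window, with optional RT
# branch-point mutation/skip. Placement uniform over spanning positions.
lariat_read_from_window <- function(win, read_length, mutated, skipped) {
  up <- win$up
  bp_base <- substr(up, nchar(up), nchar(up))
  head_ <- substr(up, 1L, nchar(up) - 1L)
  if (mutated) bp_base <- mutate_base(bp_base)
  if (skipped) bp_base <- ""
  template <- paste0(head_, bp_base, win$down)
  j <- nchar(head_) + nchar(bp_base)        # junction after the BP base
  lo <- max(1L, j - read_length + 1L)
  hi <- min(j, nchar(template) - read_length + 1L)
  if (hi < lo || j >= nchar(template)) return(NULL)
  start <- if (hi > lo) sample(lo:hi, 1L) else lo
  list(read = substr(template, start, start + read_length - 1L),
       overlap_5prime = j - start + 1L,
       overlap_3prime = read_length - (j - start + 1L))
}

#' Generate strand-specific reads with ground truth
#'
#' Reads are drawn from three classes in the configured fractions: mRNA
#' (spliced transcript), pre-mRNA (unspliced transcript span) and lariat
#' junctions. Lariat reads span the 2'-5' junction (sequence upstream of
#' the branch point followed by the intron 5' end) with the branch-point
#' base substituted with probability `rt_mutation` and deleted with
#' probability `rt_bp_skip`; a `skipping_rate` fraction instead uses the
#' branch point of a downstream intron joined to the 5' end of an upstream
#' intron. Lariat molecules are equally abundant across introns and read
#' positions are sampled uniformly along each molecule, so the number of
#' junction-spanning reads an intron yields is proportional to the number
#' of read placements that contain the junction; introns shorter than the
#' read support fewer (down to zero) such placements, which reproduces the
#' short-lariat recovery bias through containment alone.
#'
#' @param sim result of [generate_genome()].
#' @param config the same [sim_config()].
#' @param seed RNG seed.
#' @return list with `reads` (data.table `read_id`, `sequence`) and
#'   `truth` (per read: `provenance` in {mrna, premrna, lariat_canonical,
#'   lariat_skipping}, `transcript_id`, `intron_id` (donor intron or NA),
#'   `event_id`, `bp_mutated`, `bp_skipped`, junction overlaps).
#' @export
generate_reads <- function(sim, config = sim_config(), seed = 1L) {
  set.seed(seed + 1L)
  cfg <- config
  rl <- cfg$read_length
  tm <- as.data.table(sim$transcripts)
  introns <- as.data.table(sim$introns)
  truth_bp <- sim$truth
  g <- as_genome(sim$genome)
  setorder(tm, transcript_id, exon_index)
  tm[, seq_ := toupper(substr(g[chromosome], start, end))]
  tm[strand == "-", seq_ := revcomp(seq_)]
  mrna <- tm[, .(sequence = paste(seq_, collapse = "")), by = transcript_id]
  span <- tm[, .(start = min(start), end = max(end)), by = .(transcript_id, chromosome, strand)]
  span[, sequence := toupper(substr(g[chromosome], start, end))]
  span[strand == "-", sequence := revcomp(sequence)]
  intron_map <- merge(introns[, .(intron_id, transcript_id, index, sequence,
                                  length)],
                      truth_bp[, .(intron_id, true_bp_offset)],
                      by = "intron_id")
  # transcripts with >= 2 introns, for skipping lariats
  multi <- intron_map[, .N, by = transcript_id][N >= 2L, transcript_id]

  n_class <- as.vector(rmultinom(1L, cfg$depth,
                                 cfg$class_fractions[c("mrna", "premrna",
                                                       "lariat")]))
  reads <- vector("list", cfg$depth)
  truth <- vector("list", cfg$depth)
  k <- 0L
  emit <- function(seqr, prov, tx, intron, event, mut = FALSE, skp = FALSE,
                   ov5 = NA_integer_, ov3 = NA_integer_) {
    k <<- k + 1L
    id <- sprintf("r%06d", k)
    reads[[k]] <<- data.table(read_id = id, sequence = seqr)
    truth[[k]] <<- data.table(read_id = id, provenance = prov,
                              transcript_id = tx, intron_id = intron,
                              event_id = event, bp_mutated = mut,
                              bp_skipped = skp, overlap_5prime = ov5,
                              overlap_3prime = ov3)
  }
  sample_frag <- function(sq) {
    if (nchar(sq) < rl) return(NULL)
    st <- sample.int(nchar(sq) - rl + 1L, 1L)
    substr(sq, st, st + rl - 1L)
  }
  for (i in seq_len(n_class[1L])) {
    r <- NULL
    while (is.null(r)) {
      tx <- mrna[sample.int(nrow(mrna), 1L)]
      r <- sample_frag(tx$sequence)
    }
    emit(r, "mrna", tx$transcript_id, NA_character_, NA_character_)
  }
  for (i in seq_len(n_class[2L])) {
    r <- NULL
    while (is.null(r)) {
      tx <- span[sample.int(nrow(span), 1L)]
      r <- sample_frag(tx$sequence)
    }
    emit(r, "premrna", tx$transcript_id, NA_character_, NA_character_)
  }
  if (n_class[3L] > 0L && nrow(intron_map) > 0L) {
    # junction-spanning placement count per intron drives its read yield
    windows <- lapply(seq_len(nrow(intron_map)), function(i) {
      lariat_window(intron_map$sequence[i], intron_map$true_bp_offset[i], rl)
    })
    w <- vapply(windows, `[[`, integer(1), "n_span")
    skipping <- runif(n_class[3L]) < cfg$skipping_rate & length(multi) > 0L
    for (i in seq_len(n_class[3L])) {
      mut <- runif(1L) < cfg$rt_mutation
      skp <- !mut && runif(1L) < cfg$rt_bp_skip
      made <- FALSE
      if (skipping[i]) {
        for (attempt in seq_len(50L)) {
          tx_id <- sample(multi, 1L)
          sub <- intron_map[transcript_id == tx_id]
          pair <- sort(sample(sub$index, 2L))
          upi <- sub[index == pair[1L]]
          dni <- sub[index == pair[2L]]
          # branch point of the downstream intron, 5' end of the upstream
          up5 <- substr(dni$sequence,
                        max(1L, dni$true_bp_offset - rl + 2L),
                        dni$true_bp_offset)
          # 5' side may extend back into the upstream intron
          if (nchar(up5) < rl - 1L) {
            need <- rl - 1L - nchar(up5)
            up5 <- paste0(substr(upi$sequence,
                                 max(1L, nchar(upi$sequence) - need + 1L),
                                 nchar(upi$sequence)), up5)
          }
          win <- list(up = up5,
                      down = substr(upi$sequence, 1L,
                                    min(rl - 1L, nchar(upi$sequence))),
                      a = nchar(up5))
          tpl <- lariat_read_from_window(win, rl, mut, skp)
          if (is.null(tpl)) next
          emit(tpl$read, "lariat_skipping", tx_id, dni$intron_id,
               sprintf("%s.I%d-I%d", tx_id, pair[1L], pair[2L]),
               mut, skp, tpl$overlap_5prime, tpl$overlap_3prime)
          made <- TRUE
          break
        }
      } else if (any(w > 0L)) {
        ii <- sample.int(nrow(intron_map), 1L, prob = w)
        it <- intron_map[ii]
        tpl <- lariat_read_from_window(windows[[ii]], rl, mut, skp)
        if (!is.null(tpl)) {
          emit(tpl$read, "lariat_canonical", it$transcript_id, it$intron_id,
               it$intron_id, mut, skp, tpl$overlap_5prime, tpl$overlap_3prime)
          made <- TRUE
        }
      }
      if (!made) {  # no junction-containing placement; the molecule yields
                    # an ordinary intron-body read instead
        it <- intron_map[sample.int(nrow(intron_map), 1L)]
        r <- sample_frag(it$sequence)
        if (is.null(r)) {
          sp <- span[span$transcript_id == it$transcript_id]
          r <- sample_frag(sp$sequence)
        }
        emit(r, "lariat_nonjunction", it$transcript_id, it$intron_id,
             NA_character_)
      }
    }
  }
  list(reads = rbindlist(reads[seq_len(k)]),
       truth = rbindlist(truth[seq_len(k)]))
}

#' Write simulated data to standard formats
#'
#' @param sim result of [generate_genome()].
#' @param reads result of [generate_reads()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written (genome FASTA,
#'   annotation GFF3, reads FASTQ, truth TSVs).
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             reads = file.path(dir, "reads.fastq"),
             intron_truth = file.path(dir, "intron_truth.tsv"),
             read_truth = file.path(dir, "read_truth.tsv"))
  write_fasta(sim$genome, paths["genome"])
  tm <- as.data.table(sim$transcripts)
  gr <- GenomicRanges::GRanges(
    seqnames = tm$chromosome,
    ranges = IRanges::IRanges(tm$start, tm$end),
    strand = tm$strand,
    type = "exon",
    ID = sprintf("%s.exon%d", tm$transcript_id, tm$exon_index),
    Parent = tm$transcript_id,
    gene_id = tm$gene_id
  )
  rtracklayer::export(gr, paths["annotation"], format = "gff3")
  qual <- strrep("I", nchar(reads$reads$sequence))
  writeLines(paste0("@", reads$reads$read_id, "\n", reads$reads$sequence,
                    "\n+\n", qual), paths["reads"])
  fwrite(sim$truth, paths["intron_truth"], sep = "\t")
  if (nrow(reads$truth) > 0L) {
    fwrite(reads$truth, paths["read_truth"], sep = "\t")
  } else {
    writeLines("read_id", paths["read_truth"])
  }
  invisible(paths)
}

#' Simulate replicated two-condition splicing count tables
#'
#' Per intron and replicate, a total diagnostic read count is drawn
#' (Poisson) and split binomially between junction (JR) and exon-intron
#' (EI) reads according to the intron's splicing probability; a designated
#' fraction of introns has that probability halved in condition B.
#'
#' @param n_introns number of introns.
#' @param n_replicates replicate pairs (strata).
#' @param mean_depth mean diagnostic reads per intron per sample.
#' @param frac_affected fraction of introns with halved splicing
#'   probability in condition B.
#' @param se_range range of baseline splicing probabilities.
#' @param seed RNG seed.
#' @return list with `counts` (long table for [splice_table()]) and
#'   `affected` (intron ids with a true effect).
#' @export
simulate_splice_counts <- function(n_introns = 300L, n_replicates = 2L,
                                   mean_depth = 60, frac_affected = 0.1,
                                   se_range = c(0.5, 0.95), seed = 1L) {
  set.seed(seed)
  ids <- sprintf("i%04d", seq_len(n_introns))
  base_se <- runif(n_introns, se_range[1L], se_range[2L])
  affected <- sort(sample(ids, round(frac_affected * n_introns)))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (cond in c("A", "B")) {
      p <- base_se
      if (cond == "B") p[ids %in% affected] <- p[ids %in% affected] / 2
      tot <- stats::rpois(n_introns, mean_depth)
      jr <- rbinom(n_introns, tot, p)
      rows[[length(rows) + 1L]] <- data.table(
        intron_id = ids, sample_id = paste0(cond, r), condition = cond,
        replicate = r, JR = jr, EI = tot - jr)
    }
  }
  list(counts = rbindlist(rows), affected = affected)
}
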