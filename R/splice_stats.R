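#' Count diagnostic junction and exon-intron boundary reads per intron
#'
#' For each intron, `JR` counts reads assigned to the intron's adjacent
#' exon-exon junction record (spliced mRNA signal) and `EI` counts
#' genome-placed reads straddling the boundary between the intron and its
#' upstream 5' exon (pre-mRNA signal; only the upstream boundary is used).
#' Both require at least `min_overlap` bases on each side of the
#' respective boundary, and the read's orientation must agree with the
#' transcript strand.
#'
#' @param genome_hits genome-stage hit table from [classify_reads()]
#'   (`ref_id` = chromosome, `offset` 0-based).
#' @param junction_hits junction-stage hit table (`ref_id` =
#'   `junction_id`).
#' @param reads the read set (named vector or data.frame) for read
#'   lengths.
#' @param introns intron table from [derive_introns()].
#' @param junctions junction table from [build_junction_db()].
#' @param min_overlap minimum bases on each side of the boundary
#'   (default 6).
#' @return data.table `intron_id`, `JR`, `EI` (one row per intron).
#' @export
count_diagnostic_reads <- function(genome_hits, junction_hits, reads,
                                   introns, junctions, min_overlap = 6L) {
  rd <- if (is.data.frame(reads)) {
    data.table(read_id = as.character(reads$read_id),
               read_len = nchar(as.character(reads$sequence)))
  } else {
    data.table(read_id = names(reads), read_len = nchar(as.character(reads)))
  }
  it <- as.data.table(introns)
  jt <- as.data.table(junctions)[kind == "adjacent"]
  # junction record for intron i joins exons i and i+1
  jt[, intron_id := paste0(transcript_id, ".I", up_exon)]
  out <- it[, .(intron_id)]

  # JR: reads on the adjacent junction with >= min_overlap on both sides
  jr <- data.table(intron_id = character(0))
  if (!is.null(junction_hits) && nrow(junction_hits) > 0L) {
    jh <- merge(as.data.table(junction_hits), rd, by = "read_id")
    jh <- merge(jh, jt[, .(junction_id, intron_id, boundary_index,
                           jlen = nchar(sequence))],
                by.x = "ref_id", by.y = "junction_id")
    jh[, `:=`(up_side = boundary_index - offset,
              down_side = offset + read_len - boundary_index)]
    jr <- jh[orientation == "sense" & up_side >= min_overlap &
               down_side >= min_overlap, .(JR = .N), by = intron_id]
  }

  # EI: genome reads straddling the upstream-exon/intron boundary
  ei <- data.table(intron_id = character(0))
  if (!is.null(genome_hits) && nrow(genome_hits) > 0L) {
    gh <- merge(as.data.table(genome_hits), rd, by = "read_id")
    gh[, `:=`(gstart = offset + 1L, gend = offset + read_len)]
    bnd <- it[, .(intron_id, chromosome, strand,
                  # last genomic base of the upstream exon
                  exon_side = ifelse(strand == "+", start - 1L, end + 1L))]
    m <- merge(gh, bnd, by.x = "ref_id", by.y = "chromosome",
               allow.cartesian = TRUE)
    # orientation must match the transcript strand: sense hits for "+"
    # genes, antisense (read = revcomp of reference) for "-" genes
    m <- m[(strand == "+" & orientation == "sense") |
             (strand == "-" & orientation == "antisense")]
    m[, `:=`(
      exon_bases = ifelse(strand == "+", exon_side - gstart + 1L,
                          gend - exon_side + 1L),
      intron_bases = ifelse(strand == "+", gend - exon_side,
                            exon_side - gstart)
    )]
    ei <- m[exon_bases >= min_overlap & intron_bases >= min_overlap,
            .(EI = .N), by = intron_id]
  }

  out <- merge(out, jr, by = "intron_id", all.x = TRUE)
  out <- merge(out, ei, by = "intron_id", all.x = TRUE)
  out[is.na(JR), JR := 0L]
  out[is.na(EI), EI := 0L]
  setkey(out, intron_id)
  out[]
}

#' Splicing efficiency
#'
#' The proportion of spliced signal: `SE = JR / (JR + EI)`, `NA` when both
#' counts are zero. Set `ratio = TRUE` for the raw ratio `JR / EI`
#' (infinite when `EI = 0`).
#'
#' @param JR junction read counts (non-negative).
#' @param EI exon-intron boundary read counts (non-negative).
#' @param ratio return `JR / EI` instead of the bounded proportion.
#' @return numeric vector of splicing efficiencies.
#' @export
#' @examples
#' splicing_efficiency(30, 10) # 0.75
#' splicing_efficiency(0, 0)   # NA
splicing_efficiency <- function(JR, EI, ratio = FALSE) {
  if (any(JR < 0 | EI < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (ratio) return(JR / EI)
  se <- JR / (JR + EI)
  se[JR + EI == 0] <- NA_real_
  se
}

#' Cochran-Mantel-Haenszel test on stratified 2x2 splicing tables
#'
#' Tests association between read class (JR vs EI) and condition across K
#' replicate strata: the classical CMH chi-squared statistic with 1 df,
#' without continuity correction by default. Strata with a zero row or
#' column margin contribute nothing.
#'
#' @param tables a 2x2xK array (rows: JR, EI; columns: condition A, B;
#'   slices: replicate pairs), or a 2x2 matrix for K = 1.
#' @param correct apply the continuity correction (default FALSE).
#' @return list with `statistic` and `p.value` (both `NA` with a warning
#'   when every stratum is degenerate).
#' @export
cmh_test <- function(tables, correct = FALSE) {
  if (is.matrix(tables)) tables <- array(tables, dim = c(2L, 2L, 1L))
  stopifnot(length(dim(tables)) == 3L, all(dim(tables)[1:2] == 2L))
  if (any(tables < 0) || any(tables != round(tables))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- apply(tables, 3L, sum)
  informative <- vapply(seq_len(dim(tables)[3L]), function(k) {
    tk <- tables[, , k]
    sum(tk) > 0 && all(rowSums(tk) >= 0) &&
      min(rowSums(tk)) * min(colSums(tk)) > 0  # no zero margin
  }, logical(1))
  if (!any(informative)) {
    warning("all strata degenerate (zero margins); CMH statistic undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  tb <- tables[, , informative, drop = FALSE]
  a <- tb[1L, 1L, ]
  r1 <- tb[1L, 1L, ] + tb[1L, 2L, ]
  c1 <- tb[1L, 1L, ] + tb[2L, 1L, ]
  nn <- apply(tb, 3L, sum)
  ea <- r1 * c1 / nn
  r2 <- nn - r1; c2 <- nn - c1
  va <- r1 * r2 * c1 * c2 / (nn^2 * (nn - 1))
  va[nn <= 1] <- 0
  if (sum(va) == 0) {
    warning("zero CMH variance; statistic undefined", call. = FALSE)
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  dev <- abs(sum(a) - sum(ea))
  if (correct) dev <- max(0, dev - 0.5)
  stat <- dev^2 / sum(va)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1L,
                                                 lower.tail = FALSE))
}

#' False discovery rate q-values
#'
#' Storey q-values with the proportion of true nulls pi0 estimated by
#' natural-spline smoothing over a lambda grid (default 0.05..0.95 in
#' steps of 0.05), or Benjamini-Hochberg adjusted p-values
#' (`method = "bh"`). Output is monotone non-decreasing in p-value rank
#' and capped at 1.
#'
#' @param pvals p-values in `[0, 1]` (NA allowed, propagated).
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda grid for pi0 estimation.
#' @return numeric vector of q-values, same length and order as `pvals`.
#' @export
qvalues <- function(pvals, method = c("storey", "bh"),
                    lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (length(p) > 0L && (any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvals))
  if (length(p) == 0L) return(out)
  if (method == "bh") {
    out[ok] <- p.adjust(p, method = "BH")
    return(out)
  }
  m <- length(p)
  pi0 <- if (m < 20L || max(p) < max(lambda)) {
    1
  } else {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    min(1, max(stats::predict(fit, x = max(lambda))$y, 0))
  }
  if (pi0 <= 0) pi0 <- 1
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p[o], ties.method = "max")
  q <- pmin(1, cummin(q))[ro]
  out[ok] <- q
  out
}

#' RPKM expression level
#'
#' `E = R * C / (T * L) + eps`: reads in the region scaled by a constant
#' `C = 1e9`, divided by the sample's total read count and the region
#' length, plus a small constant so logarithms are defined at zero counts.
#'
#' @param R reads detected across the region.
#' @param total total reads in the sample (> 0).
#' @param region_length region length in bases (> 0).
#' @param C scaling constant (default 1e9).
#' @param eps additive constant (default 1e-5).
#' @return numeric expression values.
#' @export
#' @examples
#' rpkm(100, 1e7, 1000) # 10 + 1e-5
rpkm <- function(R, total, region_length, C = 1e9, eps = 1e-5) {
  if (any(total <= 0)) stop("total reads must be > 0", call. = FALSE)
  if (any(region_length <= 0)) stop("region length must be > 0", call. = FALSE)
  R * C / (total * region_length) + eps
}

#' Per-intron differential-splicing table across two conditions
#'
#' Assembles the per-intron 2x2xK tables (rows JR/EI, columns condition
#' A/B, strata = replicate pairs), computes splicing efficiencies, the CMH
#' test and q-values.
#'
#' @param counts data.table/data.frame with columns `intron_id`,
#'   `sample_id`, `condition`, `replicate`, `JR`, `EI`.
#' @param qvalue_method passed to [qvalues()].
#' @param correct continuity correction for the CMH test.
#' @return data.table per intron: mean SE per condition, `statistic`,
#'   `p.value`, `q.value`.
#' @export
splice_table <- function(counts, qvalue_method = "storey", correct = FALSE) {
  ct <- as.data.table(counts)
  conds <- sort(unique(ct$condition))
  if (length(conds) != 2L) stop("exactly two conditions required", call. = FALSE)
  ct[, SE := splicing_efficiency(JR, EI)]
  res <- ct[, {
    reps <- sort(unique(replicate))
    tabs <- vapply(reps, function(r) {
      sub <- .SD[replicate == r]
      rbind(JR = c(sum(sub[condition == conds[1L], JR]),
                   sum(sub[condition == conds[2L], JR])),
            EI = c(sum(sub[condition == conds[1L], EI]),
                   sum(sub[condition == conds[2L], EI])))
    }, matrix(0, 2L, 2L))
    tst <- suppressWarnings(cmh_test(array(tabs, dim = c(2L, 2L, length(reps))),
                                     correct = correct))
    .(SE_A = mean(SE[condition == conds[1L]], na.rm = TRUE),
      SE_B = mean(SE[condition == conds[2L]], na.rm = TRUE),
      statistic = tst$statistic, p.value = tst$p.value)
  }, by = intron_id]
  res[, q.value := qvalues(p.value, method = qvalue_method)]
  res[]
}
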