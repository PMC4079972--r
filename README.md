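# lariatscan

Genome-wide mapping of intron lariats and branch points from RNA-seq, in R.

## The problem

During pre-mRNA splicing the intron is excised as a **lariat**: a loop
closed by a 2′–5′ phosphodiester bond between the 5′ splice donor and the
**branch point** (usually an adenine near the intron 3′ end). Reverse
transcriptase reads through that bond, producing cDNA in which the sequence
upstream of the branch point directly precedes the intron 5′ end — often
with the branch-point base mutated. These "inverted" reads fail ordinary
genome and transcriptome alignment, so standard RNA-seq pipelines throw
away exactly the reads that pinpoint branch points at base resolution.

`lariatscan` is for transcriptomics researchers who want to recover those
reads and turn them into branch-point maps. It:

1. derives introns from a genome FASTA + GFF3/GTF annotation (the gap
   between consecutive exons, in transcript orientation);
2. builds an exhaustive **lariat signature database**: for every candidate
   branch-point position *p* of an intron of length *L*, the diagnostic
   sequence

   `signature(p) = intron[p−(r−1) … p−1] + intron[p] + intron[1 … r−1]`

   for read length *r* (all positions, or adenines only), including
   **exon-skipping** signatures for every intron pair (i < j) — there are
   S = (I−1)·I/2 such pairs for I introns — where the branch point lies in
   the downstream intron and the 3′ segment is the upstream intron's 5′
   end;
3. classifies reads through a staged workflow: genome and exon–exon
   junction windows first (≤3 mismatches), then the unmapped remainder
   against the lariat database (≤1 mismatch, because RT mutates the
   branch-point base), with multi-mapped reads flagged and removed;
4. clusters per-base branch-point observations into primary and alternate
   calls (neighbouring observations ≤1 base apart are pooled; when the top
   two members differ by <10 reads the 3′-most wins; clusters need ≥3
   supporting reads), and derives consensus matrices (information content
   against a 30%-GC background) and distance-to-3′-end statistics;
5. computes per-intron **splicing efficiency** SE = JR/(JR+EI) from
   diagnostic junction (JR) and exon–intron boundary (EI) reads, tests
   differential splicing across replicated conditions with the
   Cochran–Mantel–Haenszel χ² test, and reports Storey/BH q-values and
   RPKM expression;
6. ships a simulator that generates genomes, annotations, strand-specific
   reads (mRNA, pre-mRNA, lariat junctions with configurable RT
   branch-point mutation and skipping) and ground truth, so the whole
   pipeline is testable end to end with no downloads.

## Worked example

```r
library(lariatscan)

cfg  <- sim_config(n_genes = 20, depth = 2000)    # compact synthetic study
sim  <- generate_genome(cfg, seed = 7)
rds  <- generate_reads(sim, cfg, seed = 7)
res  <- run_pipeline(sim$genome, sim$transcripts, rds$reads,
                     run_config(preset = "pombe", seed = 7))

res$report
#>              stage n_assigned n_unique n_ambiguous
#> 1:   genome_mapped       1521     1521           0
#> 2: junction_mapped        148      148           0
#> 3:   lariat_mapped        325      298          27
#> 4:        unmapped          6        6           0

nrow(res$calls)                       # 45 branch points called
res$bp_stats$median_distance_3prime   # 12 bases from the intron 3' end

cmp <- merge(res$calls, sim$truth, by = "intron_id")
mean(cmp$primary_offset == cmp$true_bp_offset)
#> [1] 1        # every called primary branch point matches the planted one
```

The report counts reads per workflow stage: most reads map to the genome
or to exon–exon junctions; of the leftovers, the lariat-database stage
recovers the junction-spanning lariat reads (here 298 uniquely, 27
ambiguous between canonical and skipping signatures). The calls table
gives, per intron, the primary branch-point offset, its read support,
pooled cluster members and any alternate branch points; `bp_stats` bins
detection by intron length, which exposes the short-intron recovery bias.

A thin command-line front end over the same functions is installed at
`inst/scripts/lariatscan` (subcommands `build-db`, `build-junctions`,
`simulate`, `run`).

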