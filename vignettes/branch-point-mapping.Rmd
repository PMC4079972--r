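---
title: "Mapping intron lariats and branch points from RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intron lariats and branch points from RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lariatscan)
```

## The model

Splicing excises each intron as a lariat: the 2′-OH of the branch-point
base (almost always an adenine embedded in a degenerate YURAY context)
attacks the 5′ splice site, closing a loop with a 2′–5′ phosphodiester
bond. Reverse transcriptase traverses that bond, so a cDNA read crossing
the lariat junction contains intronic sequence upstream of the branch
point immediately followed by the intron 5′ end — a sequence that exists
nowhere in the genome. Two further RT behaviours matter: the branch-point
base is frequently substituted (we model a per-read probability,
default 0.2), and occasionally skipped outright (a one-base deletion,
default 0.05). The skip shifts the apparent branch point one base toward
the 5′ end, which is why raw observations cluster around the true
position.

`lariatscan` enumerates every sequence such a read could have. For an
intron of length $L$, read length $r$ and candidate branch position $p$
(iterated from the 3′ end down to the first base; all bases, or adenines
only):

$$\mathrm{sig}(p) \;=\; \underbrace{\text{intron}[p-(r-1)\,..\,p-1]}_{5'\ \text{segment}}\;
\underbrace{\text{intron}[p]}_{\text{BP}}\;
\underbrace{\text{intron}[1\,..\,r-1]}_{3'\ \text{segment}}$$

truncating each segment at the intron bounds, so every signature is at
most $2r-1$ bases. Exon-skipping lariats join the 5′ splice site of an
upstream intron $i$ to the branch point of a downstream intron $j$: the
construction concatenates intron $i$ and intron $j$, iterates candidates
over intron $j$ only (so the database stays non-redundant), and always
takes the 3′ segment from intron $i$'s 5′ end. A transcript with $I$
introns has $(I-1)I/2$ skipping classes. A branch point at intron
position 1 has an empty 5′ segment; we still emit it (the enumeration
runs to the first base) but flag it `degenerate`, and the junction
overlap filter makes such signatures inert in practice.

Reads are then classified in stages: genome, transcriptome/exon–exon
junction windows (3 mismatches, matching a permissive external-aligner
setting), and only the survivors against the lariat database
(1 mismatch, to admit the mutated branch-point base). Assigning each read
to the first stage that accepts it is what makes a lariat hit diagnostic:
had the read any ungapped genomic or spliced interpretation, it would
never reach stage three.

## Junction windows and splicing efficiency

Exon–exon junction records concatenate the last $w$ bases of the
upstream exon and the first $w$ of the downstream exon, with
$w = r - \text{min\_overlap}$, so a fully contained read necessarily
overlaps the boundary by at least `min_overlap` on each side; with
49-base reads and the default `min_overlap = 6` the windows are 43 bases.
Splicing efficiency per intron is the bounded proportion

$$SE = \frac{JR}{JR + EI},$$

where $JR$ counts reads on the intron's adjacent junction and $EI$ counts
genome reads straddling the *upstream* exon–intron boundary (the upstream
boundary only; the downstream one would double-count the same molecule
and is asymmetric under intron retention). $SE$ is `NA` when both counts
are zero; the raw ratio $JR/EI$ is available behind a flag for users who
want the unbounded odds form. Differential splicing across replicated
conditions uses the classical Cochran–Mantel–Haenszel χ² on 2×2×K tables
(rows JR/EI, columns condition, strata = replicate pairs), without
continuity correction by default; strata with a zero margin contribute
nothing, and an all-zero table yields `NA` with a warning rather than an
error so that genome-wide scans do not abort on empty introns. We
implement the statistic directly because the stock implementation rejects
single-stratum (2×2×1) input, which we require; the test suite checks it
against `stats::mantelhaen.test` for K≥2 and against
$(n-1)/n\,\chi^2_{\text{Pearson}}$ for K=1. False discovery rates use
Storey's q-value with $\pi_0$ estimated by spline smoothing over
$\lambda = 0.05, 0.10, \dots, 0.95$ (falling back to $\pi_0 = 1$, i.e.
Benjamini–Hochberg, for fewer than 20 tests, where the spline is
meaningless); expression uses RPKM, $E = RC/(TL) + 10^{-5}$ with
$C = 10^9$.

## The matcher

The matcher's contract is brute force: report every ungapped,
fully-contained placement of the read within a reference at Hamming
distance ≤ m, with `N` mismatching everything including `N` (an ambiguous
base is never evidence). The implementation prunes with a pigeonhole seed
index — any placement with ≤ m mismatches contains an exact match of one
of m+1 disjoint read pieces, so only placements sharing a seed k-mer
(k = ⌊read length/(m+1)⌋) are verified — and every candidate is then
checked explicitly, so the index is purely an optimisation. When k would
drop below 6 (tiny reads), the matcher enumerates all placements
outright. Ambiguity for `unique_only` is counted over distinct reference
*sequences*, not reference identifiers: identical duplicated references
(junctions shared between transcripts, collapsed duplicate signatures)
should not discard reads, whereas placements in two genuinely different
sequences make the read unassignable and it is flagged and excluded from
hit tables. Within one reference, the placement with fewest mismatches
(then smallest offset) is kept. Reads matching both a canonical and a
skipping signature — which share everything but the 3′ segment when the
two introns' 5′ ends agree, as GT..-starting introns often briefly do —
are therefore dropped as ambiguous and surface in the per-stage
ambiguity counts rather than in calls.

## Branch-point calling

Hits are annotated with the donor intron, branch-point offset, the read's
overlap on each side of the lariat junction (the 5′ side includes the
branch-point base) and whether a mismatch falls exactly on the
branch-point base. The stringent filter (default for the human preset)
removes antisense hits, hits whose mismatch is elsewhere than the branch
point, and hits overlapping the junction by fewer than 10 bases on either
side; the permissive preset only requires 1 base. Observations (read
counts per intron × offset) are clustered: members at most `cluster_gap`
(default 1) bases apart chain into one cluster; the representative is the
member with most reads, except that when the two best members differ by
fewer than `tie_delta` (default 10) reads the 3′-most of the two is
chosen — RT base-skipping inflates the position one base 5′ of the true
branch point, and the 3′ preference undoes exactly that. Clusters with
total support below `min_reads` (default 3) are discarded; support is
pooled across cluster members because RT errors scatter reads across
adjacent offsets (a strict per-offset variant is available). The
best-supported cluster yields the primary branch point, the rest become
alternates, necessarily more than `cluster_gap` bases away. Whether the
tie rule should compare only the two best members of a chain or all
neighbouring pairs is underdetermined; we compare the top two, which is
well-defined for chains of any length and coincides with the pairwise
reading on the 1–2-member chains that dominate real data.

Consensus matrices take the intronic window ±flank around each primary
branch point (windows clipped at intron bounds are excluded rather than
padded), and report per-column probabilities plus information content
$\sum_b p_b \log_2 (p_b/q_b)$ against a non-uniform background with 30%
GC ($q_A = q_T = 0.35$, $q_C = q_G = 0.15$), the composition appropriate
for AT-rich yeast introns. Plotting is out of scope; the matrices are the
interface to any logo renderer.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults are the study conditions the rest of the package
is validated under: 200 genes of 2–5 exons (exons 80–300 bp), intron
lengths uniform on 30–500 so a minority falls below the 49-base read
length, GC 36%, one gene per strand on average, GT..AG intron boundaries,
and a planted YURAY-like branch site whose adenine sits at distance
$5 + \mathrm{Poisson}(7)$ from the intron 3′ end (median 12, clipped to
the intron). Reads (depth 20,000) are single-end, strand-specific,
error-free outside the branch point, and split mRNA / pre-mRNA / lariat
as 0.5/0.3/0.2; exon-skipping lariats are drawn at the rarity real data
shows (0.25% of lariat reads), so skipping detection is exercised by
dedicated tests with elevated rates rather than by the defaults.

Lariat reads are modelled as uniform read positions along equally
abundant lariat molecules: the probability that an intron yields a
junction-spanning read is proportional to the number of read placements
containing its 2′–5′ junction. An intron whose junction context is
shorter than the read yields none, and short introns support few
placements — this containment effect alone reproduces the short-intron
detection deficit (roughly 45–55% of sub-read-length introns detected
versus ~96% of longer ones at the default depth). What the simulator does
*not* model: sequencing errors beyond the RT branch-point substitution,
base-quality structure, fragment-size selection (the real bias against
short lariats is stronger than containment alone because ~200 nt inserts
are size-selected), intron-lariat degradation kinetics, expression
heterogeneity between genes, paired ends, and splice-site or branch-site
sequence variation beyond the planted consensus. Passing tests therefore
demonstrate algorithmic correctness under idealised coverage, not
end-to-end performance on a real library.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive internally; BED exports are 0-based
half-open. Hit offsets are 0-based within the reference, as are
mismatch positions within the (orientation-adjusted) read. `N` bases are
permitted through the whole path but never match. Empty observation sets
produce empty call tables, not errors; an all-zero CMH table and a
zero-depth SE produce `NA`. Ties in cluster support between clusters
break toward the 3′-most representative, mirroring the within-cluster
rule. The q-value estimator caps $\hat\pi_0$ into $(0, 1]$. Signature
databases collapse exact duplicate sequences within a transcript on
serialisation, keeping every provenance in the header, so alignment-stage
ambiguity reflects genuine sequence ambiguity only.

## Problem sizes

The bundled tests run the complete workflow on the default 200-gene
simulation (~300 kb genome, ~480 introns, ~240,000 lariat signatures,
20,000 reads) in about two minutes, plus oracle-equivalence sweeps (1000
random matcher instances, 500 random introns) and small fixture suites.
These sizes were chosen so the whole validation story — signature
construction, staged classification, clustering, statistics, and
parameter recovery against planted truth — runs comfortably on a laptop;
they are a scaled-down analogue of a yeast-sized genome, not a claim
about human-scale databases, which the chunked FASTA writer supports in
principle but which are out of scope here.

## Known limitations

Gapped or spliced alignment, base-quality-aware scoring and paired-end
rescue are out of scope; the matcher is exact-Hamming by design.
Annotation-free discovery (sliding-window databases) is not implemented.
The distance-versus-length structure of branch points is reported as a
binned table only; no proximal/distal classification model is fitted.
Reads matching both canonical and skipping signatures are dropped rather
than probabilistically assigned; with very short exons this can slightly
undercount skipping support.
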