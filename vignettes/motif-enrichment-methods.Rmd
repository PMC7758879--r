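---
title: "Methods: Monte Carlo promoter motif enrichment and behavioral assay statistics"
author: "motifmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo promoter motif enrichment and behavioral assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifmc)
```

## The model

`motifmc` tests whether the promoters of a gene set — typically genes
up- or downregulated by a transcription factor such as neuronal XBP-1s —
are enriched for short binding motifs (ACGT core, CCACG box, UPRE-style
elements), relative to random gene sets.

For a gene set $S$ and motif $m$, the statistic is the mean occurrence
count per promoter,
$$\bar c_S = \frac{1}{|S|}\sum_{g\in S} c_{g,m},$$
where $c_{g,m}$ counts all (possibly overlapping) occurrences of $m$ in
the ±100 bp window around the transcription start site (TSS) of $g$.
The null distribution is generated by drawing $R$ random gene sets
uniformly without replacement from a background universe and recomputing
$\bar c$. The strict empirical p-value is the proportion of random sets
with a mean count **strictly higher** than the observed one; ties count
as "not higher". Because the strict proportion can be exactly zero, the
conservative estimator $(k+1)/(R+1)$ is always reported alongside —
with $R = 2000$ its floor is $1/2001 \approx 5\times10^{-4}$, which is
the honest resolution limit of the resampling design.

One family of null sets is shared across all motifs (a single sampling
pass), matching the presentation of a single family of cumulative null
curves; no multiple-testing correction is applied across motifs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `upstream`, `downstream` | 100 bp, 100 bp | promoter window around the TSS (total 200 bp) |
| `min_gene_length` | 500 bp | genes must be *strictly* longer to enter the analysis |
| `n_random_sets` (R) | 2000 | Monte Carlo null sets |
| `random_set_size` | 750 | genes per null set |
| `pvalue_threshold` | 1e-4 | PWM match p-value cutoff |
| `pseudocount` | 0.01 | added to PWM columns before log-odds |
| `bin_width` | 0.01 bits | score discretization of the threshold DP |

Design choices behind these values:

* **Strict length filter.** "Longer than 500 bp" is read as a strict
  inequality; a 500 bp gene is excluded. The filter removes the many
  very short genes whose promoters would otherwise bias mean counts.
* **TSS definition.** The 5' end of the annotated `gene` feature
  (`start` on the plus strand, `end` on the minus strand). This avoids
  committing to a transcript isoform; the feature type is configurable
  in `read_gff_genes()`.
* **Null set size vs observed set size.** Observed sets may have any
  size (e.g. 761 upregulated and 734 downregulated genes against null
  sets of 750): the mean-per-promoter statistic has the same expectation
  at any set size, only its variance differs. The fixed null size is a
  deliberate simplification and is configurable.
* **Null universe.** All genes passing the length filter (and carrying
  an extractable full-length promoter). A restricted universe — e.g.
  genes expressed in the tissue of interest — can be supplied via the
  `universe` configuration entry.
* **Edge policy.** Promoter windows crossing a contig edge are dropped
  by default so every promoter has the same length and mean counts stay
  comparable; `clip` mode keeps and flags them instead.

## Motif scanning

Consensus motifs use IUPAC codes; a base matches a consensus position
when its set is contained in the consensus set, so a sequence `N`
(unknown base) is matched only by a consensus `N`. This is deliberately
conservative: an unknown base never certifies a specific requirement.

PWMs are scored by log-odds in bits against the background composition
after adding a 0.01 pseudocount per column. The match threshold is the
smallest discretized score whose background tail probability is at most
`pvalue_threshold`, computed **exactly** by dynamic programming: the
score distribution of a random L-mer is built by convolving the
per-position distributions of binned scores (bin width 0.01 bits). The
scanner compares the same binned window scores against the same binned
threshold, so scanning and thresholding are mutually exact and the
tests can verify the tail probability against exhaustive enumeration
over all $4^L$ words. A matrix indistinguishable from the background
yields a threshold above the maximal score and admits no word at any
cutoff below 1. Windows containing `N` never match.

Both strands are scanned by default; a reverse-strand hit is a match of
the reverse-complemented motif at the same forward offset. A
**palindromic** motif (a consensus equal to its IUPAC reverse
complement, like `ACGT`, or a PWM equal to its reverse-complemented
matrix) would report every site twice, once per strand; such motifs are
scanned on the forward strand only, so the self-complementary ACGT core
is counted once per physical site. Overlapping occurrences are all
counted — the statistic is an occurrence count, not a parse.

The four XBP-1s-associated motif names are conventional labels; the
shipped file `inst/extdata/motifs_uprelike.tsv` contains *illustrative*
UPRE-style consensi for examples and tests, not curated matrices from
any database. Real analyses should supply their own motif definitions
(MEME-format PWMs or consensus tables).

## What the synthetic generator emulates

`generate_genome()` builds a genome of $n$ equal-length genes (default
1000 bp, all passing the 500 bp filter) laid head-to-tail on
alternating strands with intergenic spacers at least as long as the
upstream window, so promoter windows never collide and minus-strand
extraction is exercised by construction. Promoters are i.i.d. draws
from a base composition (default uniform); for each gene and motif a
Poisson-distributed number of concrete motif instances is planted at
uniform, mutually non-overlapping offsets within the ±100 bp window
(rejection sampling with bounded retries), at one rate for a designated
target set and another for the background. Every plant is recorded, so
planted counts are exactly recoverable by the scanner for motifs with
negligible chance-match probability.

It does **not** emulate real genome structure: GC heterogeneity,
repeats, operons, overlapping genes, isoform diversity, or correlated
promoter composition. Passing tests on synthetic data therefore
demonstrate the correctness of the computational procedure and the
calibration of the resampling test under its stated sampling model —
not robustness to compositional biases of real genomes, which the
single length filter of the null design deliberately does not address
(no GC- or length-matched sampling).

Behavioral simulation uses an absorbing per-minute leaving hazard for
food-leaving assays and a lazy 8-neighbor random walk (reflecting at
plate edges) for exploration tracks.

## Behavioral assay statistics

**Food-leaving probability** is the per-minute ratio of leavers to
worms present at the start of that minute, averaged over the 15-minute
window. Minutes with zero worms at the start are excluded from the
average — the ratio is undefined there — so an assay in which all worms
leave in minute 1 scores exactly 1. Leaving is treated as absorbing
within a window; an optional returns column is accepted for generality.

**Off-food exploration** scores each 0.25 cm² square with bacterial
growth outside the food patch by its concentric ring and aggregates
(default sum; max and mean are selectable and echoed in all outputs).
The protocol's declared ring sizes — 9, 25, 49, 81, 121 — equal the
*full* centered squares $3^2, 5^2, 7^2, 9^2, 11^2$, not the annuli
between them (16, 24, 32, 40), so the printed counts cannot all be
disjoint ring sizes. The default `"chebyshev"` geometry resolves this
the self-consistent way: score $k$ is the index of the smallest
centered odd square containing the cell, giving disjoint shells of 9,
16, 24, 32 and 40 squares; cells beyond ring 5 take score 5. A
`"literal"` mode is also provided that fills rings with exactly the
declared counts in proximity order (Chebyshev distance, then squared
Euclidean distance, then row/column as a deterministic tie-break).
Either mode is recorded in the output tables. The plate grid is
anchored at the patch center and partial edge squares count as whole
squares.

**On-food exploration** is the percentage of grid squares crossed by
trails: $100\times$ occupied / total.

## Numerical and degenerate-input conventions

* Coordinates are GFF3 1-based inclusive at the parser boundary and
  0-based half-open everywhere else; a plus-strand gene starting at
  1-based 1001 with a ±100 bp window yields the genomic window
  [900, 1100).
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), so genomes, null sets, logs and tracks are
  bit-reproducible; derived streams use fixed documented offsets from
  the top-level seed.
* Degenerate cases: a sequence shorter than a motif yields no hits (not
  an error); an empty gene set, a missing gene in the count table, or a
  null set size above the universe size are errors; an empty occupancy
  grid scores 0 with a warning; `R = 1` forces the strict p into
  {0, 1}.

## Validation scale

The test suite validates counting and thresholds against brute-force
oracles (exhaustive enumeration over $4^L$ words for $L \le 8$; naive
per-character matching on 100 random 200 bp promoters), and the
resampling test end-to-end on simulated studies of 2000 genes with a
200-gene target set and 500 null sets: 100 equal-rate studies for
type-I calibration (the fraction with strict $p<0.05$ must fall in the
exact binomial 99% band around 0.05) and 100 differential studies
(rates 2.0 vs 0.5) for power. These sizes were chosen as the smallest
at which the binomial bands are meaningfully tight; larger studies only
sharpen the same checks.

## Known limitations

* The null model matches sets by the length filter only; GC- or
  length-matched resampling is out of scope.
* TSS selection is gene-feature based; transcript-isoform-aware TSS
  selection is not supported.
* With $R$ null sets, empirical p-values have resolution $1/R$;
  annotations below that (e.g. $p \le 10^{-4}$ at $R = 2000$) can only
  mean "no exceedances observed".
* Exploration scoring reconstructs a protocol whose square-to-score
  mapping is ambiguous (see above); both supported geometries are
  explicit rather than authoritative.
* q-values across scanned positions, motif discovery, and enrichment
  alternatives (Fisher/hypergeometric) are out of scope.
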