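---
title: "Detecting shared whole-genome duplications and reconciling chromosome-scale scaffold orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared whole-genome duplications and reconciling chromosome-scale scaffold orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdmap)
```

## The two analyses this package implements

`wgdmap` packages two linked analyses from chromosome-scale plant genomics.

The first is **reconciliation of two independent chromosome-scale
orderings** of a draft assembly: a proximity-guided ordering (Hi-C
chromatin-contact clustering, ordering, and orienting of scaffolds, as
produced by LACHESIS-class tools) and a RAD-seq linkage map from an F1
pseudo-testcross. Proximity data order and orient scaffolds precisely at
local scale but occasionally invert whole multi-scaffold segments; a linkage
map is coarse (its resolution is set by the number of scoreable crossovers)
but reliable at large scale. Reconciling the two yields a corrected ordering,
a conservative set of scaffolds placed identically by both, and a census of
chimeric scaffolds — assembly artifacts joining sequence from different
chromosomes, betrayed by markers that map to two linkage groups and split at
single-`N` junction positions.

The second is **detection and relative dating of whole-genome duplications
(WGDs)**. A WGD leaves two genomic signatures: spatially, paired collinear
(syntenic) blocks of duplicated genes across chromosomes; temporally, a peak
in the distribution of synonymous divergence (Ks) between paralog pairs.
The package chains homologous gene pairs into syntenic blocks
(DAGChainer-style), measures syntenic depth (how many regions are homologous
to a query region — depth 1:4 or 1:5 indicates multiple rounds of WGD),
estimates Ks for the deduplicated paranome, asks which density peaks are
statistically real (SiZer), parameterises them (Gaussian mixtures selected by
BIC), matches peaks across genomes into shared WGD calls, and places each
WGD before or after speciation events using ortholog Ks distributions.

Because the real datasets behind such studies are not reproducible at desk
scale, the package carries a first-class synthetic-data module that plants
every signal the analysis is supposed to find — WGDs at known Ks depths,
chimeric joins at known positions, inversions of known extent, crosses with
known marker order — so every stage is tested against ground truth.

## The synthetic generator: what it emulates

`simulate_wgd_genome()` builds a genome of random protein-coding genes
(default 13 chromosomes x 100 genes of 300 bp, mirroring a diploid with
2n = 26) and applies WGD events oldest-first. Each event duplicates each gene
with probability `retention_rate` onto a collinear chromosome copy and
assigns the pair a true Ks drawn from Normal(`ks_mean`, `ks_sd`) truncated at
zero. The default event depths are Ks 1.71 (sd 0.35) and 0.61 (sd 0.15) —
the two ancient duplication ages recovered in Ericaceae genomes — with
retentions 0.4 and 0.5, round numbers in the range observed for ancient
events.

Divergence is *realised in the sequences* by substituting only at
NG86-synonymous codon positions (a random walk over synonymous one-step
neighbours) until the pairwise synonymous difference fraction reaches
`pS = 3/4 (1 - exp(-4/3 Ks))`, the inverse of the Jukes-Cantor correction.
This makes the true Ks recoverable by the package's own estimator without a
full codon-evolution simulator, and it is the reason the round-trip tests can
demand mean absolute error <= 0.1 for Ks <= 1. The price is realism: no
nonsynonymous change, no rate variation among sites, no codon usage bias. A
passing round-trip therefore validates the estimator's arithmetic and the
pipeline's plumbing, not its robustness to real evolutionary noise.

`fragment_and_corrupt()` cuts chromosomes into scaffolds around a target N50
and concatenates `chimera_count` scaffold pairs from different chromosomes
with exactly one `N` at the junction. One junction `N` is a modelling
commitment, not a simplification: the splitting rule downstream targets lone
`N`s, and the truth must be recoverable by that rule. Chimera partners are
drawn longest-first so that both sides of a join tend to carry markers —
a chimera with an unmarked arm is undetectable by any linkage method.

`simulate_cross()` generates a pseudo-testcross (one parent heterozygous at
every marker, 1:1 segregation) with crossovers as a Poisson process on map
distance — no interference — so the recombination fraction between markers
d cM apart is Haldane's `(1 - exp(-2d/100))/2`, and `haldane_distance()` is
its exact inverse. Missing calls are injected at 5% by default: enough to
exercise the 90% call-rate filter without dominating it.

All stage functions draw their randomness from one explicit seed through a
per-stage stream derivation; no global random state leaks between stages, and
`run_simulate()` reruns are byte-identical.

## Linkage analysis: where the design was genuinely open

Markers are filtered at a 90% call rate (inclusive: 99/110 progeny passes).
Pairwise recombination fractions use the phase-unknown estimator
`r = min(m, n - m)/n` over pairwise-complete calls; missing calls never count
as recombinant.

Grouping needed a real design decision. The natural rule — an edge when
`r <= 0.35` and LOD >= 3, groups as connected components — collapses at
realistic marker counts: with 650 markers and 110 progeny there are ~200,000
unlinked pairs, and the two-sided tail probability of a chance LOD >= 3 link
(~2-3 x 10^-4) yields dozens of spurious edges per dataset. Worse, they
arrive in correlated cliques: neighbouring markers share genotype vectors, so
one chance correlation between two chromosome regions produces many mutually
supporting edges. `group_markers()` therefore (a) applies the LOD threshold
genome-wide, adding `log10(n_pairs)` — a Bonferroni correction on the
likelihood-ratio scale, so the expected number of chance edges stays below
one at any marker count — and (b) requires an edge to be corroborated by a
common neighbour whenever both endpoints have other links. Genuine
within-chromosome edges lose nothing (a 2 cM-spaced neighbour has LOD ~25 and
dozens of common neighbours); the 13-chromosome recovery property then holds
in every seed tested. Both behaviours are switchable (`genomewide`,
`triangle_support`).

Completely linked markers (r = 0 among informative progeny) collapse into
blocks with a phase-aligned majority consensus pattern. Block ordering
minimises the sum of adjacent recombination fractions — solved exactly by
Held-Karp dynamic programming up to 10 blocks, and by nearest-neighbour
construction with 2-opt refinement beyond; the exact solver is the test
oracle for the heuristic. Positions are cumulative Haldane distances, and a
group and its reversal are the same map (the order is canonicalised by the
lexicographically smaller endpoint).

## Reconciliation

Scaffolds anchor to the LG of their markers; a scaffold whose markers hit
two LGs is a chimera candidate, and the boundary interval between the two
marker ranges is searched for a cut point: a lone `N` if one exists
(preferred), else the midpoint of the first `N`-run; an interval with no `N`
at all leaves the scaffold unsplit and flagged, and it is excluded from the
conservative tier. The junction `N` is removed from both pieces, which are
renamed `id_1`, `id_2` left to right.

Proximity clusters map to LGs by exact maximum-weight assignment on the
shared-bp matrix (a bitmask dynamic program — small cluster counts make this
cheap and deterministic). Ordering concordance is Kendall tau-b over the
scaffolds placed by both methods, with scaffolds in one linkage block
order-tied.

Inversion detection scans the proximity order for maximal runs of
non-increasing linkage ranks (ties never break a run, but are never evidence
either — `min_segment = 2` keeps single-scaffold swaps, which the map cannot
resolve, out of scope). A run is accepted only if reversing it strictly
increases the number of concordant adjacent pairs: this prevents
flip-flopping on noise. Because a linkage group and its reversal are
equivalent, candidate runs are evaluated under both map orientations and the
orientation whose corrected order ends most concordant wins; global-tau
alignment alone mis-orients a group when an inversion spans most of it.
Accepted segments are reversed in place — order flipped, orientations
complemented, `?` preserved — and every scaffold lands in one tier:
`both_consistent`, `proximity_only`, `clustered_unordered` (including split
pieces whose marker LG contradicts their cluster, which are reassigned to
the matching cluster but cannot be ordered there by proximity), or
`unclustered`. Tier accounting conserves scaffold count and total bp, and
reconciliation is idempotent on its own output.

## Synteny

Anchors (e-value <= 1e-4, self-hits and symmetric duplicates removed, tandem
self-hits within 5 gene positions collapsed) are chained per chromosome pair
by sparse dynamic programming under the classic DAGChainer regime: monotone
gene order on both sides (parallel or antiparallel), adjacent gaps at most
40 genes per side, chain score = 10 per anchor minus 1 per skipped gene per
side, blocks extracted greedily by descending score with used anchors
retired, and blocks with fewer than 5 anchors discarded. The scoring
constants are conventions, not results — every acceptance-level behaviour
depends only on the gap ceiling and anchor minimum. Chains are exactly
optimal (exhaustive-enumeration oracle at <= 12 anchors backs this in the
tests). Syntenic depth counts blocks overlapping each 20-gene window (both
sides count in self-comparisons); coverage is the length fraction of genes in
at least one block.

## Ks estimation and deduplication

`ng86_ks()` implements Nei-Gojobori (1986) site counting (per-position
synonymous fractions; changes to stops count as nonsynonymous), pathway
averaging for multi-hit codons (stop-crossing pathways excluded, with a
fallback when all pathways cross a stop), and the Jukes-Cantor correction
`Ks = -3/4 ln(1 - 4/3 pS)`. Pairs at `pS >= 3/4` are outside the correction's
domain and flagged saturated. This closed-form estimator replaces
likelihood-based codon models deliberately: it is dependency-free, exactly
symmetric, fast enough for thousands of pairs, and unbiased where the
validation operates (Ks <= 1); above Ks ~1.5 it inflates — the recovered old
peak sits slightly above its generating mean — which is a known saturation
property, not a defect the tests hide.

Gene families are connected components of the filtered hit graph (on clean
synthetic graphs this is identical to heavier clustering engines). Within a
family, the pairwise Ks matrix is reduced by average-linkage hierarchical
clustering to one value per internal node — the mean of the pairwise values
first joined there — giving exactly n-1 values per n-gene family. This is
the redundancy correction: a family of 2^k genes from k nested WGDs
contributes 2^k - 1 node values at the k true depths instead of
2^(k-1) x (2^k - 1) pairwise values dominated by the oldest event. Saturated
entries are imputed as the family maximum; node values above the Ks cap
(default 3, configurable) are excluded and counted. Ortholog samples come
from reciprocal best hits by score, ties dropped on both sides.

## Peak significance, mixtures, and WGD calls

The SiZer map evaluates the KDE derivative and its standard error on a
401-point grid over [0, 3] across 15 log-spaced bandwidths spanning 0.5-4x
the Silverman bandwidth. Significance at alpha = 0.05 is simultaneous per
bandwidth row via the effective-independent-blocks adjustment: the row
quantile is `qnorm((1 + (1 - alpha)^(1/m))/2)` with `m = range/(2h)` blocks.
Cells whose effective sample size (kernel-weighted local count) falls below
5 are coded sparse. A peak is a significant-increase run followed by a
significant-decrease run; only features persisting across at least two
adjacent bandwidths are counted, the count is the maximum over bandwidths,
and reported intervals come from the smoothest bandwidth achieving it.

Mixtures are fitted by EM (log-sum-exp E-step; degenerate components with
sd < 1e-4 or weight < 1e-3 rejected within a start; the ascent property is
asserted on every accepted run) from 20 random plus 5 k-means starts per
component count — a deliberate reduction from the hundreds of starts used by
batch tools, since the convergence basin for well-separated 1-D mixtures is
wide and all downstream checks are tolerance-based. Selection is by
`BIC = -2 loglik + (3k - 1) ln n`. BIC routinely prefers more components
than there are significant modes, so only components whose mean falls inside
a SiZer peak interval are reported (the rest are retained but suppressed),
and a reported component with mean below 0.25 is flagged as recent
background duplication/loss rather than WGD — a configurable recency
threshold mirroring how such third peaks are interpreted in diploids.

Reported component means are grouped across genomes by single linkage at a
Ks tolerance of 0.25 — half the separation of the two canonical peaks, and
larger than the between-genome scatter rate heterogeneity produces. Each
group is one WGD call; calls supported by more than one genome are shared.
Placement against a speciation event compares the call's Ks mean to the mode
of the ortholog Ks sample (KDE argmax at a Sheather-Jones plug-in
bandwidth, falling back to Silverman when the plug-in fails): more than
delta above is `before_speciation`, more than delta below is
`after_speciation`, else `indistinguishable`, where delta is half the larger
KDE peak half-width at half maximum — a scale-aware dead zone so that
overlapping peaks are never over-interpreted.

## Problem sizes and numerical choices

The validation conditions are: 13 chromosomes x 100 genes for linkage-group
recovery (110 progeny, 50 markers/chromosome); 6 chromosomes x 60 genes with
8 chimeras and 2 inversions (and several seeds) for reconciliation; 8
chromosomes x 70 genes per genome for the two-genome shared-WGD run; 20,000
draws for mixture recovery. These sizes keep every property measurable in
seconds while leaving the planted signals comfortably above their detection
thresholds — e.g. a paranome of ~600 deduplicated values is ample for SiZer
at the planted separations, and was chosen for that reason, not tuned to it.

Ties and degenerate inputs: Nxx statistics break length ties by descending
length then id; `r = 0.5` is a domain error for Haldane distance (unlinked);
all-missing marker pairs carry `NA` with their zero informative count;
empty anchor sets yield empty block tables rather than errors; a Ks sample
below 20 values yields an all-sparse SiZer map with a warning.

## Known limitations

The NG86/JC estimator saturates above Ks ~1.5 and the old-peak mean is
recovered high by roughly 0.1-0.2 at the default gene length; the synthetic
cross has no genotyping error model beyond missingness; the proximity
simulator plants only inversions, not translocation-style cluster errors;
and no absolute dating (Ma) is attempted — placement is strictly relative to
speciation modes.
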