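---
title: "Methods: centromere-spanning haplotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centromere-spanning haplotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenhaps)
```

## The problem

Human centromeres sit inside megabase-scale α-satellite arrays that
are absent from the reference assembly, so conventional maps treat the
centromere-proximal regions (CPRs) as a gap. Crossing over is
suppressed in and around these arrays, which has a strong population
genetic consequence: the SNPs flanking the gap are held together in
enormous linkage blocks — centromere-spanning haplotypes, or
*cenhaps* — whose genealogy can be very deep. Some cenhaps descend
from archaic hominins (Neanderthal/Denisovan-like lineages) and
re-entered the modern gene pool by introgression; cenhaps also differ
heritably in the size of their α-satellite arrays.

This package implements the full analysis chain on phased genotypes:

1. extraction of biallelic SNPs around a centromeric gap
   (`readVcfRegion()`), with minor-allele-count (MAC) filtering and
   interval masks;
2. pairwise LD via the 2×2 χ² test for allelic independence
   (`ldMatrix()`);
3. a windowed four-gamete filter for genotyping errors
   (`fourgtDco()`);
4. Hamming-distance UPGMA clustering into cenhap groups
   (`hammingMatrix()`, `upgma()`, `cutTree()`);
5. archaic affinity classification (`countArchaic()`,
   `summarizeByCenhap()`);
6. Nei–Gojobori (1986, method I) coding divergence/diversity and
   calibrated TMRCAs (`ng86Pair()`, `tmrcaTree()`);
7. α-satellite array-size estimation from centromeric read counts
   (`normalizeArrayCounts()`, `summarizeByGenotype()`);
8. a coalescent-style simulator that generates every input with known
   truth (`simulateGenealogy()` and friends).

## The four-gamete "double crossover" filter

Under an infinite-sites model without recombination, two linked SNPs
can show at most three of the four gametes 00/01/10/11. In a region of
suppressed crossing over, a genotyping error (or a one-SNP gene
conversion tract) makes a single site behave like a double crossover:
it conflicts with the surrounding haplotype structure on *both* sides
while the surrounding SNPs agree with each other.

`pairFails()` encodes exactly that signature: a flanking pair (left,
right) fails a focal SNP when the focal SNP shows all four gametes
with **each** of the two flanks while the flanks do not show all four
gametes between themselves. We considered the weaker reading in which
one conflicting flank suffices (`combine = "or"`, available as an
option together with `"xor"`), and rejected it as the default after
simulation: on error-injected data the one-sided rule removes nearly
half of the error-free SNPs, because any clean SNP that happens to
conflict with a nearby *error* SNP is itself discarded. The two-sided
rule is both the literal double-crossover signature and the variant
that behaves like an error filter rather than a region shredder.

`fourgtDco()` applies the test in passes of growing half-windows
(±10, ±20, ±30, ±40 surviving SNPs by default), scanning focal SNPs
5′→3′; within a pass every left×right combination in the window is
counted and the focal SNP is removed as soon as its failing-pair
count strictly exceeds the `tolerance` (so `tolerance = 0` still
permits zero failures). Removal is immediate: downstream windows see
the already-thinned surviving set. Edge SNPs with no surviving
neighbour on one side cannot be tested and are never removed. The
four-gamete status of a pair depends only on the two columns, so the
filter precomputes one S×S indicator (`fourGameteMatrix()`) and all
passes are pure window bookkeeping.

Measured behaviour on simulated data (200 haplotypes, ~1000 SNPs,
0.3% per-allele flips, tolerance 0): 70–90% of error-bearing sites
are removed. At that error density nearly half of all sites carry at
least one flip, and surviving error sites act as hazards for their
clean neighbours, so 10–20% of clean sites are also removed. Users
filtering data with error densities that high should prefer a nonzero
tolerance (the tolerance-3 setting used for real autosomal data is a
sensible default there).

## LD statistics

`chi2Independence()` is the plain Pearson χ² for a 2×2 gamete table
(1 df, no continuity correction, no exact-test fallback), with the p
value from the upper χ²(1) tail. Pairs with a zero marginal
(monomorphic column) are flagged `defined = FALSE` rather than given
an arbitrary value. `-log10(p)` is capped at the floating-point tail
floor (~323.3); the cap is recorded in the output so plots can label
saturated values honestly.

## Clustering and cenhap groups

`hammingMatrix()` returns raw mismatch counts over the chosen central
SNP subset (sites immediately flanking the gap, where exchange is
rarest). `upgma()` is written here so that tie-breaking is
deterministic (lexicographically smallest index pair) and node
heights are *half* the average inter-cluster distance — heights are
then in the same units per-lineage as divergence, which is what the
TMRCA calibration consumes. The result is a standard `hclust` object,
ultrametric by construction; `stats::hclust(method = "average")`
serves as an independent cross-check in the test-suite (its heights
are exactly twice ours).

`cutTree()` converts one or more height (or `k`) cuts into a
`CenhapPartition`; labels are assigned in decreasing group-size order
with nested re-cuts producing dotted labels ("2.1"). An explicit
labeling map, not a convention, is the interface: figure-specific
orderings belong to the caller.

Apparent recombinants between cenhaps are not defined operationally
in the source methods; `findRecombinants()` uses a left/right-flank
rule (cluster each flank separately into k groups; flag haplotypes
whose right-flank group disagrees with their left-flank group's
majority pairing) and records that rule in its output attributes.
Flagged haplotypes are excluded from divergence/TMRCA analyses when
more than 10 are found, mirroring the ">10" exclusion used for the
real data.

`matchDiploid()` implements the unphased-diploid matching used for
the HuRef genome: per candidate individual, sites are classified as
two-allele mismatches (0/0 vs 1/1), one-allele mismatches (hom vs
het) or matches, and the individual minimizing total mismatching
alleles supplies the cenhap genotype.

## Archaic affinity

Sites are polarized by the chimpanzee outgroup ("derived" = differs
from the outgroup allele) and each haplotype allele is classified
against each archaic source as DM/DN/AM/AN (derived/ancestral in the
archaic × match/non-match in the haplotype). Per haplotype the four
classes partition the usable sites — asserted in the tests. A site is
usable only when the outgroup allele equals the site's ref or alt
allele (no polarization otherwise) and the archaic state is a single
defined base; heterozygous archaic genotypes are treated as missing.
Group summaries report means with normal-approximation 95% CIs (mean
± 1.96·SE; flagged undefined below n = 2) and the introgression
ratios DM/(DM+DN) and DM/(DM+AN) computed from group means.

## Coding divergence, diversity and TMRCAs

`ng86Sites()`/`ng86Pair()` implement Nei–Gojobori method I:
per-codon synonymous site fractions from one-step enumeration
(changes to stop codons count as nonsynonymous; s + n = 3), and
multi-difference codons resolved by averaging synonymous/
nonsynonymous step counts over all orderings of the single-base
steps, including pathways through stop codons (those steps are
nonsynonymous). Proportions get the Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is flagged saturated. π~s~/π~n~
(`groupDiversity()`) are *uncorrected* mean pairwise proportions —
the expected-heterozygosity convention. Alignments are validated
(equal length, in-frame, A/C/G/T, no internal stops) and rejected
with the gene named, never silently edited.

TMRCAs (`tmrcaTree()`): the across-gene mean synonymous divergence
matrix among cenhap groups (plus the outgroup) defines the consensus
UPGMA topology; for every node, each gene contributes
`calibrationAge × h_g(node) / h_g(root)` where `h_g` is half the mean
between-clade dS of that gene and the human–outgroup root is pinned
at 6.5 My. Node age is the across-gene mean with ±2 SD error bands;
genes with zero human–outgroup divergence are excluded with a
warning. `tmrcaByRatio()` is the one-line molecular-clock scaling
used for regions with too little coding sequence: a lineage r times
as diverged as an anchor of age T dates to r·T (e.g. 2.0 × 575 ky =
1.15 My).

## Array sizes

Stage 1 divides a sample's centromeric read count (unique plus
chromosome-specific multi-mappers) by the sample's mean chr1
unique-region coverage; stage 2 divides each chromosome's stage-1
size by the sample's sum over chromosomes, absorbing
library/technology differences in total centromeric representation.
No explicit batch covariates are modelled. On chrX, female (two-copy)
sizes are multiplied by 0.5 to plot on the male hemizygote scale.
Samples in the lowest size decile are flagged rather than corrected:
a small estimate can also mean the sample's arrays diverge from the
reference centromere model (reference bias), not that they are small.

## The simulator and what passing tests mean

`simulateGenealogy()` is a structured coalescent over a single
non-recombining central locus: a modern population (default diploid
N = 10,000) and an archaic side (default N = 2,500, the smaller
archaic effective size) that split 575 ky ago (generations of 29 y);
two sampled archaic genomes split at 400 ky; a binomial 5% of sampled
tips take the introgressed lineage, entering the archaic population
at the 55 ky admixture pulse; the outgroup joins at the 6.5 My
calibration age. Defaults are the study conditions, chosen once:
sample size 200, per-allele genotyping error 0.3%, zero crossing over
centrally. Infinite-sites mutations are dropped on branches
proportionally to length (`dropMutations()`); only sites polymorphic
among the sampled modern haplotypes enter the matrix, with archaic
and outgroup states retained for `emitArchaicAnnotation()`.
Crossovers are confined to the flanks (`addFlankRecombination()`),
leaving the central genealogy untouched — deliberately not a full
ancestral-recombination-graph simulation. Codon alignments evolve by
proposal/acceptance with stop codons rejected, so equal
synonymous/nonsynonymous rates give a neutral dN/dS of 1.

Because introgression is a binomial draw over tips, a replicate can
realize introgressed tips that are *not* monophyletic (or none at
all); such replicates have no single "introgressed cenhap" and the
rank-ordering property is only asserted where the premise holds
(checked against the truth genealogy, never the clustering).

What the simulator does **not** emulate: genotype imputation
artefacts with spatial structure (errors are i.i.d. flips),
population structure within the modern sample, gene conversion
biased toward GC, α-satellite sequence evolution, and read-mapping
reference bias (array-size counts are drawn Poisson around truth).
Passing tests therefore demonstrate correctness of the statistics and
the filter dynamics under the stated model, not robustness to every
artefact of real 1000 Genomes data.

## Numerical and scale choices

* Filter problem sizes in the tests: oracle equivalence on 30×60
  matrices (100 replicates), recall/precision at 200 haplotypes ×
  1000 SNPs; both run in seconds because the pair indicator is
  computed once by cross-products.
* TMRCA recovery uses 30 genes × 500 codons and two haplotypes per
  lineage — the scale of a real centromere-proximal gene set (the
  real analyses used 21–37 genes). Much smaller gene sets leave the
  between-lineage ordering to Poisson noise: at 12 genes × 300
  codons only ~0.4 substitutions per gene separate the competing
  topologies.
* The bias-corrected (BC, non-accelerated) bootstrap percentile
  interval for cross-gene means is implemented directly (z0 from the
  bootstrap CDF at the point estimate, quantile type 6) and checked
  against a plain percentile bootstrap on symmetric data.
* Coordinates are GRanges conventions throughout (1-based,
  inclusive); BED masks are converted on read.
* Determinism: UPGMA ties break on the smallest index pair; partition
  labels order by size then smallest haplotype id, so partitions are
  invariant to haplotype input order; all simulators take explicit
  seeds and `runPipeline()` derives per-stage seeds from the config
  seed, making artifacts byte-identical across reruns.

## Known limitations

* The four-gamete filter's clean-site specificity degrades when a
  large fraction of sites carry errors (see above); tolerance 0 is
  aggressive at 0.3% per-allele error and 200 haplotypes.
* `upgma()` is O(n³) in haplotypes; clustering thousands of
  haplotypes is feasible but not fast.
* `tmrcaTree()` derives its topology from the mean dS matrix; nodes
  of the true history absent from that consensus cannot be dated.
* Per-gene calibration is a ratio estimator: dividing by each gene's
  (Poisson-noisy) human–outgroup divergence biases node ages upward
  by roughly the squared coefficient of variation of the per-gene
  root divergence (~10% at 10 synonymous root differences per gene).
  The ±2 SD bands comfortably cover the truth in the recovery tests,
  but point ages for weakly diverged gene sets run slightly old.
* The archaic-affinity ratios are computed over sites ascertained as
  polymorphic in the modern sample, which inflates both DM/(DM+DN)
  and its similarity between archaic sources relative to an
  unascertained site set; comparisons should stay within one panel.
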