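# cenhaps

Analysis of **centromere-spanning haplotypes (cenhaps)** from phased
SNP genotypes. Crossing over is suppressed in and around the
α-satellite arrays at human centromeres, so the SNPs flanking a
centromeric assembly gap travel together as enormous haplotypes whose
genealogies can predate modern humans — some descend from Neanderthal
or Denisovan-like lineages, and cenhaps differ heritably in
α-satellite array size. This package provides the full desk-scale
toolchain for finding and characterizing them, plus a truth-tracked
simulator for validating every step.

For whom: population geneticists working with phased panels (e.g.
1000 Genomes-style VCFs) around centromeres or other recombination
deserts.

## What it computes

| Step | Functions | Statistic |
|---|---|---|
| Region extraction | `readVcfRegion`, `centralSubset` | phased 0/1 haplotype matrix, MAC ≥ threshold, masks excluded |
| LD | `ldMatrix`, `chi2Independence` | 2×2 Pearson χ² for allelic independence, −log10 p |
| Error filter | `fourgtDco` | windowed four-gamete "double crossover" filter: focal SNP removed when its count of flanking pairs (left, right) with all four gametes against *both* flanks — flanks agreeing between themselves — exceeds the tolerance; passes at ±10, ±20, ±30, ±40 surviving SNPs, 5′→3′ |
| Clustering | `hammingMatrix`, `upgma`, `cutTree` | Hamming distances, deterministic UPGMA (heights = mean distance/2), height/k cuts into cenhap groups |
| Archaic affinity | `countArchaic`, `summarizeByCenhap` | per-haplotype DM/DN/AM/AN vs archaic genomes polarized by chimpanzee; group means, 95% CIs, DM/(DM+DN), DM/(DM+AN) |
| Coding divergence | `ng86Pair`, `groupDiversity`, `bootstrapCi` | Nei–Gojobori (1986) method I: pathway-averaged Sd/Nd, JC-corrected dS/dN, π_s/π_n, BC bootstrap CIs |
| TMRCA | `tmrcaTree`, `tmrcaByRatio` | node ages calibrated to a 6.5 My human–chimpanzee root, ±2 SD across genes; divergence-ratio clock scaling |
| Array size | `normalizeArrayCounts`, `summarizeByGenotype` | read counts / chr1 coverage, within-sample proportions, ecdfs by cenhap genotype (chrX females ×0.5) |
| Simulation | `simulateGenealogy`, `dropMutations`, `injectErrors`, ... | structured coalescent with archaic split, introgression pulse, flank-only crossover, genotyping errors, codon evolution, count tables |
| Orchestration | `runPipeline`, `validateConfig` | config-driven extract→filter→cluster→archaic→divergence→arraysize with TSV/newick artifacts and a JSON manifest |

## Worked example

Simulate a paper-like panel (100 haplotypes, archaic split 575 ky,
5% introgression, 0.3% genotyping error), filter, cluster, and score
archaic affinity:

```r
library(cenhaps)
p   <- simParams(nHaplotypes = 100, seed = 7)
sim <- simulateGenealogy(p)
sh  <- injectErrors(dropMutations(sim, nSites = 2e5), 0.003)
m   <- sh$matrix
m
#> HaplotypeMatrix: 100 haplotypes x 695 biallelic SNPs
#>   chrSim:197-199908
#>   MAC range: 1-48

res <- fourgtDco(m, fourgtConfig(tolerance = 3))
res
#> 4gt filter: 577 SNPs surviving, 118 removed (per pass: 35, 33, 22, 28)

flt  <- m[, res$surviving]
part <- cutTree(upgma(hammingMatrix(flt)), k = 2)
part
#> CenhapPartition: 100 haplotypes in 2 cenhap group(s)
#>   sizes: 1=89, 2=11

s <- summarizeByCenhap(countArchaic(flt, emitArchaicAnnotation(sh))$counts, part)
s[s$source == "nea", c("group","n","DM_mean","DN_mean","ratio_dmdn","ratio_dman")]
#>  group  n      DM_mean    DN_mean   ratio_dmdn   ratio_dman
#>      1 89   0.06741573 108.932584 0.0006184929 0.0005742726
#>      2 11 105.45454545   3.545455 0.9674728941 0.9191759113
```

The small cenhap group 2 holds the 11 introgressed haplotypes: it
carries 97% of the Neanderthal-derived alleles it could share
(DM/(DM+DN) = 0.967) versus 0.06% for the majority cenhap — the
signature of an introgressed archaic centromere. A lineage twice as
diverged as a 575 ky Neanderthal anchor dates by clock scaling to

```r
tmrcaByRatio(2.0, 575e3)
#> [1] 1150000
```

i.e. ~1.15 My. The same steps run end-to-end from a config via
`runPipeline()`, writing TSV/newick artifacts and a manifest.

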