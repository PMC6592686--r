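Package: cenhaps
Title: Centromere-Spanning Haplotype Analysis from Phased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and analyses centromere-spanning haplotypes
    (cenhaps) from phased SNP genotypes flanking centromeric assembly
    gaps. Provides region extraction with minor-allele-count filtering
    and interval masking, pairwise linkage-disequilibrium chi-squared
    statistics, a windowed four-gamete-test filter for genotyping
    errors and single-site gene conversions, Hamming-distance UPGMA
    clustering of haplotypes into cenhap groups, classification of
    haplotype alleles against archaic (Neanderthal/Denisovan-like)
    genomes polarized by an outgroup, Nei-Gojobori synonymous and
    nonsynonymous divergence and diversity with calibrated TMRCA
    estimation, alpha-satellite array-size estimation from normalized
    centromeric read counts, and a coalescent-style simulator that
    generates all pipeline inputs with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
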