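# Fixture builders (all in code; no binary files).

# write a small phased VCF; gts is a list of per-sample genotype
# string vectors (one element per site), e.g. c("0|1", "1|1") or "1"
writeToyVcf <- function(path, chrom, pos, ref, alt, gts) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(gts)), collapse = "\t"))
  body <- vapply(seq_along(pos), function(k)
    paste(c(chrom, pos[k], ".", ref[k], alt[k], ".", "PASS", ".", "GT",
            vapply(gts, `[`, character(1), k)), collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

# the 6 haplotype x 4 site toy used across the IO tests
toyVcf <- function(path = tempfile(fileext = ".vcf")) {
  writeToyVcf(path, "chr1", c(100, 200, 300, 400),
              rep("A", 4), rep("G", 4),
              list(s1 = c("0|1", "0|0", "1|1", "0|1"),
                   s2 = c("1|0", "0|1", "0|0", "1|1"),
                   s3 = c("0|0", "1|0", "1|0", "0|0")))
}

# expected allele matrix of toyVcf (haplotypes x sites)
toyAlleles <- function() {
  m <- rbind(s1_1 = c(0, 0, 1, 0), s1_2 = c(1, 0, 1, 1),
             s2_1 = c(1, 0, 0, 1), s2_2 = c(0, 1, 0, 1),
             s3_1 = c(0, 1, 1, 0), s3_2 = c(0, 0, 0, 0))
  storage.mode(m) <- "integer"
  m
}

# perfect-phylogeny (infinite sites, no recombination) matrix: two
# clades of nHap/2 haplotypes; sites alternate clade-diagnostic and
# subclade/singleton sites, so no pair shows four gametes
perfectTreeMatrix <- function(nHap = 30, nSites = 50) {
  stopifnot(nHap %% 2 == 0)
  half <- nHap / 2
  a <- matrix(0L, nHap, nSites)
  for (s in seq_len(nSites)) {
    type <- s %% 3
    if (type == 0) a[seq_len(half), s] <- 1L            # clade 1 marker
    else if (type == 1) a[half + seq_len(half %/% 2), s] <- 1L  # subclade
    else a[((s * 7) %% nHap) + 1L, s] <- 1L             # singleton
  }
  HaplotypeMatrix(a, chrom = "chrT", pos = seq_len(nSites) * 10L)
}

# simulated error-free haplotypes from the coalescent generator
simMatrix <- function(seed, nHap = 30, nSites = 1e5, ...) {
  p <- simParams(nHaplotypes = nHap, genotypingErrorRate = 0,
                 seed = seed, ...)
  dropMutations(simulateGenealogy(p), nSites = nSites)$matrix
}

# random 0/1 matrix as HaplotypeMatrix
randomMatrix <- function(nHap, nSites, pOne = 0.5) {
  a <- matrix(as.integer(runif(nHap * nSites) < pOne), nHap, nSites)
  # avoid monomorphic columns so the four-gamete test is exercised
  for (s in which(colSums(a) %in% c(0L, nHap))) {
    a[sample.int(nHap, 1), s] <- 1L - a[1, s]
  }
  HaplotypeMatrix(a, chrom = "chrR", pos = seq_len(nSites))
}
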