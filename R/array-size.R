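#' Stage-1 array-size normalization
#'
#' Centromeric read counts (unique + chromosome-specific multi-mapping
#' reads) divided by the sample's mean coverage of chr1 unique
#' regions, giving an array-size estimate in bases-per-1x-coverage
#' units. Scale-invariant: doubling both count and coverage leaves the
#' estimate unchanged.
#'
#' @param rawCount nonnegative read count(s).
#' @param chr1MeanCoverage positive mean coverage; a zero coverage is
#'   an error (such samples are excluded upstream).
#' @return numeric size estimate(s).
#' @export
normalizeStage1 <- function(rawCount, chr1MeanCoverage) {
  if (any(chr1MeanCoverage <= 0))
    stop("zero/negative chr1 coverage; exclude the sample")
  rawCount / chr1MeanCoverage
}

#' Stage-2 within-sample proportion normalization
#'
#' Divides each chromosome's stage-1 size by the sample's sum over all
#' chromosomes, absorbing library/technology batch variation in total
#' centromeric representation. Output sums to 1 and preserves order.
#'
#' @param stage1Sizes numeric vector of one sample's per-chromosome
#'   stage-1 sizes.
#' @return proportions summing to 1.
#' @export
normalizeStage2 <- function(stage1Sizes) {
  s <- sum(stage1Sizes)
  if (s <= 0) stop("all-zero sample; exclude")
  stage1Sizes / s
}

#' Normalize a raw centromeric count table
#'
#' Applies both normalization stages to a long-format count table.
#' Samples with zero chr1 coverage or an all-zero count row are
#' excluded with a message.
#'
#' @param counts data.frame with columns `sample`, `chrom`,
#'   `cen_count`, `chr1_mean_cov`.
#' @return the table with added columns `size1` (stage 1) and `prop`
#'   (stage 2), excluded samples dropped.
#' @export
normalizeArrayCounts <- function(counts) {
  stopifnot(all(c("sample", "chrom", "cen_count", "chr1_mean_cov")
                %in% names(counts)))
  bad.cov <- unique(counts$sample[counts$chr1_mean_cov <= 0])
  zero <- vapply(split(counts$cen_count, counts$sample), function(v)
    all(v == 0), logical(1))
  bad <- union(bad.cov, names(zero)[zero])
  if (length(bad))
    message("excluding ", length(bad),
            " sample(s) with zero coverage or all-zero counts")
  counts <- counts[!(counts$sample %in% bad), , drop = FALSE]
  counts$size1 <- normalizeStage1(counts$cen_count, counts$chr1_mean_cov)
  counts$prop <- stats::ave(counts$size1, counts$sample,
                            FUN = function(v) v / sum(v))
  counts
}

#' Summarize array sizes by cenhap genotype
#'
#' Groups per-sample array-size estimates by cenhap genotype (e.g.
#' `3_3`, `3_4`, `4_4`) and returns per-genotype empirical cumulative
#' distributions and means. For chrX, female (two-array) sizes are
#' multiplied by `chrXFemaleFactor` so they plot on the hemizygote
#' male single-array scale. Samples in the lowest decile of size are
#' flagged (`ref_bias_flag`): small estimates can also reflect
#' divergence of the sample's arrays from the reference centromere
#' model rather than genuinely small arrays.
#'
#' @param sizes named numeric vector of per-sample size estimates
#'   (stage 1 or stage 2, one chromosome).
#' @param genotypes named character vector of cenhap genotypes per
#'   sample.
#' @param sex optional named character vector (`"M"`/`"F"`) per
#'   sample; required when `chrX = TRUE`.
#' @param chrX apply the female scaling factor.
#' @param chrXFemaleFactor multiplier for female sizes on chrX.
#' @return list of class `genotypeSizeSummary`: `table` (data.frame
#'   genotype, n, mean), `ecdf` (named list of `ecdf` functions),
#'   `sizes` (the possibly rescaled sizes), `flagged` (sample ids in
#'   the lowest decile).
#' @export
summarizeByGenotype <- function(sizes, genotypes, sex = NULL, chrX = FALSE,
                                chrXFemaleFactor = 0.5) {
  common <- intersect(names(sizes), names(genotypes))
  sizes <- sizes[common]; genotypes <- genotypes[common]
  if (chrX) {
    if (is.null(sex)) stop("sex is required for chrX scaling")
    f <- names(sizes)[sex[names(sizes)] == "F"]
    sizes[f] <- sizes[f] * chrXFemaleFactor
  }
  flagged <- names(sizes)[sizes <= stats::quantile(sizes, 0.1)]
  gl <- unique(genotypes)
  tab <- data.frame(genotype = gl,
                    n = vapply(gl, function(g)
                      sum(genotypes == g), integer(1)),
                    mean = vapply(gl, function(g)
                      mean(sizes[genotypes == g]), numeric(1)))
  tab <- tab[tab$n > 0, , drop = FALSE]
  ec <- lapply(stats::setNames(tab$genotype, tab$genotype), function(g)
    stats::ecdf(sizes[genotypes == g]))
  structure(list(table = tab[order(tab$genotype), ], ecdf = ec,
                 sizes = sizes, flagged = flagged),
            class = "genotypeSizeSummary")
}

#' @export
print.genotypeSizeSummary <- function(x, ...) {
  cat("Array size by cenhap genotype:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Read a centromeric count TSV
#'
#' Columns: sample, chrom, cen_count, chr1_mean_cov.
#' @param path TSV path.
#' @return data.frame.
#' @export
readArrayCounts <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
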