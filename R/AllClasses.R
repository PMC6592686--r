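#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges findOverlaps reduce
#' @importFrom S4Vectors mcols mcols<- queryHits
NULL

setOldClass("hclust")

#' Phased haplotype matrix over biallelic SNPs
#'
#' The central container of the package: an H x S matrix of phased
#' alleles (0 = reference, 1 = alternate) for H haplotypes at S
#' biallelic SNPs, together with per-site metadata (position, ref/alt
#' allele, minor allele count) held as a [GenomicRanges::GRanges].
#' Haplotypes are rows; sites are columns, strictly ordered by
#' position. Matrices carry no missing entries: inputs are expected to
#' be fully phased/imputed and the loader rejects missing calls.
#'
#' @slot alleles integer matrix in {0,1}, rownames are haplotype ids.
#' @slot sites `GRanges` of width-1 SNP positions with metadata columns
#'   `ref`, `alt` (single bases) and `mac` (minor allele count).
#' @slot region `GRanges` of the interval(s) the sites were drawn from
#'   (may be empty when unknown).
#'
#' @seealso [HaplotypeMatrix()] the constructor, [readVcfRegion()]
#' @exportClass HaplotypeMatrix
setClass("HaplotypeMatrix",
  representation(alleles = "matrix", sites = "GRanges", region = "GRanges"))

setValidity("HaplotypeMatrix", function(object) {
  a <- object@alleles
  s <- object@sites
  msg <- character()
  if (anyNA(a)) msg <- c(msg, "allele matrix contains missing entries")
  else if (length(a) && !all(a %in% c(0L, 1L)))
    msg <- c(msg, "allele matrix entries must be 0 or 1")
  if (ncol(a) != length(s))
    msg <- c(msg, "number of allele columns must equal number of sites")
  if (is.null(rownames(a)) && nrow(a) > 0)
    msg <- c(msg, "haplotype ids (rownames) are required")
  if (length(s)) {
    mc <- mcols(s)
    if (!all(c("ref", "alt", "mac") %in% names(mc)))
      msg <- c(msg, "sites need metadata columns ref, alt, mac")
    else {
      if (any(nchar(mc$ref) != 1L) || any(nchar(mc$alt) != 1L) ||
          any(mc$ref == mc$alt))
        msg <- c(msg, "sites must be biallelic SNPs (single, distinct bases)")
      by.chr <- split(start(s), as.character(seqnames(s)))
      if (!all(vapply(by.chr, function(p) all(diff(p) > 0), logical(1))))
        msg <- c(msg, "site positions must be strictly increasing within chromosome")
      if (nrow(a) > 0) {
        n1 <- colSums(a)
        mac <- pmin(n1, nrow(a) - n1)
        if (!all(mc$mac == mac))
          msg <- c(msg, "stored mac must equal min(#0, #1) per column")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param alleles numeric/integer matrix of 0/1 phased alleles,
#'   haplotypes in rows (rownames = haplotype ids), sites in columns.
#' @param chrom chromosome name(s), recycled over sites.
#' @param pos 1-based SNP positions, strictly increasing per chromosome.
#' @param ref,alt single-character reference/alternate alleles.
#' @param region optional `GRanges` describing the source interval(s).
#' @return a [HaplotypeMatrix-class] object; `mac` is computed from the
#'   columns.
#' @examples
#' m <- HaplotypeMatrix(matrix(c(0,1,0,1,0,1), 3, 2,
#'                             dimnames = list(c("a","b","c"), NULL)),
#'                      chrom = "chr1", pos = c(100, 200))
#' nSites(m)
#' @export
HaplotypeMatrix <- function(alleles, chrom = "chr1", pos = seq_len(ncol(alleles)),
                            ref = rep("A", ncol(alleles)),
                            alt = rep("G", ncol(alleles)),
                            region = GRanges()) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(rownames(alleles)) && nrow(alleles))
    rownames(alleles) <- paste0("hap", seq_len(nrow(alleles)))
  n1 <- if (nrow(alleles)) colSums(alleles) else integer(ncol(alleles))
  sites <- GRanges(rep(chrom, length.out = ncol(alleles)),
                   IRanges(pos, width = 1L))
  mcols(sites)$ref <- rep(ref, length.out = ncol(alleles))
  mcols(sites)$alt <- rep(alt, length.out = ncol(alleles))
  mcols(sites)$mac <- as.integer(pmin(n1, nrow(alleles) - n1))
  new("HaplotypeMatrix", alleles = alleles, sites = sites, region = region)
}

#' Cenhap partition of haplotypes
#'
#' Assignment of haplotypes to cenhap groups obtained by cutting a
#' UPGMA dendrogram at one or more heights. Group labels are integers
#' assigned in decreasing group-size order (label 1 = largest group);
#' nested re-cuts produce dotted labels such as `"2.1"`.
#'
#' @slot hapIds character, haplotype ids in matrix order.
#' @slot groups factor of group labels, one per haplotype.
#' @slot tree the `hclust` dendrogram the partition was cut from.
#' @slot cutSpec list recording the cut specification (height/k and any
#'   nested re-cuts).
#' @exportClass CenhapPartition
setClass("CenhapPartition",
  representation(hapIds = "character", groups = "factor",
                 tree = "hclust", cutSpec = "list"))

setValidity("CenhapPartition", function(object) {
  if (length(object@hapIds) != length(object@groups))
    return("one group label per haplotype required")
  if (anyNA(object@groups)) return("group labels must be exhaustive")
  TRUE
})
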