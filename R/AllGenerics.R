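#' @rdname HaplotypeMatrix-class
#' @param x,object a `HaplotypeMatrix` or `CenhapPartition`.
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("siteMac", function(x) standardGeneric("siteMac"))

#' @rdname CenhapPartition-class
#' @param x a `CenhapPartition`.
#' @export
setGeneric("cenhapGroups", function(x) standardGeneric("cenhapGroups"))

#' @rdname CenhapPartition-class
#' @export
setGeneric("cenhapTree", function(x) standardGeneric("cenhapTree"))

setMethod("hapIds", "HaplotypeMatrix", function(x) rownames(x@alleles))
setMethod("alleleMatrix", "HaplotypeMatrix", function(x) x@alleles)
setMethod("sites", "HaplotypeMatrix", function(x) x@sites)
setMethod("nHap", "HaplotypeMatrix", function(x) nrow(x@alleles))
setMethod("nSites", "HaplotypeMatrix", function(x) ncol(x@alleles))
setMethod("siteMac", "HaplotypeMatrix", function(x) mcols(x@sites)$mac)

setMethod("hapIds", "CenhapPartition", function(x) x@hapIds)
setMethod("cenhapGroups", "CenhapPartition", function(x)
  stats::setNames(x@groups, x@hapIds))
setMethod("cenhapTree", "CenhapPartition", function(x) x@tree)

#' @rdname HaplotypeMatrix-class
#' @param i haplotype index (id, logical or integer).
#' @param j site index.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@alleles))
  if (missing(j)) j <- seq_len(ncol(x@alleles))
  a <- x@alleles[i, j, drop = FALSE]
  n1 <- if (nrow(a)) colSums(a) else integer(ncol(a))
  s <- x@sites[j]
  mcols(s)$mac <- as.integer(pmin(n1, nrow(a) - n1))
  new("HaplotypeMatrix", alleles = a, sites = s, region = x@region)
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nHap(object), "haplotypes x",
      nSites(object), "biallelic SNPs\n")
  if (nSites(object)) {
    rng <- range(start(object@sites))
    cat("  ", as.character(seqnames(object@sites))[1], ":",
        rng[1], "-", rng[2], "\n", sep = "")
    cat("  MAC range:", paste(range(siteMac(object)), collapse = "-"), "\n")
  }
})

setMethod("show", "CenhapPartition", function(object) {
  tab <- sort(table(object@groups), decreasing = TRUE)
  cat("CenhapPartition:", length(object@hapIds), "haplotypes in",
      length(tab), "cenhap group(s)\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})
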