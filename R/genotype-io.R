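#' Read phased genotypes from a VCF region into a HaplotypeMatrix
#'
#' Extracts biallelic SNPs from a (possibly mixed-ploidy) phased VCF,
#' keeping sites inside `region`, outside `masks`, with minor allele
#' count at least `minMac`. Diploid genotypes must be phased
#' (`|`-separated); haploid calls (e.g. male chrX) contribute a single
#' haplotype. Multi-allelic and indel records are skipped and counted
#' (reported via a message and the `"skipped"` attribute); a missing or
#' unphased diploid genotype is an error naming the offending site.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param region `GRanges` of one or more intervals to keep (1-based,
#'   inclusive), or `NULL` for all sites.
#' @param minMac minimum minor allele count (sites with `mac < minMac`
#'   are dropped).
#' @param masks `GRanges` of intervals to exclude, or `NULL`.
#' @param ploidyMode `"diploid"` (two haplotypes per sample),
#'   `"haploid"` (one), or `"mixed"` (per-genotype: haploid calls give
#'   one haplotype, phased diploid calls two; requires ploidy constant
#'   per sample across sites).
#' @return a [HaplotypeMatrix-class]; haplotype ids are `sample_1` /
#'   `sample_2` for diploids and the bare sample id for haploids. An
#'   empty region yields a 0-column matrix, not an error.
#' @export
readVcfRegion <- function(path, region = NULL, minMac = 0L, masks = NULL,
                          ploidyMode = c("diploid", "haploid", "mixed")) {
  ploidyMode <- match.arg(ploidyMode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1]
  nrec <- nrow(fix)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n.skipped <- sum(!snp)
  if (n.skipped)
    message(n.skipped, " multi-allelic/indel record(s) skipped")

  keep <- snp
  if (!is.null(region) && length(region)) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    keep <- keep & overlapsAny(gr, region)
  }
  if (!is.null(masks) && length(masks)) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    keep <- keep & !overlapsAny(gr, masks)
  }
  idx <- which(keep)
  if (!length(idx)) {
    out <- HaplotypeMatrix(matrix(integer(), nrow = 0, ncol = 0),
                           chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           region = if (is.null(region)) GRanges() else region)
    attr(out, "skipped") <- n.skipped
    return(out)
  }

  # strip any per-genotype FORMAT payload beyond GT
  gtm <- sub(":.*$", "", gt[idx, -1, drop = FALSE])
  if (anyNA(gtm)) {
    bad <- which(apply(gtm, 1, anyNA))[1]
    stop("missing genotype call at ", chrom[idx][bad], ":",
         pos[idx][bad], "; inputs must be fully imputed/phased")
  }
  if (any(grepl("\\.", gtm)))
    stop("missing genotype call at ", chrom[idx][which(apply(
      gtm, 1, function(r) any(grepl("\\.", r))))[1]], ":",
      pos[idx][which(apply(gtm, 1, function(r) any(grepl("\\.", r))))[1]],
      "; inputs must be fully imputed/phased")

  haps <- .expandGT(gtm, samples, ploidyMode, chrom[idx], pos[idx])
  m <- HaplotypeMatrix(haps, chrom = chrom[idx], pos = pos[idx],
                       ref = ref[idx], alt = alt[idx],
                       region = if (is.null(region)) GRanges() else region)
  if (minMac > 0) m <- m[, siteMac(m) >= minMac]
  attr(m, "skipped") <- n.skipped
  m
}

#' @importFrom IRanges overlapsAny
.expandGT <- function(gtm, samples, ploidyMode, chrom, pos) {
  nrec <- nrow(gtm)
  cols <- list()
  for (k in seq_along(samples)) {
    g <- gtm[, k]
    dip <- grepl("|", g, fixed = TRUE)
    if (any(grepl("/", g, fixed = TRUE))) {
      bad <- which(grepl("/", g, fixed = TRUE))[1]
      stop("unphased diploid genotype for sample ", samples[k], " at ",
           chrom[bad], ":", pos[bad])
    }
    if (all(dip)) {
      if (ploidyMode == "haploid")
        stop("diploid genotype for sample ", samples[k],
             " under ploidyMode='haploid'")
      sp <- strsplit(g, "|", fixed = TRUE)
      cols[[paste0(samples[k], "_1")]] <-
        as.integer(vapply(sp, `[`, character(1), 1L))
      cols[[paste0(samples[k], "_2")]] <-
        as.integer(vapply(sp, `[`, character(1), 2L))
    } else if (!any(dip)) {
      if (ploidyMode == "diploid")
        stop("haploid genotype for sample ", samples[k],
             " under ploidyMode='diploid'")
      cols[[samples[k]]] <- as.integer(g)
    } else {
      stop("sample ", samples[k], " mixes haploid and diploid calls")
    }
  }
  do.call(rbind, cols)
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Serializes the matrix to a minimal VCF 4.2 text file. Haplotype ids
#' of the form `sample_1`/`sample_2` are re-paired into phased diploid
#' genotype columns; any other ids are written as haploid calls.
#' Round-trips through [readVcfRegion()] with `minMac = 0` and no
#' masks.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
writeHaplotypeVcf <- function(x, path) {
  ids <- hapIds(x)
  a <- alleleMatrix(x)
  base <- sub("_[12]$", "", ids)
  phase <- ifelse(grepl("_[12]$", ids), sub("^.*_", "", ids), NA)
  gt.cols <- character(0)
  gt.mat <- NULL
  i <- 1L
  cols <- list()
  while (i <= length(ids)) {
    if (!is.na(phase[i]) && i < length(ids) && !is.na(phase[i + 1L]) &&
        base[i] == base[i + 1L] && phase[i] == "1" && phase[i + 1L] == "2") {
      cols[[base[i]]] <- paste0(a[i, ], "|", a[i + 1L, ])
      i <- i + 2L
    } else if (!is.na(phase[i])) {
      stop("cannot pair haplotype '", ids[i],
           "' into a diploid genotype column")
    } else {
      cols[[ids[i]]] <- as.character(a[i, ])
      i <- i + 1L
    }
  }
  s <- sites(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cenhaps",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(cols)), collapse = "\t"))
  if (length(s)) {
    body <- paste(as.character(seqnames(s)), start(s), ".",
                  mcols(s)$ref, mcols(s)$alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    for (cl in cols) body <- paste(body, cl, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Indices of sites in the central clustering subset
#'
#' Returns the (order-preserved) indices of sites falling inside either
#' of two intervals flanking the centromeric assembly gap, the subset
#' used for cenhap clustering. Errors if the intervals overlap each
#' other (they must sit on opposite sides of the gap).
#'
#' @param x a [HaplotypeMatrix-class].
#' @param left,right `GRanges` (length 1) of the p-side and q-side
#'   clustering intervals.
#' @return integer site indices.
#' @export
centralSubset <- function(x, left, right) {
  if (length(findOverlaps(left, right)))
    stop("left and right intervals must not overlap (they flank the gap)")
  gr <- sites(x)
  which(overlapsAny(gr, left) | overlapsAny(gr, right))
}

#' Export the site table
#'
#' @param x a [HaplotypeMatrix-class].
#' @param path optional TSV path; when `NULL` the data frame is
#'   returned only.
#' @return data.frame with columns chrom, pos, ref, alt, mac.
#' @export
siteTable <- function(x, path = NULL) {
  s <- sites(x)
  df <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                   ref = mcols(s)$ref, alt = mcols(s)$alt,
                   mac = mcols(s)$mac, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}

#' Read a BED file of mask intervals
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based
#' inclusive and reduced to non-overlapping intervals.
#'
#' @param path BED file (3+ columns, no header).
#' @return `GRanges` of masks.
#' @export
readMaskBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  reduce(GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]])))
}
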