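#' Classify one haplotype allele against an archaic genome
#'
#' Alleles are polarized by an outgroup (chimpanzee): "derived" means
#' different from the outgroup allele. Classes: DM (derived in archaic,
#' matching the haplotype), DN (derived in archaic, not matching), AM
#' (ancestral in archaic, matching), AN (ancestral in archaic, not
#' matching, i.e. derived in the haplotype). Sites lacking an outgroup
#' or archaic allele are "unusable".
#'
#' @param hapAllele,archaicAllele,outgroupAllele single-base strings
#'   (NA allowed, giving "unusable").
#' @return one of `"DM"`, `"DN"`, `"AM"`, `"AN"`, `"unusable"`.
#' @export
classifySite <- function(hapAllele, archaicAllele, outgroupAllele) {
  if (is.na(hapAllele) || is.na(archaicAllele) || is.na(outgroupAllele) ||
      nchar(archaicAllele) != 1L || nchar(outgroupAllele) != 1L)
    return("unusable")
  arch.derived <- archaicAllele != outgroupAllele
  hap.derived <- hapAllele != outgroupAllele
  if (arch.derived) {
    if (hapAllele == archaicAllele) "DM" else "DN"
  } else {
    if (hapAllele == archaicAllele) "AM" else "AN"
  }
}

#' Build/validate an archaic annotation table
#'
#' Per-site outgroup-polarized archaic states. A site is usable for a
#' source only when both the outgroup allele and that source's archaic
#' allele are defined single bases and the outgroup allele equals the
#' site's ref or alt allele (otherwise the site cannot be polarized).
#'
#' @param chrom,pos site coordinates.
#' @param outgroup outgroup (chimpanzee) alleles.
#' @param ... one or more named archaic allele vectors, e.g.
#'   `nea = ..., den = ...`.
#' @return data.frame with columns chrom, pos, outgroup and the archaic
#'   sources.
#' @export
archaicAnnotation <- function(chrom, pos, outgroup, ...) {
  src <- list(...)
  if (!length(src) || is.null(names(src)) || any(names(src) == ""))
    stop("supply named archaic allele vectors (e.g. nea=, den=)")
  data.frame(chrom = chrom, pos = as.integer(pos), outgroup = outgroup,
             src, stringsAsFactors = FALSE)
}

#' Read an archaic annotation TSV
#'
#' Expected columns: chrom, pos, outgroup, then one column per archaic
#' source.
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
readArchaicAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$pos <- as.integer(df$pos)
  df
}

#' Per-haplotype DM/DN/AM/AN counts against archaic sources
#'
#' Aligns the annotation to the matrix sites by (chrom, pos), restricts
#' to a region, and tallies the four classes per haplotype and source.
#' For every haplotype and source, DM + DN + AM + AN equals the number
#' of usable sites for that source.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param annot annotation from [archaicAnnotation()] /
#'   [readArchaicAnnotation()].
#' @param regionLimit optional `GRanges` restricting the counted sites.
#' @return list with `counts` (data.frame hap_id, source, DM, DN, AM,
#'   AN) and `usable` (named usable-site count per source). Errors if
#'   no source has a usable site.
#' @export
countArchaic <- function(x, annot, regionLimit = NULL) {
  s <- sites(x)
  key <- paste(as.character(seqnames(s)), start(s))
  akey <- paste(annot$chrom, annot$pos)
  hit <- match(key, akey)
  in.region <- if (is.null(regionLimit)) rep(TRUE, length(s))
               else overlapsAny(s, regionLimit)
  sources <- setdiff(names(annot), c("chrom", "pos", "outgroup"))
  a <- alleleMatrix(x)
  ref <- mcols(s)$ref; alt <- mcols(s)$alt
  out.al <- annot$outgroup[hit]
  polarizable <- !is.na(hit) & in.region & !is.na(out.al) &
    nchar(out.al) == 1L & (out.al == ref | out.al == alt)
  res <- list()
  usable.n <- integer(0)
  for (src in sources) {
    arch <- annot[[src]][hit]
    use <- polarizable & !is.na(arch) & nchar(arch) == 1L &
      arch %in% c("A", "C", "G", "T")
    if (!any(use)) { usable.n[src] <- 0L; next }
    # per usable site: derived state of archaic, and of each haplotype
    out.u <- out.al[use]; arch.u <- arch[use]
    ref.u <- ref[use]; alt.u <- alt[use]
    arch.derived <- arch.u != out.u
    # haplotype base at usable sites: 0 -> ref, 1 -> alt
    au <- a[, use, drop = FALSE]
    hap.base0 <- matrix(ref.u, nrow(au), ncol(au), byrow = TRUE)
    hap.base1 <- matrix(alt.u, nrow(au), ncol(au), byrow = TRUE)
    hb <- ifelse(au == 1L, hap.base1, hap.base0)
    arch.m <- matrix(arch.u, nrow(au), ncol(au), byrow = TRUE)
    ad <- matrix(arch.derived, nrow(au), ncol(au), byrow = TRUE)
    match.m <- hb == arch.m
    dm <- rowSums(ad & match.m)
    dn <- rowSums(ad & !match.m)
    am <- rowSums(!ad & match.m)
    an <- rowSums(!ad & !match.m)
    usable.n[src] <- sum(use)
    res[[src]] <- data.frame(hap_id = hapIds(x), source = src,
                             DM = dm, DN = dn, AM = am, AN = an,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(res)) stop("no usable archaic-annotated sites in region")
  list(counts = do.call(rbind, res), usable = usable.n)
}

#' Summarize archaic counts by cenhap group
#'
#' Group means of DM/DN/AM/AN per archaic source with normal-
#' approximation 95% confidence intervals (mean +/- 1.96 SE; flagged
#' undefined for groups of size < 2), introgression ratios computed
#' from group means — `ratio_dmdn = DM/(DM+DN)` and
#' `ratio_dman = DM/(DM+AN)` — and log2(count+1) display means.
#'
#' @param counts the `counts` element of [countArchaic()].
#' @param partition a [CenhapPartition-class] (or a named group vector).
#' @param exclude optional haplotype ids to drop (e.g. apparent
#'   recombinants from [findRecombinants()]).
#' @return data.frame, one row per cenhap x source, with columns n,
#'   mean/lo/hi per class, ratio_dmdn, ratio_dman, log2 means.
#' @export
summarizeByCenhap <- function(counts, partition, exclude = NULL) {
  grp <- if (is(partition, "CenhapPartition")) cenhapGroups(partition)
         else partition
  counts <- counts[!(counts$hap_id %in% exclude), , drop = FALSE]
  counts$group <- as.character(grp[counts$hap_id])
  if (anyNA(counts$group)) stop("partition does not cover all haplotypes")
  out <- list()
  for (src in unique(counts$source)) for (g in unique(counts$group)) {
    d <- counts[counts$source == src & counts$group == g, , drop = FALSE]
    n <- nrow(d)
    row <- list(group = g, source = src, n = n)
    for (cl in c("DM", "DN", "AM", "AN")) {
      v <- d[[cl]]
      m <- mean(v)
      se <- if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_
      row[[paste0(cl, "_mean")]] <- m
      row[[paste0(cl, "_lo")]] <- if (n >= 2) m - 1.96 * se else NA_real_
      row[[paste0(cl, "_hi")]] <- if (n >= 2) m + 1.96 * se else NA_real_
      row[[paste0(cl, "_log2")]] <- log2(m + 1)
    }
    dmn <- row$DM_mean + row$DN_mean
    dma <- row$DM_mean + row$AN_mean
    row$ratio_dmdn <- if (dmn > 0) row$DM_mean / dmn else NA_real_
    row$ratio_dman <- if (dma > 0) row$DM_mean / dma else NA_real_
    row$ci_defined <- n >= 2
    out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
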