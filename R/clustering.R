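#' Hamming distance matrix between haplotypes
#'
#' Raw counts of allele mismatches between every pair of haplotypes
#' over a site subset (not normalized by length).
#'
#' @param x a [HaplotypeMatrix-class].
#' @param siteSubset integer site indices (default all); must be
#'   non-empty.
#' @return a `dist` object labelled by haplotype id.
#' @export
hammingMatrix <- function(x, siteSubset = seq_len(nSites(x))) {
  if (!length(siteSubset)) stop("empty clustering site subset")
  a <- alleleMatrix(x)[, siteSubset, drop = FALSE]
  # mismatches = |ones in exactly one of the two rows|
  ones <- tcrossprod(a)
  n1 <- rowSums(a)
  d <- outer(n1, n1, "+") - 2 * ones
  stats::as.dist(d)
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Deterministic UPGMA: at each step the pair of clusters with minimal
#' average distance is merged, ties broken by the lexicographically
#' smallest index pair. Node heights are half the average inter-cluster
#' distance at the merge, so for Hamming input the tree height is in
#' units of mismatches-per-pair / 2 (the units consumed by TMRCA
#' calibration). The result is a standard `hclust` object and is
#' ultrametric by construction.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @return an `hclust` object with halved heights.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- seq_len(n)
  if (n < 2) stop("need at least two leaves")
  size <- rep(1L, n)
  id <- -(seq_len(n))            # hclust encoding: negatives = leaves
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(dm) <- Inf
  for (step in seq_len(n - 1L)) {
    sub <- dm[active, active, drop = FALSE]
    m <- min(sub)
    hits <- which(sub == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- active[hits[1, 1]]; j <- active[hits[1, 2]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- m / 2
    # weighted (arithmetic-mean) update over original leaf counts
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      dn <- (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j])
      dm[i, others] <- dn; dm[others, i] <- dn
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  res <- list(merge = merge, height = height,
              order = .leafOrder(merge, n),
              labels = rownames(dm), method = "upgma",
              dist.method = "hamming")
  class(res) <- "hclust"
  res
}

.leafOrder <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Cut a UPGMA dendrogram into cenhap groups
#'
#' Cuts the tree at a height (or into `k` groups); groups are the
#' connected subtrees below the cut. Labels are assigned in decreasing
#' group-size order (ties broken by the smallest haplotype id). A
#' nested `recut` refines named groups only, at a lower height,
#' yielding dotted labels (`"2.1"`, `"2.2"`, ...).
#'
#' @param tree an `hclust` from [upgma()].
#' @param h cut height (in tree height units), or
#' @param k number of groups (exactly one of `h`, `k`).
#' @param recut optional named list: `list("2" = list(h = ...))` or
#'   `list("2" = list(k = ...))`, re-cutting group "2" only.
#' @return a [CenhapPartition-class].
#' @export
cutTree <- function(tree, h = NULL, k = NULL, recut = NULL) {
  if (is.null(h) == is.null(k))
    stop("give exactly one of h (height) or k (group count)")
  if (!is.null(k) && k > length(tree$labels))
    stop("k exceeds the number of leaves")
  raw <- if (is.null(k)) stats::cutree(tree, h = h)
         else stats::cutree(tree, k = k)
  labels <- .sizeOrderLabels(raw)
  if (!is.null(recut)) {
    for (gname in names(recut)) {
      memb <- names(labels)[labels == gname]
      if (!length(memb)) stop("recut group '", gname, "' not found")
      spec <- recut[[gname]]
      fine <- if (!is.null(spec$h)) stats::cutree(tree, h = spec$h)
              else stats::cutree(tree, k = spec$k)
      sub <- .sizeOrderLabels(fine[memb])
      labels[memb] <- paste0(gname, ".", sub)
    }
  }
  lev <- unique(labels)
  lev <- lev[order(as.numeric(sub("\\..*$", "", lev)), lev)]
  new("CenhapPartition", hapIds = names(labels),
      groups = factor(labels, levels = lev),
      tree = tree,
      cutSpec = list(h = h, k = k, recut = recut))
}

# relabel raw cutree codes 1..k by decreasing size; ties by smallest id
.sizeOrderLabels <- function(raw) {
  tab <- table(raw)
  first.id <- vapply(names(tab), function(g)
    min(names(raw)[raw == g]), character(1))
  ord <- names(tab)[order(-as.integer(tab), first.id)]
  stats::setNames(as.character(match(as.character(raw), ord)), names(raw))
}

#' Detect apparent recombinants between cenhaps
#'
#' Clusters the left and right flanking site subsets separately into
#' `k` groups each; each left group is paired with the right group the
#' majority of its members fall into, and a haplotype whose own right
#' group disagrees with its left group's majority pairing is flagged as
#' an apparent recombinant. When more than `threshold` haplotypes are
#' flagged (default 10, the cut-off used for excluding recombinants
#' from divergence/TMRCA analyses), the attribute `"engaged"` is TRUE.
#' This operational rule is a package choice; it is recorded in the
#' `"rule"` attribute of the result.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param leftSites,rightSites disjoint site-index subsets for the two
#'   flanks.
#' @param k number of cenhap groups per flank.
#' @param threshold flag count above which filtering is engaged.
#' @return character vector of recombinant haplotype ids with
#'   attributes `engaged` (logical) and `rule`.
#' @export
findRecombinants <- function(x, leftSites, rightSites, k, threshold = 10L) {
  if (length(intersect(leftSites, rightSites)))
    stop("flank subsets must be disjoint")
  gl <- cenhapGroups(cutTree(upgma(hammingMatrix(x, leftSites)), k = k))
  gr <- cenhapGroups(cutTree(upgma(hammingMatrix(x, rightSites)), k = k))
  ids <- hapIds(x)
  gl <- gl[ids]; gr <- gr[ids]
  bad <- character(0)
  for (g in unique(gl)) {
    memb <- ids[gl == g]
    tab <- sort(table(as.character(gr[memb])), decreasing = TRUE)
    major <- names(tab)[1]
    bad <- c(bad, memb[as.character(gr[memb]) != major])
  }
  structure(bad, engaged = length(bad) > threshold,
            rule = "left/right flank majority-pairing disagreement")
}

#' Match an unphased diploid genotype to panel individuals and cenhaps
#'
#' For each candidate individual (a phased pair of panel haplotypes),
#' compares the diploid alternate-allele dosage to the candidate's
#' dosage site by site: a two-allele mismatch is 0/0 vs 1/1, a
#' one-allele mismatch is hom vs het, otherwise a match. The best
#' candidate minimizes the total number of mismatching alleles; its
#' cenhap genotype is read from the partition of its two haplotypes.
#'
#' @param dosage integer vector of alternate-allele dosages (0, 1, 2)
#'   for the diploid individual, aligned with `siteIdx`.
#' @param x a [HaplotypeMatrix-class] with diploid haplotype ids
#'   (`sample_1`/`sample_2`).
#' @param partition a [CenhapPartition-class] over the haplotypes of
#'   `x`.
#' @param siteIdx site indices of `x` the dosages refer to (default all
#'   sites).
#' @return list with `report` (data.frame sample, two_mismatch,
#'   one_mismatch, match, mismatch_alleles), `best` (sample id) and
#'   `cenhapGenotype` (e.g. `"3_5"`, sorted labels of the best
#'   individual's two haplotypes).
#' @export
matchDiploid <- function(dosage, x, partition, siteIdx = seq_len(nSites(x))) {
  if (!length(siteIdx)) stop("empty site set")
  stopifnot(length(dosage) == length(siteIdx), all(dosage %in% 0:2))
  ids <- hapIds(x)
  base <- sub("_[12]$", "", ids)
  if (any(!grepl("_[12]$", ids)))
    stop("matchDiploid needs diploid haplotype ids (sample_1/sample_2)")
  samples <- unique(base)
  a <- alleleMatrix(x)[, siteIdx, drop = FALSE]
  rep.list <- lapply(samples, function(sm) {
    cand <- a[base == sm, , drop = FALSE]
    if (nrow(cand) != 2) stop("sample ", sm, " does not have two haplotypes")
    cd <- colSums(cand)
    diff <- abs(dosage - cd)
    c(two_mismatch = sum(diff == 2), one_mismatch = sum(diff == 1),
      match = sum(diff == 0), mismatch_alleles = sum(diff))
  })
  rep.df <- data.frame(sample = samples, do.call(rbind, rep.list),
                       stringsAsFactors = FALSE)
  best <- rep.df$sample[which.min(rep.df$mismatch_alleles)]
  grp <- cenhapGroups(partition)
  g2 <- sort(as.character(grp[paste0(best, c("_1", "_2"))]))
  list(report = rep.df, best = best,
       cenhapGenotype = paste(g2, collapse = "_"))
}

#' Write a partition table as TSV
#'
#' @param partition a [CenhapPartition-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
  utils::write.table(
    data.frame(hap_id = hapIds(partition),
               group = as.character(cenhapGroups(partition))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram as newick
#'
#' @param tree an `hclust` (e.g. from [upgma()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom ape as.phylo write.tree
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}
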