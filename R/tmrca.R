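#' Calibrated TMRCA tree across cenhap groups
#'
#' Builds a UPGMA dendrogram from the across-gene mean synonymous
#' divergence matrix among cenhap groups (plus the outgroup), then
#' calibrates node heights per gene: for every internal node,
#' `TMRCA_g(node) = calibrationAge * h_g(node) / h_g(root)` where
#' `h_g(node)` is half the mean between-clade divergence of that gene
#' and `h_g(root)` is half the mean divergence between the outgroup
#' and the human groups (assumed to sit at `calibrationAge`, default
#' 6.5 My for human-chimpanzee). Node age = across-gene mean; error
#' bars = +/- 2 standard deviations across genes. Genes with zero
#' human-outgroup divergence are excluded with a warning.
#'
#' @param dsMatrices named list of per-gene group-mean dS matrices
#'   (all with identical dimnames, including `outgroup`), e.g. from
#'   [geneGroupDs()].
#' @param calibrationAge age of the human-outgroup MRCA in years.
#' @param outgroup dimname of the outgroup "group".
#' @return list of class `tmrcaTree`: `tree` (hclust over groups),
#'   `nodes` (data.frame node, members, age_mean, age_sd, age_lo,
#'   age_hi with lo/hi = mean -/+ 2 SD), `genesUsed`.
#' @export
tmrcaTree <- function(dsMatrices, calibrationAge = 6.5e6,
                      outgroup = "outgroup") {
  stopifnot(length(dsMatrices) >= 1)
  gl <- rownames(dsMatrices[[1]])
  if (!(outgroup %in% gl)) stop("outgroup '", outgroup, "' not in matrices")
  human <- setdiff(gl, outgroup)
  cal <- vapply(dsMatrices, function(m)
    mean(m[human, outgroup]) / 2, numeric(1))
  drop <- cal <= 0
  if (any(drop)) {
    warning(sum(drop), " gene(s) with zero human-outgroup divergence excluded")
    dsMatrices <- dsMatrices[!drop]
    cal <- cal[!drop]
    if (!length(dsMatrices)) stop("no usable genes")
  }
  mean.m <- Reduce(`+`, dsMatrices) / length(dsMatrices)
  tree <- upgma(stats::as.dist(mean.m))
  leafset <- function(node) {
    if (node < 0) return(tree$labels[-node])
    c(leafset(tree$merge[node, 1]), leafset(tree$merge[node, 2]))
  }
  nodes <- lapply(seq_len(nrow(tree$merge)), function(nd) {
    A <- leafset(tree$merge[nd, 1])
    B <- leafset(tree$merge[nd, 2])
    ages <- vapply(seq_along(dsMatrices), function(gi) {
      h <- mean(dsMatrices[[gi]][A, B]) / 2
      calibrationAge * h / cal[gi]
    }, numeric(1))
    data.frame(node = nd,
               members = paste(sort(c(A, B)), collapse = ","),
               age_mean = mean(ages),
               age_sd = stats::sd(ages),
               age_lo = mean(ages) - 2 * stats::sd(ages),
               age_hi = mean(ages) + 2 * stats::sd(ages))
  })
  structure(list(tree = tree, nodes = do.call(rbind, nodes),
                 genesUsed = names(dsMatrices), outgroup = outgroup,
                 calibrationAge = calibrationAge),
            class = "tmrcaTree")
}

#' @export
print.tmrcaTree <- function(x, ...) {
  cat("Calibrated TMRCA tree over",
      length(x$tree$labels), "groups,", length(x$genesUsed), "genes\n")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Scale a TMRCA by a divergence ratio (molecular clock)
#'
#' Linear molecular-clock scaling: a lineage `ratio` times as diverged
#' as an anchor lineage of known age has TMRCA `ratio * anchorTmrca`.
#' E.g. a cenhap twice as diverged as a Neanderthal-introgressed
#' cenhap of age 575 ky dates to 1.15 My.
#'
#' @param divergenceRatio positive divergence ratio.
#' @param anchorTmrca anchor TMRCA (any time unit; result in the same
#'   unit).
#' @return estimated TMRCA.
#' @export
tmrcaByRatio <- function(divergenceRatio, anchorTmrca) {
  stopifnot(divergenceRatio > 0, anchorTmrca > 0)
  divergenceRatio * anchorTmrca
}

#' Nonsynonymous replacements fixed on cenhap lineages
#'
#' Per gene, counts amino-acid-changing codon differences fixed within
#' a cenhap group relative to the consensus of all other groups. A
#' codon is "on the lineage" when one amino acid is carried by at
#' least `freq` of the group's members and differs from the amino acid
#' carried by at least `freq` of the remaining haplotypes.
#'
#' @param seqs named character vector of aligned in-frame sequences
#'   (one gene).
#' @param groups named character vector mapping sequence id to cenhap
#'   group; ids absent from `groups` are ignored.
#' @param lineage character vector of group label(s) forming the
#'   focal lineage.
#' @param freq within-group frequency required to call a state fixed.
#' @return integer count of replacement codons for this gene.
#' @export
countReplacements <- function(seqs, groups, lineage, freq = 0.9) {
  groups <- groups[names(seqs)]
  inl <- names(seqs)[groups %in% lineage]
  outl <- names(seqs)[!(groups %in% lineage) & !is.na(groups)]
  if (!length(inl) || !length(outl)) return(0L)
  cods.in <- vapply(seqs[inl], .codons, character(nchar(seqs[[1]]) / 3))
  cods.out <- vapply(seqs[outl], .codons, character(nchar(seqs[[1]]) / 3))
  if (is.null(dim(cods.in))) cods.in <- matrix(cods.in, nrow = 1)
  if (is.null(dim(cods.out))) cods.out <- matrix(cods.out, nrow = 1)
  n <- 0L
  for (k in seq_len(nrow(cods.in))) {
    aa.in <- .aa(cods.in[k, ])
    aa.out <- .aa(cods.out[k, ])
    cons <- function(v) {
      tab <- table(v)
      if (max(tab) / length(v) >= freq) names(tab)[which.max(tab)]
      else NA_character_
    }
    ci <- cons(aa.in); co <- cons(aa.out)
    if (!is.na(ci) && !is.na(co) && ci != co) n <- n + 1L
  }
  n
}

#' Per-gene divergence/diversity summary table
#'
#' One row per gene: counts of divergent (group consensus vs outgroup)
#' and polymorphic sites, mean nonsynonymous and synonymous divergence
#' to the outgroup, and nonsynonymous/synonymous diversity.
#'
#' @param genes named list of codon alignments (named character
#'   vectors incl. one outgroup sequence).
#' @param outgroupId id of the outgroup sequence in each alignment.
#' @return data.frame with columns gene, div_sites, polym_sites,
#'   nonsyn_div, syn_div, nonsyn_pi, syn_pi.
#' @export
geneTable <- function(genes, outgroupId = "outgroup") {
  rows <- lapply(names(genes), function(g) {
    seqs <- genes[[g]]
    hum <- setdiff(names(seqs), outgroupId)
    og <- seqs[[outgroupId]]
    mat <- do.call(rbind, strsplit(unname(seqs[hum]), ""))
    poly <- sum(apply(mat, 2, function(cc) length(unique(cc)) > 1))
    ogv <- strsplit(og, "")[[1]]
    div <- sum(vapply(seq_along(ogv), function(i)
      all(mat[, i] != ogv[i]), logical(1)))
    pr <- vapply(hum, function(h) {
      e <- ng86Pair(seqs[[h]], og)
      c(e$dN, e$dS)
    }, numeric(2))
    pi <- if (length(hum) >= 2) groupDiversity(seqs, hum)
          else c(pi_s = 0, pi_n = 0)
    data.frame(gene = g, div_sites = div, polym_sites = poly,
               nonsyn_div = mean(pr[1, ]), syn_div = mean(pr[2, ]),
               nonsyn_pi = pi[["pi_n"]], syn_pi = pi[["pi_s"]])
  })
  do.call(rbind, rows)
}

#' Read per-gene codon alignments from multi-FASTA files
#'
#' One FASTA per gene; the outgroup sequence is identified by its id.
#'
#' @param paths named character vector of FASTA paths (names = gene
#'   ids; defaults to basenames).
#' @return named list of validated codon alignments.
#' @export
readGeneAlignments <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fa|fasta)$", "", basename(paths))
  out <- lapply(names(paths), function(g) {
    ss <- Biostrings::readDNAStringSet(paths[[g]])
    codonAlignment(stats::setNames(as.character(ss), names(ss)), gene = g)
  })
  stats::setNames(out, names(paths))
}
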