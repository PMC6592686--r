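#' Two-locus gamete table
#'
#' Counts haplotypes by their joint alleles at two sites: `n00`, `n01`,
#' `n10`, `n11` (first digit = allele at `i`, second = allele at `j`).
#' The four counts sum to the number of haplotypes.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param i,j distinct site indices.
#' @return named integer vector `c(n00, n01, n10, n11)`.
#' @export
gameteTable <- function(x, i, j) {
  if (i == j) stop("i and j must be distinct sites")
  a <- alleleMatrix(x)
  ci <- a[, i]; cj <- a[, j]
  c(n00 = sum(ci == 0L & cj == 0L), n01 = sum(ci == 0L & cj == 1L),
    n10 = sum(ci == 1L & cj == 0L), n11 = sum(ci == 1L & cj == 1L))
}

# -log10(p) cap: smallest representable chi^2(1) upper tail
.NEGLOG10P_CAP <- 323.3062

#' Pearson chi-squared test of allelic independence on a 2x2 table
#'
#' The chi-squared statistic for independence of alleles at a pair of
#' linked SNPs, computed from observed and expected cell counts with 1
#' degree of freedom and no continuity correction; the p value is the
#' upper tail of chi-squared(1). Pairs with a zero marginal (a
#' monomorphic site) have no defined test and are flagged.
#'
#' @param tab gamete table as returned by [gameteTable()] (any order of
#'   a length-4 count vector laid out as 2x2 row-major).
#' @return list with `chi2`, `p`, `neglog10p` (capped at the
#'   floating-point tail floor, recorded in `cap`), and `defined`
#'   (FALSE when a marginal is zero, in which case the statistics are
#'   `NA`).
#' @export
chi2Independence <- function(tab) {
  o <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  r <- rowSums(o); cs <- colSums(o); n <- sum(o)
  if (any(r == 0) || any(cs == 0))
    return(list(chi2 = NA_real_, p = NA_real_, neglog10p = NA_real_,
                defined = FALSE, cap = .NEGLOG10P_CAP))
  e <- outer(r, cs) / n
  chi2 <- sum((o - e)^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  nl <- if (p > 0) -log10(p) else .NEGLOG10P_CAP
  list(chi2 = chi2, p = p, neglog10p = min(nl, .NEGLOG10P_CAP),
       defined = TRUE, cap = .NEGLOG10P_CAP)
}

#' Pairwise LD chi-squared matrix
#'
#' Computes [chi2Independence()] for every pair of sites in a subset,
#' vectorized through cross-products of the allele columns. Undefined
#' pairs (zero marginal) are kept with `defined = FALSE`.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param siteSubset integer site indices (default: all sites).
#' @return data.frame with columns `i`, `j` (site indices, i < j),
#'   `i_pos`, `j_pos`, `chi2`, `p`, `neglog10p`, `defined`. The
#'   `neglog10p` cap is attached as attribute `"cap"`.
#' @export
ldMatrix <- function(x, siteSubset = seq_len(nSites(x))) {
  s <- length(siteSubset)
  if (s < 2)
    return(structure(data.frame(i = integer(), j = integer(),
                                i_pos = integer(), j_pos = integer(),
                                chi2 = numeric(), p = numeric(),
                                neglog10p = numeric(), defined = logical()),
                     cap = .NEGLOG10P_CAP))
  a <- alleleMatrix(x)[, siteSubset, drop = FALSE]
  h <- nrow(a)
  n11 <- crossprod(a)
  n1 <- colSums(a)
  n10.ij <- outer(n1, rep(1, s)) - n11   # allele 1 at i, 0 at j
  n01.ij <- outer(rep(1, s), n1) - n11
  n00.ij <- h - n11 - n10.ij - n01.ij
  pair <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  res <- mapply(function(ii, jj)
    unlist(chi2Independence(c(n00.ij[ii, jj], n01.ij[ii, jj],
                              n10.ij[ii, jj], n11[ii, jj]))[
                                c("chi2", "p", "neglog10p", "defined")]),
    i, j)
  pos <- start(sites(x))[siteSubset]
  structure(data.frame(i = siteSubset[i], j = siteSubset[j],
                       i_pos = pos[i], j_pos = pos[j],
                       chi2 = res["chi2", ], p = res["p", ],
                       neglog10p = res["neglog10p", ],
                       defined = as.logical(res["defined", ])),
            cap = .NEGLOG10P_CAP)
}
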