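#' Four-gamete test between two sites
#'
#' TRUE when all four two-locus gametes (00, 01, 10, 11) are observed
#' among the haplotypes. Under an infinite-sites model with no
#' recombination this cannot happen, so a positive test indicates
#' recombination, gene conversion, recurrent mutation or genotyping
#' error.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param i,j distinct site indices.
#' @return logical.
#' @export
fourGamete <- function(x, i, j) {
  tab <- gameteTable(x, i, j)
  all(tab > 0L)
}

#' Precompute the pairwise four-gamete indicator matrix
#'
#' The four-gamete status of a site pair depends only on the two
#' columns, never on which other sites survive filtering, so the whole
#' S x S indicator can be computed once per matrix (via column
#' cross-products) and reused across all filter passes.
#'
#' @param x a [HaplotypeMatrix-class].
#' @return logical S x S matrix; `[i, j]` is TRUE iff sites i and j
#'   show all four gametes. Diagonal is FALSE.
#' @export
fourGameteMatrix <- function(x) {
  a <- alleleMatrix(x)
  h <- nrow(a); s <- ncol(a)
  n11 <- crossprod(a)
  n1 <- colSums(a)
  n10 <- outer(n1, rep(1, s)) - n11
  n01 <- outer(rep(1, s), n1) - n11
  n00 <- h - n11 - n10 - n01
  g <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  diag(g) <- FALSE
  g
}

#' Does a flanking pair fail the focal SNP?
#'
#' A (left, right) pair of SNPs flanking a focal SNP is a failing pair
#' when the focal SNP shows all four gametes with the flanking SNPs
#' while the flanks do not show all four gametes between themselves:
#' the focal SNP then looks like a single-site double crossover (a
#' genotyping error or short gene conversion) against a locally
#' consistent haplotype background. By default both flanks must show
#' all four gametes with the focal SNP — the focal SNP conflicts with
#' the haplotype background on each side, as a double crossover does.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param focal,left,right site indices with `left < focal < right`.
#' @param combine how the two flank tests combine: `"and"` (default;
#'   the focal SNP shows all four gametes with each of the two flanks,
#'   the literal double-crossover signature), `"or"` (at least one
#'   flank) or `"xor"` (exactly one).
#' @return logical.
#' @export
pairFails <- function(x, focal, left, right,
                      combine = c("and", "or", "xor")) {
  combine <- match.arg(combine)
  if (!(left < focal && focal < right))
    stop("need left < focal < right")
  fl <- fourGamete(x, focal, left)
  fr <- fourGamete(x, focal, right)
  hit <- switch(combine, "and" = fl && fr, "or" = fl || fr,
                "xor" = xor(fl, fr))
  hit && !fourGamete(x, left, right)
}

#' Filter configuration for the windowed four-gamete filter
#'
#' @param windows strictly increasing half-window widths, in counts of
#'   surviving SNPs per side. One filter pass is run per width, in
#'   order.
#' @param tolerance maximum number of failing flanking pairs a focal
#'   SNP may accumulate in a window before being filtered (removal
#'   when the count is strictly greater).
#' @param combine how flank hits combine, see [pairFails()].
#' @return a `list` of class `fourgtConfig`.
#' @export
fourgtConfig <- function(windows = c(10L, 20L, 30L, 40L), tolerance = 0L,
                         combine = c("and", "or", "xor")) {
  combine <- match.arg(combine)
  stopifnot(length(windows) >= 1, all(diff(windows) > 0), all(windows >= 1),
            tolerance >= 0)
  structure(list(windows = as.integer(windows),
                 tolerance = as.integer(tolerance), combine = combine),
            class = "fourgtConfig")
}

#' One 5'-to-3' pass of the windowed four-gamete filter
#'
#' Iterates focal SNPs in position order over the currently surviving
#' set. For each focal SNP the nearest `halfWindow` surviving SNPs on
#' each side are enumerated as all (left, right) combinations; if the
#' number of failing pairs ([pairFails()]) exceeds `tolerance` the
#' focal SNP is removed immediately, so windows of downstream focal
#' SNPs reflect the removal. Focal SNPs with no surviving neighbour on
#' one side have no opposite-side pair and are never removed.
#'
#' @param g four-gamete indicator from [fourGameteMatrix()].
#' @param surviving ordered integer site indices currently surviving.
#' @param halfWindow number of surviving SNPs per side.
#' @param tolerance see [fourgtConfig()].
#' @param combine see [pairFails()].
#' @return list with `surviving` (ordered indices), `removed` (integer
#'   indices) and `failCounts` (failing-pair count for each removed
#'   site).
#' @export
fourgtPass <- function(g, surviving, halfWindow, tolerance = 0L,
                       combine = c("and", "or", "xor")) {
  combine <- match.arg(combine)
  alive <- surviving
  removed <- integer(0)
  fails <- integer(0)
  k <- 1L
  while (k <= length(alive)) {
    f <- alive[k]
    left <- if (k == 1L) integer(0)
            else alive[max(1L, k - halfWindow):(k - 1L)]
    right <- if (k == length(alive)) integer(0)
             else alive[(k + 1L):min(length(alive), k + halfWindow)]
    if (length(left) && length(right)) {
      hit <- switch(combine,
        "and" = outer(g[f, left], g[f, right], "&"),
        "or" = outer(g[f, left], g[f, right], "|"),
        "xor" = outer(g[f, left], g[f, right], xor))
      nfail <- sum(hit & !g[left, right, drop = FALSE])
      if (nfail > tolerance) {
        removed <- c(removed, f)
        fails <- c(fails, nfail)
        alive <- alive[-k]
        next  # do not advance: alive[k] is now the next focal
      }
    }
    k <- k + 1L
  }
  list(surviving = alive, removed = removed, failCounts = fails)
}

#' The windowed four-gamete ("double crossover") genotyping-error filter
#'
#' Removes SNPs that behave like isolated single-site double crossovers
#' against the local haplotype background — the signature of genotyping
#' errors or short gene-conversion tracts in regions of suppressed
#' crossing over. One [fourgtPass()] is applied per half-window width
#' (default ±10, ±20, ±30, ±40 surviving SNPs), threading the
#' surviving set from pass to pass, each pass scanning 5' to 3'.
#'
#' @param x a [HaplotypeMatrix-class].
#' @param config a [fourgtConfig()].
#' @return list of class `fourgtResult`: `surviving` (site indices),
#'   `removed` (data.frame site, pos, pass, failing_pairs),
#'   `perPass` (removals per pass), `config`.
#' @export
fourgtDco <- function(x, config = fourgtConfig()) {
  stopifnot(inherits(config, "fourgtConfig"))
  g <- fourGameteMatrix(x)
  surviving <- seq_len(nSites(x))
  rem <- data.frame(site = integer(), pos = integer(), pass = integer(),
                    failing_pairs = integer())
  per.pass <- integer(length(config$windows))
  pos <- start(sites(x))
  for (p in seq_along(config$windows)) {
    r <- fourgtPass(g, surviving, config$windows[p], config$tolerance,
                    config$combine)
    surviving <- r$surviving
    per.pass[p] <- length(r$removed)
    if (length(r$removed))
      rem <- rbind(rem, data.frame(site = r$removed, pos = pos[r$removed],
                                   pass = p, failing_pairs = r$failCounts))
  }
  structure(list(surviving = surviving, removed = rem,
                 perPass = per.pass, config = config),
            class = "fourgtResult")
}

#' @export
print.fourgtResult <- function(x, ...) {
  cat("4gt filter: ", length(x$surviving), " SNPs surviving, ",
      nrow(x$removed), " removed (per pass: ",
      paste(x$perPass, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write the removal report as TSV
#'
#' @param result a `fourgtResult` from [fourgtDco()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRemovalReport <- function(result, path) {
  utils::write.table(result$removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
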