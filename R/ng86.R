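#' @importFrom Biostrings GENETIC_CODE readDNAStringSet
NULL

.BASES <- c("A", "C", "G", "T")

.aa <- function(codon) {
  x <- Biostrings::GENETIC_CODE[codon]
  unname(x)
}

#' Validate an in-frame codon alignment
#'
#' Checks equal lengths divisible by 3, an {A,C,G,T} alphabet and the
#' absence of internal stop codons; violations are rejected with the
#' gene id rather than edited.
#'
#' @param seqs named character vector of aligned CDS sequences (may
#'   also be a `DNAStringSet`); names are haplotype/outgroup ids.
#' @param gene gene id used in error messages.
#' @return the validated named character vector, invisibly usable.
#' @export
codonAlignment <- function(seqs, gene = "gene") {
  ids <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop(gene, ": aligned sequences must have equal length")
  if (L %% 3 != 0) stop(gene, ": alignment length not divisible by 3")
  if (any(grepl("[^ACGT]", seqs)))
    stop(gene, ": alphabet must be A/C/G/T only")
  for (id in names(seqs)) {
    cods <- .codons(seqs[[id]])
    if (any(.aa(cods) == "*"))
      stop(gene, ": internal stop codon in ", id)
  }
  seqs
}

.codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each codon position, the synonymous fraction is the number of
#' the three possible single-base changes that leave the amino acid
#' unchanged, divided by 3; changes creating a stop codon count as
#' nonsynonymous. `s + n = 3` for every codon.
#'
#' @param codon three-base string (not a stop codon).
#' @return named numeric `c(s = ..., n = ...)`.
#' @export
ng86Sites <- function(codon) {
  codon <- toupper(codon)
  if (.aa(codon) == "*") stop("stop codon input: ", codon)
  aa0 <- .aa(codon)
  syn <- 0
  for (p in 1:3) for (b in setdiff(.BASES, substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (.aa(mut) == aa0) syn <- syn + 1   # stop mutants differ from aa0
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# classify a single-base codon step as synonymous (1) or not (0);
# any step into or out of a stop codon is nonsynonymous
.stepSyn <- function(from, to) {
  a1 <- .aa(from); a2 <- .aa(to)
  as.numeric(a1 == a2 && a1 != "*")
}

# memoized per-codon synonymous site counts and per-codon-pair
# difference counts; ng86Pair is called once per sequence pair per
# codon, so table lookups replace re-enumeration
.ng86cache <- new.env(parent = emptyenv())

.siteTable <- function() {
  if (is.null(.ng86cache$s)) {
    cods <- names(Biostrings::GENETIC_CODE)
    cods <- gsub("U", "T", cods)
    ok <- Biostrings::GENETIC_CODE != "*"
    s <- rep(NA_real_, length(cods))
    names(s) <- cods
    s[ok] <- vapply(cods[ok], function(cd) ng86Sites(cd)[["s"]],
                    numeric(1))
    .ng86cache$s <- s
  }
  .ng86cache$s
}

.pairTable <- function() {
  if (is.null(.ng86cache$sd)) {
    .ng86cache$sd <- new.env(parent = emptyenv())
  }
  .ng86cache$sd
}

.codonPairDiffsCached <- function(c1, c2) {
  key <- paste0(c1, c2)
  tab <- .pairTable()
  v <- tab[[key]]
  if (is.null(v)) {
    v <- .codonPairDiffs(c1, c2)
    tab[[key]] <- v
  }
  v
}

# average synonymous/nonsynonymous difference counts between two
# codons over all orderings of the single-base steps (NG86 method I)
.codonPairDiffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(pos)
           else if (nd == 2) list(pos, rev(pos))
           else list(pos[c(1,2,3)], pos[c(1,3,2)], pos[c(2,1,3)],
                     pos[c(2,3,1)], pos[c(3,1,2)], pos[c(3,2,1)])
  tot.s <- 0
  for (ord in perms) {
    cur <- c1
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      tot.s <- tot.s + .stepSyn(cur, nxt)
      cur <- nxt
    }
  }
  s <- tot.s / length(perms)
  c(sd = s, nd = nd - s)
}

#' Pairwise NG86 (method I) divergence between two in-frame sequences
#'
#' Site counts are averaged over the two sequences; multi-difference
#' codons are resolved by averaging synonymous/nonsynonymous step
#' counts over all orderings of the single-base steps; proportions are
#' Jukes-Cantor corrected, `d = -(3/4) log(1 - (4/3) p)`. Proportions
#' at or beyond the JC saturation point (p >= 3/4) give `NA` distances
#' with `saturated = TRUE`.
#'
#' @param seqA,seqB equal-length in-frame sequences (character).
#' @return list of class `ngEstimate`: `S`, `N` (fractional site
#'   counts), `Sd`, `Nd` (fractional differences), `pS`, `pN`, `dS`,
#'   `dN`, `saturated`.
#' @export
ng86Pair <- function(seqA, seqB) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequence length mismatch")
  ca <- .codons(seqA); cb <- .codons(seqB)
  stab <- .siteTable()
  sa <- stab[ca]; sb <- stab[cb]
  if (anyNA(sa) || anyNA(sb)) stop("stop codon in sequence")
  S <- (sum(sa) + sum(sb)) / 2
  N <- nchar(seqA) - S
  diff <- ca != cb
  Sd <- 0; Nd <- 0
  if (any(diff)) {
    d <- vapply(which(diff), function(k)
      .codonPairDiffsCached(ca[k], cb[k]), numeric(2))
    Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = jc(pS), dN = jc(pN),
                 saturated = pS >= 0.75 || pN >= 0.75),
            class = "ngEstimate")
}

#' @export
print.ngEstimate <- function(x, ...) {
  cat(sprintf(
    "NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f pS=%.4g pN=%.4g dS=%.4g dN=%.4g\n",
    x$S, x$N, x$Sd, x$Nd, x$pS, x$pN, x$dS, x$dN))
  invisible(x)
}

#' Synonymous and nonsynonymous diversity within a group
#'
#' Expected-heterozygosity form: the average pairwise uncorrected
#' proportions `pS`/`pN` over all member pairs. A monomorphic group has
#' diversity 0.
#'
#' @param seqs named character vector of aligned in-frame sequences.
#' @param members ids of group members (>= 2).
#' @return named numeric `c(pi_s = ..., pi_n = ...)`.
#' @export
groupDiversity <- function(seqs, members) {
  if (length(members) < 2) stop("need at least two group members")
  prs <- utils::combn(members, 2)
  vals <- apply(prs, 2, function(p) {
    e <- ng86Pair(seqs[[p[1]]], seqs[[p[2]]])
    c(e$pS, e$pN)
  })
  c(pi_s = mean(vals[1, ]), pi_n = mean(vals[2, ]))
}

#' Mean pairwise synonymous divergence matrix among cenhap groups
#'
#' For one gene: mean `dS` (or uncorrected `pS`) over all
#' between-group sequence pairs, for every pair of groups including
#' the outgroup (treated as its own group).
#'
#' @param seqs named character vector of aligned in-frame sequences.
#' @param groups named character vector mapping sequence id to group
#'   label; the outgroup sequence should carry its own label (e.g.
#'   `"outgroup"`).
#' @param corrected use JC-corrected `dS` (default) or raw `pS`.
#' @return symmetric matrix of group mean synonymous divergences.
#' @export
geneGroupDs <- function(seqs, groups, corrected = TRUE) {
  groups <- groups[names(seqs)]
  if (anyNA(groups)) stop("groups must cover every sequence")
  gl <- unique(unname(groups))
  m <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in seq_along(gl)) for (j in seq_len(i - 1L)) {
    a <- names(seqs)[groups == gl[i]]
    b <- names(seqs)[groups == gl[j]]
    vals <- vapply(a, function(x) vapply(b, function(y) {
      e <- ng86Pair(seqs[[x]], seqs[[y]])
      if (corrected) e$dS else e$pS
    }, numeric(1)), numeric(length(b)))
    m[i, j] <- m[j, i] <- mean(vals)
  }
  m
}

#' Bias-corrected bootstrap percentile interval
#'
#' BC (bias-corrected, non-accelerated) percentile interval for the
#' mean of per-gene values, from `B` resamples of genes. Degenerate
#' input (all values equal) returns the point interval. Seeded and
#' reproducible.
#'
#' @param values numeric per-gene values (>= 2).
#' @param B number of bootstrap resamples (>= 200).
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @return named numeric `c(lower, upper)` with attribute
#'   `"estimate"` (the sample mean).
#' @export
bootstrapCi <- function(values, B = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(length(values) >= 2, B >= 200)
  est <- mean(values)
  if (length(unique(values)) == 1L)
    return(structure(c(lower = est, upper = est), estimate = est))
  set.seed(seed)
  stat <- vapply(seq_len(B), function(i)
    mean(sample(values, replace = TRUE)), numeric(1))
  alpha <- (1 - conf) / 2
  z0 <- stats::qnorm(mean(stat < est) + 0.5 * mean(stat == est))
  lo.p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi.p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  q <- stats::quantile(stat, c(lo.p, hi.p), names = FALSE, type = 6)
  structure(c(lower = q[1], upper = q[2]), estimate = est)
}
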