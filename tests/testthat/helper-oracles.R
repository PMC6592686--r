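# Independent reference implementations used as oracles. These are
# deliberately naive (explicit loops, no shared code with the package
# internals) and must stay that way.

# closed-form 2x2 chi-squared: H (ad - bc)^2 / (r1 r2 c1 c2)
chi2Closed <- function(n00, n01, n10, n11) {
  h <- n00 + n01 + n10 + n11
  r1 <- n00 + n01; r2 <- n10 + n11
  c1 <- n00 + n10; c2 <- n01 + n11
  h * (n00 * n11 - n01 * n10)^2 / (r1 * r2 * c1 * c2)
}

# four-gamete test by explicit haplotype iteration
naiveFourGamete <- function(a, i, j) {
  s00 <- s01 <- s10 <- s11 <- FALSE
  for (h in seq_len(nrow(a))) {
    x <- a[h, i]; y <- a[h, j]
    if (x == 0L) { if (y == 0L) s00 <- TRUE else s01 <- TRUE }
    else         { if (y == 0L) s10 <- TRUE else s11 <- TRUE }
    if (s00 && s01 && s10 && s11) return(TRUE)
  }
  FALSE
}

# pair-by-pair four-gamete table via the explicit haplotype loop
naivePairTable <- function(a) {
  s <- ncol(a)
  g4 <- matrix(FALSE, s, s)
  for (i in seq_len(s - 1)) for (j in (i + 1):s) {
    g4[i, j] <- g4[j, i] <- naiveFourGamete(a, i, j)
  }
  g4
}

# one filter pass, written as the definition reads: walk focal SNPs
# 5' to 3' over the surviving set, enumerate every (left, right)
# combination in the window, count failing pairs, remove immediately
naiveFourgtPass <- function(a, surviving, halfWindow, tolerance = 0L,
                            combine = "and", g4 = naivePairTable(a)) {
  alive <- surviving
  removed <- integer(0)
  k <- 1L
  while (k <= length(alive)) {
    f <- alive[k]
    lefts <- if (k > 1) alive[max(1, k - halfWindow):(k - 1)] else integer(0)
    rights <- if (k < length(alive))
      alive[(k + 1):min(length(alive), k + halfWindow)] else integer(0)
    nfail <- 0L
    for (l in lefts) for (r in rights) {
      fl <- g4[f, l]
      fr <- g4[f, r]
      hit <- switch(combine, "and" = fl && fr, "or" = fl || fr,
                    "xor" = xor(fl, fr))
      if (hit && !g4[l, r])
        nfail <- nfail + 1L
    }
    if (length(lefts) && length(rights) && nfail > tolerance) {
      removed <- c(removed, f)
      alive <- alive[-k]
    } else k <- k + 1L
  }
  list(surviving = alive, removed = removed)
}

naiveFourgtDco <- function(a, windows = c(10L, 20L, 30L, 40L),
                           tolerance = 0L, combine = "and") {
  g4 <- naivePairTable(a)
  surviving <- seq_len(ncol(a))
  removed <- integer(0)
  for (w in windows) {
    r <- naiveFourgtPass(a, surviving, w, tolerance, combine, g4 = g4)
    surviving <- r$surviving
    removed <- c(removed, r$removed)
  }
  list(surviving = surviving, removed = removed)
}

# NG86 oracle: fresh enumeration against the standard genetic code,
# no shared tables with the package
.oracleCode <- local({
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  code
})

oracleSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (p in 1:3) {
    for (b in bases[bases != substr(codon, p, p)]) {
      mut <- codon
      substr(mut, p, p) <- b
      if (.oracleCode[[mut]] == .oracleCode[[codon]] &&
          .oracleCode[[mut]] != "*") syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# pathway enumeration for a codon pair: average syn/nonsyn steps over
# all orderings of the single-base differences
oraclePairDiffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) matrix(1L) else
    t(as.matrix(expand.grid(rep(list(seq_along(pos)), length(pos)))))
  perms <- perms[, apply(perms, 2, function(x)
    length(unique(x)) == length(pos)), drop = FALSE]
  tot.s <- 0; npath <- 0
  for (ci in seq_len(ncol(perms))) {
    ord <- pos[perms[, ci]]
    cur <- c1
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.oracleCode[[cur]] == .oracleCode[[nxt]] &&
          .oracleCode[[cur]] != "*") tot.s <- tot.s + 1
      cur <- nxt
    }
    npath <- npath + 1
  }
  s <- tot.s / npath
  c(sd = s, nd = length(pos) - s)
}

# plain percentile bootstrap interval (for comparison with BC)
percentileCi <- function(values, B, seed, conf = 0.95) {
  set.seed(seed)
  stat <- replicate(B, mean(sample(values, replace = TRUE)))
  unname(quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 6))
}

# naive O(n^3)-style UPGMA via repeated scanning, using hclust-free
# bookkeeping; returns the cophenetic matrix (units: mean distance)
naiveUpgmaCophenetic <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  size <- rep(1, n)
  work <- dm
  diag(work) <- Inf
  while (length(active) > 1) {
    best <- c(NA, NA); bm <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (work[i, j] < bm) { bm <- work[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]])
      coph[a, b] <- coph[b, a] <- bm
    for (k in active) {
      if (k == i || k == j) next
      v <- (size[i] * work[i, k] + size[j] * work[j, k]) /
        (size[i] + size[j])
      work[i, k] <- work[k, i] <- v
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  dimnames(coph) <- dimnames(dm)
  coph
}
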