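test_that("site classification follows the DM/DN/AM/AN definitions", {
  expect_equal(classifySite("G", "G", "A"), "DM")
  expect_equal(classifySite("A", "G", "A"), "DN")
  expect_equal(classifySite("A", "A", "A"), "AM")
  expect_equal(classifySite("G", "A", "A"), "AN")
  expect_equal(classifySite("G", "G", NA), "unusable")
  expect_equal(classifySite("G", NA, "A"), "unusable")
})

mkAnnotatedMatrix <- function() {
  # 4 haplotypes x 5 sites; ref = outgroup allele everywhere
  a <- rbind(h1 = c(1, 1, 0, 0, 1), h2 = c(1, 0, 0, 1, 0),
             h3 = c(0, 1, 1, 0, 0), h4 = c(0, 0, 1, 1, 1))
  m <- HaplotypeMatrix(a, chrom = "c", pos = 1:5,
                       ref = rep("A", 5), alt = rep("G", 5))
  ann <- archaicAnnotation(chrom = rep("c", 5), pos = 1:5,
                           outgroup = rep("A", 5),
                           nea = c("G", "G", "A", "A", "G"),
                           den = c("A", "A", "A", "A", "A"))
  list(m = m, ann = ann)
}

test_that("counts partition the usable sites for every haplotype", {
  f <- mkAnnotatedMatrix()
  res <- countArchaic(f$m, f$ann)
  expect_equal(res$usable, c(nea = 5L, den = 5L))
  tot <- res$counts$DM + res$counts$DN + res$counts$AM + res$counts$AN
  expect_true(all(tot == 5L))
  # h1 matches nea at sites 1,2,5 (derived) and 3,4 (ancestral)
  h1 <- res$counts[res$counts$hap_id == "h1" &
                   res$counts$source == "nea", ]
  expect_equal(h1$DM, 3L); expect_equal(h1$DN, 0L)
  expect_equal(h1$AM, 2L); expect_equal(h1$AN, 0L)
  # against an all-ancestral archaic, derived haplotype alleles are AN
  h1d <- res$counts[res$counts$hap_id == "h1" &
                    res$counts$source == "den", ]
  expect_equal(h1d$DM, 0L)
  expect_equal(h1d$AN, 3L)
})

test_that("a haplotype equal to the outgroup has DM = AN = 0", {
  f <- mkAnnotatedMatrix()
  a <- alleleMatrix(f$m)
  a["h4", ] <- 0L   # outgroup state everywhere
  m <- HaplotypeMatrix(a, chrom = "c", pos = 1:5, ref = rep("A", 5),
                       alt = rep("G", 5))
  res <- countArchaic(m, f$ann)
  h4 <- res$counts[res$counts$hap_id == "h4" &
                   res$counts$source == "nea", ]
  expect_equal(h4$DM, 0L)
  expect_equal(h4$AN, 0L)
  expect_equal(h4$DN, 3L)   # all archaic-derived sites unmatched
})

test_that("unusable sites are dropped: polarization requires ref/alt", {
  f <- mkAnnotatedMatrix()
  f$ann$outgroup[2] <- "T"        # matches neither ref nor alt
  f$ann$nea[3] <- NA
  res <- countArchaic(f$m, f$ann)
  expect_equal(res$usable, c(nea = 3L, den = 4L))
  expect_error(countArchaic(f$m, f$ann[0, ]), "usable")
})

test_that("region limits restrict the counted sites", {
  f <- mkAnnotatedMatrix()
  lim <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 3))
  res <- countArchaic(f$m, f$ann, regionLimit = lim)
  expect_equal(unname(res$usable["nea"]), 3L)
})

test_that("cenhap summaries compute means, CIs and ratios", {
  f <- mkAnnotatedMatrix()
  res <- countArchaic(f$m, f$ann)
  part <- stats::setNames(factor(c("1", "1", "2", "2")),
                          c("h1", "h2", "h3", "h4"))
  s <- summarizeByCenhap(res$counts, part)
  expect_true(all(s$ratio_dmdn >= 0 & s$ratio_dmdn <= 1, na.rm = TRUE))
  expect_true(all(s$DM_lo <= s$DM_mean & s$DM_mean <= s$DM_hi))
  # ratios computed from group means
  g1 <- res$counts[res$counts$hap_id %in% c("h1", "h2") &
                   res$counts$source == "nea", ]
  expect_equal(s$ratio_dmdn[s$group == "1" & s$source == "nea"],
               mean(g1$DM) / (mean(g1$DM) + mean(g1$DN)))
  # two identical groups summarize identically
  cnt2 <- res$counts
  cnt2$hap_id <- paste0(cnt2$hap_id, "x")
  cnt2 <- rbind(res$counts, cnt2)
  part2 <- stats::setNames(
    factor(rep(c("1", "2"), each = 4)),
    c("h1", "h2", "h3", "h4", "h1x", "h2x", "h3x", "h4x"))
  s2 <- summarizeByCenhap(cnt2, part2)
  n1 <- s2[s2$group == "1", !(names(s2) %in% "group")]
  n2 <- s2[s2$group == "2", !(names(s2) %in% "group")]
  rownames(n1) <- rownames(n2) <- NULL
  expect_equal(n1, n2)
})

test_that("singleton groups have undefined CIs but defined means", {
  f <- mkAnnotatedMatrix()
  res <- countArchaic(f$m, f$ann)
  part <- stats::setNames(factor(c("1", "2", "2", "2")),
                          c("h1", "h2", "h3", "h4"))
  s <- summarizeByCenhap(res$counts, part)
  one <- s[s$group == "1" & s$source == "nea", ]
  expect_false(one$ci_defined)
  expect_true(is.na(one$DM_lo))
  expect_false(is.na(one$DM_mean))
})

test_that("relabelling the archaic sources permutes summaries exactly", {
  f <- mkAnnotatedMatrix()
  ann.sw <- archaicAnnotation(chrom = f$ann$chrom, pos = f$ann$pos,
                              outgroup = f$ann$outgroup,
                              nea = f$ann$den, den = f$ann$nea)
  part <- stats::setNames(factor(c("1", "1", "2", "2")),
                          c("h1", "h2", "h3", "h4"))
  s <- summarizeByCenhap(countArchaic(f$m, f$ann)$counts, part)
  sw <- summarizeByCenhap(countArchaic(f$m, ann.sw)$counts, part)
  a <- s[s$source == "nea", !(names(s) %in% "source")]
  b <- sw[sw$source == "den", !(names(sw) %in% "source")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("simulated introgressed cenhaps carry the top DM ratio", {
  ok <- 0L
  for (seed in 1:5) {
    p <- simParams(nHaplotypes = 120, seed = seed,
                   genotypingErrorRate = 0)
    sim <- simulateGenealogy(p)
    if (!length(sim$introgressed)) next
    sh <- dropMutations(sim, nSites = 1e5)
    pt <- cutTree(upgma(hammingMatrix(sh$matrix)), k = 2)
    g <- cenhapGroups(pt)
    cnt <- countArchaic(sh$matrix, emitArchaicAnnotation(sh))
    s <- summarizeByCenhap(cnt$counts, pt)
    s <- s[s$source == "nea", ]
    intro.grp <- names(sort(table(as.character(g[sim$introgressed])),
                            decreasing = TRUE))[1]
    top <- s$group[which.max(s$ratio_dmdn)]
    if (top == intro.grp) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
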