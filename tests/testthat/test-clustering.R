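test_that("hamming distances are raw mismatch counts", {
  a <- rbind(h1 = c(0, 1, 0, 1), h2 = c(0, 1, 0, 1), h3 = c(1, 0, 1, 0),
             h4 = c(0, 0, 1, 1))
  m <- HaplotypeMatrix(a, chrom = "c", pos = 1:4)
  d <- as.matrix(hammingMatrix(m))
  expect_equal(d["h1", "h2"], 0)
  expect_equal(d["h1", "h3"], 4)       # complementary over all sites
  expect_equal(d["h1", "h4"], 2)       # 0101 vs 0011
  expect_true(all(d >= 0), all(diag(d) == 0))
  expect_error(hammingMatrix(m, integer(0)), "empty")
})

test_that("UPGMA reproduces the hand-worked three-leaf tree", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(stats::as.dist(d))
  expect_equal(u$height, c(1, 4))      # merge (A,B) at 1, then C at 4
  expect_equal(u$merge[1, ], c(-2L, -1L))
  # cutting at height 2 isolates {A,B} from {C}
  p <- cutTree(u, h = 2)
  g <- cenhapGroups(p)
  expect_equal(unname(g["A"]), unname(g["B"]))
  expect_false(g[["A"]] == g[["C"]])
})

test_that("equal distances merge deterministically by lowest index", {
  d <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  u <- upgma(stats::as.dist(d))
  expect_equal(u$merge[1, ], c(-2L, -1L))
  expect_equal(unique(u$height), 1.5)
})

test_that("UPGMA is ultrametric and matches average-linkage hclust", {
  set.seed(13)
  for (rep in 1:10) {
    x <- matrix(rnorm(20 * 6), 20)
    rownames(x) <- paste0("t", 1:20)
    d <- stats::dist(x)
    u <- upgma(d)
    # ultrametric: all leaves equidistant from the root
    ph <- ape::as.phylo(u)
    depth <- ape::node.depth.edgelength(ph)[seq_len(20)]
    expect_lt(max(depth) - min(depth), 1e-9)
    # independent implementation: hclust average linkage (x2 height)
    h <- stats::hclust(d, method = "average")
    expect_equal(2 * as.matrix(stats::cophenetic(u)),
                 as.matrix(stats::cophenetic(h)), tolerance = 1e-9)
    # and the naive O(n^3) scan agrees too
    expect_equal(2 * as.matrix(stats::cophenetic(u)),
                 naiveUpgmaCophenetic(d), tolerance = 1e-9)
  }
})

test_that("tree cuts span one group to all-singleton groups", {
  set.seed(17)
  m <- randomMatrix(12, 30)
  u <- upgma(hammingMatrix(m))
  expect_equal(length(levels(cenhapGroups(cutTree(u, h = max(u$height) + 1)))),
               1L)
  expect_equal(length(levels(cenhapGroups(cutTree(u, h = -0.1)))), 12L)
  expect_error(cutTree(u, k = 13), "leaves")
  expect_error(cutTree(u), "exactly one")
  p <- cutTree(u, k = 3)
  expect_equal(sum(table(cenhapGroups(p))), 12)
})

test_that("nested re-cuts refine only the named group", {
  m <- simMatrix(55, nHap = 24, nSites = 1e5)
  u <- upgma(hammingMatrix(m))
  p1 <- cutTree(u, k = 2)
  p2 <- cutTree(u, k = 2, recut = list("1" = list(k = 4)))
  g1 <- cenhapGroups(p1); g2 <- cenhapGroups(p2)
  in1 <- names(g1)[g1 == "1"]
  expect_true(all(startsWith(as.character(g2[in1]), "1.")))
  expect_equal(as.character(g2[setdiff(names(g2), in1)]),
               as.character(g1[setdiff(names(g1), in1)]))
})

test_that("partition labels are invariant to haplotype input order", {
  m <- simMatrix(77, nHap = 20, nSites = 1e5)
  perm <- sample(nHap(m))
  mp <- m[perm, ]
  g1 <- cenhapGroups(cutTree(upgma(hammingMatrix(m)), k = 3))
  g2 <- cenhapGroups(cutTree(upgma(hammingMatrix(mp)), k = 3))
  expect_equal(as.character(g1[hapIds(m)]),
               as.character(g2[hapIds(m)]))
})

test_that("a deep two-lineage split is recovered exactly", {
  for (seed in c(5, 6, 7)) {
    p <- simParams(nHaplotypes = 40, introgressionFraction = 0.2,
                   genotypingErrorRate = 0, seed = seed)
    sim <- simulateGenealogy(p)
    sh <- dropMutations(sim, nSites = 2e5)
    pt <- cutTree(upgma(hammingMatrix(sh$matrix)), k = 2)
    g <- cenhapGroups(pt)
    # truth: the root bipartition of the sampled haplotypes' genealogy
    sub <- ape::keep.tip(sim$tree, hapIds(sh$matrix))
    root <- length(sub$tip.label) + 1L
    kids <- sub$edge[sub$edge[, 1] == root, 2]
    clade1 <- if (kids[1] <= length(sub$tip.label)) sub$tip.label[kids[1]]
              else ape::extract.clade(sub, kids[1])$tip.label
    expect_length(unique(as.character(g[clade1])), 1)
    expect_length(unique(as.character(g[setdiff(hapIds(sh$matrix),
                                                clade1)])), 1)
    expect_false(as.character(g[clade1])[1] ==
                 as.character(g[setdiff(hapIds(sh$matrix), clade1)])[1])
  }
})

test_that("spliced haplotypes are flagged as apparent recombinants", {
  p <- simParams(nHaplotypes = 30, introgressionFraction = 0.3,
                 genotypingErrorRate = 0, seed = 91)
  sh <- dropMutations(simulateGenealogy(p), nSites = 2e5)
  n <- nSites(sh$matrix)
  left <- seq_len(floor(n / 2)); right <- setdiff(seq_len(n), left)
  # no crossover: no recombinants
  expect_length(findRecombinants(sh$matrix, left, right, k = 2), 0)
  # splice one haplotype: cenhap-1 left flank, cenhap-2 right flank
  g <- cenhapGroups(cutTree(upgma(hammingMatrix(sh$matrix)), k = 2))
  a.id <- names(g)[g == "1"][1]
  b.id <- names(g)[g == "2"][1]
  a <- alleleMatrix(sh$matrix)
  a[a.id, right] <- a[b.id, right]
  spl <- HaplotypeMatrix(a, chrom = "chrSim",
                         pos = start(sites(sh$matrix)))
  found <- findRecombinants(spl, left, right, k = 2)
  expect_equal(unclass(found)[seq_along(found)], a.id,
               ignore_attr = TRUE)
  expect_false(attr(found, "engaged"))   # 1 recombinant <= 10
})

test_that("the >10 recombinant rule engages filtering", {
  p <- simParams(nHaplotypes = 60, introgressionFraction = 0.3,
                 genotypingErrorRate = 0, seed = 93)
  sh <- dropMutations(simulateGenealogy(p), nSites = 2e5)
  n <- nSites(sh$matrix)
  left <- seq_len(floor(n / 2)); right <- setdiff(seq_len(n), left)
  g <- cenhapGroups(cutTree(upgma(hammingMatrix(sh$matrix)), k = 2))
  ids1 <- names(g)[g == "1"]; ids2 <- names(g)[g == "2"]
  a <- alleleMatrix(sh$matrix)
  splice <- ids1[1:12]
  for (id in splice) a[id, right] <- a[ids2[1], right]
  spl <- HaplotypeMatrix(a, chrom = "chrSim",
                         pos = start(sites(sh$matrix)))
  found <- findRecombinants(spl, left, right, k = 2)
  expect_setequal(as.character(found), splice)
  expect_true(attr(found, "engaged"))
})

test_that("a diploid built from a sample's own haplotypes matches it", {
  path <- toyVcf()
  m <- readVcfRegion(path)
  part <- cutTree(upgma(hammingMatrix(m)), k = 2)
  a <- alleleMatrix(m)
  dosage <- a["s2_1", ] + a["s2_2", ]
  res <- matchDiploid(dosage, m, part)
  expect_equal(res$best, "s2")
  own <- res$report[res$report$sample == "s2", ]
  expect_equal(own$mismatch_alleles, 0L)
  expect_equal(own$match, nSites(m))
  g <- cenhapGroups(part)
  expect_equal(res$cenhapGenotype,
               paste(sort(as.character(g[c("s2_1", "s2_2")])),
                     collapse = "_"))
  # classes partition the site count for every candidate
  sums <- res$report$two_mismatch + res$report$one_mismatch +
    res$report$match
  expect_true(all(sums == nSites(m)))
})

test_that("mismatch classes follow the hom/het definitions", {
  a <- rbind(s1_1 = c(1L, 0L, 0L), s1_2 = c(1L, 1L, 0L))
  m <- HaplotypeMatrix(a, chrom = "c", pos = 1:3)
  part <- cutTree(upgma(stats::as.dist(matrix(c(0, 1, 1, 0), 2, 2,
    dimnames = list(rownames(a), rownames(a))))), k = 1)
  # diploid 0/0 vs candidate 1|1 -> two-allele mismatch;
  # 0/0 vs 0|1 -> one-allele; 0/0 vs 0|0 -> match
  res <- matchDiploid(c(0L, 0L, 0L), m, part)
  expect_equal(res$report$two_mismatch, 1L)
  expect_equal(res$report$one_mismatch, 1L)
  expect_equal(res$report$match, 1L)
})
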