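test_that("identical seeds reproduce simulations bit for bit", {
  p <- simParams(nHaplotypes = 30, seed = 3)
  a <- dropMutations(simulateGenealogy(p), nSites = 5e4, seed = 4)
  b <- dropMutations(simulateGenealogy(p), nSites = 5e4, seed = 4)
  expect_identical(alleleMatrix(a$matrix), alleleMatrix(b$matrix))
  expect_identical(a$fullAlleles, b$fullAlleles)
  expect_identical(a$positions, b$positions)
})

test_that("introgression fractions behave binomially", {
  p0 <- simParams(nHaplotypes = 50, introgressionFraction = 0, seed = 5)
  expect_length(simulateGenealogy(p0)$introgressed, 0)
  n <- vapply(1:12, function(s) {
    p <- simParams(nHaplotypes = 200, introgressionFraction = 0.05,
                   seed = 600 + s)
    length(simulateGenealogy(p)$introgressed)
  }, numeric(1))
  # Binomial(200, 0.05): mean 10, sd ~3.1; the 12-rep mean is within 4 se
  expect_lt(abs(mean(n) - 10), 4 * 3.08 / sqrt(12))
})

test_that("pairwise modern TMRCA matches the coalescent expectation", {
  # E[T2] = 2N generations for a sampled pair
  tm <- vapply(1:40, function(s) {
    p <- simParams(nHaplotypes = 2, N = 5000, introgressionFraction = 0,
                   seed = 700 + s)
    sim <- simulateGenealogy(p)
    stats::cophenetic(sim$tree)["hap1", "hap2"] / 2
  }, numeric(1))
  # mean of 40 Exp(1/2N) draws: se = 2N/sqrt(40)
  expect_lt(abs(mean(tm) - 10000), 4 * 10000 / sqrt(40))
})

test_that("infinite-sites central blocks never show four gametes", {
  for (seed in c(21, 22)) {
    m <- simMatrix(seed, nHap = 40, nSites = 1e5)
    expect_false(any(fourGameteMatrix(m)))
  }
})

test_that("polymorphic site counts track mutation input", {
  p <- simParams(nHaplotypes = 30, seed = 31)
  sim <- simulateGenealogy(p)
  tot.len <- sum(sim$tree$edge.length)
  lam <- p$mutationRate * tot.len
  n1 <- nSites(dropMutations(sim, nSites = 5e4, seed = 1)$matrix)
  n2 <- nSites(dropMutations(sim, nSites = 1e5, seed = 2)$matrix)
  # counts scale with the region size (Poisson, minus fixed sites)
  expect_lt(abs(n2 / n1 - 2), 0.5)
  expect_lt(n1, lam * 5e4)   # fixed/archaic-only sites are excluded
})

test_that("error injection flips exactly what it reports", {
  m <- simMatrix(51, nHap = 20, nSites = 5e4)
  e0 <- injectErrors(m, 0)
  expect_identical(alleleMatrix(e0$matrix), alleleMatrix(m))
  expect_equal(nrow(e0$errorLog), 0L)
  e1 <- injectErrors(m, 1)
  expect_identical(alleleMatrix(e1$matrix), 1L - alleleMatrix(m))
  # flips recorded match the matrix difference
  e <- injectErrors(m, 0.01, seed = 6)
  dif <- which(alleleMatrix(e$matrix) != alleleMatrix(m), arr.ind = TRUE)
  expect_equal(nrow(e$errorLog), nrow(dif))
  expect_setequal(paste(e$errorLog$hap, e$errorLog$site),
                  paste(dif[, 1], dif[, 2]))
  # flip count is Binomial(H*S, rate): within 4 sd
  ns <- nHap(m) * nSites(m)
  expect_lt(abs(nrow(e$errorLog) - ns * 0.01),
            4 * sqrt(ns * 0.01 * 0.99))
})

test_that("conversion tracts stay in range and rate 0 is a no-op", {
  m <- simMatrix(52, nHap = 20, nSites = 5e4)
  c0 <- injectConversions(m, 0, 3)
  expect_identical(alleleMatrix(c0$matrix), alleleMatrix(m))
  c1 <- injectConversions(m, 0.5, 5, seed = 8)
  expect_gt(nrow(c1$conversionLog), 0)
  expect_true(all(c1$conversionLog$start >= 1))
  expect_true(all(c1$conversionLog$end <= nSites(m)))
  expect_true(all(c1$conversionLog$end - c1$conversionLog$start < 5))
})

test_that("flank recombination leaves the central block untouched", {
  p <- simParams(nHaplotypes = 20, genotypingErrorRate = 0, seed = 61)
  sh <- dropMutations(simulateGenealogy(p), nSites = 1e5)
  n <- nSites(sh$matrix)
  central <- seq(floor(n * 0.4), ceiling(n * 0.6))
  before <- alleleMatrix(sh$matrix)
  r0 <- addFlankRecombination(sh, rate = 0, centralSites = central)
  expect_identical(alleleMatrix(r0$matrix), before)
  r1 <- addFlankRecombination(sh, rate = 0.5, centralSites = central,
                              seed = 9)
  expect_identical(alleleMatrix(r1$matrix)[, central],
                   before[, central])
  if (!is.null(r1$spliceLog))
    expect_false(any(r1$spliceLog$breakSite %in% central))
})

test_that("codon evolution respects its rate switches", {
  tr <- ape::read.tree(text = "((a:1000,b:1000):1000,outgroup:2000);")
  g0 <- simulateCodons(tr, nGenes = 2, codonsPerGene = 30,
                       synRate = 0, nonsynRate = 0, seed = 1)
  expect_equal(length(unique(g0[[1]])), 1L)
  gs <- simulateCodons(tr, nGenes = 2, codonsPerGene = 50,
                       synRate = 1e-4, nonsynRate = 0, seed = 2)
  for (g in gs) {
    e <- ng86Pair(g[["a"]], g[["outgroup"]])
    expect_equal(e$Nd, 0)
  }
  # no in-frame stops ever
  for (g in gs) expect_silent(codonAlignment(g))
})

test_that("archaic annotation mirrors the simulated tip states", {
  p <- simParams(nHaplotypes = 30, seed = 71, genotypingErrorRate = 0)
  sh <- dropMutations(simulateGenealogy(p), nSites = 1e5)
  ann <- emitArchaicAnnotation(sh)
  s <- sites(sh$matrix)
  expect_equal(ann$pos, start(s))
  expect_equal(nrow(ann), nSites(sh$matrix))
  # outgroup carries the ancestral (ref) allele at every retained site
  expect_equal(ann$outgroup, S4Vectors::mcols(s)$ref)
  # nea allele is ref or alt according to the simulated state
  nea.state <- sh$fullAlleles["nea", ]
  expect_equal(ann$nea == S4Vectors::mcols(s)$alt, nea.state == 1L)
})

test_that("sites mutated on shared archaic branches classify as DM", {
  p <- simParams(nHaplotypes = 60, seed = 81, genotypingErrorRate = 0)
  sim <- simulateGenealogy(p)
  sh <- dropMutations(sim, nSites = 2e5)
  cnt <- countArchaic(sh$matrix, emitArchaicAnnotation(sh))
  tot <- cnt$counts$DM + cnt$counts$DN + cnt$counts$AM + cnt$counts$AN
  expect_true(all(tot == cnt$usable[cnt$counts$source]))
  if (length(sim$introgressed)) {
    nea <- cnt$counts[cnt$counts$source == "nea", ]
    dm.in <- mean(nea$DM[nea$hap_id %in% sim$introgressed])
    dm.out <- mean(nea$DM[!(nea$hap_id %in% sim$introgressed)])
    expect_gt(dm.in, dm.out)
  }
})
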