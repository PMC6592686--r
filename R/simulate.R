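#' Simulation parameters
#'
#' Defaults describe the study conditions the package is exercised
#' under: a sample of 200 haplotypes from a diploid population of
#' effective size 10,000; zero crossing over inside the central block
#' (crossovers confined to flanks); an archaic lineage splitting
#' 575 ky ago (in generations of 29 y) with a 5% introgression pulse
#' ~55 ky ago; Neanderthal/Denisovan sampled-genome split at 400 ky;
#' per-allele genotyping error 0.3%; human-chimpanzee calibration
#' 6.5 My.
#'
#' @param nHaplotypes sampled modern haplotypes.
#' @param N diploid effective population size of the modern
#'   population.
#' @param archaicN diploid effective size of the archaic populations
#'   (and of the introgression founder pool), smaller than the modern
#'   size as inferred for Neanderthals/Denisovans.
#' @param crossoverRate expected flank crossovers per haplotype in the
#'   sample history (0 = none; crossovers never touch the central
#'   block).
#' @param geneConversionRate expected conversion tracts per haplotype.
#' @param conversionTractLength tract length in SNPs.
#' @param mutationRate per-base per-generation mutation rate.
#' @param genotypingErrorRate per-allele flip probability.
#' @param archaicSplitTime generations to the archaic population
#'   split.
#' @param admixtureTime generations to the introgression pulse.
#' @param denNeaSplitTime generations to the split of the two sampled
#'   archaic genomes.
#' @param introgressionFraction fraction of sampled tips carrying the
#'   introgressed haplotype.
#' @param calibrationAge human-outgroup MRCA in years.
#' @param generationTime years per generation.
#' @param seed integer RNG seed (`NULL`: use current RNG state).
#' @return list of class `simParams`.
#' @export
simParams <- function(nHaplotypes = 200L, N = 10000L, archaicN = 2500L,
                      crossoverRate = 0, geneConversionRate = 0,
                      conversionTractLength = 1L,
                      mutationRate = 1.2e-8,
                      genotypingErrorRate = 0.003,
                      archaicSplitTime = round(575000 / 29),
                      admixtureTime = round(55000 / 29),
                      denNeaSplitTime = round(400000 / 29),
                      introgressionFraction = 0.05,
                      calibrationAge = 6.5e6, generationTime = 29,
                      seed = NULL) {
  p <- as.list(environment())
  stopifnot(nHaplotypes >= 2, N >= 2, crossoverRate >= 0,
            geneConversionRate >= 0, conversionTractLength >= 1,
            mutationRate >= 0, genotypingErrorRate >= 0,
            genotypingErrorRate < 1,
            introgressionFraction >= 0, introgressionFraction <= 1,
            admixtureTime <= archaicSplitTime)
  class(p) <- "simParams"
  p
}

# internal: binary tree accumulated as coalescence events
.coalesceAll <- function(params) {
  n <- params$nHaplotypes
  n.intro <- stats::rbinom(1, n, params$introgressionFraction)
  intro <- if (n.intro > 0) sort(sample.int(n, n.intro)) else integer(0)
  tip.labels <- c(paste0("hap", seq_len(n)), "nea", "den", "outgroup")
  nt <- length(tip.labels)
  # backwards in time: introgressed tips carry archaic material, so
  # their lineages live in their own founder pool ("I") until the
  # admixture pulse, then join the archaic population
  pop <- c(ifelse(seq_len(n) %in% intro, "I", "M"), "A", "D", "O")
  node <- seq_len(nt)
  time <- 0
  next.node <- nt + 1L
  events <- list()   # (child1, child2, time, node)
  sched <- data.frame(
    t = c(params$admixtureTime, params$denNeaSplitTime,
          params$archaicSplitTime,
          params$calibrationAge / params$generationTime),
    what = c("admix", "dennea", "split", "outgroup"),
    stringsAsFactors = FALSE)
  sched <- sched[order(sched$t), ]
  si <- 1L
  # archaic-side pools (A, D and the introgression founder pool) use
  # the smaller archaic effective size
  pop.n2 <- c(M = 2 * params$N, I = 2 * params$archaicN,
              A = 2 * params$archaicN, D = 2 * params$archaicN,
              O = 2 * params$N)
  pops <- names(pop.n2)
  repeat {
    if (length(node) == 1L) break
    rates <- vapply(pops, function(p.)
      { k <- sum(pop == p.); if (k >= 2) k * (k - 1) / 2 / pop.n2[[p.]]
        else 0 }, numeric(1))
    tot <- sum(rates)
    t.next <- if (tot > 0) time + stats::rexp(1, tot) else Inf
    if (si <= nrow(sched) && sched$t[si] <= t.next) {
      time <- sched$t[si]
      w <- sched$what[si]
      si <- si + 1L
      if (w == "admix") {
        pop[pop == "I"] <- "A"
      } else if (w == "dennea") {
        pop[pop == "D"] <- "A"
      } else if (w == "split") {
        pop[pop == "A"] <- "M"
      } else if (w == "outgroup") {
        pop[pop == "O"] <- "M"
      }
      next
    }
    time <- t.next
    p. <- sample(pops, 1, prob = rates / tot)
    pick <- sample(which(pop == p.), 2)
    events[[length(events) + 1L]] <-
      c(node[pick[1]], node[pick[2]], time, next.node)
    node <- c(node[-pick], next.node)
    pop <- c(pop[-pick], p.)
    next.node <- next.node + 1L
  }
  list(events = events, tipLabels = tip.labels,
       introgressed = if (length(intro)) paste0("hap", intro)
                      else character(0))
}

.eventsToPhylo <- function(events, tipLabels) {
  nt <- length(tipLabels)
  ne <- length(events)
  node.time <- c(rep(0, nt), vapply(events, `[`, numeric(1), 3))
  edge <- matrix(0L, 2L * ne, 2L)
  elen <- numeric(2L * ne)
  # ape numbering: tips 1..nt, root nt+1, internals nt+1..; our event
  # nodes are nt+1..nt+ne in coalescence order (root = last); remap so
  # the root becomes nt+1 per ape convention
  remap <- c(seq_len(nt), rev(seq_len(ne)) + nt)
  k <- 1L
  for (i in seq_len(ne)) {
    ev <- events[[i]]
    for (child in ev[1:2]) {
      edge[k, ] <- c(remap[ev[4]], remap[child])
      elen[k] <- ev[3] - node.time[child]
      k <- k + 1L
    }
  }
  tr <- list(edge = edge, edge.length = elen, tip.label = tipLabels,
             Nnode = ne)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate a cenhap genealogy with an archaic split and introgression
#'
#' Structured coalescent over the non-recombining central block: a
#' modern population, an archaic population splitting at
#' `archaicSplitTime`, two sampled archaic genomes (`nea`, `den`,
#' splitting at `denNeaSplitTime`), a binomial fraction of sampled
#' tips entering the archaic population at `admixtureTime`
#' (introgression), and an outgroup lineage joining at the
#' calibration age. Time is in generations; all sampled tips sit at
#' time 0.
#'
#' @param params a [simParams()].
#' @return list of class `cenhapSim`: `tree` (ape `phylo` with branch
#'   lengths in generations), `tipLabels`, `introgressed` (tip
#'   labels), `archaicTips`, `outgroupTip`, `params`.
#' @export
simulateGenealogy <- function(params = simParams()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  cl <- .coalesceAll(params)
  tree <- .eventsToPhylo(cl$events, cl$tipLabels)
  structure(list(tree = tree, tipLabels = cl$tipLabels,
                 introgressed = cl$introgressed,
                 archaicTips = c("nea", "den"), outgroupTip = "outgroup",
                 params = params),
            class = "cenhapSim")
}

#' @export
print.cenhapSim <- function(x, ...) {
  cat("cenhapSim:", length(x$tipLabels) - 3, "modern haplotypes (",
      length(x$introgressed), "introgressed ), 2 archaic tips, 1 outgroup\n")
  invisible(x)
}

# descendant tip indices for every edge of a phylo
.edgeDescendants <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) desc[[tree$edge[k, 2]]])
}

#' Drop infinite-sites mutations on a simulated genealogy
#'
#' Each mutation falls on one branch (chosen proportional to branch
#' length) at a distinct position; the expected mutation count is
#' `mutationRate x total branch length x nSites`. Only sites
#' polymorphic among the modern sampled haplotypes enter the matrix
#' (0 = ancestral, 1 = derived; ref = ancestral base). Archaic and
#' outgroup tip states for the same sites are retained for
#' [emitArchaicAnnotation()]. Within the non-recombining block no
#' pair of sites can show all four gametes.
#'
#' @param sim a `cenhapSim` from [simulateGenealogy()].
#' @param nSites number of base positions in the simulated region.
#' @param chrom,regionStart coordinates assigned to the region.
#' @param seed optional RNG seed.
#' @return list of class `simHaplotypes`: `matrix` (the modern-sample
#'   [HaplotypeMatrix-class]), `fullAlleles` (all tips x sites),
#'   `sim`, plus bookkeeping (`positions`, `errorLog`, `conversionLog`,
#'   `spliceLog` filled by later steps).
#' @export
dropMutations <- function(sim, nSites = 1e6L, chrom = "chrSim",
                          regionStart = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- sim$tree
  tot.len <- sum(tree$edge.length)
  mu <- sim$params$mutationRate
  n.mut <- stats::rpois(1, mu * tot.len * nSites)
  nt <- length(tree$tip.label)
  modern <- grep("^hap", tree$tip.label)
  full <- matrix(0L, nt, 0)
  pos <- integer(0)
  if (n.mut > 0) {
    br <- sample.int(nrow(tree$edge), n.mut, replace = TRUE,
                     prob = tree$edge.length)
    pos.all <- sort(sample.int(nSites, min(n.mut, nSites))) + regionStart - 1L
    br <- br[seq_along(pos.all)]
    desc <- .edgeDescendants(tree)
    full <- matrix(0L, nt, length(br))
    for (k in seq_along(br)) full[desc[[br[k]]], k] <- 1L
    n1 <- colSums(full[modern, , drop = FALSE])
    poly <- n1 > 0 & n1 < length(modern)
    full <- full[, poly, drop = FALSE]
    pos <- pos.all[poly]
  }
  rownames(full) <- tree$tip.label
  ref <- sample(.BASES, ncol(full), replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(.BASES, r), 1),
                       character(1)))
  hm <- HaplotypeMatrix(full[modern, , drop = FALSE], chrom = chrom,
                        pos = pos, ref = ref, alt = alt,
                        region = GRanges(chrom,
                                         IRanges(regionStart,
                                                 regionStart + nSites - 1L)))
  structure(list(matrix = hm, fullAlleles = full, positions = pos,
                 ref = ref, alt = alt, sim = sim,
                 errorLog = NULL, conversionLog = NULL, spliceLog = NULL),
            class = "simHaplotypes")
}

#' Confine crossovers to the flanking regions
#'
#' Applies crossover splices between haplotype pairs strictly outside
#' the central block: for a left-flank event the recipient takes the
#' donor's alleles at all sites left of the breakpoint (and
#' symmetrically on the right), so the central block genealogy is
#' untouched. Event count is Poisson(`rate` x haplotypes). Forced
#' splices allow constructing known recombinants.
#'
#' @param sh a `simHaplotypes`.
#' @param rate expected crossovers per haplotype (0 = unchanged).
#' @param centralSites site indices of the central block (events only
#'   hit sites outside it).
#' @param force optional data.frame (`hap`, `donor`, `side`
#'   ("left"/"right"), `breakSite`) of splices to apply exactly.
#' @param seed optional RNG seed.
#' @return the modified `simHaplotypes` with `spliceLog` filled.
#' @export
addFlankRecombination <- function(sh, rate = 0, centralSites = integer(0),
                                  force = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- alleleMatrix(sh$matrix)
  S <- ncol(a); H <- nrow(a)
  left.max <- if (length(centralSites)) min(centralSites) - 1L else 0L
  right.min <- if (length(centralSites)) max(centralSites) + 1L else S + 1L
  log <- if (is.null(force)) data.frame() else force
  if (rate > 0) {
    n.ev <- stats::rpois(1, rate * H)
    if (n.ev > 0) {
      ev <- data.frame(
        hap = sample.int(H, n.ev, replace = TRUE),
        donor = sample.int(H, n.ev, replace = TRUE),
        side = sample(c("left", "right"), n.ev, replace = TRUE),
        breakSite = NA_integer_)
      ev$breakSite <- ifelse(ev$side == "left",
                             sample.int(max(left.max, 1L), n.ev,
                                        replace = TRUE),
                             right.min - 1L +
                               sample.int(max(S - right.min + 1L, 1L),
                                          n.ev, replace = TRUE))
      ev <- ev[ev$hap != ev$donor, , drop = FALSE]
      if (left.max < 1L) ev <- ev[ev$side != "left", , drop = FALSE]
      if (right.min > S) ev <- ev[ev$side != "right", , drop = FALSE]
      log <- rbind(log, ev)
    }
  }
  if (nrow(log)) {
    for (k in seq_len(nrow(log))) {
      hap <- log$hap[k]; donor <- log$donor[k]
      idx <- if (log$side[k] == "left") seq_len(log$breakSite[k])
             else log$breakSite[k]:S
      a[hap, idx] <- a[donor, idx]
    }
    sh$matrix <- HaplotypeMatrix(a, chrom = as.character(
      seqnames(sites(sh$matrix)))[1],
      pos = start(sites(sh$matrix)),
      ref = mcols(sites(sh$matrix))$ref,
      alt = mcols(sites(sh$matrix))$alt,
      region = sh$matrix@region)
  }
  sh$spliceLog <- if (nrow(log)) log else NULL
  sh
}

#' Inject independent per-allele genotyping errors
#'
#' Flips each allele of the modern-sample matrix independently with
#' probability `rate`; every flip is recorded. `rate = 1` complements
#' the matrix.
#'
#' @param sh a `simHaplotypes` (or a bare [HaplotypeMatrix-class]).
#' @param rate flip probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return the modified object; `errorLog` is a data.frame (`hap`,
#'   `site`). For a bare matrix input, a list(matrix, errorLog).
#' @export
injectErrors <- function(sh, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bare <- is(sh, "HaplotypeMatrix")
  hm <- if (bare) sh else sh$matrix
  a <- alleleMatrix(hm)
  flip <- matrix(stats::runif(length(a)) < rate, nrow(a), ncol(a))
  a[flip] <- 1L - a[flip]
  idx <- which(flip, arr.ind = TRUE)
  log <- data.frame(hap = idx[, 1], site = idx[, 2])
  s <- sites(hm)
  hm2 <- HaplotypeMatrix(a, chrom = as.character(seqnames(s)),
                         pos = start(s), ref = mcols(s)$ref,
                         alt = mcols(s)$alt, region = hm@region)
  if (bare) return(list(matrix = hm2, errorLog = log))
  sh$matrix <- hm2
  sh$errorLog <- log
  sh
}

#' Inject gene-conversion tracts
#'
#' Copies contiguous site runs from a random donor haplotype into a
#' recipient; tract count is Poisson(`rate` x haplotypes). A tract
#' length of 1 is indistinguishable from a single-site genotyping
#' error to the four-gamete filter.
#'
#' @param sh a `simHaplotypes` (or bare [HaplotypeMatrix-class]).
#' @param rate expected tracts per haplotype.
#' @param tractLength tract length in sites (>= 1).
#' @param seed optional RNG seed.
#' @return modified object; `conversionLog` records (`hap`, `donor`,
#'   `start`, `end`).
#' @export
injectConversions <- function(sh, rate, tractLength = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(tractLength >= 1)
  bare <- is(sh, "HaplotypeMatrix")
  hm <- if (bare) sh else sh$matrix
  a <- alleleMatrix(hm)
  H <- nrow(a); S <- ncol(a)
  n.ev <- stats::rpois(1, rate * H)
  log <- data.frame(hap = integer(), donor = integer(),
                    start = integer(), end = integer())
  if (n.ev > 0 && S > 0) {
    for (k in seq_len(n.ev)) {
      hap <- sample.int(H, 1)
      donor <- sample(setdiff(seq_len(H), hap), 1)
      st <- sample.int(S, 1)
      en <- min(S, st + tractLength - 1L)
      a[hap, st:en] <- a[donor, st:en]
      log <- rbind(log, data.frame(hap = hap, donor = donor,
                                   start = st, end = en))
    }
  }
  s <- sites(hm)
  hm2 <- HaplotypeMatrix(a, chrom = as.character(seqnames(s)),
                         pos = start(s), ref = mcols(s)$ref,
                         alt = mcols(s)$alt, region = hm@region)
  if (bare) return(list(matrix = hm2, conversionLog = log))
  sh$matrix <- hm2
  sh$conversionLog <- log
  sh
}

#' Archaic annotation table from simulation truth
#'
#' Emits, for every site of the modern-sample matrix, the outgroup
#' allele and each archaic tip's allele taken from the simulated tip
#' states. All sites are usable by construction.
#'
#' @param sh a `simHaplotypes` from [dropMutations()].
#' @return annotation data.frame as from [archaicAnnotation()], with
#'   one column per archaic tip.
#' @export
emitArchaicAnnotation <- function(sh) {
  s <- sites(sh$matrix)
  base.of <- function(tip) {
    st <- sh$fullAlleles[tip, ]
    unname(ifelse(st == 1L, sh$alt, sh$ref))
  }
  args <- c(list(chrom = as.character(seqnames(s)), pos = start(s),
                 outgroup = base.of(sh$sim$outgroupTip)),
            stats::setNames(lapply(sh$sim$archaicTips, base.of),
                            sh$sim$archaicTips))
  do.call(archaicAnnotation, args)
}

#' Evolve codon alignments along a genealogy
#'
#' Root codons are drawn uniformly among non-stop codons; along each
#' branch, substitution proposals arrive at rate `max(synRate,
#' nonsynRate)` per nucleotide per generation and are accepted with
#' probability `synRate/max` (synonymous) or `nonsynRate/max`
#' (nonsynonymous); proposals creating a stop codon are always
#' rejected, so alignments carry no in-frame stops. Equal rates give
#' a neutral (dN/dS = 1) process.
#'
#' @param tree an ape `phylo` with branch lengths in generations (tip
#'   labels become sequence ids).
#' @param nGenes,codonsPerGene alignment dimensions.
#' @param synRate,nonsynRate accepted substitution rates per
#'   nucleotide per generation.
#' @param seed optional RNG seed.
#' @return named list of `nGenes` codon alignments (named character
#'   vectors).
#' @export
simulateCodons <- function(tree, nGenes = 10L, codonsPerGene = 100L,
                           synRate = 1e-8, nonsynRate = 1e-8,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(synRate >= 0, nonsynRate >= 0)
  rate <- max(synRate, nonsynRate)
  codons.ok <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  codons.ok <- gsub("U", "T", codons.ok)
  nt <- length(tree$tip.label)
  genes <- vector("list", nGenes)
  po <- ape::reorder.phylo(tree, "cladewise")
  for (g in seq_len(nGenes)) {
    seqs <- vector("list", nt + tree$Nnode)
    root <- nt + 1L
    seqs[[root]] <- sample(codons.ok, codonsPerGene, replace = TRUE)
    for (k in seq_len(nrow(po$edge))) {
      par <- po$edge[k, 1]; ch <- po$edge[k, 2]
      s <- seqs[[par]]
      if (rate > 0) {
        n.prop <- stats::rpois(1, rate * po$edge.length[k] *
                                 3 * codonsPerGene)
        for (m in seq_len(n.prop)) {
          ci <- sample.int(codonsPerGene, 1)
          p <- sample.int(3, 1)
          old <- s[ci]
          b <- sample(setdiff(.BASES, substr(old, p, p)), 1)
          new <- old
          substr(new, p, p) <- b
          if (.aa(new) == "*") next
          syn <- .aa(new) == .aa(old)
          acc <- if (syn) synRate / rate else nonsynRate / rate
          if (stats::runif(1) < acc) s[ci] <- new
        }
      }
      seqs[[ch]] <- s
    }
    genes[[g]] <- stats::setNames(
      vapply(seq_len(nt), function(i) paste(seqs[[i]], collapse = ""),
             character(1)),
      tree$tip.label)
  }
  stats::setNames(genes, paste0("gene", seq_len(nGenes)))
}

#' Simulate centromeric read-count tables with known truth
#'
#' Per sample, the focal-chromosome centromeric count is
#' Poisson(coverage x summed true array size of its one or two
#' haplotypes), optionally Gamma-overdispersed; the chr1 mean coverage
#' is concentrated around `coverage`. Additional background
#' chromosomes with fixed sizes can be added to exercise the stage-2
#' normalization.
#'
#' @param samples data.frame with columns `sample`, `lineage1`,
#'   `lineage2` (`NA` for hemizygotes), optional `sex`.
#' @param lineageSizes named numeric true array sizes per lineage (in
#'   arbitrary size units).
#' @param coverage mean sequencing depth.
#' @param dispersion Gamma overdispersion (0 = pure Poisson).
#' @param chrom focal chromosome name.
#' @param backgroundSizes named numeric sizes of additional
#'   chromosomes (diploid total), e.g. `c(chr5 = 150)`.
#' @param seed optional RNG seed.
#' @return list: `counts` (data.frame sample, chrom, cen_count,
#'   chr1_mean_cov), `truth` (per-sample true focal size),
#'   `genotypes` (named `"a_b"` strings).
#' @export
simulateArrayCounts <- function(samples, lineageSizes, coverage = 10,
                                dispersion = 0, chrom = "chr11",
                                backgroundSizes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(lineageSizes > 0))
  n <- nrow(samples)
  s1 <- lineageSizes[samples$lineage1]
  s2 <- numeric(n)
  ok <- !is.na(samples$lineage2)
  s2[ok] <- lineageSizes[samples$lineage2[ok]]
  true.size <- unname(s1) + s2
  lam <- coverage * true.size
  if (dispersion > 0)
    lam <- lam * stats::rgamma(n, shape = 1 / dispersion,
                               rate = 1 / dispersion)
  cnt <- stats::rpois(n, lam)
  cov1 <- stats::rgamma(n, shape = 400, rate = 400 / coverage)
  counts <- data.frame(sample = samples$sample, chrom = chrom,
                       cen_count = cnt, chr1_mean_cov = cov1,
                       stringsAsFactors = FALSE)
  if (!is.null(backgroundSizes)) {
    for (bc in names(backgroundSizes)) {
      counts <- rbind(counts, data.frame(
        sample = samples$sample, chrom = bc,
        cen_count = stats::rpois(n, coverage * backgroundSizes[[bc]]),
        chr1_mean_cov = cov1, stringsAsFactors = FALSE))
    }
  }
  gt <- vapply(seq_len(n), function(i) {
    ls <- c(samples$lineage1[i], samples$lineage2[i])
    paste(sort(ls[!is.na(ls)]), collapse = "_")
  }, character(1))
  list(counts = counts,
       truth = stats::setNames(true.size, samples$sample),
       genotypes = stats::setNames(gt, samples$sample))
}
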