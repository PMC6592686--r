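#' Validate a pipeline configuration
#'
#' Checks the whole configuration and returns every problem found (an
#' empty character vector means the config is valid); nothing is
#' computed.
#'
#' @param config named list (or path to a YAML file) with elements
#'   `seed`, `input` (`mode` = "simulate" or "vcf" plus mode-specific
#'   fields), `filter` (`windows`, `tolerance`), `cluster` (`h` or
#'   `k`) and optional `central`, `archaic`, `divergence`,
#'   `arraysize` blocks.
#' @return character vector of error messages (length 0 when ok).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  add <- function(e) errs <<- c(errs, e)
  if (is.null(config$seed)) add("seed: missing")
  inp <- config$input
  if (is.null(inp$mode) || !inp$mode %in% c("simulate", "vcf"))
    add("input.mode: must be 'simulate' or 'vcf'")
  else if (inp$mode == "vcf") {
    if (is.null(inp$path)) add("input.path: missing")
    else if (!file.exists(inp$path)) add(paste0("input.path: '", inp$path,
                                                "' does not exist"))
    for (f in c("p_begin", "p_end", "q_begin", "q_end", "p_c", "q_c"))
      if (is.null(inp[[f]])) add(paste0("input.", f, ": missing"))
    if (!is.null(inp$p_begin) && !is.null(inp$p_end) &&
        inp$p_end < inp$p_begin) add("input: p_end < p_begin")
    if (!is.null(inp$q_begin) && !is.null(inp$q_end) &&
        inp$q_end < inp$q_begin) add("input: q_end < q_begin")
    if (!is.null(inp$mask) && !file.exists(inp$mask))
      add(paste0("input.mask: '", inp$mask, "' does not exist"))
  }
  flt <- config$filter
  if (!is.null(flt)) {
    if (!is.null(flt$tolerance) && flt$tolerance < 0)
      add("filter.tolerance: must be >= 0")
    if (!is.null(flt$windows) &&
        (any(flt$windows < 1) || any(diff(flt$windows) <= 0)))
      add("filter.windows: must be strictly increasing positive")
  }
  cl <- config$cluster
  if (is.null(cl) || (is.null(cl$h) && is.null(cl$k)))
    add("cluster: one of h or k is required")
  if (!is.null(config$central$fraction) &&
      (config$central$fraction <= 0 || config$central$fraction > 1))
    add("central.fraction: must be in (0, 1]")
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageSeed <- function(seed, stage) (seed * 131L + stage) %% .Machine$integer.max

#' Run the cenhap analysis pipeline
#'
#' Orchestrates extract -> filter -> cluster -> archaic -> divergence
#' -> arraysize over a config, writing TSV/newick/VCF artifacts and a
#' JSON manifest to `outDir`. Deterministic given `config$seed`;
#' completed stages recorded in the manifest are skipped on rerun
#' (`resume = TRUE`). A stage failure halts with a stage-named error;
#' earlier outputs are preserved.
#'
#' @param config named list or YAML path (see [validateConfig()]).
#' @param outDir output directory (created if needed).
#' @param resume skip stages already marked complete in the manifest.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, resume = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  man.path <- file.path(outDir, "manifest.json")
  man <- if (resume && file.exists(man.path))
    jsonlite::read_json(man.path, simplifyVector = TRUE)
  else list(package = "cenhaps",
            version = as.character(utils::packageVersion("cenhaps")),
            config = config, stages = list(), files = list())
  man$config <- config
  done <- function(st) isTRUE(man$stages[[st]]$complete) &&
    all(file.exists(file.path(outDir, unlist(man$stages[[st]]$files))))
  mark <- function(st, files, info = list()) {
    man$stages[[st]] <<- c(list(complete = TRUE, files = files), info)
    for (f in files)
      man$files[[f]] <<- unname(tools::md5sum(file.path(outDir, f)))
    jsonlite::write_json(man, man.path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  seed <- config$seed
  state <- new.env()

  # -- stage 1: extract -------------------------------------------------
  st <- "extract"
  if (!done(st) || TRUE) {  # matrix always needed in memory
    set.seed(.stageSeed(seed, 1L))
    if (config$input$mode == "simulate") {
      pl <- config$input$params %||% list()
      pl$seed <- .stageSeed(seed, 1L)
      params <- do.call(simParams, pl)
      sim <- simulateGenealogy(params)
      sh <- dropMutations(sim, nSites = config$input$nSites %||% 2e5L)
      if (params$genotypingErrorRate > 0)
        sh <- injectErrors(sh, params$genotypingErrorRate)
      state$sh <- sh
      state$matrix <- sh$matrix
    } else {
      inp <- config$input
      region <- GRanges(inp$chrom, IRanges(c(inp$p_begin, inp$q_begin),
                                           c(inp$p_end, inp$q_end)))
      masks <- if (!is.null(inp$mask)) readMaskBed(inp$mask) else NULL
      state$matrix <- readVcfRegion(inp$path, region,
                                    minMac = inp$min_mac %||% 0L,
                                    masks = masks,
                                    ploidyMode = inp$ploidy %||% "diploid")
    }
    siteTable(state$matrix, file.path(outDir, "sites.tsv"))
    writeHaplotypeVcf(state$matrix, file.path(outDir, "extracted.vcf"))
    mark(st, c("sites.tsv", "extracted.vcf"),
         list(n_hap = nHap(state$matrix), n_sites = nSites(state$matrix)))
  }

  # -- stage 2: filter --------------------------------------------------
  st <- "filter"
  flt <- config$filter
  if (is.null(flt)) {
    state$filtered <- state$matrix
  } else {
    cfg <- fourgtConfig(windows = flt$windows %||% c(10L, 20L, 30L, 40L),
                        tolerance = flt$tolerance %||% 0L)
    res <- fourgtDco(state$matrix, cfg)
    state$filtered <- state$matrix[, res$surviving]
    writeRemovalReport(res, file.path(outDir, "removed.tsv"))
    writeHaplotypeVcf(state$filtered, file.path(outDir, "filtered.vcf"))
    mark(st, c("removed.tsv", "filtered.vcf"),
         list(removed = nrow(res$removed), perPass = res$perPass))
  }

  # -- stage 3: cluster -------------------------------------------------
  st <- "cluster"
  m <- state$filtered
  central <- if (config$input$mode == "simulate") {
    frac <- config$central$fraction %||% 0.5
    n <- nSites(m)
    lo <- floor(n * (0.5 - frac / 2)) + 1L
    hi <- ceiling(n * (0.5 + frac / 2))
    seq(lo, hi)
  } else {
    inp <- config$input
    centralSubset(m, GRanges(inp$chrom, IRanges(inp$p_c, inp$p_end)),
                  GRanges(inp$chrom, IRanges(inp$q_begin, inp$q_c)))
  }
  tree <- upgma(hammingMatrix(m, central))
  part <- if (!is.null(config$cluster$h))
    cutTree(tree, h = config$cluster$h)
  else cutTree(tree, k = config$cluster$k)
  state$partition <- part
  state$central <- central
  writePartition(part, file.path(outDir, "partition.tsv"))
  writeNewick(tree, file.path(outDir, "upgma.nwk"))
  mark(st, c("partition.tsv", "upgma.nwk"),
       list(groups = length(levels(cenhapGroups(part)))))

  # -- stage 4: archaic -------------------------------------------------
  st <- "archaic"
  if (isTRUE(config$archaic$enabled %||%
             (config$input$mode == "simulate"))) {
    annot <- if (!is.null(config$archaic$annotation))
      readArchaicAnnotation(config$archaic$annotation)
    else emitArchaicAnnotation(state$sh)
    cnt <- countArchaic(m, annot)
    summ <- summarizeByCenhap(cnt$counts, part)
    utils::write.table(summ, file.path(outDir, "archaic_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mark(st, "archaic_summary.tsv")
    state$archaic <- summ
  }

  # -- stage 5: divergence ----------------------------------------------
  st <- "divergence"
  dv <- config$divergence
  if (isTRUE(dv$enabled %||% (config$input$mode == "simulate"))) {
    set.seed(.stageSeed(seed, 5L))
    genes <- if (!is.null(dv$genes)) readGeneAlignments(dv$genes)
    else {
      gs <- simulateCodons(state$sh$sim$tree,
                           nGenes = dv$nGenes %||% 6L,
                           codonsPerGene = dv$codonsPerGene %||% 100L,
                           synRate = dv$synRate %||% 5e-8,
                           nonsynRate = dv$nonsynRate %||% 1e-8)
      lapply(gs, function(g)
        g[c(hapIds(m), state$sh$sim$outgroupTip)])
    }
    groups <- stats::setNames(
      as.character(cenhapGroups(part))[match(names(genes[[1]]),
                                             hapIds(part))],
      names(genes[[1]]))
    groups[state$sh$sim$outgroupTip %||% "outgroup"] <- "outgroup"
    gt <- geneTable(genes, outgroupId = "outgroup")
    utils::write.table(gt, file.path(outDir, "gene_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ds <- lapply(genes, geneGroupDs, groups = groups)
    tt <- tmrcaTree(ds, calibrationAge =
                      dv$calibration %||% 6.5e6)
    utils::write.table(tt$nodes, file.path(outDir, "tmrca_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeNewick(tt$tree, file.path(outDir, "tmrca.nwk"))
    mark(st, c("gene_table.tsv", "tmrca_nodes.tsv", "tmrca.nwk"))
    state$tmrca <- tt
  }

  # -- stage 6: arraysize ------------------------------------------------
  st <- "arraysize"
  az <- config$arraysize
  if (isTRUE(az$enabled %||% (config$input$mode == "simulate"))) {
    set.seed(.stageSeed(seed, 6L))
    if (!is.null(az$counts)) {
      counts <- readArrayCounts(az$counts)
      norm <- normalizeArrayCounts(counts)
    } else {
      grp <- as.character(cenhapGroups(part))
      lin.sizes <- az$sizes %||% {
        gl <- levels(cenhapGroups(part))
        stats::setNames(80 + 40 * seq_along(gl) / length(gl), gl)
      }
      ids <- hapIds(part)
      half <- floor(length(ids) / 2)
      samples <- data.frame(
        sample = paste0("s", seq_len(half)),
        lineage1 = grp[2 * seq_len(half) - 1L],
        lineage2 = grp[2 * seq_len(half)],
        stringsAsFactors = FALSE)
      ac <- simulateArrayCounts(samples, unlist(lin.sizes),
                                coverage = az$coverage %||% 10)
      counts <- ac$counts
      norm <- normalizeArrayCounts(counts)
      state$arrayTruth <- ac
    }
    utils::write.table(norm, file.path(outDir, "array_sizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mark(st, "array_sizes.tsv")
  }

  invisible(man)
}
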