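## Stage orchestration. Stages communicate through an environment and
## persist their outputs under outDir, so they can also be re-run
## individually (the CLI subcommands) against a previous run's directory.

.pipelineStages <- c("simulate", "preprocess", "classify", "network",
                     "preserve", "diffcor", "hubs", "enrich")

#' Run the full analysis pipeline
#'
#' Chains simulation (or raw-data ingestion), preprocessing, fertility and
#' expression-class assignment, consensus network construction, module
#' preservation, differential correlation, hub identification and
#' enrichment, writing one TSV per result to `outDir` together with a run
#' manifest (configuration, seed, stage checksums). Each randomized stage
#' derives its seed from the root seed and the stage name, so identical
#' config + seed reproduce byte-identical outputs.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param simConfig optional `SimulationConfig`; when given, stage
#'   `simulate` generates the inputs.
#' @param inputPaths optional named list of input files for real data:
#'   `foreground`, `background` (optional), `probes`, `samples`, and
#'   optionally `gene_positions` (BED), `intervals` (named character vector
#'   of BED paths), `gene_sets` (GMT).
#' @param stages subset of stages to run, in pipeline order.
#' @param verbose log each stage to standard error.
#' @return invisibly, the state environment with the in-memory results
#'   (`se`, `pca`, `classification`, `net`, `preservation`, `diffcor`,
#'   `hubs`, `enrichment`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        simConfig = NULL, inputPaths = NULL,
                        stages = .pipelineStages, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- match.arg(stages, .pipelineStages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$cfg <- config
  state$outDir <- outDir
  state$simConfig <- simConfig
  state$inputPaths <- inputPaths
  state$verbose <- verbose
  state$written <- character()
  for (st in .pipelineStages) {
    if (!st %in% stages) next
    coexLog("stage ", st, " started", verbose = verbose)
    ok <- tryCatch({
      switch(st,
             simulate = .stageSimulate(state),
             preprocess = .stagePreprocess(state),
             classify = .stageClassify(state),
             network = .stageNetwork(state),
             preserve = .stagePreserve(state),
             diffcor = .stageDiffcor(state),
             hubs = .stageHubs(state),
             enrich = .stageEnrich(state))
      TRUE
    }, error = function(e) {
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    coexLog("stage ", st, " done", verbose = verbose)
  }
  .writeManifest(state)
  invisible(state)
}

.out <- function(state, name) file.path(state$outDir, name)

.saveTable <- function(state, df, name, header = character()) {
  path <- .out(state, name)
  writeResultTSV(df, path, header)
  state$written <- union(state$written, name)
  invisible(path)
}

.saveMatrix <- function(state, m, name, idColumn = "probe_id") {
  path <- .out(state, name)
  writeExpressionTSV(m, path, idColumn)
  state$written <- union(state$written, name)
  invisible(path)
}

## ---------------------------------------------------------------------------
.stageSimulate <- function(state) {
  simCfg <- state$simConfig
  if (is.null(simCfg)) stop("no simulation config supplied")
  simCfg$seed <- stageSeed(state$cfg$seed, "simulate")
  sim <- simulateDataset(simCfg)
  state$sim <- sim
  state$bundle <- simulateAnnotations(sim@truth, simCfg,
                                      seed = stageSeed(state$cfg$seed,
                                                       "annotations"))
  .saveMatrix(state, sim@foreground, "foreground.tsv")
  .saveMatrix(state, sim@background, "background.tsv")
  .saveMatrix(state, assay(sim@se), "expression_log2.tsv")
  .saveTable(state, as.data.frame(rowData(sim@se)), "probes.tsv",
             "probe annotation: probe_id, gene_id, is_negative_control")
  .saveTable(state, as.data.frame(colData(sim@se)), "samples.tsv",
             c("sample table; weights in grams, sperm_count in cells",
               "planted_* columns are simulation ground truth"))
  tr <- sim@truth
  truthDF <- data.frame(gene_id = names(tr$module_of_gene),
                        module = unname(tr$module_of_gene),
                        loading = unname(tr$loadings[
                          names(tr$module_of_gene)]),
                        disrupted = names(tr$module_of_gene) %in%
                          unlist(tr$disrupted_genes))
  .saveTable(state, truthDF, "truth_genes.tsv",
             "planted module membership and loadings")
  writeBED(genePositions(state$bundle), .out(state, "gene_positions.bed"))
  ints <- intervalSets(state$bundle)
  for (nm in names(ints))
    writeBED(ints[[nm]], .out(state, paste0("intervals_", nm, ".bed")))
  writeGMT(geneSets(state$bundle), .out(state, "gene_sets.gmt"),
           descriptions = setNames(state$bundle@setCategory,
                                   names(geneSets(state$bundle))))
  state$written <- union(state$written,
                         c("gene_positions.bed",
                           paste0("intervals_", names(ints), ".bed"),
                           "gene_sets.gmt"))
  invisible(TRUE)
}

.loadRawInputs <- function(state) {
  if (!is.null(state$sim)) {
    sim <- state$sim
    state$foreground <- sim@foreground
    state$background <- sim@background
    state$probeData <- as.data.frame(rowData(sim@se))
    state$sampleTable <- as.data.frame(colData(sim@se))
    return(invisible(TRUE))
  }
  ip <- state$inputPaths
  fgPath <- if (!is.null(ip$foreground)) ip$foreground
    else .out(state, "foreground.tsv")
  bgPath <- if (!is.null(ip$background)) ip$background
    else { p <- .out(state, "background.tsv"); if (file.exists(p)) p
      else NULL }
  state$foreground <- readExpressionTSV(fgPath)
  state$background <- if (!is.null(bgPath)) readExpressionTSV(bgPath)
    else NULL
  prPath <- if (!is.null(ip$probes)) ip$probes else .out(state, "probes.tsv")
  pd <- read.delim(prPath, sep = "\t", comment.char = "#")
  pd$is_negative_control <- as.logical(pd$is_negative_control)
  pd$gene_id[is.na(pd$gene_id)] <- ""
  state$probeData <- pd
  smPath <- if (!is.null(ip$samples)) ip$samples
    else .out(state, "samples.tsv")
  state$sampleTable <- readSampleTable(smPath)
  invisible(TRUE)
}

.stagePreprocess <- function(state) {
  .loadRawInputs(state)
  cfgP <- state$cfg$preprocess
  fg <- state$foreground
  corr <- if (!is.null(state$background))
    backgroundCorrectHalf(fg, state$background, cfgP$offset)
  else fg
  pd <- state$probeData[match(rownames(corr), state$probeData$probe_id), ]
  se <- makeCoexExperiment(corr, pd, state$sampleTable,
                           scaleTag = "background_corrected")
  flt <- filterExpressed(se, cfgP$negctrl_quantile, cfgP$brightness_factor,
                         cfgP$min_sample_fraction)
  coexLog("expression filter kept ", length(flt$kept), " of ", nrow(se),
          " probes", verbose = state$verbose)
  se <- se[flt$kept, ]
  se <- log2Transform(se)
  se <- quantileNormalize(se)
  se <- ebBatchAdjust(se)
  state$se <- se
  state$pca <- pcaSamples(se)
  state$outliers <- flagOutlierSamples(state$pca, cfgP$k_mad)
  if (length(state$outliers))
    coexLog("flagged expression outlier sample(s): ",
            paste(state$outliers, collapse = ", "),
            verbose = state$verbose)
  .saveMatrix(state, assay(se), "preprocessed_matrix.tsv")
  .saveTable(state,
             data.frame(sample_id = rownames(state$pca$scores),
                        state$pca$scores[, seq_len(min(5L,
                          ncol(state$pca$scores))), drop = FALSE],
                        check.names = FALSE),
             "pca_scores.tsv",
             "sample scores on leading PCs of the scaled log2 matrix")
  .saveTable(state,
             data.frame(component = seq_along(state$pca$explained),
                        explained_fraction = state$pca$explained),
             "pca_explained.tsv", "per-component explained fraction")
  .saveTable(state,
             data.frame(sample_id = names(flt$thresholds),
                        detection_threshold = unname(flt$thresholds)),
             "detection_thresholds.tsv",
             "per-array negative-control detection threshold (intensity)")
  .saveTable(state, data.frame(sample_id = state$outliers),
             "outlier_flags.tsv",
             "samples beyond the PC1/PC2 MAD rule (flagged, not removed)")
  invisible(TRUE)
}

.requireSE <- function(state) {
  if (!is.null(state$se)) return(invisible(TRUE))
  m <- readExpressionTSV(.out(state, "preprocessed_matrix.tsv"))
  st <- readSampleTable(.out(state, "samples.tsv"))
  st <- st[match(colnames(m), st$sample_id), ]
  state$se <- makeCoexExperiment(m, sampleData = st,
                                 scaleTag = "batch_adjusted")
  state$pca <- pcaSamples(state$se)
  invisible(TRUE)
}

.stageClassify <- function(state) {
  .requireSE(state)
  st <- as.data.frame(colData(state$se))
  if (!"testis_weight" %in% names(st))
    stop("sample table with phenotypes is required for classification")
  cls <- classifyFertility(st, pooledPure = state$cfg$preprocess$pooled_pure)
  cls <- splitExpressionClass(cls, state$pca)
  state$classification <- cls
  iv <- attr(cls, "reference_interval")
  .saveTable(state, cls, "classification.tsv",
             c("fertility classes from relative testis weight (g/g) and sperm count",
               sprintf("PC1 reference interval: [%.4f, %.4f]", iv[1L],
                       iv[2L])))
  invisible(TRUE)
}

.requireClassification <- function(state) {
  if (!is.null(state$classification)) return(invisible(TRUE))
  path <- .out(state, "classification.tsv")
  if (!file.exists(path)) stop("classification is missing; run 'classify'")
  state$classification <- read.delim(path, sep = "\t", comment.char = "#")
  invisible(TRUE)
}

## expression submatrix of one population restricted to a class
.popMatrix <- function(state, population, classes, expressionClasses = NULL) {
  cls <- state$classification
  keep <- cls$population %in% population & cls$fertility_class %in% classes
  if (!is.null(expressionClasses))
    keep <- keep & cls$expression_class %in% expressionClasses
  ids <- intersect(colnames(state$se), cls$sample_id[keep])
  assay(state$se)[, ids, drop = FALSE]
}

.hybridPopulations <- function(state) {
  pops <- unique(state$classification$population[
    state$classification$fertility_class != "pure"])
  sort(pops)
}

.stageNetwork <- function(state) {
  .requireSE(state)
  .requireClassification(state)
  cfgN <- state$cfg$network
  pops <- .hybridPopulations(state)
  fertile <- lapply(pops, function(p) .popMatrix(state, p, "fertile"))
  names(fertile) <- pops
  pooled <- do.call(cbind, fertile)
  flt <- connectivityFilter(pooled, cfgN$beta,
                            center = cfgN$connectivity_center,
                            verbose = state$verbose)
  coexLog("connectivity filter kept ", length(flt$kept), " of ",
          nrow(pooled), " probes", verbose = state$verbose)
  fertile <- lapply(fertile, function(x) x[flt$kept, , drop = FALSE])
  sft <- pickSoftThreshold(cor(t(pooled[flt$kept, , drop = FALSE])),
                           betas = c(1:8, 10, 12, 14, 16))
  net <- buildConsensusNetwork(fertile, beta = cfgN$beta,
                               minModuleSize = cfgN$min_module_size,
                               deepSplit = cfgN$deep_split,
                               mergeHeight = cfgN$merge_height,
                               calibrationQuantile =
                                 cfgN$calibration_quantile,
                               verbose = state$verbose)
  state$net <- net
  labels <- moduleLabels(net)
  geneOf <- .geneOfProbe(state)
  .saveTable(state,
             data.frame(probe_id = names(labels),
                        gene_id = unname(geneOf[names(labels)]),
                        module = unname(labels)),
             "modules.tsv",
             "consensus module assignment; module 0 is the unassigned bin")
  .saveTable(state, sft$table, "soft_threshold.tsv",
             sprintf("scale-free fit diagnostics; recommended beta = %d",
                     sft$recommended))
  for (p in networkPopulations(net)) {
    me <- moduleEigengenes(net)[[p]]
    .saveMatrix(state, me, paste0("eigengenes_", p, ".tsv"),
                idColumn = "module")
    .saveMatrix(state, moduleKME(net)[[p]], paste0("kme_", p, ".tsv"))
  }
  ## module-trait correlations: eigengenes recomputed over all hybrids of
  ## each population, correlated with the fertility (and any motility)
  ## traits
  mtRows <- list()
  traitsAll <- .traitTable(state)
  for (p in pops) {
    xAll <- .popMatrix(state, p, c("fertile", "intermediate", "subfertile"))
    xAll <- xAll[networkProbes(net), , drop = FALSE]
    meAll <- moduleEigengenesAll(xAll, labels)$eigengenes
    mt <- moduleTraitCorrelation(meAll, traitsAll[colnames(xAll), ,
                                                  drop = FALSE])
    mt$population <- p
    mtRows[[p]] <- mt
  }
  mtDF <- do.call(rbind, mtRows)
  rownames(mtDF) <- NULL
  state$moduleTrait <- mtDF
  .saveTable(state, mtDF, "module_trait.tsv",
             "Pearson eigengene-trait correlations over all hybrids per population")
  saveRDS(net, .out(state, "network.rds"))
  invisible(TRUE)
}

.geneOfProbe <- function(state) {
  pd <- if (!is.null(state$probeData)) state$probeData
    else if (!is.null(state$sim)) as.data.frame(rowData(state$sim@se))
    else NULL
  if (is.null(pd)) {
    path <- .out(state, "probes.tsv")
    if (file.exists(path))
      pd <- read.delim(path, sep = "\t", comment.char = "#")
  }
  if (is.null(pd))
    return(setNames(rownames(state$se), rownames(state$se)))
  setNames(as.character(pd$gene_id), pd$probe_id)
}

.traitTable <- function(state) {
  st <- as.data.frame(colData(state$se))
  tr <- data.frame(rel_testis = st$testis_weight / st$body_weight,
                   sperm = st$sperm_count, row.names = st$sample_id)
  for (mt in c("VCL", "VAP", "VSL", "ALH", "BCF"))
    if (mt %in% names(st)) tr[[mt]] <- st[[mt]]
  tr
}

.requireNetwork <- function(state) {
  if (!is.null(state$net)) return(invisible(TRUE))
  path <- .out(state, "network.rds")
  if (!file.exists(path)) stop("network is missing; run 'network'")
  state$net <- readRDS(path)
  invisible(TRUE)
}

.presTestGroups <- list(
  intermediate = list(classes = "intermediate", expr = NULL),
  SFNE = list(classes = "subfertile", expr = "SFNE"),
  SFAE = list(classes = "subfertile", expr = "SFAE"))

.stagePreserve <- function(state) {
  .requireSE(state); .requireClassification(state); .requireNetwork(state)
  cfgP <- state$cfg$preservation
  net <- state$net
  labels <- moduleLabels(net)
  rows <- list()
  for (p in networkPopulations(net)) {
    disc <- .popMatrix(state, p, "fertile")[networkProbes(net), ,
                                            drop = FALSE]
    for (g in names(.presTestGroups)) {
      gdef <- .presTestGroups[[g]]
      test <- .popMatrix(state, p, gdef$classes, gdef$expr)
      if (ncol(test) < 5L) {
        coexLog("preservation: skipping ", p, "/", g, " (",
                ncol(test), " samples)", verbose = state$verbose)
        next
      }
      test <- test[networkProbes(net), , drop = FALSE]
      rep <- modulePreservation(
        disc, test, labels, beta = net@params$beta,
        nPermZ = cfgP$n_perm_z, nPermSig = cfgP$n_perm_sig,
        alpha = cfgP$alpha, bonferroni = cfgP$bonferroni,
        seed = stageSeed(state$cfg$seed, paste0("preserve_", p, "_", g)),
        verbose = FALSE)
      df <- merge(preservationSummary(rep), preservationPValues(rep),
                  by = "module")
      df <- cbind(population = p, test_group = g, df)
      rows[[paste(p, g)]] <- df
      coexLog("preservation ", p, "/", g, " done",
              verbose = state$verbose)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  state$preservation <- out
  .saveTable(state, out, "preservation.tsv",
             c("module preservation: Z scores, bands and the seven permutation p-values",
               "Z_summary bands: strong >= 10, weak in [2, 10), none < 2"))
  invisible(TRUE)
}

.stageDiffcor <- function(state) {
  .requireSE(state); .requireClassification(state); .requireNetwork(state)
  cfgD <- state$cfg$diffcor
  net <- state$net
  labels <- moduleLabels(net)
  rows <- list()
  for (p in networkPopulations(net)) {
    ref <- .popMatrix(state, p, "fertile")[networkProbes(net), ,
                                           drop = FALSE]
    for (g in c("SFNE", "SFAE")) {
      test <- .popMatrix(state, p, "subfertile", g)
      if (ncol(test) < 5L) next
      test <- test[networkProbes(net), , drop = FALSE]
      res <- geneMedianLFC(ref, test, labels, nPerm = cfgD$n_perm,
                           floorAbsCor = cfgD$min_abs_ref_cor,
                           alpha = cfgD$alpha,
                           seed = stageSeed(state$cfg$seed,
                                            paste0("diffcor_", p, "_", g)))
      res <- cbind(population = p, test_group = g, res)
      rows[[paste(p, g)]] <- res
      coexLog("diffcor ", p, "/", g, " done", verbose = state$verbose)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  state$diffcor <- out
  .saveTable(state, out, "diffcor.tsv",
             "per-gene median log2 fold change of within-module |correlation|")
  summ <- list()
  for (key in names(rows)) {
    s <- diffcorModuleSummary(rows[[key]])
    s <- cbind(population = rows[[key]]$population[1L],
               test_group = rows[[key]]$test_group[1L], s)
    summ[[key]] <- s
  }
  summDF <- do.call(rbind, summ)
  rownames(summDF) <- NULL
  state$diffcorSummary <- summDF
  .saveTable(state, summDF, "diffcor_summary.tsv",
             "percent of module genes with significant coexpression loss/reversal")
  invisible(TRUE)
}

.loadBundle <- function(state) {
  if (!is.null(state$bundle)) return(invisible(TRUE))
  gp <- .out(state, "gene_positions.bed")
  if (!file.exists(gp)) {
    state$bundle <- NULL
    return(invisible(FALSE))
  }
  genePos <- readBED(gp)
  intFiles <- list.files(state$outDir, pattern = "^intervals_.*\\.bed$")
  ints <- lapply(intFiles, function(f) readBED(.out(state, f)))
  names(ints) <- sub("^intervals_(.*)\\.bed$", "\\1", intFiles)
  gmt <- .out(state, "gene_sets.gmt")
  sets <- if (file.exists(gmt)) readGMT(gmt) else list()
  cats <- attr(sets, "description")
  if (is.null(cats)) cats <- setNames(rep("term", length(sets)),
                                      names(sets))
  cats[!cats %in% c("term", "cell_type", "qtt")] <- "term"
  state$bundle <- AnnotationBundle(genePositions = genePos,
                                   intervalSets = ints,
                                   geneSets = sets[names(sets)],
                                   setCategories = cats)
  invisible(TRUE)
}

.stageHubs <- function(state) {
  .requireSE(state); .requireNetwork(state)
  cfgH <- state$cfg$hubs
  geneOf <- .geneOfProbe(state)
  hubs <- identifyHubs(state$net, kmeThreshold = cfgH$kme_threshold,
                       edgeThreshold = cfgH$edge_threshold,
                       topNDegree = cfgH$top_n_degree,
                       combineRule = cfgH$combine_rule,
                       geneOfProbe = geneOf)
  .loadBundle(state)
  if (!is.null(state$bundle) && length(intervalSets(state$bundle))) {
    gp <- genePositions(state$bundle)
    for (nm in names(intervalSets(state$bundle))) {
      reg <- genesInIntervals(gp, intervalSets(state$bundle)[[nm]])
      hubs[[paste0("in_", nm)]] <- hubs$gene_id %in% reg
    }
  }
  state$hubs <- hubs
  .saveTable(state, hubs, "hubs.tsv",
             "hub genes by kME and intramodular degree; per-region membership flags")

  if (!is.null(state$bundle) && length(intervalSets(state$bundle))) {
    labels <- moduleLabels(state$net)
    expressedGenes <- unique(geneOf[rownames(state$se)])
    expressedGenes <- expressedGenes[nzchar(expressedGenes)]
    moduleGenes <- unique(geneOf[names(labels)[labels > 0L]])
    hubGenes <- unique(hubs$gene_id[hubs$is_hub])
    gp <- genePositions(state$bundle)
    enr <- list()
    for (nm in names(intervalSets(state$bundle))) {
      reg <- genesInIntervals(gp, intervalSets(state$bundle)[[nm]])
      for (uniName in c("expressed", "module_assigned")) {
        uni <- if (uniName == "expressed") expressedGenes else moduleGenes
        pe <- permutationRegionEnrichment(
          intersect(hubGenes, uni), uni, reg,
          nDraws = state$cfg$enrichment$n_draws,
          seed = stageSeed(state$cfg$seed,
                           paste0("hubenr_", nm, "_", uniName)))
        enr[[paste(nm, uniName)]] <-
          data.frame(region_set = nm, universe = uniName,
                     n_hubs = length(intersect(hubGenes, uni)),
                     observed = pe$observed,
                     null_mean = pe$null_mean,
                     null_q95 = pe$null_quantile,
                     empirical_p = pe$empirical_p,
                     significant = pe$significant)
      }
    }
    enrDF <- do.call(rbind, enr)
    rownames(enrDF) <- NULL
    state$hubEnrichment <- enrDF
    .saveTable(state, enrDF, "hub_region_enrichment.tsv",
               "hub genes vs region gene sets: permutation draws from each universe")
  }
  invisible(TRUE)
}

.stageEnrich <- function(state) {
  .requireSE(state); .requireNetwork(state)
  .loadBundle(state)
  if (is.null(state$bundle) || !length(geneSets(state$bundle))) {
    coexLog("no gene sets available; enrichment skipped",
            verbose = state$verbose)
    return(invisible(FALSE))
  }
  geneOf <- .geneOfProbe(state)
  labels <- moduleLabels(state$net)
  moduleGenes <- lapply(split(names(labels)[labels > 0L],
                              labels[labels > 0L]),
                        function(pr) unique(geneOf[pr]))
  universe <- unique(geneOf[rownames(state$se)])
  universe <- universe[nzchar(universe)]
  enr <- setOverrepresentation(moduleGenes, state$bundle, universe,
                               termMin = state$cfg$enrichment$term_min,
                               termMax = state$cfg$enrichment$term_max)
  state$enrichment <- enr
  if (!is.null(enr))
    .saveTable(state, enr, "enrichment.tsv",
               "gene-set over-representation (one-sided Fisher, BH within category)")
  invisible(TRUE)
}

.writeManifest <- function(state) {
  lines <- c("# run manifest", .flattenConfig(state$cfg),
             sprintf("run.timestamp=%s", .timestamp()))
  for (f in sort(state$written)) {
    path <- .out(state, f)
    if (file.exists(path))
      lines <- c(lines, sprintf("checksum.%s=%s", f,
                                unname(tools::md5sum(path))))
  }
  writeLines(lines, .out(state, "manifest.txt"))
  invisible(TRUE)
}
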