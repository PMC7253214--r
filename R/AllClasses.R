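#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end findOverlaps
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------------
## ConsensusNetwork
## ---------------------------------------------------------------------------

#' Consensus coexpression network
#'
#' Holds everything produced by [buildConsensusNetwork()]: the per-population
#' signed adjacency-derived topological overlap matrices (TOMs), the
#' calibrated consensus TOM, the average-linkage dendrogram, module labels
#' (positive integers; 0 is the unassigned "bin"), per-population module
#' eigengenes and kME matrices, and the parameters used.
#'
#' Accessors: `moduleLabels()` (named integer vector), `moduleEigengenes()`
#' (list per population of module x sample matrices), `moduleKME()` (list per
#' population of probe x module matrices), `consensusTOM()`,
#' `populationTOM(object, population)`, `networkProbes()`,
#' `networkPopulations()`.
#'
#' @slot probes character vector of probe identifiers in network order.
#' @slot populations character names of the cohorts used (e.g. F2, HZ).
#' @slot toms list of per-population TOM matrices (calibrated scale).
#' @slot consTOM consensus TOM matrix.
#' @slot dendro the `hclust` object over `1 - consTOM`.
#' @slot labels named integer module labels, 0 = unassigned.
#' @slot eigengenes list per population: module x sample eigengene matrix.
#' @slot kme list per population: probe x module kME matrix.
#' @slot propVarExplained list per population: named numeric per module.
#' @slot params list of network parameters used.
#' @aliases moduleLabels moduleEigengenes moduleKME consensusTOM
#'   populationTOM networkProbes networkPopulations
#' @export
setClass("ConsensusNetwork",
  representation(probes = "character", populations = "character",
                 toms = "list", consTOM = "matrix", dendro = "ANY",
                 labels = "integer", eigengenes = "list", kme = "list",
                 propVarExplained = "list", params = "list"))

setValidity("ConsensusNetwork", function(object) {
  msgs <- character()
  n <- length(object@probes)
  if (anyDuplicated(object@probes)) msgs <- c(msgs, "duplicated probe ids")
  if (!all(dim(object@consTOM) == c(n, n)))
    msgs <- c(msgs, "consensus TOM dimension does not match probes")
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels length does not match probes")
  if (length(object@labels) && min(object@labels) < 0L)
    msgs <- c(msgs, "module labels must be >= 0")
  if (!all(names(object@toms) == object@populations))
    msgs <- c(msgs, "TOM list names must equal populations")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ConsensusNetwork-class
#' @param object,x a `ConsensusNetwork`.
#' @param population population name.
#' @param ... unused.
#' @export
setMethod("moduleLabels", "ConsensusNetwork", function(object, ...)
  object@labels)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("moduleEigengenes", "ConsensusNetwork", function(object, ...)
  object@eigengenes)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("moduleKME", "ConsensusNetwork", function(object, ...) object@kme)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("consensusTOM", "ConsensusNetwork", function(object, ...)
  object@consTOM)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("populationTOM", "ConsensusNetwork",
  function(object, population, ...) {
    if (!population %in% object@populations)
      stop("unknown population '", population, "'", call. = FALSE)
    object@toms[[population]]
  })

#' @rdname ConsensusNetwork-class
#' @export
setMethod("networkProbes", "ConsensusNetwork", function(object, ...)
  object@probes)

#' @rdname ConsensusNetwork-class
#' @export
setMethod("networkPopulations", "ConsensusNetwork", function(object, ...)
  object@populations)

setMethod("show", "ConsensusNetwork", function(object) {
  tab <- table(object@labels[object@labels > 0L])
  cat("ConsensusNetwork with", length(object@probes), "probes across",
      length(object@populations), "populations (",
      paste(object@populations, collapse = ", "), ")\n")
  cat("  soft power:", object@params$beta,
      " modules:", length(tab),
      " unassigned:", sum(object@labels == 0L), "\n")
  if (length(tab))
    cat("  module sizes:", paste(as.integer(tab), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## PreservationReport
## ---------------------------------------------------------------------------

#' Module preservation report
#'
#' Result of [modulePreservation()]: per module the seven observed
#' preservation statistics (four density: meanCor, meanAdj, propVarExplained,
#' meanSignedKME; three connectivity: cor_kIM, cor_kME, cor_cor), their
#' permutation Z scores, `Z_density`, `Z_connectivity`,
#' `Z_summary = (Z_density + Z_connectivity) / 2`, the median-rank statistic,
#' the seven one-sided permutation p-values, a preservation band
#' (`strong` / `weak` / `none` for Z_summary >= 10 / in [2, 10) / < 2) and the
#' `all_significant` flag (all seven p < alpha).
#'
#' Accessors: `preservationSummary()`, `preservationObserved()`,
#' `preservationZ()`, `preservationPValues()`.
#'
#' @slot observed data.frame of observed statistics, one row per module.
#' @slot zscores data.frame of per-statistic permutation Z scores.
#' @slot pvalues data.frame of the seven one-sided permutation p-values.
#' @slot summary data.frame: module, moduleSize, Z_density, Z_connectivity,
#'   Z_summary, median_rank, preserved_flag, all_significant, min_p.
#' @slot params list of preservation parameters used.
#' @aliases preservationSummary preservationObserved preservationZ
#'   preservationPValues
#' @export
setClass("PreservationReport",
  representation(observed = "data.frame", zscores = "data.frame",
                 pvalues = "data.frame", summary = "data.frame",
                 params = "list"))

setValidity("PreservationReport", function(object) {
  msgs <- character()
  pv <- as.matrix(object@pvalues[, -1, drop = FALSE])
  if (length(pv) && (any(pv <= 0) || any(pv > 1)))
    msgs <- c(msgs, "p-values must lie in (0, 1]")
  s <- object@summary
  if (nrow(s)) {
    ok <- abs(s$Z_summary - (s$Z_density + s$Z_connectivity) / 2) < 1e-8
    ok[!is.finite(s$Z_summary)] <- TRUE
    if (!all(ok)) msgs <- c(msgs, "Z_summary must average the two medians")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname PreservationReport-class
#' @param object a `PreservationReport`.
#' @param ... unused.
#' @export
setMethod("preservationSummary", "PreservationReport", function(object, ...)
  object@summary)

#' @rdname PreservationReport-class
#' @export
setMethod("preservationObserved", "PreservationReport", function(object, ...)
  object@observed)

#' @rdname PreservationReport-class
#' @export
setMethod("preservationZ", "PreservationReport", function(object, ...)
  object@zscores)

#' @rdname PreservationReport-class
#' @export
setMethod("preservationPValues", "PreservationReport", function(object, ...)
  object@pvalues)

setMethod("show", "PreservationReport", function(object) {
  s <- object@summary
  cat("PreservationReport for", nrow(s), "modules\n")
  if (nrow(s)) {
    cat(sprintf("  %-8s %6s %10s %10s %9s %6s\n", "module", "size",
                "Z_summary", "medianRank", "flag", "allSig"))
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-8s %6d %10.2f %10.1f %9s %6s\n", s$module[i],
                  s$moduleSize[i], s$Z_summary[i], s$median_rank[i],
                  s$preserved_flag[i], s$all_significant[i]))
  }
})

## ---------------------------------------------------------------------------
## AnnotationBundle
## ---------------------------------------------------------------------------

#' Gene annotation bundle
#'
#' Container for the annotation inputs of the enrichment stage: gene
#' positions (`GRanges`, 0-based half-open intervals stored with their BED
#' coordinates in `mcols()$bedStart` / `bedEnd`), named genomic interval sets
#' (`GRangesList`, e.g. GWAS sterility regions, trans-eQTL hotspots), and
#' named gene sets with a category each (`term`, `cell_type` or `qtt`).
#'
#' @slot genePos `GRanges` named by gene id.
#' @slot intervals `GRangesList` of named region sets.
#' @slot sets named list of character vectors of gene ids.
#' @slot setCategory named character, one of term/cell_type/qtt per set.
#' @aliases genePositions intervalSets geneSets
#' @export
setClass("AnnotationBundle",
  representation(genePos = "GRanges", intervals = "GRangesList",
                 sets = "list", setCategory = "character"))

setValidity("AnnotationBundle", function(object) {
  msgs <- character()
  if (length(object@sets) &&
      !identical(names(object@sets), names(object@setCategory)))
    msgs <- c(msgs, "gene sets and categories must share names")
  if (length(object@setCategory) &&
      !all(object@setCategory %in% c("term", "cell_type", "qtt")))
    msgs <- c(msgs, "set categories must be term, cell_type or qtt")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AnnotationBundle-class
#' @param object an `AnnotationBundle`.
#' @param category optional filter: `term`, `cell_type` or `qtt`.
#' @param ... unused.
#' @export
setMethod("genePositions", "AnnotationBundle", function(object, ...)
  object@genePos)

#' @rdname AnnotationBundle-class
#' @export
setMethod("intervalSets", "AnnotationBundle", function(object, ...)
  object@intervals)

#' @rdname AnnotationBundle-class
#' @export
setMethod("geneSets", "AnnotationBundle", function(object, category = NULL,
                                                   ...) {
  if (is.null(category)) return(object@sets)
  object@sets[object@setCategory == category]
})

setMethod("show", "AnnotationBundle", function(object) {
  cat("AnnotationBundle:", length(object@genePos), "gene positions,",
      length(object@intervals), "interval sets,",
      length(object@sets), "gene sets\n")
  if (length(object@setCategory))
    print(table(object@setCategory))
})

#' Construct an AnnotationBundle
#'
#' @param genePositions `GRanges` named by gene id (or a data.frame with
#'   columns chrom, start, end, gene_id in 0-based half-open coordinates).
#' @param intervalSets named list of `GRanges` (or of data.frames as above).
#' @param geneSets named list of character gene-id vectors.
#' @param setCategories named character vector mapping each gene set to
#'   `term`, `cell_type` or `qtt` (default: all `term`).
#' @return an [AnnotationBundle-class] object.
#' @export
AnnotationBundle <- function(genePositions = GRanges(),
                             intervalSets = list(),
                             geneSets = list(), setCategories = NULL) {
  toGR <- function(x) {
    if (is(x, "GRanges")) return(x)
    gr <- GRanges(x$chrom, IRanges(x$start + 1L, x$end))
    gr$bedStart <- x$start
    gr$bedEnd <- x$end
    if (!is.null(x$gene_id)) names(gr) <- x$gene_id
    if (!is.null(x$name)) gr$name <- x$name
    gr
  }
  genePos <- toGR(genePositions)
  ints <- GRangesList(lapply(intervalSets, toGR))
  if (is.null(setCategories))
    setCategories <- setNames(rep("term", length(geneSets)), names(geneSets))
  new("AnnotationBundle", genePos = genePos, intervals = ints,
      sets = geneSets, setCategory = setCategories[names(geneSets)])
}
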