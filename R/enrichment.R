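#' Identify module hub genes
#'
#' Two routes into the hub set of each module: (1) probes whose kME,
#' combined across populations by `combineRule` (default `min`: both
#' populations must pass), reaches `kmeThreshold`; (2) the `topNDegree`
#' probes per population by intramodular degree, where the degree of probe i
#' is the number of module partners j with `TOM_ij >= edgeThreshold` (ties
#' broken by higher summed TOM, then by probe id). Results are reported at
#' both probe and gene level (a gene is a hub if any of its probes is).
#'
#' @param net a [ConsensusNetwork-class].
#' @param kmeThreshold kME cutoff (default 0.85).
#' @param edgeThreshold TOM edge weight defining a connection (default 0.1).
#' @param topNDegree number of top-connected probes per population
#'   (default 5).
#' @param combineRule `"min"` or `"mean"` across populations.
#' @param geneOfProbe optional named character mapping probe id to gene id
#'   (defaults to the probe id itself).
#' @return data.frame: probe_id, gene_id, module, kme_combined, kme_hub,
#'   degree per population, degree_hub, is_hub.
#' @export
identifyHubs <- function(net, kmeThreshold = 0.85, edgeThreshold = 0.1,
                         topNDegree = 5L, combineRule = c("min", "mean"),
                         geneOfProbe = NULL) {
  combineRule <- match.arg(combineRule)
  labels <- moduleLabels(net)
  pops <- networkPopulations(net)
  kmes <- moduleKME(net)
  probes <- networkProbes(net)
  if (is.null(geneOfProbe))
    geneOfProbe <- setNames(probes, probes)
  mods <- sort(unique(labels[labels > 0L]))
  rows <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    mcol <- as.character(m)
    kmeMat <- vapply(pops, function(p) kmes[[p]][members, mcol],
                     numeric(length(members)))
    kmeComb <- if (combineRule == "min") apply(kmeMat, 1L, min)
      else rowMeans(kmeMat)
    kmeHub <- kmeComb >= kmeThreshold

    degMat <- matrix(0L, length(members), length(pops),
                     dimnames = list(members, pops))
    degHub <- rep(FALSE, length(members))
    if (length(members) <= topNDegree) {
      warning("module ", m, " has <= topNDegree members; all eligible")
      degHub[] <- TRUE
    }
    for (p in pops) {
      tm <- populationTOM(net, p)[members, members, drop = FALSE]
      diag(tm) <- 0
      deg <- rowSums(tm >= edgeThreshold)
      degMat[, p] <- as.integer(deg)
      if (length(members) > topNDegree) {
        ord <- order(-deg, -rowSums(tm), members)
        degHub[ord[seq_len(topNDegree)]] <- TRUE
      }
    }
    df <- data.frame(probe_id = members,
                     gene_id = unname(geneOfProbe[members]),
                     module = mcol, kme_combined = kmeComb,
                     kme_hub = kmeHub, stringsAsFactors = FALSE,
                     row.names = NULL)
    for (p in pops) df[[paste0("degree_", p)]] <- degMat[, p]
    df$degree_hub <- degHub
    df$is_hub <- kmeHub | degHub
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  ## gene-level flag: a gene is a hub if any of its probes is
  hubGenes <- unique(out$gene_id[out$is_hub])
  out$gene_is_hub <- out$gene_id %in% hubGenes
  out
}

#' One-sided Fisher overlap test
#'
#' Hypergeometric upper-tail probability of observing at least `k` genes in
#' the overlap of a module of size `K` and a gene set of size `n` inside a
#' universe of size `N`:
#' \deqn{p = \sum_{x \ge k} \binom{K}{x}\binom{N-K}{n-x} / \binom{N}{n}.}
#' Computed with `stats::phyper` (log-gamma arithmetic, stable up to
#' N of 1e6 and beyond). The odds ratio comes from the 2x2 table; when any
#' cell is zero a 0.5 continuity correction is applied and reported.
#'
#' @param k overlap count.
#' @param K module size.
#' @param n gene-set size.
#' @param N universe size.
#' @return list: `p`, `odds_ratio`, `continuity_corrected`.
#' @export
#' @examples
#' fisherOverlap(2, 2, 2, 4)$p  # 1/6
fisherOverlap <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("inconsistent overlap counts", call. = FALSE)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- K - k; cc <- n - k; d <- N - K - n + k
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  list(p = p, odds_ratio = or, continuity_corrected = corrected)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)} mapped back to the
#' input order; delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation across modules
#'
#' Intersects every gene set with the declared universe, keeps sets whose
#' intersected size lies within `[termMin, termMax]`, and tests each
#' (module, set) pair with the one-sided [fisherOverlap()] test. BH
#' correction is applied within each annotation category (term / cell_type /
#' qtt) separately, mirroring per-table corrections.
#'
#' @param moduleGenes named list: module label -> character gene ids.
#' @param bundle an [AnnotationBundle-class] (or a named list of gene sets,
#'   then all sets are category `term`).
#' @param universe character vector of gene ids; modules and sets are
#'   intersected with it before testing.
#' @param termMin,termMax inclusive size window after intersection
#'   (defaults 11 and 499: more than 10 and fewer than 500 genes).
#' @return data.frame: set, category, module, overlap (k), set_size (n),
#'   module_size (K), universe_size (N), odds_ratio, p, q.
#' @export
setOverrepresentation <- function(moduleGenes, bundle, universe,
                                  termMin = 11L, termMax = 499L) {
  if (is(bundle, "AnnotationBundle")) {
    sets <- geneSets(bundle)
    cats <- bundle@setCategory
  } else {
    sets <- bundle
    cats <- setNames(rep("term", length(sets)), names(sets))
  }
  universe <- unique(universe)
  N <- length(universe)
  if (!N) stop("empty universe", call. = FALSE)
  rows <- list()
  for (s in names(sets)) {
    setU <- intersect(sets[[s]], universe)
    if (!length(setU)) {
      coexLog("gene set ", s, " does not intersect the universe; skipped",
              verbose = FALSE)
      next
    }
    n <- length(setU)
    if (n < termMin || n > termMax) next
    for (m in names(moduleGenes)) {
      modU <- intersect(moduleGenes[[m]], universe)
      K <- length(modU)
      if (!K) next
      k <- length(intersect(modU, setU))
      ft <- fisherOverlap(k, K, n, N)
      rows[[length(rows) + 1L]] <-
        data.frame(set = s, category = unname(cats[s]), module = m,
                   overlap = k, set_size = n, module_size = K,
                   universe_size = N, odds_ratio = ft$odds_ratio, p = ft$p,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cat in unique(out$category)) {
    sel <- out$category == cat
    out$q[sel] <- bhAdjust(out$p[sel])
  }
  out
}

#' Genes overlapping genomic intervals
#'
#' A gene is included when it shares at least one basepair with any interval
#' on the same chromosome under 0-based half-open arithmetic
#' (`max(starts) < min(ends)`). Positions and intervals are `GRanges` as
#' produced by [readBED()] / [AnnotationBundle()]; genes without a position
#' are excluded and counted in the log.
#'
#' @param genePos `GRanges` named by gene id.
#' @param intervals `GRanges` of regions.
#' @param genes optional subset of gene ids to test (default: all named
#'   positions).
#' @return character vector of overlapping gene ids.
#' @export
genesInIntervals <- function(genePos, intervals, genes = NULL) {
  if (is.null(names(genePos)))
    stop("gene positions must be named by gene id", call. = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(genePos))
    if (length(missing))
      coexLog(length(missing), " gene(s) without position excluded",
              verbose = FALSE)
    genePos <- genePos[names(genePos) %in% genes]
  }
  hits <- findOverlaps(genePos, intervals)
  unique(names(genePos)[S4Vectors::queryHits(hits)])
}

#' Permutation test for hub enrichment in genomic regions
#'
#' Compares the observed number of hub genes inside a region gene set
#' against `nDraws` random same-size draws (without replacement) from the
#' universe. Enrichment is called significant when the observed count equals
#' or exceeds the 95% quantile of the null (smallest value with >= 95% of
#' draws at or below it); the empirical p-value uses the add-one rule.
#'
#' @param hubGenes character hub gene ids (must be a subset of `universe`
#'   in size).
#' @param universe character gene universe to draw from.
#' @param regionGenes character gene ids inside the regions.
#' @param nDraws number of random draws (default 10000).
#' @param quantileLevel null quantile for the significance rule
#'   (default 0.95).
#' @param seed integer seed.
#' @return list: `observed`, `null_quantile`, `empirical_p`, `significant`,
#'   `null_mean`.
#' @export
permutationRegionEnrichment <- function(hubGenes, universe, regionGenes,
                                        nDraws = 10000L,
                                        quantileLevel = 0.95, seed = 1L) {
  hubGenes <- unique(hubGenes)
  universe <- unique(universe)
  if (length(hubGenes) > length(universe))
    stop("hub set larger than the universe", call. = FALSE)
  inRegion <- universe %in% regionGenes
  observed <- sum(hubGenes %in% regionGenes)
  nullCounts <- withSeed(seed, {
    vapply(seq_len(nDraws), function(i)
      sum(inRegion[sample.int(length(universe), length(hubGenes))]),
      numeric(1L))
  })
  qNull <- quantile(nullCounts, quantileLevel, type = 1L, names = FALSE)
  p <- (1 + sum(nullCounts >= observed)) / (nDraws + 1)
  list(observed = observed, null_quantile = qNull, empirical_p = p,
       significant = observed >= qNull, null_mean = mean(nullCounts))
}

#' Thresholded TOM edge list
#'
#' Plain edge export (probe_i, probe_j, weight) of within-module TOM edges
#' at or above the threshold, for external network tools.
#'
#' @param net a [ConsensusNetwork-class].
#' @param population population whose TOM to export.
#' @param edgeThreshold minimum TOM weight.
#' @return data.frame: probe_a, probe_b, module, weight.
#' @export
tomEdgeList <- function(net, population, edgeThreshold = 0.1) {
  tm <- populationTOM(net, population)
  labels <- moduleLabels(net)
  rows <- list()
  for (m in sort(unique(labels[labels > 0L]))) {
    members <- names(labels)[labels == m]
    sub <- tm[members, members, drop = FALSE]
    idx <- which(upper.tri(sub) & sub >= edgeThreshold, arr.ind = TRUE)
    if (!nrow(idx)) next
    rows[[length(rows) + 1L]] <-
      data.frame(probe_a = members[idx[, 1L]], probe_b = members[idx[, 2L]],
                 module = as.character(m), weight = sub[idx],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(probe_a = character(), probe_b = character(),
                      module = character(), weight = numeric()))
  do.call(rbind, rows)
}
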