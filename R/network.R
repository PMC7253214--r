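#' Connectivity-based probe filter
#'
#' Computes, on the pooled fertile samples, each probe's soft connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} under the signed adjacency
#' \eqn{a_{ij} = ((1 + cor_{ij})/2)^\beta} and keeps probes whose
#' connectivity is strictly above the median (or mean) connectivity.
#' Zero-variance probes are dropped before the correlation and logged.
#'
#' @param x probes x samples numeric matrix (fertile samples only).
#' @param beta soft-threshold power.
#' @param center `"median"` (default) or `"mean"`.
#' @param verbose emit log messages.
#' @return list: `kept` (character probe ids), `connectivity` (named numeric
#'   over all non-constant probes), `threshold`.
#' @export
connectivityFilter <- function(x, beta = 5L, center = c("median", "mean"),
                               verbose = FALSE) {
  center <- match.arg(center)
  if (nrow(x) < 3L) stop("need >= 3 probes", call. = FALSE)
  v <- apply(x, 1L, var)
  if (any(v <= .Machine$double.eps)) {
    coexLog("connectivityFilter: dropping ", sum(v <= .Machine$double.eps),
            " zero-variance probe(s)", verbose = verbose)
    x <- x[v > .Machine$double.eps, , drop = FALSE]
  }
  a <- signedAdjacency(cor(t(x)), beta)
  k <- colSums(a) - 1
  thr <- if (center == "median") median(k) else mean(k)
  kept <- names(k)[k > thr]
  if (!length(kept))
    warning("no probe has connectivity strictly above the ", center)
  list(kept = kept, connectivity = k, threshold = thr)
}

#' Signed soft-threshold adjacency
#'
#' \deqn{a_{ij} = \left(\frac{1 + cor_{ij}}{2}\right)^\beta}
#' so that perfectly anticorrelated probes get adjacency 0, uncorrelated
#' probes \eqn{2^{-\beta}}, and perfectly correlated probes 1. The diagonal
#' is set to 1.
#'
#' @param corMat correlation matrix with entries in [-1, 1].
#' @param beta positive integer soft power.
#' @return adjacency matrix in [0, 1].
#' @export
#' @examples
#' signedAdjacency(matrix(c(1, 0, 0, 1), 2), beta = 5)
signedAdjacency <- function(corMat, beta = 5L) {
  .assertScalarNumber(beta, "beta", 1, Inf, integer = TRUE)
  if (any(corMat < -1 - 1e-8 | corMat > 1 + 1e-8))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a <- ((1 + pmin(pmax(corMat, -1), 1)) / 2)^beta
  diag(a) <- 1
  a
}

#' Soft-threshold diagnostics table
#'
#' For each candidate power, reports the scale-free topology fit (the R^2 of
#' the log10-log10 regression of binned connectivity frequency on
#' connectivity) together with the mean and median connectivity, and
#' recommends the lowest power whose median connectivity has reached a low
#' plateau: the relative drop to the next candidate falls below
#' `plateauTolerance` (default 5%). The final choice stays with the caller.
#'
#' @param corMat probe correlation matrix.
#' @param betas increasing integer candidate powers (>= 2 values).
#' @param plateauTolerance relative median-connectivity drop defining the
#'   plateau.
#' @param nBins histogram bins for the scale-free fit.
#' @return list: `table` (data.frame beta, scaleFreeR2, meanK, medianK) and
#'   `recommended` beta.
#' @export
pickSoftThreshold <- function(corMat, betas = c(1:10, 12, 14, 16, 18, 20),
                              plateauTolerance = 0.05, nBins = 10L) {
  if (length(betas) < 2L) stop("need >= 2 candidate betas", call. = FALSE)
  betas <- sort(as.integer(betas))
  rows <- lapply(betas, function(b) {
    a <- signedAdjacency(corMat, b)
    k <- colSums(a) - 1
    data.frame(beta = b, scaleFreeR2 = .scaleFreeFit(k, nBins),
               meanK = mean(k), medianK = median(k))
  })
  tab <- do.call(rbind, rows)
  rel <- -diff(tab$medianK) / tab$medianK[-nrow(tab)]
  hit <- which(rel < plateauTolerance)
  recommended <- if (length(hit)) tab$beta[hit[1L]]
    else tab$beta[nrow(tab)]
  list(table = tab, recommended = recommended)
}

.scaleFreeFit <- function(k, nBins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(NA_real_)
  cuts <- cut(k, breaks = nBins)
  freq <- tapply(k, cuts, length)
  centers <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(centers[ok]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' Converts a (signed) adjacency matrix into the topological overlap matrix
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with shared-neighbor sum \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.
#'
#' @param a adjacency matrix (symmetric, entries in [0, 1], unit diagonal).
#' @return TOM matrix in [0, 1].
#' @export
tomFromAdjacency <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  L <- a %*% a - 2 * a            # removes the u = i and u = j terms
  k <- colSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Calibrated consensus TOM
#'
#' Rescales each population's TOM so that its `calibrationQuantile` quantile
#' of off-diagonal entries equals the across-population mean of those
#' quantiles (single-quantile multiplicative calibration), then takes the
#' componentwise minimum. The consensus therefore retains only topological
#' overlap present in every cohort.
#'
#' @param tomList named list of TOM matrices over the same probes in the
#'   same order.
#' @param calibrationQuantile quantile used for calibration (default 0.95).
#' @return list: `consensus` TOM and `calibrated` (the rescaled inputs).
#' @export
consensusTOMFromList <- function(tomList, calibrationQuantile = 0.95) {
  stopifnot(length(tomList) >= 1L)
  dn <- dimnames(tomList[[1L]])
  for (tm in tomList)
    if (!identical(dimnames(tm), dn))
      stop("TOM probe sets/order differ between populations", call. = FALSE)
  qs <- vapply(tomList, function(tm)
    quantile(.lowerTri(tm), calibrationQuantile, names = FALSE), numeric(1L))
  target <- mean(qs)
  calibrated <- lapply(seq_along(tomList), function(i) {
    tm <- if (qs[i] > 0) tomList[[i]] * (target / qs[i]) else tomList[[i]]
    tm[tm > 1] <- 1
    diag(tm) <- 1
    tm
  })
  names(calibrated) <- names(tomList)
  consensus <- Reduce(pmin, calibrated)
  list(consensus = consensus, calibrated = calibrated)
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' UPGMA agglomeration via `stats::hclust(method = "average")`; ties are
#' resolved deterministically by the implementation's pair ordering, so the
#' dendrogram is reproducible for identical input.
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal.
#' @return an `hclust` object.
#' @export
averageLinkageCluster <- function(diss) {
  if (any(!is.finite(diss)))
    stop("dissimilarity contains non-finite values", call. = FALSE)
  hclust(as.dist(diss), method = "average")
}

#' Adaptive dendrogram cut into modules
#'
#' Re-implementation of the adaptive branch-decomposition idea behind
#' dynamic tree cutting (equivalence with other implementations is not
#' claimed; planted-module recovery is the validation). The dendrogram is
#' descended from the root; at each branch the candidate split into its two
#' children is scored by the relative separation
#' \deqn{q = \frac{\bar d_{cross} - \max_c \bar d_{within}(c)}
#'   {1 - \max_c \bar d_{within}(c)}}
#' (mean cross-child dissimilarity against the denser child's mean internal
#' dissimilarity, normalized by the room left on the dissimilarity scale).
#' The split is accepted when `q` exceeds a threshold that decreases with
#' `deepSplit` (0 is the most conservative), so homogeneous branches stop
#' splitting while fused modules and accreted stray objects are separated;
#' branches spanning more than 40% of a network at least four modules wide
#' are always opened. Final
#' branches smaller than `minModuleSize` are dissolved; a second stage
#' assigns each unassigned object to the module with the closest medoid,
#' provided its dissimilarity to that medoid stays below the midpoint
#' between that module's core radius and the background dissimilarity
#' level. Remaining objects keep label 0 ("bin"). Labels are ordered by
#' decreasing module size.
#'
#' @param dendro `hclust` object.
#' @param diss the dissimilarity matrix the dendrogram was built from.
#' @param deepSplit integer 0-4; 0 is the most conservative.
#' @param minModuleSize minimum objects per module.
#' @return named integer vector of module labels (0 = unassigned).
#' @export
dynamicTreeCut <- function(dendro, diss, deepSplit = 0L,
                           minModuleSize = 50L) {
  .assertScalarNumber(deepSplit, "deepSplit", 0, 4, integer = TRUE)
  .assertScalarNumber(minModuleSize, "minModuleSize", 2, Inf,
                      integer = TRUE)
  n <- length(dendro$order)
  if (minModuleSize > n) {
    warning("minModuleSize exceeds the number of objects; all unassigned")
    return(setNames(rep(0L, n), dendro$labels))
  }
  splitTol <- 0.14 - 0.02 * deepSplit
  merge <- dendro$merge

  ## bottom-up pass: members, size, internal pair-sum and the cross-child
  ## pair-sum of every internal node
  members <- vector("list", n - 1L)
  sizeN <- integer(n - 1L)
  withinSum <- numeric(n - 1L)
  crossSum <- numeric(n - 1L)
  chMembers <- function(ch) if (ch < 0L) -ch else members[[ch]]
  chWithin <- function(ch) if (ch < 0L) 0 else withinSum[ch]
  for (i in seq_len(n - 1L)) {
    ml <- chMembers(merge[i, 1L])
    mr <- chMembers(merge[i, 2L])
    cs <- sum(diss[ml, mr])
    crossSum[i] <- cs
    withinSum[i] <- chWithin(merge[i, 1L]) + chWithin(merge[i, 2L]) + cs
    members[[i]] <- c(ml, mr)
    sizeN[i] <- length(ml) + length(mr)
  }
  chSize <- function(ch) if (ch < 0L) 1L else sizeN[ch]
  meanW <- function(ch) {
    s <- chSize(ch)
    if (s < 2L) return(NA_real_)
    chWithin(ch) / (s * (s - 1) / 2)
  }

  ## top-down descent
  lab <- rep(0L, n)
  nextLab <- 0L
  stack <- c(n - 1L)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    l <- merge[nd, 1L]; r <- merge[nd, 2L]
    meanCross <- crossSum[nd] / (as.numeric(chSize(l)) * chSize(r))
    mw <- suppressWarnings(max(meanW(l), meanW(r), na.rm = TRUE))
    q <- if (is.finite(mw)) (meanCross - mw) / max(1 - mw, 1e-12)
      else 1                                 # two singletons: trivially apart
    ## branches spanning most of a large network are opened regardless: no
    ## plausible module covers it, and the separation rule takes over below
    forced <- sizeN[nd] > 0.4 * n && sizeN[nd] >= 4 * minModuleSize
    if (forced || q >= splitTol) {
      for (ch in c(l, r)) if (ch > 0L) stack <- c(stack, ch)
    } else if (sizeN[nd] >= minModuleSize) {
      nextLab <- nextLab + 1L
      lab[members[[nd]]] <- nextLab
    }
  }

  ## stage 2: medoid assignment of unassigned objects. The acceptance
  ## radius sits halfway between the branch core (largest member-to-medoid
  ## dissimilarity) and the background level (median of all pairwise
  ## dissimilarities), so peeled peripheral members are recovered while
  ## unrelated objects stay in the bin.
  proper <- setdiff(unique(lab), 0L)
  if (length(proper) && any(lab == 0L)) {
    medBackground <- median(diss[upper.tri(diss)])
    medoids <- integer(length(proper))
    radius <- numeric(length(proper))
    for (i in seq_along(proper)) {
      mem <- which(lab == proper[i])
      dsum <- colSums(diss[mem, mem, drop = FALSE])
      medoids[i] <- mem[which.min(dsum)]
      rmax <- max(diss[medoids[i], mem])
      radius[i] <- (rmax + max(medBackground, rmax)) / 2
    }
    un <- which(lab == 0L)
    dMed <- diss[un, medoids, drop = FALSE]
    best <- max.col(-dMed, ties.method = "first")
    ok <- dMed[cbind(seq_along(un), best)] <= radius[best]
    lab[un[ok]] <- proper[best[ok]]
  }
  .relabelBySize(setNames(as.integer(lab), dendro$labels))
}

.relabelBySize <- function(lab) {
  sizes <- sort(table(lab[lab > 0L]), decreasing = TRUE)
  map <- setNames(seq_along(sizes), names(sizes))
  out <- ifelse(lab > 0L, map[as.character(lab)], 0L)
  setNames(as.integer(out), names(lab))
}

#' Module eigengene
#'
#' The first principal component of a module's per-probe standardized
#' expression, rescaled to unit variance over samples and oriented so that
#' the mean kME (correlation of member probes with the eigengene) is
#' non-negative. Also returns the proportion of module variance explained,
#' the mean squared kME over members.
#'
#' @param x probes x samples matrix containing at least the member probes.
#' @param members character probe ids (>= 2).
#' @return list: `me` (named numeric over samples), `propVarExplained`,
#'   `kME` (named numeric over members).
#' @export
moduleEigengene <- function(x, members) {
  if (length(members) < 2L) stop("need >= 2 member probes", call. = FALSE)
  m <- x[members, , drop = FALSE]
  v <- apply(m, 1L, var)
  if (all(v <= .Machine$double.eps))
    stop("all member probes are constant; eigengene undefined",
         call. = FALSE)
  if (any(v <= .Machine$double.eps)) {
    warning(sum(v <= .Machine$double.eps),
            " constant member probe(s) excluded from the eigengene")
    m <- m[v > .Machine$double.eps, , drop = FALSE]
  }
  z <- t(scale(t(m)))                    # standardize each probe
  sv <- svd(t(z), nu = 1L, nv = 0L)
  me <- sv$u[, 1L]
  me <- me / sd(me)
  kme <- drop(.safeCor(t(m), me))
  if (mean(kme) < 0) {
    me <- -me
    kme <- -kme
  }
  names(me) <- colnames(x)
  kme <- setNames(drop(.safeCor(t(x[members, , drop = FALSE]), me)), members)
  list(me = me, propVarExplained = mean(kme^2), kME = kme)
}

#' Eigengenes of all modules
#'
#' @param x probes x samples matrix.
#' @param labels named integer module labels over the probes of `x`
#'   (0 = unassigned, skipped).
#' @return list: `eigengenes` (module x sample matrix, rows named by module
#'   label) and `propVarExplained` (named numeric).
#' @export
moduleEigengenesAll <- function(x, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  me <- matrix(NA_real_, length(mods), ncol(x),
               dimnames = list(as.character(mods), colnames(x)))
  pve <- setNames(numeric(length(mods)), as.character(mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    eg <- moduleEigengene(x, members)
    me[i, ] <- eg$me
    pve[i] <- eg$propVarExplained
  }
  list(eigengenes = me, propVarExplained = pve)
}

#' Merge modules with close consensus eigengenes
#'
#' The consensus eigengene dissimilarity between two modules is the maximum
#' over populations of `1 - cor(ME_a, ME_b)`. Modules are clustered by
#' average linkage on this dissimilarity and every cluster below
#' `mergeHeight` is merged; eigengenes are recomputed and the procedure
#' repeats until no pair remains below the threshold.
#'
#' @param exprList named list per population of probes x samples matrices
#'   (identical probes).
#' @param labels named integer module labels.
#' @param mergeHeight eigengene dissimilarity threshold (default 0.2).
#' @return named integer labels after merging, ordered by decreasing size.
#' @export
mergeCloseModules <- function(exprList, labels, mergeHeight = 0.2) {
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    consDiss <- matrix(0, length(mods), length(mods),
                       dimnames = list(mods, mods))
    meL <- lapply(exprList, function(x)
      moduleEigengenesAll(x, labels)$eigengenes)
    for (me in meL) {
      d <- 1 - .safeCor(t(me))
      consDiss <- pmax(consDiss, d)
    }
    diag(consDiss) <- 0
    hc <- hclust(as.dist(consDiss), method = "average")
    grp <- cutree(hc, h = mergeHeight)
    if (max(table(grp)) == 1L) break
    map <- setNames(grp, mods)
    newLab <- ifelse(labels > 0L, map[as.character(labels)], 0L)
    labels <- setNames(as.integer(newLab), names(labels))
  }
  .relabelBySize(labels)
}

#' Module membership (kME)
#'
#' Pearson correlation of each probe's expression with each module
#' eigengene. Zero-variance probes get kME 0.
#'
#' @param x probes x samples matrix.
#' @param eigengenes module x sample matrix from [moduleEigengenesAll()].
#' @return probes x modules matrix of kME values in [-1, 1].
#' @export
kmeMatrix <- function(x, eigengenes) {
  stopifnot(identical(colnames(x), colnames(eigengenes)))
  km <- .safeCor(t(x), t(eigengenes))
  dimnames(km) <- list(rownames(x), rownames(eigengenes))
  km
}

#' Module-trait correlations
#'
#' Pearson correlation between each module eigengene and each trait, with
#' the two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees
#' of freedom. Samples with a missing trait value are dropped pairwise;
#' constant traits are reported as NA.
#'
#' @param eigengenes module x sample matrix.
#' @param traits data.frame/matrix of traits with rownames matching the
#'   eigengene samples.
#' @return data.frame: module, trait, r, n, p.
#' @export
moduleTraitCorrelation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  common <- intersect(colnames(eigengenes), rownames(traits))
  if (length(common) < 4L)
    stop("need >= 4 samples shared between eigengenes and traits",
         call. = FALSE)
  out <- list()
  for (m in rownames(eigengenes)) {
    for (tr in colnames(traits)) {
      tv <- traits[common, tr]
      ok <- is.finite(tv)
      n <- sum(ok)
      if (n < 4L || sd(tv[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- cor(eigengenes[m, common][ok], tv[ok])
        tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
        p <- 2 * pt(-abs(tstat), df = n - 2)
      }
      out[[length(out) + 1L]] <- data.frame(module = m, trait = tr, r = r,
                                            n = n, p = p)
    }
  }
  do.call(rbind, out)
}

#' Build a signed consensus coexpression network
#'
#' End-to-end consensus construction from per-population fertile expression
#' matrices: Pearson correlation, signed soft-threshold adjacency,
#' topological overlap, quantile-calibrated consensus TOM, average-linkage
#' clustering, adaptive tree cut, eigengene-based module merging, and
#' per-population eigengenes and kME.
#'
#' @param exprList named list per population of probes x samples matrices
#'   over identical probes (fertile samples only).
#' @param beta soft power.
#' @param minModuleSize,deepSplit,mergeHeight,calibrationQuantile see
#'   [pipelineConfig()].
#' @param verbose log stage progress.
#' @return a [ConsensusNetwork-class].
#' @export
buildConsensusNetwork <- function(exprList, beta = 5L, minModuleSize = 50L,
                                  deepSplit = 0L, mergeHeight = 0.2,
                                  calibrationQuantile = 0.95,
                                  verbose = FALSE) {
  stopifnot(is.list(exprList), length(exprList) >= 1L,
            !is.null(names(exprList)))
  probes <- rownames(exprList[[1L]])
  for (x in exprList)
    if (!identical(rownames(x), probes))
      stop("populations must share an identical probe set and order",
           call. = FALSE)
  coexLog("adjacency/TOM for ", length(exprList), " population(s), ",
          length(probes), " probes", verbose = verbose)
  toms <- lapply(exprList, function(x)
    tomFromAdjacency(signedAdjacency(cor(t(x)), beta)))
  cons <- consensusTOMFromList(toms, calibrationQuantile)
  coexLog("clustering consensus TOM", verbose = verbose)
  diss <- 1 - cons$consensus
  diag(diss) <- 0
  dendro <- averageLinkageCluster(diss)
  labels <- dynamicTreeCut(dendro, diss, deepSplit, minModuleSize)
  coexLog("initial modules: ", length(unique(labels[labels > 0L])),
          verbose = verbose)
  labels <- mergeCloseModules(exprList, labels, mergeHeight)
  coexLog("modules after merging: ", length(unique(labels[labels > 0L])),
          verbose = verbose)
  eig <- lapply(exprList, function(x) moduleEigengenesAll(x, labels))
  eigengenes <- lapply(eig, `[[`, "eigengenes")
  pve <- lapply(eig, `[[`, "propVarExplained")
  kme <- lapply(names(exprList), function(p)
    kmeMatrix(exprList[[p]], eigengenes[[p]]))
  names(kme) <- names(exprList)
  new("ConsensusNetwork", probes = probes,
      populations = names(exprList), toms = cons$calibrated,
      consTOM = cons$consensus, dendro = dendro, labels = labels,
      eigengenes = eigengenes, kme = kme, propVarExplained = pve,
      params = list(beta = beta, min_module_size = minModuleSize,
                    deep_split = deepSplit, merge_height = mergeHeight,
                    calibration_quantile = calibrationQuantile))
}
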