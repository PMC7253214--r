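## Precompute what every (module or permuted) gene set evaluation needs:
## full correlation matrices and standardized sample x probe matrices.
.presPrecompute <- function(discovery, test) {
  stopifnot(identical(rownames(discovery), rownames(test)))
  list(probes = rownames(discovery),
       corD = .safeCor(t(discovery)), corT = .safeCor(t(test)),
       zD = scale(t(discovery)), zT = scale(t(test)),
       nD = ncol(discovery), nT = ncol(test))
}

## first left singular vector of a standardized sample x gene block,
## oriented for non-negative mean kME; returns the kME vector
.blockKME <- function(z, idx) {
  zi <- z[, idx, drop = FALSE]
  zi[, !is.finite(colSums(zi))] <- 0      # constant genes contribute nothing
  me <- svd(zi, nu = 1L, nv = 0L)$u[, 1L]
  kme <- drop(.safeCor(zi, me))
  if (mean(kme) < 0) kme <- -kme
  kme
}

.presStatNames <- c("meanCor", "meanAdj", "propVarExplained",
                    "meanSignedKME", "cor_kIM", "cor_kME", "cor_cor")
.presDensityStats <- .presStatNames[1:4]
.presConnStats <- .presStatNames[5:7]

## the seven preservation statistics for one gene-index set
.presStatsIdx <- function(pre, idx, beta) {
  cD <- pre$corD[idx, idx]
  cT <- pre$corT[idx, idx]
  lt <- lower.tri(cD)
  aD <- ((1 + cD) / 2)^beta
  aT <- ((1 + cT) / 2)^beta
  kmeD <- .blockKME(pre$zD, idx)
  kmeT <- .blockKME(pre$zT, idx)
  kimD <- colSums(aD) - 1
  kimT <- colSums(aT) - 1
  c(meanCor = mean(cT[lt]),
    meanAdj = mean(aT[lt]),
    propVarExplained = mean(kmeT^2),
    meanSignedKME = mean(kmeT),
    cor_kIM = .scalarCor(kimD, kimT),
    cor_kME = .scalarCor(kmeD, kmeT),
    cor_cor = .scalarCor(cD[lt], cT[lt]))
}

.scalarCor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Observed module preservation statistics
#'
#' Computes, per module, the seven preservation statistics comparing a
#' discovery cohort to a test cohort over the same probes: four density
#' statistics evaluated in the test cohort (`meanCor`, mean pairwise
#' correlation; `meanAdj`, mean signed adjacency at power `beta`;
#' `propVarExplained`, mean squared kME; `meanSignedKME`) and three
#' connectivity statistics correlating discovery and test patterns
#' (`cor_kIM`, intramodular connectivity; `cor_kME`; `cor_cor`, pairwise
#' correlations). Modules smaller than 3 probes are skipped with a warning.
#'
#' @param discovery,test probes x samples matrices over identical probes.
#' @param labels named integer module labels over those probes.
#' @param beta soft power for the adjacency-based statistics.
#' @return data.frame with `module`, `moduleSize` and the seven statistics.
#' @export
preservationStatistics <- function(discovery, test, labels, beta = 5L) {
  pre <- .presPrecompute(discovery, test)
  mods <- sort(unique(labels[labels > 0L]))
  rows <- list()
  for (m in mods) {
    idx <- match(names(labels)[labels == m], pre$probes)
    if (length(idx) < 3L) {
      warning("module ", m, " has fewer than 3 probes; skipped")
      next
    }
    st <- .presStatsIdx(pre, idx, beta)
    rows[[length(rows) + 1L]] <-
      data.frame(module = as.character(m), moduleSize = length(idx),
                 t(st), check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Permutation-based module preservation (Z scores and significance)
#'
#' For each module, `nPermZ` random gene sets of the same size are drawn
#' without replacement from all network probes in the test cohort; each
#' statistic's permutation Z score is
#' \eqn{Z_s = (s_{obs} - \overline{s_{perm}}) / sd(s_{perm})}.
#' `Z_density` is the median of the four density Zs, `Z_connectivity` the
#' median of the three connectivity Zs, and
#' \eqn{Z_{summary} = (Z_{density} + Z_{connectivity}) / 2}; bands
#' >= 10 / [2, 10) / < 2 are labelled strong / weak / none. One-sided
#' permutation p-values use `nPermSig` draws from the same null with the
#' add-one rule \eqn{p = (1 + \#\{perm \ge obs\})/(n + 1)}; a module is
#' flagged `all_significant` when all seven p-values fall below `alpha`
#' (optionally Bonferroni-corrected across the seven statistics). The
#' median-rank statistic averages the median cross-module rank of the
#' density statistics and of the connectivity statistics (rank 1 = most
#' preserved).
#'
#' @inheritParams preservationStatistics
#' @param nPermZ permutations for Z scores (default 500).
#' @param nPermSig permutations for significance tests (default 1000).
#' @param alpha per-statistic significance level (default 0.05).
#' @param bonferroni divide `alpha` by 7.
#' @param seed integer seed for the permutation draws.
#' @param verbose log progress.
#' @return a [PreservationReport-class].
#' @export
modulePreservation <- function(discovery, test, labels, beta = 5L,
                               nPermZ = 500L, nPermSig = 1000L,
                               alpha = 0.05, bonferroni = FALSE,
                               seed = 1L, verbose = FALSE) {
  .assertScalarNumber(nPermZ, "nPermZ", 100, Inf, integer = TRUE)
  .assertScalarNumber(nPermSig, "nPermSig", 100, Inf, integer = TRUE)
  .assertScalarNumber(alpha, "alpha", 1e-12, 1 - 1e-12)
  pre <- .presPrecompute(discovery, test)
  obs <- preservationStatistics(discovery, test, labels, beta)
  if (is.null(obs) || !nrow(obs))
    stop("no module with >= 3 probes", call. = FALSE)
  nPerm <- max(nPermZ, nPermSig)
  p <- length(pre$probes)
  alphaEff <- if (bonferroni) alpha / 7 else alpha

  zRows <- list(); pRows <- list(); sRows <- list()
  withSeed(seed, {
    for (r in seq_len(nrow(obs))) {
      q <- obs$moduleSize[r]
      stats <- matrix(NA_real_, nPerm, 7L,
                      dimnames = list(NULL, .presStatNames))
      for (b in seq_len(nPerm))
        stats[b, ] <- .presStatsIdx(pre, sample.int(p, q), beta)
      o <- unlist(obs[r, .presStatNames])
      zstats <- stats[seq_len(nPermZ), , drop = FALSE]
      mu <- colMeans(zstats)
      sdv <- apply(zstats, 2L, sd)
      z <- (o - mu) / sdv
      if (any(sdv == 0)) {
        coexLog("degenerate permutation null for module ", obs$module[r],
                verbose = verbose)
        z[sdv == 0] <- ifelse(o[sdv == 0] >= mu[sdv == 0], Inf, -Inf)
      }
      sstats <- stats[seq_len(nPermSig), , drop = FALSE]
      pv <- (1 + colSums(sweep(sstats, 2L, o, ">="))) / (nPermSig + 1)
      zRows[[r]] <- z
      pRows[[r]] <- pv
      coexLog("module ", obs$module[r], " permutations done",
              verbose = verbose)
    }
  })
  zDF <- data.frame(module = obs$module,
                    do.call(rbind, zRows), check.names = FALSE)
  pDF <- data.frame(module = obs$module,
                    do.call(rbind, pRows), check.names = FALSE)

  zDens <- apply(zDF[, .presDensityStats, drop = FALSE], 1L, median)
  zConn <- apply(zDF[, .presConnStats, drop = FALSE], 1L, median)
  zSummary <- (zDens + zConn) / 2
  flag <- ifelse(zSummary >= 10, "strong",
                 ifelse(zSummary >= 2, "weak", "none"))
  allSig <- apply(pDF[, .presStatNames, drop = FALSE], 1L,
                  function(v) all(v < alphaEff))
  minP <- apply(pDF[, .presStatNames, drop = FALSE], 1L, min)

  ## median rank over modules: higher observed statistic = rank 1
  rkD <- apply(-as.matrix(obs[, .presDensityStats, drop = FALSE]), 2L, rank)
  rkC <- apply(-as.matrix(obs[, .presConnStats, drop = FALSE]), 2L, rank)
  rkD <- matrix(rkD, nrow = nrow(obs))
  rkC <- matrix(rkC, nrow = nrow(obs))
  medianRank <- (apply(rkD, 1L, median) + apply(rkC, 1L, median)) / 2

  summaryDF <- data.frame(module = obs$module, moduleSize = obs$moduleSize,
                          Z_density = zDens, Z_connectivity = zConn,
                          Z_summary = zSummary, median_rank = medianRank,
                          preserved_flag = flag, all_significant = allSig,
                          min_p = minP, stringsAsFactors = FALSE)
  new("PreservationReport", observed = obs, zscores = zDF, pvalues = pDF,
      summary = summaryDF,
      params = list(beta = beta, n_perm_z = nPermZ, n_perm_sig = nPermSig,
                    alpha = alpha, bonferroni = bonferroni, seed = seed))
}
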