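#' Pairwise differential correlation (Fisher z)
#'
#' For each requested probe pair, compares the Pearson correlation in a test
#' cohort against a reference cohort with the Fisher z statistic
#' \deqn{z = \frac{\mathrm{atanh}(r_T) - \mathrm{atanh}(r_R)}
#'   {\sqrt{1/(n_T - 3) + 1/(n_R - 3)}}}
#' and a two-sided normal p-value. Pairs are classified by their sign
#' pattern at level `alpha`: `loss` (same sign, |r| decreased), `reversal`
#' (sign change), `gain` (|r| increased), else `none`. Correlations at
#' exactly |r| = 1 are clamped to 1 - 1e-12 before atanh.
#'
#' @param exprRef,exprTest probes x samples matrices over identical probes.
#' @param pairs two-column matrix/data.frame of probe ids (or indices).
#' @param alpha significance level for the class labels.
#' @return data.frame: probe_a, probe_b, r_ref, r_test, z_diff, p, class.
#' @export
pairwiseDiffCor <- function(exprRef, exprTest, pairs, alpha = 0.05) {
  stopifnot(identical(rownames(exprRef), rownames(exprTest)))
  nR <- ncol(exprRef); nT <- ncol(exprTest)
  if (nR < 5L || nT < 5L)
    stop("need >= 5 samples in each cohort", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (is.character(pairs)) {
    ia <- match(pairs[, 1L], rownames(exprRef))
    ib <- match(pairs[, 2L], rownames(exprRef))
  } else {
    ia <- as.integer(pairs[, 1L]); ib <- as.integer(pairs[, 2L])
  }
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("unknown probe id in pairs", call. = FALSE)
  rRef <- numeric(length(ia)); rTest <- numeric(length(ia))
  for (k in seq_along(ia)) {
    rRef[k] <- .scalarCor(exprRef[ia[k], ], exprRef[ib[k], ])
    rTest[k] <- .scalarCor(exprTest[ia[k], ], exprTest[ib[k], ])
  }
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- (atanh(clamp(rTest)) - atanh(clamp(rRef))) /
    sqrt(1 / (nT - 3) + 1 / (nR - 3))
  p <- 2 * pnorm(-abs(z))
  cls <- rep("none", length(z))
  sig <- p < alpha
  eps <- 1e-8           # correlations this small carry no usable sign
  flip <- sign(rRef) != sign(rTest) & abs(rRef) > eps & abs(rTest) > eps
  cls[sig & flip] <- "reversal"
  cls[sig & !flip & abs(rTest) < abs(rRef)] <- "loss"
  cls[sig & !flip & abs(rTest) > abs(rRef)] <- "gain"
  data.frame(probe_a = rownames(exprRef)[ia],
             probe_b = rownames(exprRef)[ib],
             r_ref = rRef, r_test = rTest, z_diff = z, p = p, class = cls,
             stringsAsFactors = FALSE)
}

## per-gene median log2 fold change of within-module |correlation|,
## given the two cohort correlation matrices restricted to one module
.medianLFCModule <- function(cRef, cTest, floor) {
  q <- nrow(cRef)
  lfc <- log2(pmax(abs(cTest), floor) / pmax(abs(cRef), floor))
  diag(lfc) <- NA
  medLfc <- apply(lfc, 1L, median, na.rm = TRUE)
  dR <- cRef; diag(dR) <- NA
  dT <- cTest; diag(dT) <- NA
  medRef <- apply(dR, 1L, median, na.rm = TRUE)
  medTest <- apply(dT, 1L, median, na.rm = TRUE)
  list(median_lfc = medLfc, median_ref = medRef, median_test = medTest)
}

#' Gene-level differential coexpression by median log fold change
#'
#' For every gene in every module, computes the median over its module
#' partners of \eqn{\log_2(\max(|r_{test}|, floor) / \max(|r_{ref}|,
#' floor))}, where the floor guards against division by near-zero reference
#' correlations. Significance comes from a permutation null in which the
#' cohort labels of the pooled samples are shuffled `nPerm` times (jointly
#' for all genes, preserving gene-gene dependence) and the statistic is
#' recomputed; the two-sided empirical p-value uses the add-one rule. A
#' gene is flagged `loss` when significant with negative median LFC and no
#' sign flip of its median partner correlation, `reversal` when significant
#' with a sign flip, and `none` otherwise.
#'
#' @param exprRef,exprTest probes x samples matrices over identical probes
#'   (reference = fertile cohort, test = a subfertile group).
#' @param labels named integer module labels (0 ignored); modules smaller
#'   than 3 probes are skipped.
#' @param nPerm permutations (default 100).
#' @param floorAbsCor reference floor on |r| (default 0.01).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return data.frame: probe_id, module, median_lfc, median_ref_cor,
#'   median_test_cor, median_sign_flip, empirical_p, flag.
#' @export
geneMedianLFC <- function(exprRef, exprTest, labels, nPerm = 100L,
                          floorAbsCor = 0.01, alpha = 0.05, seed = 1L) {
  stopifnot(identical(rownames(exprRef), rownames(exprTest)))
  .assertScalarNumber(nPerm, "nPerm", 50, Inf, integer = TRUE)
  .assertScalarNumber(floorAbsCor, "floorAbsCor", 0, 0.2 - 1e-12)
  mods <- sort(unique(labels[labels > 0L]))
  pooled <- cbind(exprRef, exprTest)
  nR <- ncol(exprRef); nT <- ncol(exprTest)
  out <- list()
  withSeed(seed, {
    permIdx <- replicate(nPerm, sample.int(nR + nT), simplify = FALSE)
    for (m in mods) {
      members <- names(labels)[labels == m]
      if (length(members) < 3L) {
        coexLog("module ", m, " smaller than 3 genes; skipped",
                verbose = FALSE)
        next
      }
      xm <- pooled[members, , drop = FALSE]
      obs <- .medianLFCModule(
        .safeCor(t(xm[, seq_len(nR), drop = FALSE])),
        .safeCor(t(xm[, nR + seq_len(nT), drop = FALSE])), floorAbsCor)
      permMat <- matrix(NA_real_, length(members), nPerm)
      for (b in seq_len(nPerm)) {
        px <- xm[, permIdx[[b]], drop = FALSE]
        permMat[, b] <- .medianLFCModule(
          .safeCor(t(px[, seq_len(nR), drop = FALSE])),
          .safeCor(t(px[, nR + seq_len(nT), drop = FALSE])),
          floorAbsCor)$median_lfc
      }
      pv <- (1 + rowSums(abs(permMat) >= abs(obs$median_lfc))) / (nPerm + 1)
      eps <- 1e-8
      flip <- sign(obs$median_test) != sign(obs$median_ref) &
        abs(obs$median_ref) > eps & abs(obs$median_test) > eps
      flag <- rep("none", length(members))
      flag[pv < alpha & flip] <- "reversal"
      flag[pv < alpha & !flip & obs$median_lfc < 0] <- "loss"
      out[[length(out) + 1L]] <- data.frame(
        probe_id = members, module = as.character(m),
        median_lfc = obs$median_lfc, median_ref_cor = obs$median_ref,
        median_test_cor = obs$median_test, median_sign_flip = flip,
        empirical_p = pv, flag = flag, stringsAsFactors = FALSE,
        row.names = NULL)
    }
  })
  do.call(rbind, out)
}

#' Per-module summary of differential coexpression
#'
#' @param result data.frame from [geneMedianLFC()].
#' @return data.frame per module: gene counts and percent flagged
#'   (loss / reversal / any).
#' @export
diffcorModuleSummary <- function(result) {
  sp <- split(result, result$module)
  rows <- lapply(sp, function(d)
    data.frame(module = d$module[1L], n_genes = nrow(d),
               pct_loss = 100 * mean(d$flag == "loss"),
               pct_reversal = 100 * mean(d$flag == "reversal"),
               pct_flagged = 100 * mean(d$flag != "none")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
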