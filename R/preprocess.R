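#' Background-correct raw intensities ("half" rule with offset)
#'
#' Applies the standard "half" background correction for two-color-style
#' intensity arrays: the local background is subtracted from the foreground,
#' differences below 0.5 are reset to 0.5, and a fixed offset is added to
#' stabilise the variance of low intensities:
#' \deqn{y = \max(F - B, 0.5) + \mathrm{offset}.}
#'
#' @param foreground,background numeric matrices of identical shape and
#'   dimnames (or `SummarizedExperiment` plus matrix).
#' @param offset non-negative offset added after flooring (default 50).
#' @return matrix (or `SummarizedExperiment`) of corrected intensities;
#'   the scale tag becomes `background_corrected`.
#' @export
#' @examples
#' backgroundCorrectHalf(matrix(100), matrix(60), offset = 50)  # 90
backgroundCorrectHalf <- function(foreground, background, offset = 50) {
  .assertScalarNumber(offset, "offset", 0, Inf)
  isSE <- is(foreground, "SummarizedExperiment")
  fg <- if (isSE) assay(foreground) else foreground
  if (!identical(dim(fg), dim(background)))
    stop("foreground and background shapes differ", call. = FALSE)
  out <- pmax(fg - background, 0.5) + offset
  if (isSE) {
    se <- foreground
    assay(se) <- out
    metadata(se)$scale_tag <- "background_corrected"
    return(se)
  }
  out
}

#' Negative-control-based expression filter
#'
#' Per array, the detection threshold is `brightnessFactor` times the
#' `negctrlQuantile` quantile of the negative-control probe intensities on
#' that array. A probe is called expressed (kept) if its intensity reaches
#' the threshold on at least `ceiling(minSampleFraction * n_samples)` arrays.
#' Negative-control probes are never kept.
#'
#' @param se expression `SummarizedExperiment` on the intensity scale, with
#'   `is_negative_control` in `rowData()`.
#' @param negctrlQuantile quantile of the negative-control distribution
#'   (default 0.98).
#' @param brightnessFactor multiplicative brightness margin (default 1.10,
#'   i.e. 10% brighter than background).
#' @param minSampleFraction minimum fraction of arrays on which a probe must
#'   be detected (default 0.10).
#' @return list with `kept` (character probe ids, negative controls
#'   excluded), `thresholds` (named per-array threshold vector) and
#'   `detected` (logical matrix).
#' @export
filterExpressed <- function(se, negctrlQuantile = 0.98,
                            brightnessFactor = 1.10,
                            minSampleFraction = 0.10) {
  .assertScalarNumber(negctrlQuantile, "negctrlQuantile", 1e-12, 1 - 1e-12)
  .assertScalarNumber(brightnessFactor, "brightnessFactor", 1e-12, Inf)
  .assertScalarNumber(minSampleFraction, "minSampleFraction", 1e-12,
                      1 - 1e-12)
  x <- assay(se)
  nc <- rowData(se)$is_negative_control
  if (is.null(nc) || !any(nc))
    stop("no negative-control probes available on the arrays", call. = FALSE)
  thresholds <- brightnessFactor *
    apply(x[nc, , drop = FALSE], 2L, quantile, probs = negctrlQuantile,
          names = FALSE)
  detected <- sweep(x, 2L, thresholds, ">=")
  needed <- ceiling(minSampleFraction * ncol(x))
  keep <- rowSums(detected) >= needed & !nc
  list(kept = rownames(x)[keep],
       thresholds = setNames(thresholds, colnames(x)),
       detected = detected)
}

#' Quantile-normalize expression between arrays
#'
#' Makes the sorted value vector of every array equal to the mean of the
#' sorted input vectors; ties within an array receive the mean of the
#' reference values at their rank positions. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
#' rule; the operation is idempotent.
#'
#' @param x numeric matrix or `SummarizedExperiment` (no missing values).
#' @return the normalized object; scale tag becomes `normalized`.
#' @export
quantileNormalize <- function(x) {
  isSE <- is(x, "SummarizedExperiment")
  m <- if (isSE) assay(x) else x
  if (any(!is.finite(m)))
    stop("quantile normalization requires complete finite values",
         call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (isSE) {
    assay(x) <- out
    metadata(x)$scale_tag <- "normalized"
    return(x)
  }
  out
}

#' Log2-transform intensities
#'
#' @param x positive numeric matrix or `SummarizedExperiment`.
#' @return elementwise log2; scale tag becomes `log2`.
#' @export
log2Transform <- function(x) {
  isSE <- is(x, "SummarizedExperiment")
  m <- if (isSE) assay(x) else x
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at row %d (%s), column %d (%s)",
                 bad[1L, 1L], rownames(m)[bad[1L, 1L]], bad[1L, 2L],
                 colnames(m)[bad[1L, 2L]]), call. = FALSE)
  out <- log2(m)
  if (isSE) {
    assay(x) <- out
    metadata(x)$scale_tag <- "log2"
    return(x)
  }
  out
}

#' Empirical-Bayes batch adjustment (location and scale)
#'
#' Adjusts known batch effects with the parametric empirical-Bayes
#' location/scale model: genes are standardized by grand mean and pooled
#' variance, per-batch location and scale parameters are estimated and
#' shrunk toward a normal / inverse-gamma prior whose hyperparameters are
#' fit across genes by the method of moments, and the adjusted values are
#' returned on the original scale. Delegates to `sva::ComBat`, the reference
#' implementation of this model. With a single batch the input is returned
#' unchanged; zero-variance genes are passed through unadjusted with a
#' warning. No covariates are protected.
#'
#' @param x numeric genes x samples matrix or `SummarizedExperiment`.
#' @param batch character/factor batch label per sample (taken from
#'   `colData()$batch` when `x` is a `SummarizedExperiment`).
#' @return adjusted object; scale tag becomes `batch_adjusted`.
#' @export
ebBatchAdjust <- function(x, batch = NULL) {
  isSE <- is(x, "SummarizedExperiment")
  m <- if (isSE) assay(x) else x
  if (isSE && is.null(batch)) batch <- colData(x)$batch
  if (is.null(batch) || length(batch) != ncol(m))
    stop("need one batch label per sample", call. = FALSE)
  batch <- factor(batch)
  if (any(table(batch) < 2L))
    stop("every batch needs >= 2 samples", call. = FALSE)
  if (nlevels(batch) < 2L) {
    out <- m
  } else {
    v <- apply(m, 1L, var)
    constant <- v < .Machine$double.eps
    out <- m
    if (any(constant))
      warning(sum(constant),
              " zero-variance gene(s) passed through unadjusted")
    if (any(!constant)) {
      adj <- suppressMessages(
        sva::ComBat(dat = m[!constant, , drop = FALSE], batch = batch,
                    par.prior = TRUE, mean.only = FALSE))
      out[!constant, ] <- adj
    }
  }
  if (isSE) {
    assay(x) <- out
    metadata(x)$scale_tag <- "batch_adjusted"
    return(x)
  }
  out
}

#' Sample-space PCA of an expression matrix
#'
#' Singular value decomposition of the probe-wise centered and unit-variance
#' scaled matrix; zero-variance probes are dropped with a warning. Component
#' signs are fixed so that the loading of largest magnitude is positive, and
#' components are ordered by non-increasing explained variance fraction.
#'
#' @param x probes x samples matrix or `SummarizedExperiment`.
#' @return list of class `"PCAResult"`: `scores` (sample x component),
#'   `loadings` (probe x component), `explained` (fractions summing to 1
#'   over the non-degenerate components).
#' @export
pcaSamples <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) assay(x) else x
  if (ncol(m) < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  v <- apply(m, 1L, var)
  if (any(v <= .Machine$double.eps)) {
    warning(sum(v <= .Machine$double.eps),
            " zero-variance probe(s) dropped before PCA")
    m <- m[v > .Machine$double.eps, , drop = FALSE]
  }
  pc <- prcomp(t(m), center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  loadings <- pc$rotation
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, loadings = loadings, explained = expl),
            class = "PCAResult")
}

#' Flag outlier samples on the leading principal components
#'
#' Deterministic replacement for by-eye outlier removal: a sample is flagged
#' when its score on PC1 or PC2 deviates from the component median by more
#' than `kMad` median absolute deviations (default 6).
#'
#' @param pca a `"PCAResult"` from [pcaSamples()].
#' @param kMad MAD multiplier.
#' @return character vector of flagged sample ids.
#' @export
flagOutlierSamples <- function(pca, kMad = 6) {
  stopifnot(inherits(pca, "PCAResult"))
  sc <- pca$scores[, seq_len(min(2L, ncol(pca$scores))), drop = FALSE]
  flagged <- rep(FALSE, nrow(sc))
  for (k in seq_len(ncol(sc))) {
    med <- median(sc[, k])
    mad_k <- mad(sc[, k])
    if (mad_k > 0)
      flagged <- flagged | abs(sc[, k] - med) > kMad * mad_k
  }
  rownames(sc)[flagged]
}
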