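#' Classify samples into fertility classes
#'
#' Hybrids are classified from two fertility phenotypes — relative testis
#' weight (testis weight / body weight, g/g) and sperm count — against
#' reference statistics computed from the pure subspecies samples:
#' \itemize{
#'   \item \strong{subfertile}: either phenotype falls outside the pure
#'     sample range (min-max);
#'   \item \strong{fertile}: both phenotypes lie within one sample standard
#'     deviation (n-1 denominator) of the pure mean;
#'   \item \strong{intermediate}: all remaining hybrids (inside the range but
#'     more than 1 SD out on at least one phenotype).
#' }
#' Boundary values count as within. Pure samples are labelled `pure`. By
#' default the reference statistics pool both pure subspecies (`pooledPure`);
#' per-subspecies statistics (taking, per hybrid, the more permissive bound)
#' are available as a switch.
#'
#' @param sampleTable data.frame with `sample_id`, `population`,
#'   `body_weight`, `testis_weight`, `sperm_count`; populations named in
#'   `purePopulations` are the reference.
#' @param purePopulations population labels of pure subspecies samples.
#' @param pooledPure pool the pure subspecies when computing mean/SD/range.
#' @return data.frame: `sample_id`, `population`, `fertility_class`,
#'   `expression_class` (filled by [splitExpressionClass()], initially
#'   `not_applicable`), `relative_testis_weight`, `sperm_count`.
#' @export
classifyFertility <- function(sampleTable,
                              purePopulations = c("pure_dom", "pure_mus"),
                              pooledPure = TRUE) {
  need <- c("sample_id", "population", "body_weight", "testis_weight",
            "sperm_count")
  miss <- setdiff(need, names(sampleTable))
  if (length(miss))
    stop("sample table lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  badPh <- !is.finite(sampleTable$testis_weight) |
    !is.finite(sampleTable$body_weight) | !is.finite(sampleTable$sperm_count)
  if (any(badPh))
    stop("missing phenotype for sample(s): ",
         paste(sampleTable$sample_id[badPh], collapse = ", "), call. = FALSE)
  rtw <- sampleTable$testis_weight / sampleTable$body_weight
  traits <- cbind(rel_testis = rtw, sperm = sampleTable$sperm_count)
  isPure <- sampleTable$population %in% purePopulations
  if (sum(isPure) < 2L)
    stop("need >= 2 pure-subspecies samples for reference statistics",
         call. = FALSE)

  refStats <- function(sel) {
    apply(traits[sel, , drop = FALSE], 2L, function(v)
      c(mean = mean(v), sd = sd(v), lo = min(v), hi = max(v)))
  }
  stats <- if (pooledPure) list(pooled = refStats(isPure))
    else lapply(purePopulations, function(p)
      refStats(isPure & sampleTable$population == p))

  classifyOne <- function(v) {
    ## against each reference (pooled: one), take the most permissive call
    calls <- vapply(stats, function(st) {
      inRange <- all(v >= st["lo", ] & v <= st["hi", ])
      if (!inRange) return("subfertile")
      within1 <- all(abs(v - st["mean", ]) <= st["sd", ])
      if (within1) "fertile" else "intermediate"
    }, character(1L))
    if ("fertile" %in% calls) "fertile"
    else if ("intermediate" %in% calls) "intermediate"
    else "subfertile"
  }
  cls <- character(nrow(sampleTable))
  cls[isPure] <- "pure"
  for (i in which(!isPure)) cls[i] <- classifyOne(traits[i, ])
  data.frame(sample_id = sampleTable$sample_id,
             population = sampleTable$population,
             fertility_class = cls,
             expression_class = "not_applicable",
             relative_testis_weight = rtw,
             sperm_count = sampleTable$sperm_count,
             stringsAsFactors = FALSE)
}

#' Split subfertile samples into SFNE / SFAE by PC1
#'
#' The reference interval is the min-max range of PC1 scores over the union
#' of fertile hybrids and pure subspecies samples. A subfertile sample whose
#' PC1 score lies strictly outside this interval is labelled SFAE
#' ("subfertile aberrant expression"); all other subfertile samples are SFNE
#' ("subfertile normal expression"). Samples at the interval endpoints count
#' as inside.
#'
#' @param classification data.frame from [classifyFertility()].
#' @param pca a `"PCAResult"` from [pcaSamples()] covering all samples, or a
#'   named PC1 score vector.
#' @return the classification data.frame with `expression_class` filled and
#'   a `pc1_score` column; `attr(, "reference_interval")` holds the interval.
#' @export
splitExpressionClass <- function(classification, pca) {
  pc1 <- if (inherits(pca, "PCAResult")) pca$scores[, 1L] else pca
  sc <- pc1[classification$sample_id]
  if (any(is.na(sc)))
    stop("PC1 score missing for sample(s): ",
         paste(classification$sample_id[is.na(sc)], collapse = ", "),
         call. = FALSE)
  ref <- classification$fertility_class %in% c("fertile", "pure")
  if (!any(ref))
    stop("empty reference group (no fertile or pure samples)", call. = FALSE)
  interval <- range(sc[ref])
  out <- classification
  out$pc1_score <- unname(sc)
  subf <- out$fertility_class == "subfertile"
  out$expression_class[subf] <-
    ifelse(sc[subf] < interval[1L] | sc[subf] > interval[2L], "SFAE", "SFNE")
  attr(out, "reference_interval") <- interval
  out
}
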