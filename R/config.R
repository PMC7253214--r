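#' Pipeline configuration
#'
#' Builds the nested list of tuning parameters consumed by every stage of the
#' pipeline. Defaults are the values of the study design this package
#' implements: a signed consensus network at soft power 5, deepSplit 0,
#' minimum module size 50, eigengene merge height 0.2; 500 permutations for
#' preservation Z scores and 1000 for the seven significance tests; 100
#' permutations for differential correlation; kME hub threshold 0.85 with a
#' 0.1 TOM edge weight and top-5 intramodular degree; 10,000 draws for the
#' region-enrichment permutation test; gene-set size window 11-499; and the
#' "half" background correction with offset 50 followed by the 98th-percentile
#' negative-control brightness filter (10% brighter in at least 10% of
#' samples).
#'
#' @param network named list overriding network parameters: `beta`
#'   (positive integer soft power), `min_module_size`, `deep_split` (0-4),
#'   `merge_height` in (0,1), `calibration_quantile` in (0,1),
#'   `connectivity_center` ("median" or "mean").
#' @param preservation list: `n_perm_z`, `n_perm_sig`, `alpha`,
#'   `bonferroni` (logical).
#' @param diffcor list: `n_perm`, `min_abs_ref_cor`, `alpha`.
#' @param hubs list: `kme_threshold`, `edge_threshold`, `top_n_degree`,
#'   `combine_rule` ("min" or "mean").
#' @param enrichment list: `n_draws`, `term_min`, `term_max`.
#' @param preprocess list: `offset`, `negctrl_quantile`, `brightness_factor`,
#'   `min_sample_fraction`, `k_mad`, `pooled_pure` (logical; pool both pure
#'   subspecies when computing fertility reference statistics).
#' @param seed integer root seed; per-stage seeds are derived from it with
#'   [stageSeed()].
#' @return a validated nested list of class `"PipelineConfig"`.
#' @export
#' @examples
#' cfg <- pipelineConfig(network = list(beta = 6))
#' cfg$network$beta
pipelineConfig <- function(network = list(), preservation = list(),
                           diffcor = list(), hubs = list(),
                           enrichment = list(), preprocess = list(),
                           seed = 1L) {
  cfg <- list(
    network = list(beta = 5L, min_module_size = 50L, deep_split = 0L,
                   merge_height = 0.2, calibration_quantile = 0.95,
                   connectivity_center = "median"),
    preservation = list(n_perm_z = 500L, n_perm_sig = 1000L, alpha = 0.05,
                        bonferroni = FALSE),
    diffcor = list(n_perm = 100L, min_abs_ref_cor = 0.01, alpha = 0.05),
    hubs = list(kme_threshold = 0.85, edge_threshold = 0.1,
                top_n_degree = 5L, combine_rule = "min"),
    enrichment = list(n_draws = 10000L, term_min = 11L, term_max = 499L),
    preprocess = list(offset = 50, negctrl_quantile = 0.98,
                      brightness_factor = 1.10, min_sample_fraction = 0.10,
                      k_mad = 6, pooled_pure = TRUE),
    seed = as.integer(seed)
  )
  user <- list(network = network, preservation = preservation,
               diffcor = diffcor, hubs = hubs, enrichment = enrichment,
               preprocess = preprocess)
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(extra))
      stop(sprintf("unknown %s parameter(s): %s", sec,
                   paste(extra, collapse = ", ")), call. = FALSE)
    cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
  }
  validatePipelineConfig(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

validatePipelineConfig <- function(cfg) {
  n <- cfg$network
  .assertScalarNumber(n$beta, "network.beta", 1, Inf, integer = TRUE)
  .assertScalarNumber(n$min_module_size, "network.min_module_size", 2, Inf,
                      integer = TRUE)
  .assertScalarNumber(n$deep_split, "network.deep_split", 0, 4,
                      integer = TRUE)
  .assertScalarNumber(n$merge_height, "network.merge_height", 1e-12, 1 - 1e-12)
  .assertScalarNumber(n$calibration_quantile, "network.calibration_quantile",
                      1e-12, 1 - 1e-12)
  if (!n$connectivity_center %in% c("median", "mean"))
    stop("network.connectivity_center must be 'median' or 'mean'",
         call. = FALSE)
  p <- cfg$preservation
  .assertScalarNumber(p$n_perm_z, "preservation.n_perm_z", 100, Inf,
                      integer = TRUE)
  .assertScalarNumber(p$n_perm_sig, "preservation.n_perm_sig", 100, Inf,
                      integer = TRUE)
  .assertScalarNumber(p$alpha, "preservation.alpha", 1e-12, 1 - 1e-12)
  d <- cfg$diffcor
  .assertScalarNumber(d$n_perm, "diffcor.n_perm", 50, Inf, integer = TRUE)
  .assertScalarNumber(d$min_abs_ref_cor, "diffcor.min_abs_ref_cor", 0,
                      0.2 - 1e-12)
  .assertScalarNumber(d$alpha, "diffcor.alpha", 1e-12, 1 - 1e-12)
  h <- cfg$hubs
  .assertScalarNumber(h$kme_threshold, "hubs.kme_threshold", 1e-12,
                      1 - 1e-12)
  .assertScalarNumber(h$edge_threshold, "hubs.edge_threshold", 1e-12,
                      1 - 1e-12)
  .assertScalarNumber(h$top_n_degree, "hubs.top_n_degree", 1, Inf,
                      integer = TRUE)
  if (!h$combine_rule %in% c("min", "mean"))
    stop("hubs.combine_rule must be 'min' or 'mean'", call. = FALSE)
  e <- cfg$enrichment
  .assertScalarNumber(e$n_draws, "enrichment.n_draws", 1, Inf,
                      integer = TRUE)
  .assertScalarNumber(e$term_min, "enrichment.term_min", 1, Inf,
                      integer = TRUE)
  .assertScalarNumber(e$term_max, "enrichment.term_max", 1, Inf,
                      integer = TRUE)
  if (e$term_min >= e$term_max)
    stop("enrichment.term_min must be < enrichment.term_max", call. = FALSE)
  q <- cfg$preprocess
  .assertScalarNumber(q$offset, "preprocess.offset", 0, Inf)
  .assertScalarNumber(q$negctrl_quantile, "preprocess.negctrl_quantile",
                      1e-12, 1 - 1e-12)
  .assertScalarNumber(q$brightness_factor, "preprocess.brightness_factor",
                      1e-12, Inf)
  .assertScalarNumber(q$min_sample_fraction, "preprocess.min_sample_fraction",
                      1e-12, 1 - 1e-12)
  .assertScalarNumber(q$k_mad, "preprocess.k_mad", 0, Inf)
  .assertScalarNumber(cfg$seed, "seed", -2^31, 2^31, integer = TRUE)
  invisible(TRUE)
}

## flatten a nested config into section.key=value lines and back
.flattenConfig <- function(cfg) {
  out <- character()
  for (sec in setdiff(names(cfg), "seed")) {
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      out <- c(out, sprintf("%s.%s=%s", sec, key,
                            if (is.logical(v)) tolower(as.character(v))
                            else format(v, digits = 17)))
    }
  }
  c(out, sprintf("seed=%d", cfg$seed))
}

#' Write / read a pipeline configuration file
#'
#' The on-disk format is a flat `section.key=value` text file; `#` starts a
#' comment. Unknown keys are an error on read, which catches typos early.
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @param path file path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` returns a `PipelineConfig`.
#' @export
writePipelineConfig <- function(cfg, path) {
  writeLines(.flattenConfig(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  sections <- list(network = list(), preservation = list(), diffcor = list(),
                   hubs = list(), enrichment = list(), preprocess = list())
  seed <- 1L
  charKeys <- c("connectivity_center", "combine_rule")
  logicalKeys <- c("bonferroni", "pooled_pure")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "seed") { seed <- as.integer(val); next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% names(sections))
      stop("unknown config key: '", key, "'", call. = FALSE)
    sections[[parts[1L]]][[parts[2L]]] <-
      if (parts[2L] %in% charKeys) val
      else if (parts[2L] %in% logicalKeys) as.logical(toupper(val))
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for '", key, "'",
                             call. = FALSE)
        if (num == round(num)) as.integer(num) else num
      }
  }
  pipelineConfig(network = sections$network,
                 preservation = sections$preservation,
                 diffcor = sections$diffcor, hubs = sections$hubs,
                 enrichment = sections$enrichment,
                 preprocess = sections$preprocess, seed = seed)
}
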