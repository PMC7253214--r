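#' Simulation configuration
#'
#' Parameters of the synthetic two-population expression generator. The
#' defaults emulate the study design this package implements: two hybrid
#' mapping cohorts (F2, HZ) sharing 15 consensus modules, with per-population
#' fertile / intermediate / subfertile-normal-expression (SFNE) /
#' subfertile-aberrant-expression (SFAE) class sizes of 102/92/69/37 (F2) and
#' 79/41/38/17 (HZ), plus 16 + 16 pure subspecies males. Module sizes span
#' 50-300 probes (about 3,000 module + background probes in total, a
#' desk-scale stand-in for the full array). Expression follows a
#' linear-Gaussian factor model on the log2 scale:
#' \deqn{x_{gs} = \mu_g + \lambda_g f_{m(g),s} + c_g A_s + \gamma_{g,b(s)} +
#'   \delta_{g,b(s)} \epsilon_{gs}}
#' with per-module latent factors f, gene loadings lambda (a random +/-1
#' orientation per module), a global aberrant-expression axis c that only
#' SFAE samples load on (A_s = `sfae_axis_effect`), batch location/scale
#' effects gamma/delta, and iid noise. In subfertile samples, disrupted
#' modules have the factor term of a chosen gene fraction either replaced by
#' an independent draw (`decouple`) or sign-flipped (`reverse`). Two fertility
#' phenotypes (relative testis weight, sperm count) are driven by a subset of
#' module factors and mapped into class-consistent bands relative to the pure
#' samples, so the phenotype classification rule recovers the planted
#' classes.
#'
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of module sizes (default: evenly spaced
#'   between 50 and 300).
#' @param n_background_genes expressed genes belonging to no module.
#' @param n_unexpressed_genes genes below the detection filter.
#' @param n_negative_controls negative-control probes.
#' @param class_sizes named list per hybrid population of class counts
#'   (fertile, intermediate, SFNE, SFAE).
#' @param pure_sizes named counts of pure subspecies samples.
#' @param n_batches named number of batches per hybrid population.
#' @param loading_range range of |lambda| in (0, 1].
#' @param noise_sd residual SD on the log2 scale.
#' @param batch_location_sd SD of per-gene batch location offsets.
#' @param batch_scale_range range of per-gene batch scale multipliers.
#' @param phenotype_weights named list (one per phenotype) of named module
#'   weight vectors.
#' @param phenotype_noise_sd SD of phenotype noise.
#' @param subfertile_shift,intermediate_shift downward shift (in factor SD
#'   units, along the fertility direction) applied to phenotype-driving
#'   module factors of subfertile / intermediate samples.
#' @param disruption_spec named list per disrupted module:
#'   `list(mode = "decouple"|"reverse", gene_fraction = ...)`.
#' @param sfae_axis_effect displacement of SFAE samples along the planted
#'   aberrant-expression axis (log2-scale SD units).
#' @param sfae_axis_gene_fraction fraction of expressed genes on the axis.
#' @param duplicate_probe_fraction fraction of genes carrying a second probe
#'   (identical structural terms, independent noise).
#' @param mu_range range of baseline log2 expression of expressed genes.
#' @param seed integer seed.
#' @return validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
    n_modules = 15L,
    module_sizes = NULL,
    n_background_genes = 300L,
    n_unexpressed_genes = 150L,
    n_negative_controls = 100L,
    class_sizes = list(
      F2 = c(fertile = 102L, intermediate = 92L, SFNE = 69L, SFAE = 37L),
      HZ = c(fertile = 79L, intermediate = 41L, SFNE = 38L, SFAE = 17L)),
    pure_sizes = c(pure_dom = 16L, pure_mus = 16L),
    n_batches = c(F2 = 2L, HZ = 2L),
    loading_range = c(0.35, 0.98),
    noise_sd = 0.6,
    batch_location_sd = 0.3,
    batch_scale_range = c(0.8, 1.25),
    phenotype_weights = list(
      rel_testis = c(M1 = 0.7, M2 = 0.6, M3 = -0.5),
      sperm = c(M1 = 0.6, M4 = 0.7)),
    phenotype_noise_sd = 0.6,
    subfertile_shift = 1.2,
    intermediate_shift = 0.6,
    disruption_spec = list(
      M1 = list(mode = "decouple", gene_fraction = 1.0),
      M2 = list(mode = "decouple", gene_fraction = 0.6),
      M3 = list(mode = "reverse", gene_fraction = 0.5)),
    sfae_axis_effect = 3,
    sfae_axis_gene_fraction = 0.3,
    duplicate_probe_fraction = 0.05,
    mu_range = c(7, 12),
    seed = 1L) {
  if (is.null(module_sizes))
    module_sizes <- as.integer(round(seq(300, 50, length.out = n_modules)))
  cfg <- list(n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              n_background_genes = as.integer(n_background_genes),
              n_unexpressed_genes = as.integer(n_unexpressed_genes),
              n_negative_controls = as.integer(n_negative_controls),
              class_sizes = class_sizes, pure_sizes = pure_sizes,
              n_batches = n_batches, loading_range = loading_range,
              noise_sd = noise_sd, batch_location_sd = batch_location_sd,
              batch_scale_range = batch_scale_range,
              phenotype_weights = phenotype_weights,
              phenotype_noise_sd = phenotype_noise_sd,
              subfertile_shift = subfertile_shift,
              intermediate_shift = intermediate_shift,
              disruption_spec = disruption_spec,
              sfae_axis_effect = sfae_axis_effect,
              sfae_axis_gene_fraction = sfae_axis_gene_fraction,
              duplicate_probe_fraction = duplicate_probe_fraction,
              mu_range = mu_range, seed = as.integer(seed))
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("module_sizes must have n_modules entries", call. = FALSE)
  if (any(cfg$module_sizes < 2L))
    stop("every module needs >= 2 genes", call. = FALSE)
  if (sum(unlist(cfg$pure_sizes)) < 2L)
    stop("need >= 2 pure samples for fertility classification", call. = FALSE)
  for (pop in names(cfg$class_sizes)) {
    cs <- cfg$class_sizes[[pop]]
    need <- c("fertile", "intermediate", "SFNE", "SFAE")
    if (!all(need %in% names(cs)))
      stop("class_sizes for ", pop, " must name ",
           paste(need, collapse = ", "), call. = FALSE)
    if (cs["fertile"] < 2L)
      stop("need >= 2 fertile samples per population", call. = FALSE)
  }
  mods <- paste0("M", seq_len(cfg$n_modules))
  badD <- setdiff(names(cfg$disruption_spec), mods)
  if (length(badD))
    stop("disruption_spec refers to unknown module(s): ",
         paste(badD, collapse = ", "), call. = FALSE)
  for (d in cfg$disruption_spec) {
    if (!d$mode %in% c("decouple", "reverse"))
      stop("disruption mode must be 'decouple' or 'reverse'", call. = FALSE)
    if (d$gene_fraction <= 0 || d$gene_fraction > 1)
      stop("disruption gene_fraction must lie in (0, 1]", call. = FALSE)
  }
  badW <- setdiff(unlist(lapply(cfg$phenotype_weights, names)), mods)
  if (length(badW))
    stop("phenotype_weights refer to unknown module(s): ",
         paste(badW, collapse = ", "), call. = FALSE)
  if (cfg$loading_range[1L] <= 0 || cfg$loading_range[2L] > 1 ||
      diff(cfg$loading_range) < 0)
    stop("loading_range must satisfy 0 < low <= high <= 1", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$batch_location_sd < 0)
    stop("batch_location_sd must be >= 0", call. = FALSE)
  if (cfg$batch_scale_range[1L] <= 0 ||
      diff(cfg$batch_scale_range) < 0)
    stop("batch_scale_range must satisfy 0 < low <= high", call. = FALSE)
  if (cfg$sfae_axis_effect < 0)
    stop("sfae_axis_effect must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Simulated dataset container
#'
#' Returned by [simulateDataset()]. `se` is the combined log2-scale
#' expression `SummarizedExperiment` over all populations (probe annotation
#' in `rowData`, sample table plus planted class labels in `colData`);
#' `foreground` / `background` are matched raw-intensity fixtures for testing
#' the preprocessing stage (`foreground = 2^x + background + noise`); `truth`
#' is the planted ground truth (see [simulateDataset()]).
#'
#' @slot se `SummarizedExperiment`, log2-scale expression.
#' @slot foreground,background raw-intensity matrices.
#' @slot truth list of planted ground truth.
#' @slot config the `SimulationConfig` used.
#' @export
setClass("CoexSimulation",
  representation(se = "SummarizedExperiment", foreground = "matrix",
                 background = "matrix", truth = "list", config = "list"))

setMethod("show", "CoexSimulation", function(object) {
  cat("CoexSimulation:", nrow(object@se), "probes x", ncol(object@se),
      "samples;", object@config$n_modules, "planted modules;",
      length(object@truth$disrupted_modules), "disrupted\n")
  print(table(colData(object@se)$population, colData(object@se)$planted_class))
})

#' Simulate a two-population expression dataset with planted ground truth
#'
#' Generates the full synthetic study described in [simulationConfig()]:
#' a combined log2-scale expression matrix over both hybrid populations and
#' the pure subspecies samples, raw-intensity foreground/background fixtures,
#' probe annotation (including duplicate probes and negative controls), a
#' sample phenotype table, and the planted truth needed to score every
#' downstream stage.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @return a [CoexSimulation-class]. `truth` contains `module_of_gene`,
#'   `module_of_probe`, `loadings` (named, signed), `module_sign`, `factors`
#'   (module x sample), `shifted_factors`, `disrupted_modules`,
#'   `disrupted_genes`, `axis_genes`, `axis_loadings`, `phenotype_weights`,
#'   `latent_phenotypes`, `batch_effects`, and `pure_stats`.
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(
#'   n_modules = 3, module_sizes = c(30, 30, 30),
#'   n_background_genes = 30, n_unexpressed_genes = 10,
#'   n_negative_controls = 10,
#'   class_sizes = list(
#'     F2 = c(fertile = 20, intermediate = 5, SFNE = 5, SFAE = 5),
#'     HZ = c(fertile = 20, intermediate = 5, SFNE = 5, SFAE = 5)),
#'   pure_sizes = c(pure_dom = 5, pure_mus = 5), seed = 7))
#' sim
simulateDataset <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, .simulateDatasetImpl(config))
}

.simulateDatasetImpl <- function(cfg) {
  mods <- paste0("M", seq_len(cfg$n_modules))
  sizes <- setNames(cfg$module_sizes, mods)

  ## ---- genes and probes -------------------------------------------------
  nMod <- sum(sizes)
  geneMod <- sprintf("g%05d", seq_len(nMod))
  geneBg <- sprintf("b%05d", seq_len(cfg$n_background_genes))
  geneUn <- sprintf("u%05d", seq_len(cfg$n_unexpressed_genes))
  genes <- c(geneMod, geneBg, geneUn)
  moduleOfGene <- setNames(c(rep(mods, times = sizes),
                             rep("background", cfg$n_background_genes),
                             rep("unexpressed", cfg$n_unexpressed_genes)),
                           genes)
  expressed <- c(geneMod, geneBg)

  ## ---- samples ----------------------------------------------------------
  smp <- list()
  for (pop in names(cfg$class_sizes)) {
    cs <- cfg$class_sizes[[pop]]
    for (cl in names(cs)) {
      if (cs[[cl]] == 0L) next
      ids <- sprintf("%s_%s_%03d", pop, cl, seq_len(cs[[cl]]))
      smp[[length(smp) + 1L]] <- data.frame(
        sample_id = ids, population = pop,
        planted_class = if (cl %in% c("SFNE", "SFAE")) "subfertile" else cl,
        planted_expression_class = if (cl %in% c("SFNE", "SFAE")) cl
          else "not_applicable",
        stringsAsFactors = FALSE)
    }
  }
  for (pop in names(cfg$pure_sizes)) {
    if (cfg$pure_sizes[[pop]] == 0L) next
    ids <- sprintf("%s_%03d", pop, seq_len(cfg$pure_sizes[[pop]]))
    smp[[length(smp) + 1L]] <- data.frame(
      sample_id = ids, population = pop, planted_class = "pure",
      planted_expression_class = "not_applicable", stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, smp)
  nS <- nrow(samples)

  ## batches: per hybrid population; pure samples ride along in batch 1
  hybPops <- names(cfg$class_sizes)
  samples$batch <- NA_character_
  for (pop in hybPops) {
    sel <- samples$population == pop
    nb <- cfg$n_batches[[pop]]
    samples$batch[sel] <- sprintf("%s_b%d", pop,
                                  1L + (seq_len(sum(sel)) - 1L) %% nb)
  }
  pureSel <- is.na(samples$batch)
  samples$batch[pureSel] <- sprintf("%s_b1",
                                    hybPops[1L + (seq_len(sum(pureSel)) - 1L)
                                            %% length(hybPops)])

  ## ---- structural parameters --------------------------------------------
  moduleSign <- setNames(sample(c(-1, 1), cfg$n_modules, replace = TRUE),
                         mods)
  lam <- setNames(numeric(length(genes)), genes)
  lam[geneMod] <- runif(nMod, cfg$loading_range[1L], cfg$loading_range[2L]) *
    moduleSign[moduleOfGene[geneMod]]

  nAxis <- floor(cfg$sfae_axis_gene_fraction * length(expressed))
  axisGenes <- sort(sample(expressed, nAxis))
  axisLoad <- setNames(rnorm(nAxis), axisGenes)

  mu <- setNames(numeric(length(genes)), genes)
  mu[expressed] <- runif(length(expressed), cfg$mu_range[1L],
                         cfg$mu_range[2L])
  mu[geneUn] <- rnorm(cfg$n_unexpressed_genes, 2, 0.4)

  ## factors: iid standard normal per (module, sample)
  f <- matrix(rnorm(cfg$n_modules * nS), cfg$n_modules, nS,
              dimnames = list(mods, samples$sample_id))

  ## fertility direction per module = sign of its summed phenotype weight
  wSum <- setNames(numeric(cfg$n_modules), mods)
  for (w in cfg$phenotype_weights)
    wSum[names(w)] <- wSum[names(w)] + w
  fertDir <- sign(wSum)

  fShift <- f
  subf <- samples$planted_class == "subfertile"
  interm <- samples$planted_class == "intermediate"
  drive <- mods[fertDir != 0]
  if (length(drive)) {
    fShift[drive, subf] <- fShift[drive, subf] -
      cfg$subfertile_shift * fertDir[drive]
    fShift[drive, interm] <- fShift[drive, interm] -
      cfg$intermediate_shift * fertDir[drive]
  }

  ## ---- expression -------------------------------------------------------
  x <- matrix(mu, length(genes), nS,
              dimnames = list(genes, samples$sample_id))
  struct <- matrix(0, length(genes), nS, dimnames = dimnames(x))
  isModGene <- moduleOfGene[genes] %in% mods
  struct[isModGene, ] <- lam[genes[isModGene]] *
    fShift[moduleOfGene[genes[isModGene]], , drop = FALSE]

  ## targeted disruption in subfertile samples
  disruptedGenes <- list()
  for (m in names(cfg$disruption_spec)) {
    dsp <- cfg$disruption_spec[[m]]
    members <- genes[moduleOfGene == m]
    nSel <- max(1L, round(dsp$gene_fraction * length(members)))
    sel <- sort(sample(members, nSel))
    disruptedGenes[[m]] <- sel
    if (any(subf)) {
      if (dsp$mode == "decouple") {
        struct[sel, subf] <- lam[sel] *
          matrix(rnorm(length(sel) * sum(subf)), length(sel), sum(subf))
      } else {
        struct[sel, subf] <- -struct[sel, subf]
      }
    }
  }
  x <- x + struct

  ## aberrant-expression axis (SFAE samples only)
  A <- ifelse(samples$planted_expression_class == "SFAE",
              cfg$sfae_axis_effect, 0)
  x[axisGenes, ] <- x[axisGenes, ] + outer(axisLoad, A)

  ## batch location/scale effects + noise
  batches <- sort(unique(samples$batch))
  gamma <- matrix(rnorm(length(genes) * length(batches), 0,
                        cfg$batch_location_sd),
                  length(genes), length(batches),
                  dimnames = list(genes, batches))
  delta <- matrix(runif(length(genes) * length(batches),
                        cfg$batch_scale_range[1L],
                        cfg$batch_scale_range[2L]),
                  length(genes), length(batches),
                  dimnames = list(genes, batches))
  bIdx <- match(samples$batch, batches)
  eps <- matrix(rnorm(length(genes) * nS, 0, cfg$noise_sd),
                length(genes), nS)
  ## unexpressed genes fluctuate less (they sit at the noise floor)
  eps[moduleOfGene == "unexpressed", ] <-
    eps[moduleOfGene == "unexpressed", ] * 0.3
  x <- x + gamma[, bIdx] + delta[, bIdx] * eps

  ## ---- probes (one per gene, plus duplicates, plus negative controls) ---
  probeData <- data.frame(probe_id = paste0("p_", genes), gene_id = genes,
                          is_negative_control = FALSE,
                          stringsAsFactors = FALSE)
  X <- x
  rownames(X) <- probeData$probe_id
  nDup <- floor(cfg$duplicate_probe_fraction * length(expressed))
  if (nDup > 0L) {
    dupGenes <- sort(sample(expressed, nDup))
    ## identical structural terms, independent (batch-scaled) noise
    dup <- x[dupGenes, , drop = FALSE] -
      delta[dupGenes, bIdx, drop = FALSE] *
        eps[match(dupGenes, genes), , drop = FALSE] +
      delta[dupGenes, bIdx, drop = FALSE] *
        matrix(rnorm(nDup * nS, 0, cfg$noise_sd), nDup, nS)
    rownames(dup) <- paste0("p_", dupGenes, "_2")
    X <- rbind(X, dup)
    probeData <- rbind(probeData,
                       data.frame(probe_id = rownames(dup),
                                  gene_id = dupGenes,
                                  is_negative_control = FALSE))
  }
  if (cfg$n_negative_controls > 0L) {
    nc <- matrix(rnorm(cfg$n_negative_controls * nS, 2, 0.3),
                 cfg$n_negative_controls, nS)
    nc <- nc + matrix(rnorm(length(nc), 0, 0.15), nrow(nc))
    rownames(nc) <- sprintf("NC%04d", seq_len(cfg$n_negative_controls))
    X <- rbind(X, nc)
    probeData <- rbind(probeData,
                       data.frame(probe_id = rownames(nc), gene_id = "",
                                  is_negative_control = TRUE))
  }

  ## ---- phenotypes: driven by the same (shifted) factor scores ------------
  phen <- .simulatePhenotypes(cfg, fShift, samples)
  samples <- cbind(samples, phen$table)

  se <- makeCoexExperiment(X, probeData, samples, scaleTag = "log2")

  ## ---- raw-intensity fixtures -------------------------------------------
  bgTrue <- matrix(rnorm(nrow(X) * nS, 120, 10), nrow(X), nS,
                   dimnames = dimnames(X))
  fg <- 2^X + bgTrue + matrix(rnorm(length(X), 0, 5), nrow(X))
  bg <- bgTrue + matrix(rnorm(length(X), 0, 5), nrow(X))
  fg <- pmax(fg, 1)
  bg <- pmax(bg, 1)

  truth <- list(module_of_gene = moduleOfGene,
                module_of_probe = setNames(
                  ifelse(probeData$gene_id == "", "negative_control",
                         moduleOfGene[probeData$gene_id]),
                  probeData$probe_id),
                loadings = lam[geneMod], module_sign = moduleSign,
                module_sizes = sizes,
                factors = f, shifted_factors = fShift,
                disrupted_modules = names(cfg$disruption_spec),
                disrupted_genes = disruptedGenes,
                axis_genes = axisGenes, axis_loadings = axisLoad,
                phenotype_weights = cfg$phenotype_weights,
                latent_phenotypes = phen$latent,
                pure_stats = phen$pure_stats,
                batch_effects = list(location = gamma, scale = delta))
  new("CoexSimulation", se = se, foreground = fg, background = bg,
      truth = truth, config = unclass(cfg))
}

## Map latent phenotype scores into class-consistent trait bands relative to
## the pure samples. Fertile traits land strictly within 1 sample SD of the
## pure mean; intermediate traits stay within the pure range but >1 SD out on
## one trait; subfertile traits fall below the pure minimum on relative
## testis weight (and for the lower half also on sperm count).
.simulatePhenotypes <- function(cfg, f, samples) {
  traits <- names(cfg$phenotype_weights)
  nS <- nrow(samples)
  latent <- matrix(0, length(traits), nS,
                   dimnames = list(traits, samples$sample_id))
  for (tr in traits) {
    w <- cfg$phenotype_weights[[tr]]
    latent[tr, ] <- colSums(f[names(w), , drop = FALSE] * w) +
      rnorm(nS, 0, cfg$phenotype_noise_sd)
    latent[tr, ] <- latent[tr, ] /
      sqrt(sum(w^2) + cfg$phenotype_noise_sd^2)
  }
  base <- list(rel_testis = c(mu = 0.0082, sd = 0.0009),
               sperm = c(mu = 18e6, sd = 3.5e6))
  pure <- samples$planted_class == "pure"
  fert <- samples$planted_class == "fertile"
  interm <- samples$planted_class == "intermediate"
  subf <- samples$planted_class == "subfertile"

  vals <- matrix(NA_real_, length(traits), nS, dimnames = dimnames(latent))
  pureStats <- list()
  ## which subfertile samples are out of range on the second trait as well
  bothOut <- subf & latent[1L, ] < median(latent[1L, subf])
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    b <- base[[tr]]
    z <- latent[tr, ]
    vals[tr, pure] <- b["mu"] + b["sd"] * z[pure]
    m <- mean(vals[tr, pure]); s <- sd(vals[tr, pure])
    lo <- min(vals[tr, pure]); hi <- max(vals[tr, pure])
    pureStats[[tr]] <- c(mean = m, sd = s, lo = lo, hi = hi)
    vals[tr, fert] <- m + 0.95 * s * tanh(0.8 * z[fert])
    ## intermediate: beyond 1 SD on the low side, but inside the range
    devMax <- max(1.10, min(1.6, (m - lo) / s - 0.05))
    u <- pnorm(-z[interm])
    if (ti == 1L) {
      vals[tr, interm] <- m - s * (1.05 + (devMax - 1.05) * u)
    } else {
      vals[tr, interm] <- m + 0.95 * s * tanh(0.8 * z[interm])
    }
    ## subfertile: below the pure range on trait 1; trait 2 out for half
    u2 <- pnorm(-z[subf])
    if (ti == 1L) {
      vals[tr, subf] <- lo - s * (0.3 + 1.5 * u2)
    } else {
      inSet <- bothOut[subf]
      v <- m + 0.95 * s * tanh(0.8 * z[subf])
      v[inSet] <- lo - s * (0.2 + 1.2 * u2[inSet])
      vals[tr, subf] <- v
    }
  }
  vals[] <- pmax(vals, 0)
  bodyW <- rnorm(nS, 20, 1.5)
  tab <- data.frame(body_weight = bodyW,
                    testis_weight = vals["rel_testis", ] * bodyW,
                    sperm_count = round(pmax(vals["sperm", ], 0)))
  ## optional sperm-motility traits, driven by the same latent axis
  tab$VCL <- 120 + 25 * latent["sperm", ] + rnorm(nS, 0, 10)
  tab$VAP <- 60 + 12 * latent["sperm", ] + rnorm(nS, 0, 6)
  list(table = tab, latent = latent, pure_stats = pureStats)
}

#' Simulate gene annotations matched to a simulated dataset
#'
#' Places every expressed gene uniformly on a synthetic genome (20
#' chromosomes of 50 Mb, 0-based half-open coordinates), then constructs
#' interval sets shaped like GWAS sterility regions and trans-eQTL hotspots,
#' and gene sets (term / cell-type / QTT categories) overlapping chosen
#' modules at a configurable Jaccard index, plus size-matched random control
#' sets. Interval sets capture each hub-candidate gene (top decile of
#' absolute loading) of the target modules with probability
#' `min(1, enrichmentMultiplier * regionFraction)` and every other gene with
#' probability `regionFraction`, so a multiplier of 1 is the null.
#'
#' @param truth the `truth` list of a [CoexSimulation-class].
#' @param config the `SimulationConfig` used to generate it.
#' @param seed integer seed.
#' @param targetModules modules whose hub candidates are enriched in the
#'   interval sets and mirrored by gene sets.
#' @param regionFraction genome-wide capture probability of the regions.
#' @param enrichmentMultiplier capture-probability multiplier for
#'   hub-candidate genes of the target modules (must keep the probability
#'   at or below 1).
#' @param jaccard target Jaccard index between each planted gene set and its
#'   module.
#' @param nControlSets number of size-matched random control sets per
#'   category.
#' @return an [AnnotationBundle-class].
#' @export
simulateAnnotations <- function(truth, config, seed = 1L,
                                targetModules = c("M1", "M2"),
                                regionFraction = 0.1,
                                enrichmentMultiplier = 3,
                                jaccard = 0.5, nControlSets = 3L) {
  pHub <- enrichmentMultiplier * regionFraction
  if (pHub > 1)
    stop("requested enrichment is infeasible: multiplier x fraction > 1",
         call. = FALSE)
  mods <- paste0("M", seq_len(config$n_modules))
  if (length(setdiff(targetModules, mods)))
    stop("targetModules outside the simulated modules", call. = FALSE)
  withSeed(seed, {
    expressed <- names(truth$module_of_gene)[
      truth$module_of_gene != "unexpressed"]
    nG <- length(expressed)
    chroms <- paste0("chr", c(1:19, "X"))
    chromLen <- 50e6
    geneLen <- 5000L
    chrom <- sample(chroms, nG, replace = TRUE)
    start <- floor(runif(nG, 0, chromLen - geneLen))
    genePos <- data.frame(chrom = chrom, start = as.integer(start),
                          end = as.integer(start + geneLen),
                          gene_id = expressed)

    ## hub candidates: top decile of |loading| within each target module
    hubCand <- character()
    for (m in targetModules) {
      lamM <- abs(truth$loadings[names(truth$module_of_gene)[
        truth$module_of_gene == m]])
      hubCand <- c(hubCand,
                   names(lamM)[lamM >= quantile(lamM, 0.9)])
    }
    capture <- ifelse(expressed %in% hubCand, pHub, regionFraction)
    intervalSets <- list()
    for (setName in c("sterility_regions", "hotspots")) {
      inRegion <- runif(nG) < capture
      g <- genePos[inRegion, , drop = FALSE]
      intervalSets[[setName]] <- data.frame(
        chrom = g$chrom, start = pmax(0L, g$start - 100L),
        end = g$end + 100L,
        name = sprintf("%s_%04d", setName, seq_len(nrow(g))))
    }

    ## gene sets overlapping target modules at the requested Jaccard
    sets <- list(); cats <- character()
    for (m in targetModules) {
      members <- names(truth$module_of_gene)[truth$module_of_gene == m]
      K <- length(members)
      o <- round(2 * K * jaccard / (1 + jaccard))
      o <- min(o, K)
      other <- setdiff(expressed, members)
      s <- c(sample(members, o), sample(other, K - o))
      nm <- paste0("term_", m)
      sets[[nm]] <- sort(s); cats[nm] <- "term"
    }
    ## cell-type-like and QTT-like sets mirror the first target module
    m1 <- targetModules[1L]
    members <- names(truth$module_of_gene)[truth$module_of_gene == m1]
    o <- min(round(2 * length(members) * jaccard / (1 + jaccard)),
             length(members))
    ctSet <- c(sample(members, o),
               sample(setdiff(expressed, members), length(members) - o))
    sets[["celltype_spermatid"]] <- sort(ctSet)
    cats["celltype_spermatid"] <- "cell_type"
    qttSet <- c(sample(members, o),
                sample(setdiff(expressed, members), length(members) - o))
    sets[["qtt_set"]] <- sort(qttSet)
    cats["qtt_set"] <- "qtt"
    ## size-matched random controls
    for (i in seq_len(nControlSets)) {
      nm <- sprintf("control_%02d", i)
      sets[[nm]] <- sort(sample(expressed, length(members)))
      cats[nm] <- "term"
    }
    AnnotationBundle(genePositions = genePos, intervalSets = intervalSets,
                     geneSets = sets, setCategories = cats)
  })
}
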