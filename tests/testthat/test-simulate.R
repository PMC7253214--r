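test_that("the same seed reproduces the dataset exactly", {
  s1 <- simulateDataset(tinySimConfig(seed = 7))
  s2 <- simulateDataset(tinySimConfig(seed = 7))
  expect_identical(SummarizedExperiment::assay(s1@se),
                   SummarizedExperiment::assay(s2@se))
  expect_identical(s1@foreground, s2@foreground)
  expect_identical(s1@truth$loadings, s2@truth$loadings)
  s3 <- simulateDataset(tinySimConfig(seed = 8))
  expect_false(identical(SummarizedExperiment::assay(s1@se),
                         SummarizedExperiment::assay(s3@se)))
})

test_that("pairwise correlation matches the closed-form factor model", {
  ## two genes sharing one factor with lambda = 1, noise SD = 1:
  ## cor = (1*1) / sqrt((1 + 1) * (1 + 1)) = 0.5
  cfg <- simulationConfig(
    n_modules = 1, module_sizes = 2L, n_background_genes = 2,
    n_unexpressed_genes = 2, n_negative_controls = 2,
    loading_range = c(1, 1), noise_sd = 1,
    batch_location_sd = 0, batch_scale_range = c(1, 1),
    class_sizes = list(F2 = c(fertile = 500, intermediate = 1, SFNE = 1,
                              SFAE = 1)),
    pure_sizes = c(pure_dom = 5, pure_mus = 5), n_batches = c(F2 = 1),
    phenotype_weights = list(rel_testis = c(M1 = 0.5), sperm = c(M1 = 0.5)),
    disruption_spec = list(), sfae_axis_effect = 0,
    duplicate_probe_fraction = 0, seed = 42)
  sim <- simulateDataset(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  fert <- cd$sample_id[cd$planted_class == "fertile"]
  x <- SummarizedExperiment::assay(sim@se)
  genes <- names(sim@truth$module_of_gene)[sim@truth$module_of_gene == "M1"]
  r <- cor(x[paste0("p_", genes[1]), fert], x[paste0("p_", genes[2]), fert])
  expect_lt(abs(abs(r) - 0.5), 0.1)
})

test_that("full decoupling removes within-module correlation in subfertile samples", {
  sim <- simulateDataset(tinySimConfig(seed = 3))
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  x <- SummarizedExperiment::assay(sim@se)
  m1 <- paste0("p_", names(sim@truth$module_of_gene)[
    sim@truth$module_of_gene == "M1"])
  subf <- cd$sample_id[cd$planted_class == "subfertile"]
  fert <- cd$sample_id[cd$planted_class == "fertile"]
  cSub <- cor(t(x[m1, subf]))
  cFer <- cor(t(x[m1, fert]))
  expect_lt(abs(mean(cSub[upper.tri(cSub)])), 0.12)
  expect_gt(mean(cFer[upper.tri(cFer)]), 0.25)
})

test_that("marginal gene variance matches the generative model", {
  cfg <- simulationConfig(
    n_modules = 2, module_sizes = c(20, 20), n_background_genes = 20,
    n_unexpressed_genes = 5, n_negative_controls = 5,
    batch_location_sd = 0, batch_scale_range = c(1, 1), noise_sd = 0.6,
    class_sizes = list(F2 = c(fertile = 600, intermediate = 1, SFNE = 1,
                              SFAE = 1)),
    pure_sizes = c(pure_dom = 5, pure_mus = 5), n_batches = c(F2 = 1),
    phenotype_weights = list(rel_testis = c(M1 = 0.5), sperm = c(M2 = 0.5)),
    disruption_spec = list(), sfae_axis_effect = 0,
    duplicate_probe_fraction = 0, seed = 5)
  sim <- simulateDataset(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  fert <- cd$sample_id[cd$planted_class == "fertile"]
  x <- SummarizedExperiment::assay(sim@se)
  lam <- sim@truth$loadings
  axis <- sim@truth$axis_loadings
  vObs <- apply(x[paste0("p_", names(lam)), fert], 1L, var)
  vExp <- lam^2 + 0.6^2 +
    ifelse(names(lam) %in% names(axis), 0, 0)  # axis inactive (effect 0)
  expect_lt(median(abs(vObs - vExp) / vExp), 0.15)
})

test_that("planted within-module correlation exceeds between-module by >= 0.2", {
  sim <- simulateDataset(tinySimConfig(seed = 11))
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  fert <- cd$sample_id[cd$planted_class == "fertile"]
  x <- SummarizedExperiment::assay(sim@se)
  tm <- sim@truth$module_of_probe[rownames(x)]
  within <- c(); between <- c()
  for (m in c("M2", "M3")) {      # M1 is decoupled in subfertile, still fine
    mi <- rownames(x)[tm == m]
    cc <- cor(t(x[mi, fert]))
    within <- c(within, abs(cc[upper.tri(cc)]))
  }
  m2 <- rownames(x)[tm == "M2"]; m3 <- rownames(x)[tm == "M3"]
  between <- abs(cor(t(x[m2, fert]), t(x[m3, fert])))
  expect_gte(mean(within) - mean(between), 0.2)
})

test_that("simulated phenotypes recover the planted fertility classes", {
  sim <- simulateDataset(tinySimConfig(seed = 2))
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  cls <- classifyFertility(cd)
  expect_identical(unname(cls$fertility_class), unname(cd$planted_class))
})

test_that("infeasible simulation configs are rejected", {
  expect_error(tinySimConfig(pure_sizes = c(pure_dom = 1, pure_mus = 0)),
               "pure")
  expect_error(tinySimConfig(
    disruption_spec = list(M9 = list(mode = "decouple",
                                     gene_fraction = 1))), "M9")
  expect_error(tinySimConfig(
    disruption_spec = list(M1 = list(mode = "destroy", gene_fraction = 1))),
    "mode")
  expect_error(tinySimConfig(loading_range = c(0, 0.9)), "loading_range")
})

test_that("simulated annotations hit their design targets", {
  sim <- simulateDataset(tinySimConfig(seed = 5))
  ## Jaccard 1 reproduces the module exactly
  b1 <- simulateAnnotations(sim@truth, sim@config, seed = 1,
                            targetModules = "M2", jaccard = 1)
  m2 <- names(sim@truth$module_of_gene)[sim@truth$module_of_gene == "M2"]
  expect_setequal(geneSets(b1)$term_M2, m2)
  ## multiplier 1 is the null: region fraction matches genome-wide fraction
  b2 <- simulateAnnotations(sim@truth, sim@config, seed = 2,
                            targetModules = "M2", regionFraction = 0.2,
                            enrichmentMultiplier = 1)
  reg <- genesInIntervals(genePositions(b2),
                          intervalSets(b2)$sterility_regions)
  nGenes <- length(genePositions(b2))
  expect_lt(abs(length(reg) / nGenes - 0.2),
            3 * sqrt(0.2 * 0.8 / nGenes) + 0.02)
  ## infeasible enrichment errors out
  expect_error(simulateAnnotations(sim@truth, sim@config, seed = 3,
                                   regionFraction = 0.5,
                                   enrichmentMultiplier = 3), "infeasible")
  ## multiplier 3 on 10% regions captures ~30% of target hub candidates
  b3 <- simulateAnnotations(sim@truth, sim@config, seed = 4,
                            targetModules = "M1", regionFraction = 0.1,
                            enrichmentMultiplier = 3)
  lamM1 <- abs(sim@truth$loadings[names(sim@truth$module_of_gene)[
    sim@truth$module_of_gene == "M1"]])
  hubCand <- names(lamM1)[lamM1 >= quantile(lamM1, 0.9)]
  reg3 <- genesInIntervals(genePositions(b3),
                           intervalSets(b3)$sterility_regions)
  expect_gt(mean(hubCand %in% reg3), 0.05)   # enriched over the 10% baseline
})
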