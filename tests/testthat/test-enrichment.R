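test_that("Fisher overlap equals exhaustive hypergeometric summation", {
  ## complete enumeration: universe of 4, two sets of 2 -> P(overlap >= 2)
  ## counts C(2,2)*C(2,0)/C(4,2) = 1/6
  expect_equal(fisherOverlap(2, 2, 2, 4)$p, 1 / 6, tolerance = 1e-12)
  expect_equal(fisherOverlap(0, 10, 5, 100)$p, 1, tolerance = 1e-12)
  set.seed(23)
  for (i in 1:50) {
    N <- sample(20:2000, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fisherOverlap(k, K, n, N)$p, hyperTailOracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  ## large-N stability (log-gamma arithmetic, no overflow)
  big <- fisherOverlap(120, 1000, 5000, 1e6)
  expect_true(is.finite(big$p) && big$p > 0 && big$p < 1e-50)
  expect_error(fisherOverlap(5, 4, 10, 100), "inconsistent")
  ## continuity correction is reported when a cell is empty
  expect_true(fisherOverlap(0, 3, 3, 10)$continuity_corrected)
  expect_false(fisherOverlap(2, 5, 5, 20)$continuity_corrected)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(24)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
    ## lowering a p-value never raises any q
    p2 <- p
    p2[1] <- p[1] / 2
    expect_true(all(bhAdjust(p2) <= q + 1e-12))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hub identification follows the kME and degree rules", {
  set.seed(25)
  n <- 40
  q <- 10
  f <- rnorm(n)
  mk <- function(tag) {
    x <- t(sapply(seq_len(q), function(i)
      (0.5 + 0.05 * i) * f + rnorm(n, 0, 0.3)))
    dimnames(x) <- list(paste0("p", 1:q), paste0(tag, 1:n))
    x
  }
  exprs <- list(F2 = mk("a"), HZ = mk("b"))
  net <- buildConsensusNetwork(exprs, minModuleSize = 5)
  hubs <- identifyHubs(net, kmeThreshold = 0.85, edgeThreshold = 0.1,
                       topNDegree = 3)
  ## kME rule with combine = min: both populations must pass
  kme <- moduleKME(net)
  comb <- pmin(kme$F2[hubs$probe_id, 1], kme$HZ[hubs$probe_id, 1])
  expect_identical(unname(hubs$kme_hub), unname(comb >= 0.85))
  ## degree rule equals exhaustive enumeration per population
  for (p in c("F2", "HZ")) {
    tm <- populationTOM(net, p)[hubs$probe_id, hubs$probe_id]
    diag(tm) <- 0
    degOracle <- rowSums(tm >= 0.1)
    expect_identical(unname(hubs[[paste0("degree_", p)]]),
                     unname(as.integer(degOracle)))
  }
  expect_identical(sum(hubs$degree_hub), length(unique(unlist(
    lapply(c("F2", "HZ"), function(p) {
      tm <- populationTOM(net, p)[hubs$probe_id, hubs$probe_id]
      diag(tm) <- 0
      deg <- rowSums(tm >= 0.1)
      ord <- order(-deg, -rowSums(tm), hubs$probe_id)
      hubs$probe_id[ord[1:3]]
    })))))
  expect_true(all(hubs$is_hub == (hubs$kme_hub | hubs$degree_hub)))
  ## kME 0.9 in one population but below threshold in the other: min rule
  km <- moduleKME(net)
  cand <- hubs$probe_id[kme$F2[hubs$probe_id, 1] >= 0.85 &
                          kme$HZ[hubs$probe_id, 1] < 0.85]
  if (length(cand))
    expect_false(any(hubs$kme_hub[hubs$probe_id %in% cand]))
})

test_that("gene-set over-representation applies the size window and BH families", {
  universe <- paste0("g", 1:400)
  moduleGenes <- list(m1 = paste0("g", 1:50), m2 = paste0("g", 51:120))
  sets <- list(tooSmall = paste0("g", 1:9),             # < 11 after filter
               hit = paste0("g", c(1:40, 200:219)),     # overlaps m1
               rand = paste0("g", 301:360))
  out <- setOverrepresentation(moduleGenes, sets, universe,
                               termMin = 11, termMax = 499)
  expect_false("tooSmall" %in% out$set)
  hit <- out[out$set == "hit" & out$module == "m1", ]
  expect_equal(hit$overlap, 40)
  expect_equal(hit$p, hyperTailOracle(40, 50, 60, 400), tolerance = 1e-10)
  expect_lt(hit$q, 0.001)
  ## module identical to the set: k = K = n
  out2 <- setOverrepresentation(list(m = paste0("g", 1:30)),
                                list(s = paste0("g", 1:30)), universe)
  expect_equal(out2$overlap, 30)
  expect_equal(out2$set_size, 30)
  expect_equal(out2$module_size, 30)
  ## BH is applied within category
  b <- AnnotationBundle(geneSets = list(t1 = sets$hit, c1 = sets$hit),
                        setCategories = c(t1 = "term", c1 = "cell_type"))
  out3 <- setOverrepresentation(moduleGenes, b, universe)
  expect_equal(out3$q[out3$category == "term"],
               bhAdjust(out3$p[out3$category == "term"]))
})

test_that("interval membership uses 0-based half-open overlap arithmetic", {
  gp <- AnnotationBundle(
    genePositions = data.frame(chrom = c("chr1", "chr1", "chr2"),
                               start = c(100, 100, 100),
                               end = c(200, 200, 200),
                               gene_id = c("gIn", "gAbut", "gChrom")))
  gr <- genePositions(gp)
  regIn <- AnnotationBundle(intervalSets = list(
    r = data.frame(chrom = "chr1", start = 150, end = 250)))
  expect_identical(genesInIntervals(gr[1], intervalSets(regIn)$r), "gIn")
  ## half-open abutment [100,200) vs [200,300): no overlap
  regAbut <- AnnotationBundle(intervalSets = list(
    r = data.frame(chrom = "chr1", start = 200, end = 300)))
  expect_length(genesInIntervals(gr["gAbut"], intervalSets(regAbut)$r), 0L)
  ## different chromosome: no overlap
  expect_length(genesInIntervals(gr["gChrom"], intervalSets(regIn)$r), 0L)
})

test_that("permutation region enrichment matches the exact hypergeometric tail", {
  universe <- paste0("g", 1:10)
  hubs <- paste0("g", 1:3)
  region <- paste0("g", c(2, 3, 5, 7, 9))
  res <- permutationRegionEnrichment(hubs, universe, region,
                                     nDraws = 10000, seed = 2)
  expect_equal(res$observed, 2)
  exact <- hyperTailOracle(2, 5, 3, 10)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$empirical_p - exact), 3 * se + 2e-4)
  ## same seed reproduces the outcome exactly
  res2 <- permutationRegionEnrichment(hubs, universe, region,
                                      nDraws = 10000, seed = 2)
  expect_identical(res, res2)
  ## empty intersection
  res3 <- permutationRegionEnrichment(hubs, universe, paste0("x", 1:4),
                                      nDraws = 500, seed = 1)
  expect_equal(res3$observed, 0)
  expect_false(res3$significant && res3$observed > 0)
  expect_error(permutationRegionEnrichment(paste0("g", 1:20), universe,
                                           region), "larger")
})

test_that("thresholded edge list exports within-module TOM edges", {
  set.seed(26)
  n <- 30
  f <- rnorm(n)
  x <- t(sapply(1:8, function(i) 0.8 * f + rnorm(n, 0, 0.4)))
  dimnames(x) <- list(paste0("p", 1:8), paste0("s", 1:n))
  net <- buildConsensusNetwork(list(A = x), minModuleSize = 4)
  el <- tomEdgeList(net, "A", edgeThreshold = 0.1)
  tm <- populationTOM(net, "A")
  for (i in seq_len(nrow(el)))
    expect_gte(tm[el$probe_a[i], el$probe_b[i]], 0.1)
  labels <- moduleLabels(net)
  expect_true(all(labels[el$probe_a] == labels[el$probe_b]))
})
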