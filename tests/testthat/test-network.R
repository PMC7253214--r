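test_that("signed adjacency hits its closed-form values", {
  cm <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(signedAdjacency(cm, 5)[1, 2], 1)
  cm[1, 2] <- cm[2, 1] <- -1
  expect_equal(signedAdjacency(cm, 5)[1, 2], 0)
  cm[1, 2] <- cm[2, 1] <- 0
  expect_equal(signedAdjacency(cm, 5)[1, 2], 0.03125)   # (1/2)^5
  expect_error(signedAdjacency(matrix(c(1, 2, 2, 1), 2), 5), "\\[-1, 1\\]")
  expect_error(signedAdjacency(cm, 2.5), "integer")
})

test_that("connectivity filter keeps strictly-above-center probes", {
  ## engineered soft connectivities: with beta = 1 on a hand-set matrix
  set.seed(21)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("p%02d", 1:20), paste0("s", 1:30)))
  flt <- connectivityFilter(x, beta = 5)
  ## brute-force oracle
  a <- ((1 + cor(t(x))) / 2)^5; diag(a) <- 1
  k <- colSums(a) - 1
  expect_setequal(flt$kept, names(k)[k > median(k)])
  expect_equal(flt$connectivity, k)
  ## mean switch
  fltM <- connectivityFilter(x, beta = 5, center = "mean")
  expect_setequal(fltM$kept, names(k)[k > mean(k)])
  ## all-equal connectivity: empty set with a warning
  y <- matrix(rep(rnorm(10), each = 4), 4, 10, byrow = FALSE,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  expect_warning(fltE <- connectivityFilter(y, beta = 5), "no probe")
  expect_length(fltE$kept, 0L)
})

test_that("soft-threshold diagnostics are monotone and exact at cor = 0", {
  set.seed(2)
  x <- matrix(rnorm(40 * 50), 40, 50,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:50)))
  cm <- cor(t(x))
  res <- pickSoftThreshold(cm, betas = c(1, 2, 4, 6, 8, 10))
  expect_true(all(diff(res$table$medianK) <= 1e-12))
  ## all-zero correlations: k = (n - 1) * (1/2)^beta exactly
  cz <- diag(25)
  dimnames(cz) <- list(paste0("p", 1:25), paste0("p", 1:25))
  rz <- pickSoftThreshold(cz, betas = c(2, 5))
  expect_equal(rz$table$medianK, 24 * 0.5^c(2, 5))
  expect_equal(rz$table$meanK, 24 * 0.5^c(2, 5))
  ## plateau recommendation equals a direct application of the rule
  tab <- res$table
  rel <- -diff(tab$medianK) / tab$medianK[-nrow(tab)]
  oracle <- if (any(rel < 0.05)) tab$beta[which(rel < 0.05)[1]]
    else tab$beta[nrow(tab)]
  expect_equal(res$recommended, oracle)
})

test_that("TOM matches the brute-force triple-loop oracle", {
  ## perfect clique
  a1 <- matrix(1, 3, 3)
  expect_equal(tomFromAdjacency(a1)[1, 2], 1)
  ## empty graph
  a0 <- diag(3)
  expect_true(all(tomFromAdjacency(a0)[upper.tri(a0)] == 0))
  ## random 6-node adjacencies vs the O(n^3) oracle
  for (s in 1:5) {
    a <- randomAdjacency(6, seed = s)
    expect_equal(tomFromAdjacency(a), tomOracle(a), tolerance = 1e-12)
  }
  tom <- tomFromAdjacency(randomAdjacency(10, seed = 9))
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("consensus TOM calibrates quantiles and takes the minimum", {
  t1 <- tomFromAdjacency(randomAdjacency(8, seed = 1))
  ## identical populations: consensus equals the input
  cons <- consensusTOMFromList(list(a = t1, b = t1), 0.95)
  expect_equal(cons$consensus, t1, tolerance = 1e-12)
  ## an all-zero population forces an all-zero consensus off-diagonal
  tz <- diag(8)
  dimnames(tz) <- dimnames(t1)
  consZ <- consensusTOMFromList(list(a = t1, b = tz), 0.95)
  expect_true(all(consZ$consensus[upper.tri(tz)] == 0))
  ## consensus never exceeds any calibrated input
  t2 <- tomFromAdjacency(randomAdjacency(8, seed = 2))
  consR <- consensusTOMFromList(list(a = t1, b = t2), 0.95)
  expect_true(all(consR$consensus <= consR$calibrated$a + 1e-12))
  expect_true(all(consR$consensus <= consR$calibrated$b + 1e-12))
  ## calibration: the 0.95 quantiles of the calibrated TOMs agree
  q <- sapply(consR$calibrated, function(m)
    quantile(m[lower.tri(m)], 0.95, names = FALSE))
  expect_equal(unname(q[1]), unname(q[2]), tolerance = 1e-10)
  ## probe order mismatch errors
  t3 <- t2[c(2:8, 1), c(2:8, 1)]
  expect_error(consensusTOMFromList(list(a = t1, b = t3)), "order|probe")
})

test_that("average-linkage clustering reproduces a brute-force UPGMA", {
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  hc <- averageLinkageCluster(d3)
  expect_equal(hc$height[1], 1)
  ## identical rows merge first at height 0
  d0 <- matrix(0.5, 4, 4); diag(d0) <- 0
  d0[1, 2] <- d0[2, 1] <- 0
  expect_equal(averageLinkageCluster(d0)$height[1], 0)
  ## 8-point random dissimilarity vs the O(n^3) oracle
  set.seed(5)
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_equal(sort(averageLinkageCluster(m)$height), sort(upgmaOracle(m)),
               tolerance = 1e-12)
  m[1, 2] <- NaN
  expect_error(averageLinkageCluster(m), "non-finite")
})

test_that("tree cut separates planted blocks and bins the rest", {
  ## two well-separated blocks of 60
  n <- 120
  diss <- matrix(0.9, n, n)
  diss[1:60, 1:60] <- 0.1
  diss[61:120, 61:120] <- 0.1
  diag(diss) <- 0
  dimnames(diss) <- list(paste0("o", 1:n), paste0("o", 1:n))
  dend <- averageLinkageCluster(diss)
  lab <- dynamicTreeCut(dend, diss, deepSplit = 0, minModuleSize = 50)
  expect_identical(length(unique(lab[lab > 0])), 2L)
  expect_identical(sum(lab == 0L), 0L)
  expect_identical(length(unique(lab[1:60])), 1L)
  expect_identical(length(unique(lab[61:120])), 1L)
  ## a single block below the minimum size is fully unassigned
  small <- diss[1:30, 1:30]
  dendS <- averageLinkageCluster(small)
  expect_warning(labAll0 <- dynamicTreeCut(dendS, small, 0, 50L),
                 "exceeds")
  expect_true(all(labAll0 == 0L))
})

test_that("tree cut recovers five planted modules from noisy dissimilarity", {
  set.seed(13)
  sizes <- c(80, 75, 70, 65, 60)
  truth <- rep(seq_along(sizes), sizes)
  n <- length(truth) + 60                       # plus background objects
  truth <- c(truth, rep(0, 60))
  base <- matrix(0.95, n, n)
  for (m in seq_along(sizes)) {
    idx <- which(truth == m)
    base[idx, idx] <- 0.55
  }
  noise <- matrix(runif(n * n, -0.04, 0.04), n)
  diss <- pmin(pmax(base + (noise + t(noise)) / 2, 0), 1)
  diag(diss) <- 0
  dimnames(diss) <- list(paste0("o", 1:n), paste0("o", 1:n))
  dend <- averageLinkageCluster(diss)
  lab <- dynamicTreeCut(dend, diss, deepSplit = 0, minModuleSize = 50)
  expect_gte(adjustedRand(lab[truth > 0], truth[truth > 0]), 0.9)
})

test_that("module eigengenes satisfy their defining properties", {
  set.seed(8)
  n <- 40
  prof <- rnorm(n)
  x <- rbind(p1 = 2 * prof + 5, p2 = -3 * prof + 1, p3 = rnorm(n))
  colnames(x) <- paste0("s", 1:n)
  ## two probes with identical standardized profiles
  x0 <- rbind(a = prof, b = 2 * prof + 3)
  colnames(x0) <- paste0("s", 1:n)
  eg <- moduleEigengene(x0, c("a", "b"))
  expect_equal(abs(cor(eg$me, prof)), 1, tolerance = 1e-10)
  expect_equal(sd(eg$me), 1, tolerance = 1e-10)
  expect_equal(eg$propVarExplained, 1, tolerance = 1e-10)
  ## probe and its negation: orientation keeps mean kME >= 0
  eg2 <- moduleEigengene(x, c("p1", "p2"))
  expect_gte(mean(eg2$kME), 0)
  expect_equal(eg2$propVarExplained, 1, tolerance = 1e-10)
  ## 30-probe module vs a dense SVD oracle
  set.seed(10)
  f <- rnorm(50)
  mod <- t(sapply(1:30, function(i) runif(1, 0.5, 1) * f + rnorm(50, 0, 0.4)))
  dimnames(mod) <- list(paste0("g", 1:30), paste0("s", 1:50))
  eg3 <- moduleEigengene(mod, rownames(mod))
  z <- t(scale(t(mod)))
  u <- svd(t(z))$u[, 1]
  u <- u / sd(u)
  expect_lt(min(max(abs(eg3$me - u)), max(abs(eg3$me + u))), 1e-8)
  ## degenerate input
  flat <- matrix(3, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_error(moduleEigengene(flat, c("a", "b")), "constant")
})

test_that("kME is the Pearson correlation with the eigengene", {
  set.seed(12)
  me <- matrix(rnorm(30), 1, dimnames = list("1", paste0("s", 1:30)))
  x <- rbind(same = me[1, ], neg = -me[1, ], noise = rnorm(30))
  colnames(x) <- colnames(me)
  km <- kmeMatrix(x, me)
  expect_equal(km["same", "1"], 1, tolerance = 1e-12)
  expect_equal(km["neg", "1"], -1, tolerance = 1e-12)
  expect_equal(km["noise", "1"], cor(x["noise", ], me[1, ]),
               tolerance = 1e-12)
  ## zero-variance probe gets kME 0
  x2 <- rbind(x, flat = rep(1, 30))
  expect_equal(suppressWarnings(kmeMatrix(x2, me))["flat", "1"], 0)
})

test_that("close modules merge by consensus eigengene distance", {
  set.seed(6)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k, label) {
    m <- t(sapply(seq_len(k), function(i) 0.9 * f + rnorm(n, 0, 0.3)))
    rownames(m) <- paste0(label, seq_len(k))
    m
  }
  ## modules 1 and 2 share factor f1; module 3 is independent
  xa <- rbind(mk(f1, 10, "a"), mk(f1, 10, "b"), mk(f2, 10, "c"))
  colnames(xa) <- paste0("s", 1:n)
  xb <- xa + matrix(rnorm(length(xa), 0, 0.2), nrow(xa))
  labels <- setNames(rep(1:3, each = 10), rownames(xa))
  merged <- mergeCloseModules(list(A = xa, B = xb), labels,
                              mergeHeight = 0.2)
  expect_identical(length(unique(merged)), 2L)
  expect_identical(length(unique(merged[1:20])), 1L)
  ## max rule: dissimilar in one population means no merge
  xb2 <- xb
  xb2[11:20, ] <- matrix(rnorm(10 * n), 10)   # decouple module 2 in pop B
  merged2 <- mergeCloseModules(list(A = xa, B = xb2), labels, 0.2)
  expect_identical(length(unique(merged2)), 3L)
})

test_that("module-trait correlation matches the t-distribution formula", {
  ## r = 0.5 at n = 27 gives t = 2.887 and the matching p
  set.seed(33)
  me <- matrix(rnorm(27), 1, dimnames = list("1", paste0("s", 1:27)))
  ## build a trait with exact sample correlation 0.5
  z <- scale(rnorm(27))
  zme <- scale(me[1, ])
  resid <- scale(z - drop(cor(z, zme)) * zme)
  trait <- 0.5 * zme + sqrt(1 - 0.25) * resid
  traits <- data.frame(t1 = drop(trait), row.names = colnames(me))
  mt <- moduleTraitCorrelation(me, traits)
  expect_equal(mt$r, 0.5, tolerance = 1e-10)
  expect_equal(mt$p, 2 * pt(-2.886751, df = 25), tolerance = 1e-5)
  ## identical trait: r = 1, p ~ 0
  traits2 <- data.frame(t1 = me[1, ], row.names = colnames(me))
  mt2 <- moduleTraitCorrelation(me, traits2)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
  expect_lt(mt2$p, 1e-20)
  ## constant trait: NA
  mt3 <- moduleTraitCorrelation(me, data.frame(t1 = rep(1, 27),
                                               row.names = colnames(me)))
  expect_true(is.na(mt3$r))
})

test_that("module labels are invariant to probe and sample order", {
  sim <- simulateDataset(tinySimConfig(seed = 6))
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  x <- SummarizedExperiment::assay(sim@se)
  keep <- !sim@truth$module_of_probe[rownames(x)] %in%
    c("unexpressed", "negative_control")
  x <- x[keep, ]
  fert <- lapply(c("F2", "HZ"), function(p)
    x[, cd$sample_id[cd$population == p & cd$planted_class == "fertile"]])
  names(fert) <- c("F2", "HZ")
  net1 <- buildConsensusNetwork(fert, minModuleSize = 25)
  set.seed(1)
  pi <- sample(nrow(x))
  si <- lapply(fert, function(m) m[pi, sample(ncol(m))])
  net2 <- buildConsensusNetwork(si, minModuleSize = 25)
  l1 <- moduleLabels(net1)
  l2 <- moduleLabels(net2)[names(l1)]
  expect_gte(adjustedRand(l1, l2), 0.999)
})
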