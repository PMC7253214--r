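test_that("half background correction follows max(F - B, 0.5) + offset", {
  F <- matrix(c(100, 60, 55), 1, dimnames = list("p", c("a", "b", "c")))
  B <- matrix(c(60, 60, 60), 1, dimnames = list("p", c("a", "b", "c")))
  out <- backgroundCorrectHalf(F, B, offset = 50)
  expect_equal(unname(out[1, ]), c(90, 50.5, 50.5))
  ## floor property: everything >= 0.5 + offset
  set.seed(1)
  F2 <- matrix(runif(200, 0, 100), 20)
  B2 <- matrix(runif(200, 0, 100), 20)
  expect_true(all(backgroundCorrectHalf(F2, B2, 50) >= 50.5))
  expect_error(backgroundCorrectHalf(F2, B2[1:10, ]), "shape")
})

test_that("expression filter reproduces the negative-control rule exactly", {
  ## 10 probes x 5 arrays; brute-force enumeration of the rule
  set.seed(42)
  vals <- matrix(runif(50, 40, 120), 10, 5,
                 dimnames = list(sprintf("p%02d", 1:10), paste0("a", 1:5)))
  nc <- matrix(runif(20, 40, 60), 4, 5,
               dimnames = list(paste0("nc", 1:4), paste0("a", 1:5)))
  m <- rbind(vals, nc)
  pd <- data.frame(probe_id = rownames(m),
                   gene_id = c(sprintf("g%02d", 1:10), rep("", 4)),
                   is_negative_control = rep(c(FALSE, TRUE), c(10, 4)))
  se <- makeCoexExperiment(m, pd, scaleTag = "background_corrected")
  flt <- filterExpressed(se, 0.98, 1.10, 0.10)
  ## oracle: per array threshold and the keep rule, written out longhand
  thr <- sapply(1:5, function(a) 1.10 * quantile(nc[, a], 0.98))
  needed <- ceiling(0.10 * 5)              # = 1 array
  keepOracle <- sapply(1:10, function(i) sum(vals[i, ] >= thr) >= needed)
  expect_setequal(flt$kept, rownames(vals)[keepOracle])
  expect_equal(unname(flt$thresholds), unname(thr))
  ## negative controls are never kept
  expect_false(any(grepl("^nc", flt$kept)))
  ## boundary: detected on exactly one of five arrays -> kept
  one <- m
  one["p01", ] <- c(max(thr) + 1, rep(0, 4))
  seOne <- makeCoexExperiment(one, pd, scaleTag = "background_corrected")
  expect_true("p01" %in% filterExpressed(seOne)$kept)
  ## below threshold everywhere -> dropped
  none <- m
  none["p02", ] <- 0
  seNone <- makeCoexExperiment(none, pd, scaleTag = "background_corrected")
  expect_false("p02" %in% filterExpressed(seNone)$kept)
  ## no negative controls is a precondition error
  seNc <- makeCoexExperiment(vals, pd[1:10, ],
                             scaleTag = "background_corrected")
  expect_error(filterExpressed(seNc), "negative-control")
})

test_that("quantile normalization equalizes sorted vectors to their mean", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  rownames(m) <- paste0("p", 1:3)
  out <- quantileNormalize(m)
  expect_equal(unname(out[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "b"]), c(1.5, 3, 4.5))
  ## identical arrays are a fixed point
  m2 <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantileNormalize(m2), m2)
  ## idempotence and the defining property on random input
  set.seed(7)
  m3 <- matrix(rexp(60), 12, 5)
  q1 <- quantileNormalize(m3)
  expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)
  sorted <- apply(q1, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
})

test_that("log2 transform validates positivity and reports coordinates", {
  m <- matrix(c(8, 1, 2), 3, 1, dimnames = list(c("x", "y", "z"), "s"))
  expect_equal(unname(log2Transform(m)[, 1]), c(3, 0, 1))
  m[2, 1] <- 0
  expect_error(log2Transform(m), "row 2")
})

test_that("empirical-Bayes batch adjustment honors its contracts", {
  set.seed(3)
  x <- matrix(rnorm(50 * 400, 8), 50, 400,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:400)))
  ## single batch: identity
  out1 <- ebBatchAdjust(x[, 1:20], rep("b1", 20))
  expect_equal(out1, x[, 1:20], tolerance = 1e-8)
  ## a pure additive shift between two batches of 200 samples is removed
  batch <- rep(c("b1", "b2"), each = 200)
  shifted <- x
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 2
  adj <- ebBatchAdjust(shifted, batch)
  gap <- rowMeans(adj[, batch == "b2"]) - rowMeans(adj[, batch == "b1"])
  expect_lt(mean(abs(gap)), 0.05 * 2)
  ## batches of one sample are a precondition error
  expect_error(ebBatchAdjust(x[, 1:20], c(rep("b1", 19), "b2")),
               ">= 2 samples")
  ## zero-variance gene passes through with a warning
  xc <- x; xc[1, ] <- 5
  expect_warning(adj2 <- ebBatchAdjust(xc, batch), "zero-variance")
  expect_equal(unname(adj2[1, ]), rep(5, 400))
})

test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(9)
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  res <- pcaSamples(m)
  ## oracle: eigendecomposition of the covariance of the scaled variables
  z <- scale(t(m))
  ev <- eigen(cov(z))
  expect_equal(res$explained[1:2], ev$values[1:2] / sum(ev$values),
               tolerance = 1e-8)
  sc <- z %*% ev$vectors
  for (k in 1:2)
    expect_lt(min(max(abs(res$scores[, k] - sc[, k])),
                  max(abs(res$scores[, k] + sc[, k]))), 1e-8)
  expect_equal(sum(res$explained), 1, tolerance = 1e-9)
  expect_true(all(diff(res$explained) < 1e-12))
  ## rank-1 input: PC1 explains everything
  r1 <- outer(c(1, 2, 3, 4), c(1, -1, 2))
  dimnames(r1) <- dimnames(m)
  resR1 <- pcaSamples(r1)
  expect_equal(resR1$explained[1], 1, tolerance = 1e-9)
  expect_error(pcaSamples(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("outlier flagging applies the PC-space MAD rule", {
  set.seed(4)
  scores <- cbind(PC1 = rnorm(30), PC2 = rnorm(30))
  rownames(scores) <- paste0("s", 1:30)
  pca <- structure(list(scores = scores, loadings = NULL,
                        explained = c(0.6, 0.4)), class = "PCAResult")
  expect_length(flagOutlierSamples(pca, kMad = 6), 0L)
  scores2 <- scores
  scores2["s1", "PC1"] <- median(scores[, 1]) + 10 * mad(scores[, 1])
  pca2 <- structure(list(scores = scores2, explained = c(0.6, 0.4)),
                    class = "PCAResult")
  expect_identical(flagOutlierSamples(pca2, kMad = 6), "s1")
  expect_length(flagOutlierSamples(pca2, kMad = Inf), 0L)
  ## all-identical scores: MAD is zero, nothing flagged
  same <- structure(list(scores = matrix(1, 10, 2,
                                         dimnames = list(paste0("s", 1:10),
                                                         NULL)),
                         explained = c(1, 0)), class = "PCAResult")
  expect_length(flagOutlierSamples(same), 0L)
})
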