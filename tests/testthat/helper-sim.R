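# shared fixtures and scoring helpers ---------------------------------------

# adjusted Rand index, computed from the contingency table
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sik <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (sik - expected) / ((ai + bj) / 2 - expected)
}

# map detected module labels to planted modules by best overlap
matchToPlanted <- function(labels, planted) {
  vapply(split(planted, labels), function(v)
    names(sort(table(v), decreasing = TRUE))[1L], character(1L))
}

# a small, quick two-population simulation used across tests; any
# simulationConfig argument can be overridden through ...
tinySimConfig <- function(seed = 1, ...) {
  args <- list(
    n_modules = 3, module_sizes = c(40, 35, 30),
    n_background_genes = 60, n_unexpressed_genes = 20,
    n_negative_controls = 15,
    class_sizes = list(
      F2 = c(fertile = 30, intermediate = 8, SFNE = 10, SFAE = 6),
      HZ = c(fertile = 25, intermediate = 6, SFNE = 8, SFAE = 5)),
    pure_sizes = c(pure_dom = 8, pure_mus = 8),
    phenotype_weights = list(rel_testis = c(M1 = 0.7, M2 = 0.6),
                             sperm = c(M1 = 0.6, M3 = 0.7)),
    disruption_spec = list(M1 = list(mode = "decouple",
                                     gene_fraction = 1.0)),
    seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulationConfig, args)
}

# single-population config used for preservation / diffcor calibration:
# modules embedded in a majority-background universe, batch effects to be
# removed before testing
presSimConfig <- function(seed = 1, nFertile = 100, nSFNE = 60,
                          moduleSize = 60, nBackground = 1500, ...) {
  args <- list(
    n_modules = 6, module_sizes = rep(moduleSize, 6),
    n_background_genes = nBackground, n_unexpressed_genes = 10,
    n_negative_controls = 10,
    class_sizes = list(F2 = c(fertile = nFertile, intermediate = 2,
                              SFNE = nSFNE, SFAE = 2)),
    pure_sizes = c(pure_dom = 8, pure_mus = 8), n_batches = c(F2 = 2),
    phenotype_weights = list(rel_testis = c(M1 = 0.7, M2 = 0.6),
                             sperm = c(M1 = 0.6, M3 = 0.5)),
    disruption_spec = list(M1 = list(mode = "decouple",
                                     gene_fraction = 1.0),
                           M2 = list(mode = "decouple",
                                     gene_fraction = 0.6)),
    seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulationConfig, args)
}

# batch-adjusted expressed-probe matrix plus planted labels for one sim
presMatrices <- function(sim) {
  cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
  x <- SummarizedExperiment::assay(sim@se)
  tm <- sim@truth$module_of_probe[rownames(x)]
  keep <- !tm %in% c("unexpressed", "negative_control")
  x <- suppressWarnings(ebBatchAdjust(x[keep, , drop = FALSE], cd$batch))
  tm <- tm[rownames(x)]
  labels <- setNames(integer(length(tm)), rownames(x))
  isMod <- grepl("^M", tm)
  labels[isMod] <- as.integer(sub("^M", "", tm[isMod]))
  list(x = x, samples = cd, planted = tm, labels = labels)
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
randomAdjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  a
}

# brute-force O(n^3) TOM oracle (independent of the matrix implementation)
tomOracle <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# brute-force UPGMA oracle returning successive merge heights
upgmaOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      dd <- mean(d[active[[i]], active[[j]]])
      if (dd < bestD - 1e-15) { bestD <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestD)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  heights
}

# hypergeometric upper tail by direct log-choose summation (oracle)
hyperTailOracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  x <- k:min(K, n)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}
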