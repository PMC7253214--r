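# discoex

**Consensus gene-coexpression networks and their disruption in subfertile
hybrids.**

Hybrid males of the two European house-mouse subspecies (*Mus musculus
domesticus* × *M. m. musculus*) are frequently subfertile, and the
Dobzhansky–Muller model predicts that the underlying incompatibilities
disrupt *interactions* between genes rather than single genes in
isolation. Coexpression networks make those interactions measurable:
genes that are tightly co-regulated in fertile testes form modules, and a
loss of that co-regulation in subfertile animals points at the disrupted
pathways and their candidate driver genes.

`discoex` implements the full analysis chain for this design, usable by
anyone with two expression cohorts, a phenotype table and a set of
annotation files:

* **Preprocessing** — "half" background correction
  (`max(F − B, 0.5) + 50`), negative-control expression filtering (10%
  brighter than the 98th percentile of negative controls on ≥ 10% of
  arrays), log2, quantile normalization, empirical-Bayes batch adjustment
  (ComBat), PCA, MAD-rule outlier flagging.
* **Classification** — fertile / intermediate / subfertile from relative
  testis weight and sperm count against pure-subspecies reference
  statistics; subfertile samples split into SFNE / SFAE by the fertile +
  pure PC1 range.
* **Consensus network** — signed adjacency `((1 + r)/2)^β` (β = 5),
  topological overlap, quantile-calibrated consensus TOM (componentwise
  minimum across cohorts), average-linkage clustering with an adaptive
  tree cut (minimum module size 50, eigengene merge height 0.2), module
  eigengenes, kME, module–trait correlations.
* **Preservation** — the seven density/connectivity preservation
  statistics with permutation `Z_summary` (strong ≥ 10 / weak 2–10 /
  absent < 2; 500 permutations), median rank, and seven one-sided
  permutation significance tests (1000 permutations; a module is
  non-preserved when any statistic fails).
* **Differential correlation** — per-gene median log2 fold change of
  within-module |correlation| with a 100-permutation label-shuffling
  null; loss / reversal flags; per-pair Fisher-z tests.
* **Hubs and enrichment** — kME ≥ 0.85 and top-5 intramodular degree
  hubs, hypergeometric gene-set over-representation with BH correction,
  0-based half-open interval overlap, and the 10,000-draw permutation
  test of hub enrichment in candidate sterility regions.
* **Synthetic data** — a generator that plants consensus modules, batch
  effects, fertility phenotypes, an aberrant-expression axis and targeted
  module disruptions, so every stage can be scored against ground truth.

Expression data travel as `SummarizedExperiment`, genomic annotations as
`GRanges`; networks and preservation results are S4 objects with
accessors (`moduleLabels()`, `consensusTOM()`, `preservationSummary()`,
…).

## Worked example

Simulate the study-scale design (15 planted modules across two hybrid
cohorts, three modules disrupted in subfertile samples), build the
consensus network from the fertile samples, and test preservation of the
three largest detected modules in the F2 subfertile-normal-expression
group:

```r
library(discoex)

sim <- simulateDataset(simulationConfig(seed = 1))
sim
#> CoexSimulation: 3321 probes x 507 samples; 15 planted modules; 3 disrupted
#>            fertile intermediate pure subfertile
#>   F2           102           92    0        106
#>   HZ            79           41    0         55
#>   pure_dom       0            0   16          0
#>   pure_mus       0            0   16          0

cd <- as.data.frame(SummarizedExperiment::colData(sim@se))
x  <- SummarizedExperiment::assay(sim@se)
keep <- !sim@truth$module_of_probe[rownames(x)] %in%
  c("unexpressed", "negative_control")
xa <- ebBatchAdjust(x[keep, ], cd$batch)

fertile <- lapply(c("F2", "HZ"), function(p)
  xa[, cd$sample_id[cd$population == p & cd$planted_class == "fertile"]])
names(fertile) <- c("F2", "HZ")
net <- buildConsensusNetwork(fertile)
net
#> ConsensusNetwork with 3071 probes across 2 populations ( F2, HZ )
#>   soft power: 5  modules: 14  unassigned: 389
#>   module sizes: 313, 301, 274, 260, 241, 219, 197, 185, 163, 139, 125, 108, 85, 72

lab <- moduleLabels(net)
lab[!lab %in% 1:3] <- 0L
pres <- modulePreservation(
  xa[, cd$sample_id[cd$population == "F2" & cd$planted_class == "fertile"]],
  xa[, cd$sample_id[cd$population == "F2" &
                      cd$planted_expression_class == "SFNE"]],
  lab, nPermZ = 200, nPermSig = 200, seed = 1)
pres
#> PreservationReport for 3 modules
#>   module     size  Z_summary medianRank      flag allSig
#>   1           313      -4.99        3.0      none  FALSE
#>   2           301       8.30        1.8      weak  FALSE
#>   3           274      20.49        1.2    strong  FALSE
```

Reading the output: the network recovers 14 modules plus an unassigned
"bin" of 389 probes. Detected module 1 corresponds to the planted module
that is fully decoupled in subfertile samples — its `Z_summary` of −5.0
("none") says its co-regulation is absent in the SFNE group; module 2
(60% decoupled) is only weakly preserved (8.3); module 3, whose
disruption is a sign reversal of half its genes, keeps much of its
connectivity structure (`Z_summary` 20.5) — reversals are caught by the
differential-correlation stage (`geneMedianLFC()`), not by density-based
preservation.

The same chain runs from files through `runPipeline()` /
`inst/scripts/discoex` (subcommands `simulate`, `preprocess`, `classify`,
`network`, `preserve`, `diffcor`, `hubs`, `enrich`, `run-all`), writing
one TSV per result plus a run manifest; identical config + seed gives
byte-identical outputs.

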