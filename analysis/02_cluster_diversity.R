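#!/usr/bin/env Rscript
# Per-age clustering and diversity. Reads the simulated course from
# results/data, runs filtering, median normalization, Gamma-Poisson HVG
# selection, RMT-guided embedding + Louvain clustering with DE-based
# refinement at each age, and quantifies diversity (Rao/Shannon/Simpson)
# and cluster distinctiveness (classifier error, relative diameter).
#
# Expected pattern (mirrors the real retina course): cluster number and
# all diversity indices increase with age while classifier error and
# relative diameter decrease — precursors become more, and more
# discrete, types.

library(fatecourse)

seed <- as.integer(Sys.getenv("FATECOURSE_SEED", "1"))
dat <- read_tenx("results/data")
cfg <- default_config(seed = seed)

run <- run_timecourse(list(counts = dat$counts, cells = dat$cells),
                      cfg, partition_source = "cluster",
                      min_genes_per_cell = 50, min_cells_per_gene = 5,
                      stages = "cluster")
dir.create("results", showWarnings = FALSE)
write_run(run, "results/cluster")

counts <- vapply(run$partitions, function(p) p$n_clusters, integer(1))
cat("clusters per age:", counts, "\n")
div <- do.call(rbind, lapply(run$diversity, function(d)
  data.frame(age = d$age, rao = d$rao, shannon = d$shannon,
             simpson = d$simpson, err = d$classifier_error,
             rel_diam = d$relative_diameter)))
print(round(div, 3))

truth <- read.delim("results/data/cells.tsv")
planted <- tapply(truth$true_state[match(colnames(run$X$X),
                                         truth$cell_id)],
                  run$cells$age, function(s) length(unique(s)))
cat("planted effective states:", planted, "\n")
cat("recovered / planted ratio:", round(counts / planted, 2), "\n")
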