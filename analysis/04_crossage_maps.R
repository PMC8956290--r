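#!/usr/bin/env Rscript
# Supervised cross-age correspondence. Trains boosted-tree classifiers
# on each older age and assigns the preceding age's cells to those
# clusters, then quantifies the correspondence with ARI, NCE and
# per-label occupancy fractions.
#
# Expected pattern: early mappings are diffuse (high NCE, low ARI)
# because early clusters do not prefigure later identities; consecutive
# mappings sharpen with age as types become specified.

library(fatecourse)

seed <- as.integer(Sys.getenv("FATECOURSE_SEED", "1"))
dat <- read_tenx("results/data")
cfg <- default_config(seed = seed)

run <- run_timecourse(list(counts = dat$counts, cells = dat$cells),
                      cfg, partition_source = "truth",
                      min_genes_per_cell = 50, min_cells_per_gene = 5,
                      stages = "xmap")
dir.create("results/xmap", showWarnings = FALSE, recursive = TRUE)

summary <- do.call(rbind, lapply(names(run$xmap), function(nm) {
  ct <- run$xmap[[nm]]
  if (!inherits(ct, "confusion_table"))
    return(data.frame(pair = nm, ari = NA, nce = NA, mean_of = NA))
  write.table(ct$N, file.path("results/xmap",
                              paste0("confusion_",
                                     gsub("[^0-9A-Za-z]+", "_", nm),
                                     ".tsv")),
              sep = "\t", quote = FALSE)
  ofs <- vapply(seq_len(nrow(ct$N))[ct$a > 0],
                function(i) occupancy_fraction(ct, i), numeric(1))
  data.frame(pair = nm, ari = ari(ct),
             nce = if (ncol(ct$N) > 1) nce(ct) else NA,
             mean_of = mean(ofs))
}))
write.table(summary, "results/xmap/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary, digits = 3)
cat("NCE trend (first vs last mapping):", round(summary$nce[1], 3),
    "->", round(summary$nce[nrow(summary)], 3), "\n")
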