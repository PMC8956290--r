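#!/usr/bin/env Rscript
# Laterality analysis. Scores every early cell for the planted
# ipsilateral and contralateral signatures, calls putative I-/C-cells by
# the two-sided 1.5-SD rule, pushes the I-cells' mass through the
# composed transport maps to the terminal age to estimate per-type
# ipsilateral fractions, and contrasts I-cells against the rest per age
# (fold change > 1.5, Bonferroni p < 5e-5).

library(fatecourse)

seed <- as.integer(Sys.getenv("FATECOURSE_SEED", "1"))
dat <- read_tenx("results/data")
cfg <- default_config(seed = seed)
sets <- read_gmt("results/data/cell_sets.gmt")

run <- run_timecourse(list(counts = dat$counts, cells = dat$cells),
                      cfg, partition_source = "truth",
                      min_genes_per_cell = 50, min_cells_per_gene = 5,
                      stages = "transport")
dir.create("results/laterality", showWarnings = FALSE, recursive = TRUE)

cells <- read.delim("results/data/cells.tsv")
cells <- cells[match(colnames(run$X$X), cells$cell_id), ]

# planted signature gene sets are recorded next to the simulated data
lat_meta <- read.delim("results/data/laterality_genes.tsv")
ipsi <- lat_meta$gene[lat_meta$set == "ipsi"]
contra <- lat_meta$gene[lat_meta$set == "contra"]

early <- run$cells$age <= max(run$ages[run$ages <= 3])
si <- signature_score(run$X, ipsi)
sc <- signature_score(run$X, contra)
calls <- call_laterality(si[early], sc[early], k_sd = cfg$k_sd)
print(calls)
cat("score correlation among early cells:",
    round(cor(si[early], sc[early]), 3), "(anticorrelated)\n")

# propagate called I-cells to terminal types, starting at the last
# signature-positive age (laterality is only identifiable while the
# signature is expressed)
src <- max(which(run$ages <= 3))
sel_src <- which(run$cells$age == run$ages[src])
calls_src <- call_laterality(si[sel_src], sc[sel_src], k_sd = cfg$k_sd)
long <- compose_maps(run$maps[src:length(run$maps)])
term_sel <- run$cells$age == run$ages[length(run$ages)]
term_types <- cells$destined_type[term_sel]
prop <- propagate_ipsi(calls_src, long, term_types)
write.table(prop, "results/laterality/ipsi_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(prop, digits = 3)
planted_lineage <- sort(unique(cells$destined_type[cells$laterality == "I"]))
cat("planted I-lineage types:", planted_lineage, "| I-mass they carry:",
    round(sum(prop$i_mass[prop$type %in% planted_lineage]), 3), "\n")

# per-age I-vs-rest differential expression
for (a in run$ages[-length(run$ages)]) {
  sel <- run$cells$age == a
  is_i <- cells$laterality[sel] == "I"
  if (sum(is_i) < 3) next
  de <- de_ipsi(run$X$X[, sel], is_i, fc_thresh = cfg$fc_thresh,
                p_thresh = cfg$bonf_thresh)
  cat("day", a, ":", sum(de$significant), "significant laterality genes\n")
}
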