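# fatecourse

Analysis workflow for asking how postmitotic neuronal precursors — modeled
on mouse retinal ganglion cells, whose adult repertoire comprises ~45
transcriptomic types — diversify into discrete types across a
developmental time course of single-cell RNA-seq (five immature ages plus
an adult reference, days 0/1/3/6/11/20). The package implements the full
computational chain for that question and ships a synthetic-data
generator with planted ground truth so every estimator can be validated.

The core quantities:

- **Fate vector** `f(β; u, t)`: for each cell `u` at age `t`, the
  probability that it is a precursor of terminal type `β`, obtained by
  composing entropic unbalanced optimal-transport couplings between
  consecutive ages (`Π = argmin ⟨c,Π⟩ − εH(Π) + λ₁KL(Π1‖Q̂) +
  λ₂KL(Πᵀ1‖P̂)`, squared-Euclidean cost on shared highly variable genes,
  growth-rescaled source marginal), summing over each terminal cluster
  and normalizing per cell.
- **Potential** `P(u;t) = 1/Σ_β f_β²`: inverse participation ratio,
  ranging from 1 (committed) to the type count (uninformative); its mean
  declining with age is the signature of progressive fate restriction.
- **Fate coupling** `C(α,β;t)`: Pearson correlation of two types' fate
  probabilities across cells, calibrated by a within-cell randomization
  null; decays logistically (`C = 1/(1+e^{β₀+β₁t})`) as types decouple.
- **Specification time** `τ_sp(β)`: earliest modeled age at which type
  β's precursors localize in cluster space, i.e. the fitted localization
  `1 − (1/Σ_k p_k²)/N(t)` crosses `0.95(1 − 1/N(t))`.
- **Cluster correspondence**: cross-age supervised classification
  (gradient-boosted trees, shared-feature retraining) summarized by the
  adjusted Rand index, normalized conditional entropy, and occupancy
  fractions.
- **Laterality**: ipsilateral/contralateral signature scores, two-sided
  1.5-SD calls, descendant propagation through the transport maps, and
  I-vs-rest differential expression.

## Worked example

```r
library(fatecourse)

# a synthetic 6-age course: 12 terminal types in 4 subclasses, planted
# decoupling schedule, Gamma-Poisson counts, batch structure
sim <- synth_timecourse(n_types = 12, n_subclasses = 4,
                        n_cells_per_age = 250, seed = 3)
print(sim$truth)
#> ground_truth: 1750 cells, 12 types, ages 0/1/3/6/11/20
#> planted states per age: 3 6 12 15 15 12

run <- run_timecourse(sim, default_config(seed = 3),
                      partition_source = "truth",
                      min_genes_per_cell = 50,
                      stages = c("transport", "fates"))

round(sapply(run$potentials, mean), 2)
#>    0    1    3    6   11
#> 5.32 3.69 2.38 1.62 1.25
```

The mean inferred potential falls monotonically from 5.3 (a day-0 cell
is effectively choosing among ~5 of the 12 fates) to 1.25 just before
the terminal age — progressive restriction, recovered from counts alone.
The inferred specification times rank-correlate with the planted
decoupling schedule (`cor(run$specification$tau_sp,
type_decouple_times(sim$truth$tree), method = "spearman")` gave 0.81 for
this course), and within-subclass fate couplings exceed between-subclass
couplings at early ages
(`subclass_coupling_test(run$couplings[[2]], sim$truth$tree$subclass)`,
two-sided t-test p = 5.1e-06).

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes the course to `results/data/`,
`02_cluster_diversity.R` clusters each age and quantifies diversity,
`03_transport_fates.R` runs the transport chain and fate statistics,
`04_crossage_maps.R` the supervised correspondence, `05_laterality.R`
the laterality analysis. Each reads the previous script's outputs from
`results/`.

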