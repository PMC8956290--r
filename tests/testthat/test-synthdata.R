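test_that("fate tree structure and determinism", {
  tree <- make_fate_tree(45, 8, seed = 5)
  expect_equal(length(tree_internal_nodes(tree)), 44)  # binary: n-1
  expect_equal(tree$n_types, 45L)
  # subclasses are clades: leaf sets of subclass roots are contiguous
  # blocks that partition the leaves
  expect_equal(sort(unique(tree$subclass)), 1:8)
  expect_equal(length(tree$subclass), 45)

  # decouple times non-decreasing from root to every leaf
  for (leaf in 1:45) {
    path <- tree_path(tree, leaf)
    tims <- tree$decouple_time[path]
    tims <- tims[!is.na(tims)]
    expect_true(all(diff(tims) >= 0))
  }

  expect_identical(make_fate_tree(12, 4, seed = 3),
                   make_fate_tree(12, 4, seed = 3))
  expect_error(make_fate_tree(5, 9), "n_subclasses")
})

test_that("minimal two-type tree decouples at the first age", {
  tree <- make_fate_tree(2, 1, age_grid = c(0, 1, 2), seed = 1)
  expect_equal(tree$decouple_time[tree$root], 0)
  truth <- simulate_fates(tree, 50, seed = 1)
  term <- truth$cells$age == 2
  expect_true(all(truth$potential[term] == 1))
})

test_that("planted fate vectors are normalized and terminal point masses", {
  sim <- synth_small()
  truth <- sim$truth
  expect_lt(max(abs(rowSums(truth$fates) - 1)), 1e-12)
  term <- truth$cells$age == max(truth$age_grid)
  expect_true(all(apply(truth$fates[term, ], 1, max) == 1))
  expect_true(all(truth$potential[term] == 1))
})

test_that("zero sharpness keeps pre-terminal fates uniform", {
  tree <- make_fate_tree(8, 2, seed = 2)
  truth <- simulate_fates(tree, 40, sharpness = 0, seed = 2)
  pre <- truth$cells$age < max(truth$age_grid)
  expect_lt(max(abs(truth$fates[pre, ] - 1 / 8)), 1e-12)
  expect_lt(max(abs(truth$potential[pre] - 8)), 1e-9)
})

test_that("mean planted potential decreases with age across replicates", {
  # expectation over >= 10 seeds; each seed's trajectory averaged
  prof <- sapply(1:10, function(s) {
    tree <- make_fate_tree(10, 3, seed = s)
    truth <- simulate_fates(tree, 60, seed = s + 100)
    tapply(truth$potential, truth$cells$age, mean)
  })
  mean_prof <- rowMeans(prof)
  expect_true(all(diff(mean_prof) < 0))
})

test_that("sibling pairs decoupling late stay fate-correlated longer", {
  tree <- make_fate_tree(12, 4, seed = 6)
  truth <- simulate_fates(tree, 400, seed = 7)
  pd <- type_decouple_times(tree)
  late_pair <- order(pd, decreasing = TRUE)[1:2]
  early_pair <- order(pd)[1:2]
  mid_age <- truth$age_grid[3]
  sel <- truth$cells$age == mid_age
  c_late <- cor(truth$fates[sel, late_pair[1]], truth$fates[sel, late_pair[2]])
  c_early <- cor(truth$fates[sel, early_pair[1]],
                 truth$fates[sel, early_pair[2]])
  expect_gt(c_late, c_early)
})

test_that("library-size shape is recoverable from simulated counts", {
  tree <- make_fate_tree(4, 2, seed = 1)
  truth <- simulate_fates(tree, c(0, 0, 0, 0, 0, 600), seed = 1)
  sim <- simulate_counts(truth, n_genes = 300, programs_per_type = 10,
                         libsize_shape = 25, seed = 1)
  hv <- select_hvgs(sim$counts)
  expect_lt(abs(hv$alpha - 25) / 25, 0.10)
})

test_that("HVG selection on one-type data recovers program genes only", {
  tree <- make_fate_tree(2, 1, seed = 3)
  # only terminal-age cells of a single type, no batch effects
  truth <- simulate_fates(tree, c(0, 0, 0, 0, 0, 800), seed = 3)
  one_type <- truth$cells$destined_type == 1
  truth$cells <- truth$cells[one_type, ]
  truth$fates <- truth$fates[one_type, , drop = FALSE]
  truth$potential <- truth$potential[one_type]
  sim <- simulate_counts(truth, n_genes = 300, programs_per_type = 10,
                         batch_effect_sd = 0, seed = 3)
  hv <- select_hvgs(sim$counts)
  sel_genes <- hv$table$gene[hv$table$selected]
  active <- rownames(sim$counts)[c(sim$program_genes$type[[1]],
                                   sim$program_genes$maturation[[6]])]
  # program genes dominate the selection; stray selections stay within
  # the null leakage rate of the mean + 0.8 sd rule
  expect_gt(length(sel_genes), 0)
  expect_gt(mean(active %in% sel_genes), 0.9)
  expect_lt(sum(!(sel_genes %in% active)), 0.05 * nrow(sim$counts))
})

test_that("count simulation is reproducible and writes byte-identical MTX", {
  tree <- make_fate_tree(4, 2, seed = 9)
  truth <- simulate_fates(tree, 30, seed = 9)
  s1 <- simulate_counts(truth, n_genes = 250, programs_per_type = 8,
                        seed = 11)
  s2 <- simulate_counts(truth, n_genes = 250, programs_per_type = 8,
                        seed = 11)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  d1 <- file.path(tempdir(), "mtx_a"); d2 <- file.path(tempdir(), "mtx_b")
  s1$truth <- truth; s2$truth <- truth
  write_synthdata(s1, d1); write_synthdata(s2, d2)
  expect_identical(readLines(file.path(d1, "matrix.mtx")),
                   readLines(file.path(d2, "matrix.mtx")))
})

test_that("generator rejects invalid configurations", {
  tree <- make_fate_tree(6, 2, seed = 1)
  truth <- simulate_fates(tree, 20, seed = 1)
  expect_error(simulate_counts(truth, n_genes = 50,
                               programs_per_type = 10), "smaller")
})

test_that("planted laterality labels and signals behave as configured", {
  sim <- synth_small()
  truth <- sim$truth
  lat <- sim$laterality
  early <- truth$cells$age <= lat$fade_age
  frac_i <- mean(truth$cells$laterality[early] == "I")
  expect_gt(frac_i, 0.02)
  expect_lt(frac_i, 0.2)
  # I cells are destined to the planted ipsilateral lineage
  i_cells <- truth$cells$laterality == "I"
  expect_true(all(truth$cells$destined_type[i_cells] %in% lat$il_types))

  norm <- normalize_log(filter_cells_genes(sim$counts, 50, 5))
  keep <- match(colnames(norm$X), truth$cells$cell_id)
  early_n <- truth$cells$age[keep] <= lat$fade_age
  si <- signature_score(norm, lat$ipsi_genes)
  sc <- signature_score(norm, lat$contra_genes)
  # mutually exclusive expression: scores anticorrelated among early cells
  expect_lt(cor(si[early_n], sc[early_n]), 0)

  # signature fades: no significant laterality DE at the last age
  last <- truth$cells$age[keep] == max(truth$age_grid)
  is_i_last <- truth$cells$laterality[keep][last] == "I"
  # propagate planted I lineage to last age via destined types
  is_lineage <- truth$cells$destined_type[keep][last] %in% lat$il_types
  de <- de_ipsi(norm$X[, last], is_lineage)
  sig <- de$significant &
    de$gene %in% c(lat$ipsi_genes, lat$contra_genes)
  expect_equal(sum(sig), 0)

  expect_error(plant_laterality(truth, sim, 0.1, lat$ipsi_genes,
                                lat$ipsi_genes, fade_age = 1),
               "disjoint")
})
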