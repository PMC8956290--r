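test_that("signature scores rank expressing cells on top", {
  set.seed(40)
  X <- matrix(rpois(20 * 100, 2), 20, 100,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  X[1:3, 1] <- 30                        # cell 1 maxes the set genes
  X <- log1p(X)
  s <- signature_score(X, c("g01", "g02", "g03"))
  expect_equal(which.max(s), 1)
  expect_error(signature_score(X, c("nope1", "nope2")), "no genes")
  # rank variant agrees on the top cell
  s_rank <- signature_score(X, c("g01", "g02", "g03"), method = "rank")
  expect_equal(which.max(s_rank), 1)
})

test_that("laterality calls respect the two-sided SD rule", {
  set.seed(41)
  n <- 1000
  ipsi <- rnorm(n); contra <- rnorm(n)
  calls <- call_laterality(ipsi, contra, k_sd = 1.5)
  i_set <- which(calls$call == "I")
  expect_true(all(ipsi[i_set] > mean(ipsi) + 1.5 * sd(ipsi)))
  expect_true(all(contra[i_set] < mean(contra) - 1.5 * sd(contra)))
  # cells at both means are unassigned
  calls2 <- call_laterality(c(0, ipsi), c(0, contra))
  expect_equal(as.character(calls2$call[1]), "unassigned")
  # k = 0: every cell on the correct side of both means is called
  calls0 <- call_laterality(ipsi, contra, k_sd = 0)
  manual_i <- ipsi > mean(ipsi) & contra < mean(contra)
  expect_equal(calls0$call == "I", manual_i)
})

test_that("planted ipsilateral cells are recovered by score and call", {
  sim <- synth_small()
  truth <- sim$truth
  lat <- sim$laterality
  norm <- normalize_log(filter_cells_genes(sim$counts, 50, 5))
  keep <- match(colnames(norm$X), truth$cells$cell_id)
  early <- which(truth$cells$age[keep] <= lat$fade_age)
  si <- signature_score(norm, lat$ipsi_genes)[early]
  sc <- signature_score(norm, lat$contra_genes)[early]
  planted_i <- truth$cells$laterality[keep][early] == "I"
  # AUROC of the ipsi score against the planted label
  r <- rank(si)
  auroc <- (mean(r[planted_i]) - (sum(planted_i) + 1) / 2) /
    sum(!planted_i)
  expect_gte(auroc, 0.9)

  calls <- call_laterality(si, sc)
  called_frac <- mean(calls$call == "I")
  expect_gt(called_frac, 0.02)
  expect_lt(called_frac, 0.2)
  # called I cells are enriched for the planted label
  expect_gt(mean(planted_i[calls$call == "I"]), 0.8)
})

test_that("ipsilateral mass propagates to the planted lineage types", {
  sim <- synth_small()
  truth <- sim$truth
  lat <- sim$laterality
  ages <- truth$age_grid
  norm <- normalize_log(filter_cells_genes(sim$counts, 50, 5))
  keep <- match(colnames(norm$X), truth$cells$cell_id)
  hv <- select_hvgs(sim$counts[rownames(norm$X), colnames(norm$X)])
  Xh <- norm$X[hv$table$selected[match(rownames(norm$X), hv$table$gene)], ]
  age_vec <- truth$cells$age[keep]
  idx <- lapply(ages, function(a) which(age_vec == a))
  maps <- lapply(seq_len(length(ages) - 1), function(i)
    solve_coupling(Xh[, idx[[i]]], Xh[, idx[[i + 1]]],
                   days_gap = ages[i + 1] - ages[i]))
  # propagate from the last signature-positive age: laterality is only
  # identifiable while the planted signature is expressed
  src <- max(which(ages <= lat$fade_age))
  long <- compose_maps(maps[src:(length(ages) - 1)])
  term_types <- truth$cells$destined_type[keep][idx[[length(ages)]]]
  planted_i <- truth$cells$laterality[keep][idx[[src]]] == "I"
  prop <- propagate_ipsi(planted_i, long, term_types)
  expect_true(all(prop$i_fraction >= 0 & prop$i_fraction <= 1))
  expect_equal(sum(prop$i_mass), 1)
  # descendant mass concentrates in the planted lineage far beyond the
  # chance level (|lineage| / n_types)
  in_lineage <- prop$type %in% lat$il_types
  chance <- length(lat$il_types) / length(prop$type)
  expect_gte(sum(prop$i_mass[in_lineage]), 2 * chance)

  # no I calls at all: all fractions zero
  none <- propagate_ipsi(rep(FALSE, nrow(long$plan)), long, term_types)
  expect_true(all(none$i_fraction == 0))
})

test_that("ipsi-vs-rest DE finds planted genes early and nothing late", {
  sim <- synth_small()
  truth <- sim$truth
  lat <- sim$laterality
  norm <- normalize_log(filter_cells_genes(sim$counts, 50, 5))
  keep <- match(colnames(norm$X), truth$cells$cell_id)
  early <- truth$cells$age[keep] <= lat$fade_age
  is_i <- truth$cells$laterality[keep] == "I"
  de_early <- de_ipsi(norm$X[, early], is_i[early])
  sig_genes <- de_early$gene[de_early$significant]
  expect_true(all(lat$ipsi_genes %in% sig_genes))

  # identical groups give no significant genes
  set.seed(43)
  Xr <- log1p(matrix(rpois(30 * 200, 2), 30, 200))
  de_null <- de_ipsi(Xr, rep(c(TRUE, FALSE), 100))
  expect_equal(sum(de_null$significant), 0)
  expect_error(de_ipsi(Xr, rep(TRUE, 200)), "both")
})
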