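test_that("RMT dimension choice is calibrated on pure noise", {
  hits <- sapply(1:8, function(s) {
    set.seed(s)
    X <- matrix(rnorm(150 * 400), 150, 400)  # genes x cells
    choose_dim_rmt(X)
  })
  expect_gte(mean(hits <= 2), 0.95)
})

test_that("RMT dimension choice counts planted factors", {
  set.seed(20)
  n <- 500; p <- 120
  base <- matrix(rnorm(p * n), p, n)
  for (k in 1:3) {
    u <- rnorm(p); v <- rnorm(n)
    base <- base + 4 * outer(u, v) / sqrt(p)
  }
  expect_equal(choose_dim_rmt(base), 3)
  # exact duplication doubles every eigenvalue, so the planted factors
  # must survive; noise eigenvalues may also clear the threshold
  expect_gte(choose_dim_rmt(rbind(base, base)), 3)
})

test_that("PCA embedding reproduces principal scores up to sign", {
  set.seed(21)
  X <- matrix(rnorm(30 * 80), 30, 80)
  emb <- embed_cells(X, k = 4, mode = "pca")
  ref <- prcomp(scale(t(X)), center = FALSE)$x[, 1:4]
  for (j in 1:4)
    expect_gt(abs(cor(emb$H[, j], ref[, j])), 0.999)
})

test_that("iNMF loadings are nonnegative and mix planted batches", {
  set.seed(22)
  n <- 120
  # two batches that are copies up to a shift on 10% of genes
  base <- matrix(rexp(50 * n), 50, n)
  base[1:10, 1:40] <- base[1:10, 1:40] + 3          # real structure
  shifted <- base
  shifted[41:45, ] <- shifted[41:45, ] + 4           # batch-specific genes
  X <- cbind(base, shifted)
  batches <- rep(1:2, each = n)
  emb <- embed_cells(X, batches, k = 4, mode = "inmf", seed = 1)
  expect_true(all(emb$H >= 0))
  # a linear classifier cannot separate the batches well after integration
  dat <- data.frame(y = batches == 2, emb$H)
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial))
  acc <- mean((fitted(fit) > 0.5) == dat$y)
  expect_lt(acc, 0.6)
})

test_that("graph clustering recovers separated blobs and is deterministic", {
  blobs <- make_blobs(n_per = 250, d = 8, sep = 10, seed = 23)
  part <- graph_cluster(blobs$X, n_neighbors = 30, seed = 1)
  expect_equal(part$n_clusters, 2)
  N <- table(blobs$labels, part$cluster)
  expect_equal(ari(unclass(N)), 1)

  part2 <- graph_cluster(blobs$X, n_neighbors = 30, seed = 1)
  expect_identical(part$cluster, part2$cluster)
  expect_error(graph_cluster(blobs$X, n_neighbors = 500), "smaller")
})

test_that("one isotropic blob is not shattered", {
  counts <- sapply(1:5, function(s) {
    set.seed(s + 40)
    X <- matrix(rnorm(300 * 6), 300, 6)
    graph_cluster(X, n_neighbors = 30, seed = s)$n_clusters
  })
  expect_true(all(counts <= 4))
})

test_that("differential expression follows the size-balanced formula", {
  set.seed(24)
  n <- 300
  X <- matrix(rpois(40 * 2 * n, 3), 40, 2 * n)
  cl <- rep(1:2, each = n)
  X[1, cl == 1] <- X[1, cl == 1] + 8       # planted up in cluster 1
  X[2, cl == 2] <- 0                        # exclusive to cluster 1
  X <- log1p(X)
  rownames(X) <- sprintf("g%02d", 1:40)
  de <- de_genes(X, cl, 1, 2)
  expect_true(de$significant[de$gene == "g01"])
  expect_equal(de$logfc[de$gene == "g02"], 10)   # capped infinity
  expect_true(de$significant[de$gene == "g02"])

  # identical clusters: duplicated cells carry no signal
  Xdup <- cbind(X[, cl == 1], X[, cl == 1])
  de0 <- de_genes(Xdup, rep(1:2, each = n), 1, 2)
  expect_equal(sum(de0$significant), 0)
})

test_that("a planted two-fold expression shift is reliably detected", {
  hits <- sapply(1:10, function(s) {
    set.seed(s + 60)
    n <- 300
    base <- rgamma(2 * n, 20, 10)
    base[1:n] <- 2 * base[1:n]             # 2-fold shift in expression
    X <- rbind(planted = base,
               matrix(rgamma(10 * 2 * n, 20, 10), 10, 2 * n))
    de <- de_genes(X, rep(1:2, each = n), 1, 2)
    de$significant[1]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("refinement merges artificial splits but keeps real types", {
  set.seed(25)
  n <- 360
  X <- matrix(rpois(60 * n, 2), 60, n)
  cl_true <- rep(1:2, each = n / 2)
  X[1:25, cl_true == 2] <- X[1:25, cl_true == 2] + 6   # 25 program genes
  X <- log1p(X)
  rownames(X) <- sprintf("g%02d", 1:60)
  # artificially split cluster 1 into two halves
  part <- new_partition(ifelse(cl_true == 2, 3, rep(1:2, n / 2)))
  ref <- refine_partition(part, X)
  expect_equal(ref$n_clusters, 2)
  merged <- table(ref$cluster, cl_true)
  expect_equal(ari(unclass(merged)), 1)
  # distinct programs survive refinement
  part2 <- new_partition(cl_true)
  ref2 <- refine_partition(part2, X)
  expect_equal(ref2$n_clusters, 2)
  # refinement never increases cluster count and is identity on one cluster
  expect_lte(ref$n_clusters, part$n_clusters)
  single <- new_partition(rep(1, n))
  expect_equal(refine_partition(single, X)$n_clusters, 1)
})

test_that("contaminant clusters are removed by marker purity", {
  set.seed(26)
  n <- 240
  X <- matrix(rpois(40 * n, 1), 40, n)
  cl <- rep(1:3, each = n / 3)
  X[1:2, cl != 3] <- X[1:2, cl != 3] + 7        # main class markers
  X[3:4, cl == 3] <- X[3:4, cl == 3] + 7        # foreign class markers
  X[25:39, cl == 3] <- X[25:39, cl == 3] + 6    # full foreign program
  X[11:22, cl == 2] <- X[11:22, cl == 2] + 5    # keeps 1 and 2 distinct
  X <- log1p(X)
  rownames(X) <- c("MarkA1", "MarkA2", "MarkB1", "MarkB2",
                   sprintf("g%02d", 5:40))
  sets <- list(main = c("MarkA1", "MarkA2"), foreign = c("MarkB1", "MarkB2"))
  part <- new_partition(cl)
  ref <- refine_partition(part, X, marker_sets = sets,
                          target_class = "main")
  expect_equal(ref$n_clusters, 2)
  expect_true(any(vapply(ref$log, function(l) l$action == "remove",
                         logical(1))))
})
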