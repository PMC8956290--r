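test_that("coupling matrix is the Pearson correlation of fate columns", {
  # 4-cell hand-worked table
  F <- cbind(c(0.6, 0.5, 0.2, 0.1),
             c(0.3, 0.3, 0.5, 0.7),
             c(0.1, 0.2, 0.3, 0.2))
  C <- coupling_matrix(F)
  expect_equal(C[1, 2], cor(F[, 1], F[, 2]))
  expect_equal(C[1, 2], -0.9506541514, tolerance = 1e-9)  # precomputed
  expect_equal(C[1, 1], 1)
  Fz <- cbind(F[, 1:2], 0.25)           # zero-variance column
  expect_true(is.na(coupling_matrix(Fz)[3, 3]))

  # identical columns couple at 1; complementary 2-type system at -1
  F2 <- cbind(runif(10), 0)
  F2 <- cbind(F2[, 1], F2[, 1], 1 - 2 * F2[, 1])
  C2 <- coupling_matrix(F2 / rowSums(F2))
  expect_equal(C2[1, 2], 1)
  F3 <- cbind(runif(10))
  F3 <- cbind(F3, 1 - F3)
  expect_equal(coupling_matrix(F3)[1, 2], -1)
})

test_that("coupling matrix is invariant under cell permutation", {
  set.seed(30)
  F <- matrix(rgamma(200 * 6, 1), 200, 6)
  F <- F / rowSums(F)
  expect_equal(unclass(coupling_matrix(F)),
               unclass(coupling_matrix(F[sample(200), ])))
})

test_that("randomization null behaves and reproduces", {
  set.seed(31)
  F <- matrix(rgamma(400 * 8, 1), 400, 8)
  F <- F / rowSums(F)
  null1 <- coupling_null(F, n_perm = 20, seed = 5)
  null2 <- coupling_null(F, n_perm = 20, seed = 5)
  expect_identical(null1$max_abs, null2$max_abs)
  expect_equal(length(null1$max_abs), 20)
  expect_error(coupling_null(F, n_perm = 0), "positive")
})

test_that("network export thresholds edges and fixes layouts", {
  C <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.3,
                0.1, 0.3, 1), 3, 3)
  net <- export_network(C, threshold = 0.2)
  expect_equal(nrow(net$edges), 2)       # 0.5 and 0.3 survive
  expect_equal(nrow(export_network(C, threshold = 0.9)$edges), 0)
  expect_equal(nrow(export_network(C, threshold = 0)$edges), 3)
  net_l <- export_network(C, threshold = 0.2, layout_seed = 1)
  expect_equal(dim(net_l$layout), c(3, 2))
  f <- tempfile(fileext = ".tsv")
  export_network(C, path = f)
  expect_true(file.exists(f))
})

test_that("logistic decay parameters are recovered from noisy series", {
  set.seed(32)
  t_grid <- c(0, 1, 3, 6, 11)
  b0 <- -2; b1 <- 0.5
  ok <- replicate(20, {
    y <- 1 / (1 + exp(b0 + b1 * t_grid)) + rnorm(5, sd = 0.01)
    fit <- fit_coupling_decay(matrix(y, 1), t_grid, min_first = -Inf,
                              seed = sample.int(1e6, 1))
    abs(fit$beta0 - b0) / abs(b0) < 0.1 & abs(fit$beta1 - b1) / b1 < 0.1
  })
  expect_gte(mean(ok), 0.9)
})

test_that("decay fitting skips, flags and anchors as configured", {
  t_grid <- c(0, 1, 3, 6, 11)
  # constant series: no decay -> degenerate flag
  fit_const <- fit_coupling_decay(matrix(0.5, 1, 5), t_grid,
                                  min_first = -Inf)
  expect_true(fit_const$degenerate[1])
  # all-zero series skipped
  fit0 <- fit_coupling_decay(matrix(0, 1, 5), t_grid, min_first = -Inf)
  expect_true(is.na(fit0$beta0[1]))
  # sub-threshold first-age coupling skipped under the default filter
  y <- 1 / (1 + exp(-2 + 0.5 * t_grid))
  fit_low <- fit_coupling_decay(matrix(0.1 * y / max(y), 1, 5), t_grid)
  expect_true(is.na(fit_low$beta0[1]))
  # list-of-matrices input fits each retained pair
  set.seed(33)
  Cs <- lapply(seq_along(t_grid), function(i) {
    v <- 0.8 * exp(-0.3 * t_grid[i])
    M <- matrix(v, 3, 3); diag(M) <- 1; M
  })
  fits <- fit_coupling_decay(Cs, t_grid)
  expect_equal(nrow(fits), 3)
  expect_true(all(is.finite(fits$beta1)))
})

test_that("localization follows its closed forms", {
  F10 <- matrix(0, 30, 2); F10[, 1] <- 1   # every cell a type-1 precursor
  cl10 <- rep(1:10, 3)
  # all precursors inside one of 10 clusters -> 1 - 1/10
  part10 <- c(rep(5, 21), 1:9)             # 10 clusters present, all prec
  expect_equal(localization(F10[1:21, , drop = FALSE],
                            rep(5, 21), 1), 0)  # single cluster: N = 1
  all_in_one <- rep(c(5, 1, 2, 3, 4, 6, 7, 8, 9, 10), 3)
  F_first <- matrix(0, 30, 2)
  F_first[all_in_one == 5, 1] <- 1         # precursors only in cluster 5
  F_first[all_in_one != 5, 2] <- 1
  expect_equal(localization(F_first, all_in_one, 1), 1 - 1 / 10)
  # uniform spread across 10 clusters -> 0
  expect_equal(localization(F10, cl10, 1), 0)
  # p = (0.5, 0.5) over 10 clusters -> 1 - 2/10
  F_two <- matrix(0, 30, 2)
  F_two[all_in_one %in% c(5, 7), 1] <- 1
  F_two[!all_in_one %in% c(5, 7), 2] <- 1
  expect_equal(localization(F_two, all_in_one, 1), 1 - 2 / 10)
  # type with no precursors -> NA
  expect_true(is.na(localization(F10, cl10, 2)))
})

test_that("localization stays within its bound on random inputs", {
  set.seed(34)
  for (r in 1:20) {
    n <- 100
    F <- matrix(rgamma(n * 5, 1), n, 5); F <- F / rowSums(F)
    cl <- sample(1:6, n, replace = TRUE)
    N <- length(unique(cl))
    for (b in 1:5) {
      l <- localization(F, cl, b)
      if (!is.na(l)) {
        expect_gte(l, -1e-12)
        expect_lte(l, 1 - 1 / N + 1e-12)
      }
    }
  }
})

test_that("specification time handles boundary conventions", {
  t_grid <- c(0, 1, 3, 6, 11)
  N <- c(4, 4, 5, 6, 8)
  # already above threshold at t = 0
  high <- rep(0.95, 5)
  st <- specification_time(high, N, t_grid)
  expect_equal(st$tau_sp, 0)
  expect_false(st$censored)
  # never crosses: censored at the end of the modeled interval
  low <- c(0.05, 0.1, 0.12, 0.15, 0.18)
  st2 <- specification_time(low, N, t_grid, terminal_t = 36)
  expect_true(st2$censored)
  expect_equal(st2$tau_sp, 36)
  expect_error(specification_time(c(0.1, NA, NA, NA, 0.2), N, t_grid),
               "3 usable")
})

test_that("within-subclass couplings test separates signal from null", {
  set.seed(35)
  # planted: block-correlated fates within subclasses
  n <- 400
  block <- function() {
    shared <- rgamma(n, 2)
    sapply(1:3, function(i) shared * runif(n, 0.8, 1.2) + rgamma(n, 0.3))
  }
  F <- cbind(block(), block(), block())
  F <- F / rowSums(F)
  C <- coupling_matrix(F)
  labs <- rep(1:3, each = 3)
  res <- subclass_coupling_test(C, labs)
  expect_lt(res$p_value, 0.01)
  expect_gt(median(res$within), median(res$between))

  # random labels: type-I error control near nominal
  pvals <- sapply(1:20, function(s) {
    set.seed(s + 100)
    Fr <- matrix(rgamma(n * 9, 1), n, 9); Fr <- Fr / rowSums(Fr)
    subclass_coupling_test(coupling_matrix(Fr),
                           sample(rep(1:3, each = 3)))$p_value
  })
  expect_gte(mean(pvals > 0.01), 0.8)
  expect_error(subclass_coupling_test(C, rep(1, 9)), "two subclasses")
})
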