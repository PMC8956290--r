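test_that("trivial couplings conserve mass", {
  # one source cell, one target cell
  tm <- solve_coupling(matrix(1:3), matrix(1:3), eps = 0.1,
                       lam1 = Inf, lam2 = Inf)
  expect_equal(unname(tm$plan), matrix(1), tolerance = 1e-8)
  expect_true(tm$converged)
})

test_that("entropic cost approaches the exact optimum at small eps", {
  # balanced problems with uniform marginals: the linear-program optimum
  # is the best permutation assignment (Birkhoff-von Neumann)
  set.seed(10)
  for (n in 3:6) {
    X_i <- matrix(rnorm(2 * n), nrow = 2)
    X_j <- matrix(rnorm(2 * n), nrow = 2)
    tm <- solve_coupling(X_i, X_j, eps = 5e-4, lam1 = Inf, lam2 = Inf,
                         normalize_cost = FALSE, max_iter = 20000)
    C <- as.matrix(dist(rbind(t(X_i), t(X_j))))[1:n, n + 1:n]^2
    lp <- lp_transport_cost_uniform(C)
    ent_cost <- sum(tm$plan * C)
    expect_lt(ent_cost, lp * 1.01 + 1e-12)
    # the converged plan meets the marginals only to solver tolerance,
    # so its cost can undercut the exact optimum by that same margin
    expect_gt(ent_cost, lp * (1 - 1e-3))
  }
})

test_that("large-eps balanced limit is the product of marginals", {
  set.seed(11)
  X_i <- matrix(rnorm(3 * 5), nrow = 3)
  X_j <- matrix(rnorm(3 * 7), nrow = 3)
  tm <- solve_coupling(X_i, X_j, eps = 1e3, lam1 = Inf, lam2 = Inf,
                       normalize_cost = TRUE)
  outer_ab <- outer(tm$a, tm$b)
  expect_lt(max(abs(tm$plan - outer_ab)), 1e-3)
})

test_that("balanced marginals match targets and respect permutations", {
  set.seed(12)
  X_i <- matrix(rnorm(4 * 8), nrow = 4)
  X_j <- matrix(rnorm(4 * 6), nrow = 4)
  g <- runif(8, 0.5, 2)
  tm <- solve_coupling(X_i, X_j, eps = 0.05, lam1 = Inf, lam2 = Inf,
                       g = g, days_gap = 2)
  expect_lt(max(abs(rowSums(tm$plan) - tm$a)), 1e-6)
  expect_lt(max(abs(colSums(tm$plan) - tm$b)), 1e-6)
  expect_equal(tm$a, g^2 / sum(g^2))
  # permuting source cells permutes the plan rows identically
  p <- sample(8)
  tm_p <- solve_coupling(X_i[, p], X_j, eps = 0.05, lam1 = Inf,
                         lam2 = Inf, g = g[p], days_gap = 2)
  expect_equal(tm_p$plan, tm$plan[p, ], tolerance = 1e-7)
})

test_that("unbalanced relaxation loosens marginals but keeps mass near 1", {
  set.seed(13)
  X_i <- matrix(rnorm(4 * 10), nrow = 4)
  X_j <- matrix(rnorm(4 * 10), nrow = 4)
  tm <- solve_coupling(X_i, X_j, eps = 0.05, lam1 = 1, lam2 = 50)
  expect_true(all(tm$plan >= 0))
  expect_gt(sum(tm$plan), 0.5)
  expect_lt(sum(tm$plan), 2)
  expect_true(tm$converged)
})

test_that("growth estimation modes behave as specified", {
  set.seed(14)
  X <- matrix(rnorm(5 * 20), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  # default mode: unit growth, so the rescaled source marginal is uniform
  g0 <- estimate_growth(X, growth_iters = 0)
  expect_equal(unname(g0[1:20]), rep(1, 20), ignore_attr = TRUE)
  tm <- solve_coupling(X, X, g = as.numeric(g0), lam1 = Inf, lam2 = Inf,
                       eps = 0.1)
  expect_equal(tm$a, rep(1 / 20, 20))

  # zero iterations return the marker initialization unchanged
  gi <- estimate_growth(X, proliferation_markers = c("g1", "g2"),
                        growth_iters = 0)
  expect_equal(length(attr(gi, "history")), 1)

  # a planted expanding subpopulation attracts more outgoing mass
  set.seed(15)
  src <- cbind(matrix(rnorm(6 * 30, 0), 6, 30),
               matrix(rnorm(6 * 30, 5), 6, 30))
  tgt <- cbind(matrix(rnorm(6 * 20, 0), 6, 20),
               matrix(rnorm(6 * 60, 5), 6, 60))   # second group tripled
  g3 <- estimate_growth(src, tgt, growth_iters = 3, eps = 0.05)
  expect_gt(mean(g3[31:60]), mean(g3[1:30]))
})

test_that("map composition is associative and handles permutations", {
  set.seed(16)
  P1 <- matrix(runif(12), 3, 4)
  P2 <- matrix(runif(20), 4, 5)
  P3 <- matrix(runif(15), 5, 3)
  left <- compose_maps(list(compose_maps(list(P1, P2)), P3))
  right <- compose_maps(list(P1, compose_maps(list(P2, P3))))
  expect_lt(max(abs(left$plan - right$plan)), 1e-10)

  perm <- diag(4)[, c(2, 1, 4, 3)]
  expect_equal(compose_maps(list(P1, perm))$plan, P1[, c(2, 1, 4, 3)])

  # two uniform maps compose to a uniform product: 4 * (1/12) * (1/20)
  u1 <- matrix(1 / 12, 3, 4); u2 <- matrix(1 / 20, 4, 5)
  expect_equal(compose_maps(list(u1, u2))$plan, matrix(1 / 60, 3, 5),
               tolerance = 1e-12)
  expect_error(compose_maps(list(P1, P3)), "not composable")
})

test_that("fate vectors sum cluster mass and normalize per cell", {
  Pi <- matrix(c(0.1, 0.2, 0.3,
                 0.4, 0.0, 0.0), nrow = 2, byrow = TRUE)
  cl <- c(1, 1, 2)
  f <- fate_vectors(Pi, cl)
  # hand arithmetic: row 1 -> (0.3, 0.3)/0.6; row 2 -> (0.4, 0)/0.4
  expect_equal(unclass(f), matrix(c(0.5, 1, 0.5, 0), 2, 2),
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(unclass(f)) - 1)), 1e-9)

  # single terminal cluster: every fate is 1
  f1 <- fate_vectors(Pi, c(1, 1, 1))
  expect_true(all(unclass(f1) == 1))

  # zero-mass row gets a uniform fallback with a warning
  Pi0 <- rbind(Pi, 0)
  expect_warning(f0 <- fate_vectors(Pi0, cl), "zero transported mass")
  expect_equal(unclass(f0)[3, ], c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("ancestor and descendant distributions normalize correctly", {
  Pi <- diag(3)
  anc <- ancestors_descendants(Pi, 2, "ancestors")
  expect_equal(anc, c(0, 1, 0))
  set.seed(17)
  P <- matrix(runif(20), 4, 5)
  expect_equal(sum(ancestors_descendants(P, c(1, 3), "ancestors")), 1)
  expect_equal(sum(ancestors_descendants(P, c(2, 4), "descendants")), 1)
})

test_that("potential is the inverse participation ratio", {
  expect_equal(potential(c(1, rep(0, 44))), 1)
  expect_equal(potential(rep(1 / 45, 45)), 45)
  expect_equal(potential(c(0.5, 0.5)), 2)
  F <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(potential(F), c(1, 2))
})
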