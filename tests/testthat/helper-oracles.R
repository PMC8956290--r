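# Independent oracles and small data builders used across tests.

# all permutations of 1..n (recursive enumeration; n <= 7)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# exact balanced OT cost with uniform marginals: by Birkhoff-von Neumann
# the optimum over doubly stochastic matrices is attained at a
# permutation matrix, so brute-force over all n! assignments
lp_transport_cost_uniform <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  best <- Inf
  for (p in all_perms(n)) {
    cost <- sum(C[cbind(seq_len(n), p)]) / n
    if (cost < best) best <- cost
  }
  best
}

# independent conditional-entropy computation from raw counts
oracle_nce <- function(N) {
  q <- N / sum(N)
  qi <- rowSums(q); qj <- colSums(q)
  ce <- 0
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q)))
    if (q[i, j] > 0) ce <- ce - q[i, j] * log(q[i, j] / qi[i])
  ce / (-sum(qj[qj > 0] * log(qj[qj > 0])))
}

# labels from a contingency table (for cross-checking ARI against an
# independent implementation working on label vectors)
table_to_labels <- function(N) {
  ref <- rep(rep(seq_len(nrow(N)), ncol(N)), as.vector(N))
  test <- rep(rep(seq_len(ncol(N)), each = nrow(N)), as.vector(N))
  list(ref = ref, test = test)
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 200, d = 5, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d), n_per, d),
             matrix(stats::rnorm(n_per * d, mean = sep), n_per, d))
  list(X = X, labels = rep(1:2, each = n_per))
}

# small cached synthetic course shared by the heavier tests
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_timecourse(n_types = 8, n_subclasses = 4,
                                 n_cells_per_age = 150, n_genes = 450,
                                 programs_per_type = 12,
                                 laterality = TRUE, seed = 42)
    cache
  }
})

# replicate transport/fate runs on the study conditions (12 types in 4
# subclasses, 250 cells per developmental age), used by the recovery
# checks; cached across test files
acceptance_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(c(3L, 7L, 21L, 33L), function(s) {
        sim <- synth_timecourse(n_types = 12, n_subclasses = 4,
                                n_cells_per_age = 250, seed = s)
        run <- run_timecourse(sim, default_config(seed = s),
                              partition_source = "truth",
                              min_genes_per_cell = 50,
                              min_cells_per_gene = 5,
                              stages = c("transport", "fates"))
        attr(run, "sim") <- sim
        run
      })
    cache
  }
})

acceptance_run <- function() acceptance_runs()[[1]]

# one clustered pipeline run (de-novo clustering + cross-age mapping)
trend_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- synth_timecourse(n_types = 12, n_subclasses = 4,
                              n_cells_per_age = 250, seed = 5)
      cache <<- run_timecourse(sim, default_config(seed = 5),
                               partition_source = "cluster",
                               min_genes_per_cell = 50,
                               min_cells_per_gene = 5,
                               stages = c("cluster", "xmap"))
    }
    cache
  }
})
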