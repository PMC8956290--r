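#' Construct a confusion (contingency) table object
#'
#' @param N reference x test count matrix.
#' @return object of class \code{confusion_table}: list with \code{N},
#'   row marginals \code{a}, column marginals \code{b}, total \code{n}
#'   and joint probability weights \code{q}.
#' @export
confusion_table <- function(N) {
  N <- as.matrix(N)
  if (any(N < 0)) stop("counts must be nonnegative")
  n <- sum(N)
  if (n == 0) stop("empty contingency table")
  structure(list(N = N, a = rowSums(N), b = colSums(N), n = n, q = N / n),
            class = "confusion_table")
}

.as_ct <- function(N) if (inherits(N, "confusion_table")) N else
  confusion_table(N)

#' Adjusted Rand index of a contingency table
#'
#' Pair-count form: with \eqn{a_i, b_j} the marginals and \eqn{n} the
#' total,
#' \deqn{ARI = \frac{\sum_{ij}\binom{N_{ij}}{2} -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
#'  {\frac12\left[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}\right] -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}}
#' ARI is 1 for a one-to-one correspondence and 0 in expectation under
#' random association; it is invariant to relabeling of either partition.
#'
#' @param N contingency counts (matrix or \code{confusion_table}).
#' @return scalar ARI.
#' @export
ari <- function(N) {
  ct <- .as_ct(N)
  sum_ij <- sum(choose(ct$N, 2))
  sum_a <- sum(choose(ct$a, 2))
  sum_b <- sum(choose(ct$b, 2))
  exp_idx <- sum_a * sum_b / choose(ct$n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)  # degenerate: single cluster each side
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Normalized conditional entropy of a contingency table
#'
#' Conditional entropy of the test labels given the classifier-assigned
#' reference labels, \eqn{H = -\sum_{ij} q_{ij} \log(q_{ij}/q_{i\cdot})},
#' normalized by the Shannon entropy of the test labels
#' \eqn{-\sum_j q_{\cdot j}\log q_{\cdot j}}. 0 means a fully specific
#' mapping (every reference label pins down the test cluster); 1 means
#' statistical independence. Natural logarithms; the ratio is base
#' invariant.
#'
#' @param N contingency counts (reference rows x test columns).
#' @return scalar NCE in [0, 1].
#' @export
nce <- function(N) {
  ct <- .as_ct(N)
  q <- ct$q
  qi <- rowSums(q)
  qj <- colSums(q)
  h_test <- -sum(qj[qj > 0] * log(qj[qj > 0]))
  if (h_test == 0)
    stop("NCE undefined: test partition has a single cluster")
  pos <- q > 0
  ce <- -sum(q[pos] * log(q[pos] / qi[row(q)[pos]]))
  ce / h_test
}

#' Occupancy fraction of one reference label
#'
#' Measures whether reference label \code{i} maps to test clusters in a
#' localized or diffuse way: the bracketed occupation number
#' \eqn{1/\sum_j (q_{ij}/q_{i\cdot})^2} ranges from 1 (all mass in one of
#' the \eqn{t} test clusters) to \eqn{t} (uniform spread); dividing by
#' \eqn{t} gives a fraction in \eqn{(0, 1]}.
#'
#' @param N contingency counts.
#' @param i reference row index.
#' @return scalar occupancy fraction.
#' @export
occupancy_fraction <- function(N, i) {
  ct <- .as_ct(N)
  if (ct$a[i] == 0) stop("reference label ", i, " has no cells")
  frac <- ct$N[i, ] / ct$a[i]
  occupation <- 1 / sum(frac^2)
  occupation / ncol(ct$N)
}

# Train a softprob booster on 60% of each cluster (capped at `cap` cells),
# validate on the rest, and bootstrap-upsample clusters whose held-out
# error exceeds `max_err` (up to 2x the cap), retraining until every
# cluster passes or `max_rounds` is reached.
.train_protocol <- function(Z, labels, seed, frac = 0.6, cap = 300,
                            max_err = 0.10, nrounds = 60, max_rounds = 3) {
  ids <- sort(unique(labels))
  lab <- match(labels, ids) - 1L
  set.seed(as.integer(seed))
  train <- unlist(lapply(ids, function(k) {
    idx <- which(labels == k)
    sample(idx, min(cap, max(1L, floor(frac * length(idx)))))
  }))
  heldout <- setdiff(seq_along(labels), train)
  fit <- function(tr_idx, extra = integer(0)) {
    sel <- c(tr_idx, extra)
    xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(ids),
                    eval_metric = "mlogloss", eta = 0.2, max_depth = 6,
                    subsample = 0.6, nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(Z[sel, , drop = FALSE],
                                  label = lab[sel]),
      nrounds = nrounds, verbose = 0)
  }
  booster <- fit(train)
  errs <- rep(0, length(ids))
  for (round in seq_len(max_rounds)) {
    if (length(heldout) == 0) break
    pr <- stats::predict(booster,
                         xgboost::xgb.DMatrix(Z[heldout, , drop = FALSE]))
    hard <- max.col(pr, ties.method = "first") - 1L
    errs <- vapply(seq_along(ids) - 1L, function(k) {
      sel <- lab[heldout] == k
      if (!any(sel)) return(0)
      mean(hard[sel] != k)
    }, numeric(1))
    bad <- which(errs > max_err)
    if (length(bad) == 0) break
    extra <- unlist(lapply(bad, function(k) {
      pool <- intersect(train, which(lab == k - 1L))
      sample(pool, min(2L * cap, length(pool)), replace = TRUE)
    }))
    booster <- fit(train, extra)
  }
  list(booster = booster, ids = ids, errors = errs)
}

# top-`n` features of a booster by average information gain
.top_features <- function(booster, feature_names, n = 500) {
  imp <- xgboost::xgb.importance(model = booster)
  got <- imp$Feature[order(-imp$Gain)]
  utils::head(got, n)
}

#' Map test clusters onto reference clusters by supervised classification
#'
#' Implements the full cross-age correspondence protocol: z-score the
#' shared features in each dataset; train boosted-tree classifiers on both
#' (per cluster, a random 60\% of cells up to 300 are used for training,
#' the rest for validation; clusters with held-out error above 10\% are
#' bootstrap-upsampled and the classifier retrained); take the top 500
#' features of each classifier by average information gain and intersect
#' them; retrain the reference classifier on the intersection; assign
#' every test cell to the reference cluster with the highest predicted
#' probability (ties broken toward the lowest cluster index); and tabulate
#' assignments against the test cells' own clusters.
#'
#' @param X_ref,X_test genes x cells normalized log-expression for the
#'   reference and test datasets (HVG-restricted); at least 50 shared
#'   genes required.
#' @param part_ref,part_test matching \code{cluster_partition}s (or
#'   integer vectors).
#' @param seed integer seed controlling sampling and training.
#' @param top_n features kept per classifier (default 500).
#' @param nrounds boosting rounds (default 60).
#' @return a \code{confusion_table} (reference rows x test columns) with
#'   attributes \code{assigned} (per test cell) and \code{features} (the
#'   shared feature set used).
#' @export
map_clusters <- function(X_ref, part_ref, X_test, part_test, seed = 1L,
                         top_n = 500, nrounds = 60) {
  X_ref <- .as_mat(X_ref); X_test <- .as_mat(X_test)
  cl_ref <- if (inherits(part_ref, "cluster_partition")) part_ref$cluster
            else part_ref
  cl_test <- if (inherits(part_test, "cluster_partition")) part_test$cluster
             else part_test
  ok_ref <- !is.na(cl_ref); ok_test <- !is.na(cl_test)
  common <- intersect(rownames(X_ref), rownames(X_test))
  if (length(common) < 50)
    stop("fewer than 50 shared features between datasets")
  zscore <- function(X, genes, keep) {
    Z <- t(as.matrix(X[genes, keep, drop = FALSE]))
    mu <- colMeans(Z); sdv <- apply(Z, 2, stats::sd); sdv[sdv == 0] <- 1
    Z <- sweep(sweep(Z, 2, mu), 2, sdv, "/")
    colnames(Z) <- genes
    Z
  }
  Zr <- zscore(X_ref, common, ok_ref)
  Zt <- zscore(X_test, common, ok_test)
  lr <- cl_ref[ok_ref]; lt <- cl_test[ok_test]
  small <- names(table(lr))[table(lr) < 5]
  if (length(small))
    warning("reference clusters with < 5 cells: ",
            paste(small, collapse = ", "))

  fit_r <- .train_protocol(Zr, lr, seed = seed, nrounds = nrounds)
  fit_t <- .train_protocol(Zt, lt, seed = seed + 1L, nrounds = nrounds)
  g_r <- .top_features(fit_r$booster, common, top_n)
  g_t <- .top_features(fit_t$booster, common, top_n)
  g <- intersect(g_r, g_t)
  if (length(g) == 0) stop("empty feature intersection")

  fit_final <- .train_protocol(Zr[, g, drop = FALSE], lr, seed = seed + 2L,
                               nrounds = nrounds)
  prob <- stats::predict(fit_final$booster,
                         xgboost::xgb.DMatrix(Zt[, g, drop = FALSE]))
  assigned <- fit_final$ids[max.col(prob, ties.method = "first")]

  ref_ids <- sort(unique(lr)); test_ids <- sort(unique(lt))
  N <- table(factor(assigned, levels = ref_ids),
             factor(lt, levels = test_ids))
  out <- confusion_table(unclass(N))
  dimnames(out$N) <- list(reference = ref_ids, test = test_ids)
  attr(out, "assigned") <- assigned
  attr(out, "features") <- g
  out
}

#' @export
#' @method print confusion_table
print.confusion_table <- function(x, ...) {
  cat("confusion_table:", nrow(x$N), "reference x", ncol(x$N),
      "test clusters,", x$n, "cells\n")
  cat("ARI", round(ari(x), 4))
  if (ncol(x$N) > 1) cat(", NCE", round(nce(x), 4))
  cat("\n")
  invisible(x)
}
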