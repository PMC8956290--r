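#' Rao, Shannon and Simpson diversity of a cluster partition
#'
#' For cluster frequencies \eqn{p_i} and pairwise distances \eqn{d_{ij}}
#' scaled to [0, 1]: Rao \eqn{= \sum_{ij} p_i p_j d_{ij}}, Shannon
#' \eqn{H = -\sum_i p_i \log p_i} (natural log, \eqn{0\log 0 = 0}),
#' Simpson \eqn{S = \sum_i p_i^2}. Rao and Shannon increase with
#' diversity; Simpson decreases.
#'
#' @param p cluster relative frequencies; must sum to 1 (tolerance 1e-8).
#' @param D symmetric distance matrix in [0, 1] with zero diagonal; only
#'   needed for Rao (identity: all-ones off-diagonal if missing).
#' @return named numeric vector \code{c(rao, shannon, simpson)}.
#' @export
diversity_indices <- function(p, D = NULL) {
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  if (any(p < 0)) stop("p must be nonnegative")
  n <- length(p)
  if (is.null(D)) D <- 1 - diag(n)
  stopifnot(nrow(D) == n, ncol(D) == n)
  if (any(D < -1e-12) || any(D > 1 + 1e-12))
    stop("distances must lie in [0, 1]")
  rao <- as.numeric(t(p) %*% D %*% p)
  pp <- p[p > 0]
  c(rao = rao, shannon = -sum(pp * log(pp)), simpson = sum(p^2))
}

#' Cluster-centroid distance matrix for Rao diversity
#'
#' Correlation distance between cluster centroids of the (HVG-restricted)
#' log-expression, min-max scaled to [0, 1] with a zero diagonal.
#'
#' @param X normalized log-expression (genes x cells).
#' @param partition \code{cluster_partition} or integer vector.
#' @return symmetric distance matrix over clusters.
#' @export
cluster_distances <- function(X, partition) {
  X <- .as_mat(X)
  cl <- if (inherits(partition, "cluster_partition")) partition$cluster
        else partition
  ids <- sort(unique(cl[!is.na(cl)]))
  cent <- sapply(ids, function(k)
    Matrix::rowMeans(X[, which(cl == k), drop = FALSE]))
  D <- 1 - stats::cor(cent)
  diag(D) <- 0
  if (max(D) > 0) D <- D / max(D)
  D
}

#' Mean held-out classification error across clusters
#'
#' Trains a gradient-boosted tree multi-class classifier on a random half
#' of the cells (stratified by cluster) and reports the per-cluster
#' misclassification rate on the held-out half, averaged over clusters.
#' Lower error means more distinct clusters. Clusters with fewer than 4
#' cells are excluded with a warning; a single cluster returns 0.
#'
#' @param E embedding (\code{embedding} object or cells x k matrix) used
#'   as features.
#' @param partition \code{cluster_partition} or integer vector.
#' @param split_frac training fraction (default 0.5).
#' @param seed integer seed for the split and the learner.
#' @param nrounds boosting rounds (default 60).
#' @return mean per-cluster test error in [0, 1].
#' @export
classifier_error <- function(E, partition, split_frac = 0.5, seed = 1L,
                             nrounds = 60) {
  H <- if (inherits(E, "embedding")) E$H else as.matrix(E)
  cl <- if (inherits(partition, "cluster_partition")) partition$cluster
        else partition
  ok <- !is.na(cl)
  H <- H[ok, , drop = FALSE]; cl <- cl[ok]
  tab <- table(cl)
  small <- names(tab)[tab < 4]
  if (length(small)) {
    warning("excluding clusters with < 4 cells: ",
            paste(small, collapse = ", "))
    keep <- !(cl %in% as.integer(small))
    H <- H[keep, , drop = FALSE]; cl <- cl[keep]
  }
  ids <- sort(unique(cl))
  if (length(ids) < 2) return(0)
  set.seed(as.integer(seed))
  lab <- match(cl, ids) - 1L
  train <- unlist(lapply(ids, function(k) {
    idx <- which(cl == k)
    sample(idx, max(2L, floor(split_frac * length(idx))))
  }))
  test <- setdiff(seq_along(cl), train)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = length(ids),
                  eta = 0.2, max_depth = 6, subsample = 0.6, nthread = 1,
                  seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(H[train, , drop = FALSE],
                                label = lab[train]),
    nrounds = nrounds, verbose = 0)
  pred <- stats::predict(booster,
                         xgboost::xgb.DMatrix(H[test, , drop = FALSE]))
  errs <- vapply(seq_along(ids) - 1L, function(k) {
    sel <- lab[test] == k
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] != k)
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Mean relative cluster diameter in standardized PC space
#'
#' For each cluster, \eqn{r_C} is the median Euclidean distance of its
#' cells to the cluster centroid and \eqn{d_C} the median distance of its
#' cells to the centroid of the nearest external cluster, both in the top
#' standardized principal components; the statistic is the mean of
#' \eqn{r_C / d_C} over clusters. Lower values mean better-separated
#' clusters; the ratio is invariant to a global rescaling of coordinates.
#'
#' @param X_pcs cells x d coordinate matrix (e.g. top 20 PCs), z-scored
#'   per column internally.
#' @param partition \code{cluster_partition} or integer vector; at least
#'   2 clusters.
#' @return mean r_C / d_C.
#' @export
relative_diameter <- function(X_pcs, partition) {
  cl <- if (inherits(partition, "cluster_partition")) partition$cluster
        else partition
  ok <- !is.na(cl)
  Z <- as.matrix(X_pcs)[ok, , drop = FALSE]; cl <- cl[ok]
  ids <- sort(unique(cl))
  if (length(ids) < 2)
    stop("relative diameter requires at least 2 clusters")
  sdv <- apply(Z, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(Z, 2, colMeans(Z)), 2, sdv, "/")
  cent <- t(sapply(ids, function(k)
    colMeans(Z[cl == k, , drop = FALSE])))
  ratio <- vapply(seq_along(ids), function(i) {
    cells <- Z[cl == ids[i], , drop = FALSE]
    dc_own <- sqrt(rowSums(sweep(cells, 2, cent[i, ])^2))
    other <- setdiff(seq_along(ids), i)
    # nearest external cluster by centroid distance
    cd <- sqrt(rowSums(sweep(cent[other, , drop = FALSE], 2, cent[i, ])^2))
    j <- other[which.min(cd)]
    dc_ext <- sqrt(rowSums(sweep(cells, 2, cent[j, ])^2))
    stats::median(dc_own) / stats::median(dc_ext)
  }, numeric(1))
  mean(ratio)
}

#' Per-age diversity report
#'
#' Convenience wrapper assembling cluster frequencies, centroid distances
#' and all diversity statistics for one age.
#'
#' @param X normalized log-expression (genes x cells) at one age.
#' @param partition that age's \code{cluster_partition}.
#' @param E optional embedding for the classifier error.
#' @param age age label carried through to the output.
#' @param seed seed for the classifier split.
#' @return list of class \code{diversity_report}: \code{age}, \code{p},
#'   \code{D}, \code{rao}, \code{shannon}, \code{simpson},
#'   \code{classifier_error} (NA when \code{E} missing),
#'   \code{relative_diameter}.
#' @export
diversity_report <- function(X, partition, E = NULL, age = NA, seed = 1L) {
  X <- .as_mat(X)
  cl <- partition$cluster
  p <- as.vector(table(cl)) / sum(!is.na(cl))
  D <- cluster_distances(X, partition)
  idx <- diversity_indices(p, D)
  pcs <- stats::prcomp(t(as.matrix(X)), rank. = min(20, nrow(X) - 1,
                                                    ncol(X) - 1))$x
  structure(list(age = age, p = p, D = D,
                 rao = idx[["rao"]], shannon = idx[["shannon"]],
                 simpson = idx[["simpson"]],
                 classifier_error = if (is.null(E)) NA_real_ else
                   classifier_error(E, partition, seed = seed),
                 relative_diameter = if (partition$n_clusters < 2)
                   NA_real_ else relative_diameter(pcs, partition)),
            class = "diversity_report")
}
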