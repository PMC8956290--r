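#' Choose latent dimensionality by random-matrix theory
#'
#' Counts the eigenvalues of the sample gene-gene correlation matrix that
#' exceed the 99th percentile of the Tracy-Widom law for the largest
#' eigenvalue of a white Wishart matrix of matching dimensions (Johnstone's
#' centering and scaling; TW1 99th percentile 2.0234). Eigenvalues above
#' this threshold indicate structure beyond sampling noise.
#'
#' @param X genes x cells matrix restricted to highly variable genes (raw
#'   or normalized; each gene is standardized internally). Constant genes
#'   are dropped.
#' @param quantile_tw Tracy-Widom (beta = 1) quantile used as the
#'   threshold; default the 99th percentile.
#' @return integer k, the number of supra-threshold eigenvalues.
#' @export
choose_dim_rmt <- function(X, quantile_tw = 2.0234) {
  X <- .as_mat(X)
  n <- ncol(X)                      # observations (cells)
  if (n < 2) stop("need at least 2 cells")
  Z <- t(as.matrix(X))              # n x p
  sdv <- apply(Z, 2, stats::sd)
  Z <- Z[, sdv > 0, drop = FALSE]
  p <- ncol(Z)
  if (p < 1) stop("no variable genes")
  Z <- scale(Z)
  # eigenvalues of cor matrix = singular values^2 / (n-1)
  ev <- svd(Z, nu = 0, nv = 0)$d^2 / (n - 1)
  mu <- (sqrt(n - 1) + sqrt(p))^2
  sig <- (sqrt(n - 1) + sqrt(p)) *
    (1 / sqrt(n - 1) + 1 / sqrt(p))^(1 / 3)
  thr <- (mu + sig * quantile_tw) / (n - 1)
  as.integer(sum(ev > thr))
}

#' Embed cells in a shared latent space, integrating batches
#'
#' Two modes. \code{"inmf"} (the default with more than one batch) is an
#' integrative non-negative matrix factorization: every batch b is
#' factorized as \eqn{X_b \approx (W + V_b) H_b} with a shared gene-factor
#' matrix W and batch-specific components \eqn{V_b} (all factors
#' non-negative, multiplicative updates, penalty \code{lambda} on
#' \eqn{V_b H_b}), after which the per-cell loadings are
#' quantile-normalized across batches factor by factor against the largest
#' batch. \code{"pca"} is a standard principal-component embedding, used
#' for single-batch data.
#'
#' @param X genes x cells normalized log-expression (HVG-restricted),
#'   matrix or \code{\link{normalize_log}} result.
#' @param batches per-cell batch labels (ignored in PCA mode).
#' @param k latent dimensionality, e.g. from \code{\link{choose_dim_rmt}}.
#' @param mode "auto", "inmf" or "pca".
#' @param lambda iNMF integration penalty (default 5).
#' @param n_iter iNMF update sweeps (default 60).
#' @param seed integer seed for the factor initialization.
#' @return object of class \code{embedding}: list with \code{H} (cells x
#'   k loadings; non-negative in iNMF mode), \code{k}, \code{mode},
#'   \code{batches}.
#' @export
embed_cells <- function(X, batches = NULL, k, mode = c("auto", "inmf", "pca"),
                        lambda = 5, n_iter = 60, seed = 1L) {
  mode <- match.arg(mode)
  X <- .as_mat(X)
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  if (is.null(batches)) batches <- rep(1L, ncol(X))
  batches <- as.factor(batches)
  if (mode == "auto")
    mode <- if (nlevels(batches) > 1) "inmf" else "pca"

  if (mode == "pca") {
    Z <- scale(t(as.matrix(X)))
    Z[, !is.finite(colSums(Z))] <- 0
    H <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x[, seq_len(k),
                                                            drop = FALSE]
  } else {
    set.seed(as.integer(seed))
    Xd <- as.matrix(X)
    g <- nrow(Xd)
    lv <- levels(batches)
    Xb <- lapply(lv, function(b) Xd[, batches == b, drop = FALSE])
    W <- matrix(stats::runif(g * k, 0, 1), g, k)
    V <- lapply(lv, function(b) matrix(stats::runif(g * k, 0, 0.1), g, k))
    H <- lapply(Xb, function(x)
      matrix(stats::runif(k * ncol(x), 0, 1), k, ncol(x)))
    eps <- 1e-10
    for (it in seq_len(n_iter)) {
      for (b in seq_along(lv)) {
        Wb <- W + V[[b]]
        H[[b]] <- H[[b]] * (crossprod(Wb, Xb[[b]])) /
          (crossprod(Wb) %*% H[[b]] +
             lambda * crossprod(V[[b]]) %*% H[[b]] + eps)
      }
      HHt <- lapply(H, tcrossprod)
      num <- Reduce(`+`, lapply(seq_along(lv), function(b)
        Xb[[b]] %*% t(H[[b]])))
      den <- Reduce(`+`, lapply(seq_along(lv), function(b)
        (W + V[[b]]) %*% HHt[[b]]))
      W <- W * num / (den + eps)
      for (b in seq_along(lv)) {
        num_v <- Xb[[b]] %*% t(H[[b]])
        den_v <- (W + V[[b]]) %*% HHt[[b]] + lambda * V[[b]] %*% HHt[[b]]
        V[[b]] <- V[[b]] * num_v / (den_v + eps)
      }
    }
    # scale factors to comparable magnitude, then quantile-normalize
    # loadings across batches against the largest batch
    Hc <- lapply(H, function(h) t(h))
    ref <- which.max(vapply(Hc, nrow, integer(1)))
    for (f in seq_len(k)) {
      rv <- sort(Hc[[ref]][, f])
      for (b in seq_along(lv)) {
        if (b == ref) next
        x <- Hc[[b]][, f]
        q <- (rank(x, ties.method = "average") - 0.5) / length(x)
        Hc[[b]][, f] <- stats::quantile(rv, probs = q, names = FALSE,
                                        type = 7)
      }
    }
    H <- matrix(0, ncol(Xd), k)
    for (b in seq_along(lv)) H[batches == lv[b], ] <- Hc[[b]]
  }
  rownames(H) <- colnames(X)
  structure(list(H = H, k = as.integer(k), mode = mode, batches = batches),
            class = "embedding")
}

#' @export
#' @method print embedding
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$H), "cells x", x$k, "factors (", x$mode, ")\n")
  invisible(x)
}

#' Cluster cells on a kNN graph with Jaccard weights and Louvain
#'
#' Builds a k-nearest-neighbour graph on the embedding coordinates
#' (Euclidean), weights each edge by the Jaccard overlap of the two cells'
#' neighbour sets, and partitions the graph with the Louvain algorithm.
#' Clusters are renumbered by decreasing size.
#'
#' @param E an \code{\link{embed_cells}} result, or a cells x k coordinate
#'   matrix.
#' @param n_neighbors neighbours per cell (default 30).
#' @param resolution Louvain modularity resolution (default 0.5;
#'   igraph's gamma — 0.5 keeps a single homogeneous population in one
#'   or two communities instead of shattering it).
#' @param seed integer seed (Louvain is order-dependent).
#' @return object of class \code{cluster_partition}: list with
#'   \code{cluster} (integer per cell, 1 = largest), \code{sizes},
#'   \code{age} (NULL here) and \code{log}.
#' @export
graph_cluster <- function(E, n_neighbors = 30, resolution = 0.5,
                          seed = 1L) {
  H <- if (inherits(E, "embedding")) E$H else as.matrix(E)
  n <- nrow(H)
  if (n_neighbors >= n) stop("n_neighbors must be smaller than cell count")
  knn <- FNN::get.knn(H, k = n_neighbors)$nn.index
  nbr <- lapply(seq_len(n), function(i) c(i, knn[i, ]))
  ii <- rep(seq_len(n), each = n_neighbors)
  jj <- as.vector(t(knn))
  pairs <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nbr[[pairs[r, 1]]]; b <- nbr[[pairs[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, weights = w[keep],
                                  resolution = resolution)
  cl <- igraph::membership(comm)
  new_partition(as.integer(cl))
}

#' Construct a cluster partition (internal)
#'
#' Renumbers cluster ids contiguously by decreasing size unless
#' \code{relabel = FALSE} (used when ids carry external meaning, e.g.
#' planted type labels).
#' @keywords internal
new_partition <- function(cluster, age = NULL, log = list(),
                          relabel = TRUE) {
  keep <- !is.na(cluster)
  if (relabel) {
    sizes <- sort(table(cluster[keep]), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes), names(sizes))
    cluster[keep] <- relab[as.character(cluster[keep])]
  } else {
    sizes <- table(cluster[keep])
  }
  structure(list(cluster = as.integer(cluster),
                 sizes = as.integer(sizes),
                 n_clusters = length(sizes), age = age, log = log),
            class = "cluster_partition")
}

#' @export
#' @method print cluster_partition
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", x$n_clusters, "clusters over",
      sum(!is.na(x$cluster)), "cells\n")
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  if (length(x$log)) cat(length(x$log), "refinement actions logged\n")
  invisible(x)
}

#' Differential expression between two clusters
#'
#' Log fold change uses the size-balanced definition
#' \eqn{\ln[(|C_b| \sum_{n \in C_a} X_{gn}) / (|C_a| \sum_{n \in C_b}
#' X_{gn})]}; p-values come from a two-sided Wilcoxon rank-sum test on the
#' normalized log values, FDR-adjusted across tested genes. A gene is
#' significant when \eqn{|\log FC| > 0.5} and adjusted p < 1e-5. Infinite
#' fold changes (expression confined to one cluster) are capped at
#' \eqn{\pm 10}.
#'
#' @param X normalized log-expression (genes x cells).
#' @param partition a \code{cluster_partition} or integer vector.
#' @param a,b the two cluster ids to contrast.
#' @param logfc_thresh,p_thresh significance thresholds (defaults 0.5,
#'   1e-5 on the FDR-adjusted p).
#' @param logfc_cap cap for infinite log fold changes (default 10).
#' @return data.frame: \code{gene}, \code{logfc}, \code{p}, \code{padj},
#'   \code{significant}; genes with zero expression in both clusters are
#'   skipped.
#' @export
de_genes <- function(X, partition, a, b, logfc_thresh = 0.5,
                     p_thresh = 1e-5, logfc_cap = 10) {
  X <- .as_mat(X)
  cl <- if (inherits(partition, "cluster_partition")) partition$cluster
        else partition
  ia <- which(cl == a); ib <- which(cl == b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both clusters must be nonempty")
  Xa <- as.matrix(X[, ia, drop = FALSE])
  Xb <- as.matrix(X[, ib, drop = FALSE])
  sa <- rowSums(Xa); sb <- rowSums(Xb)
  test <- sa > 0 | sb > 0
  logfc <- log((length(ib) * sa) / (length(ia) * sb))
  logfc[logfc > logfc_cap] <- logfc_cap
  logfc[logfc < -logfc_cap] <- -logfc_cap
  p <- rep(NA_real_, nrow(X))
  for (g in which(test)) {
    p[g] <- suppressWarnings(
      stats::wilcox.test(Xa[g, ], Xb[g, ], exact = FALSE)$p.value)
  }
  # degenerate (all-tied) genes return NaN; a gene exclusive to one side
  # with constant values still separates perfectly
  p[test & !is.finite(p)] <- 1
  padj <- rep(NA_real_, nrow(X))
  padj[test] <- stats::p.adjust(p[test], method = "BH")
  genes <- rownames(X)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(X)))
  out <- data.frame(gene = genes, logfc = logfc, p = p, padj = padj,
                    stringsAsFactors = FALSE)[test, ]
  out$significant <- abs(out$logfc) > logfc_thresh &
    !is.na(out$padj) & out$padj < p_thresh
  rownames(out) <- NULL
  out
}

#' Refine a partition by merging indistinct clusters and removing impure ones
#'
#' Builds an average-linkage dendrogram over cluster centroids (in the
#' embedding space when given, else in expression space), tests every
#' terminal sibling pair for differential expression, merges pairs with
#' fewer than \code{min_de} significant genes, and iterates to stability.
#' When \code{marker_sets} and \code{target_class} are given, clusters
#' whose annotation is not the target class — or that are flagged as
#' doublets — are removed (their cells set to NA). Every action is logged.
#'
#' @param partition a \code{cluster_partition}.
#' @param X normalized log-expression (genes x cells).
#' @param embedding optional \code{embedding} for centroid distances.
#' @param marker_sets optional named marker list for purity removal.
#' @param target_class class label to retain (default: the class of the
#'   plurality of cells).
#' @param min_de merge threshold on significant DE genes (default 10).
#' @param ... passed to \code{\link{de_genes}}.
#' @return refined \code{cluster_partition}; refinement never increases
#'   the cluster count.
#' @export
refine_partition <- function(partition, X, embedding = NULL,
                             marker_sets = NULL, target_class = NULL,
                             min_de = 10, ...) {
  stopifnot(inherits(partition, "cluster_partition"))
  X <- .as_mat(X)
  cl <- partition$cluster
  log <- partition$log
  coords <- if (!is.null(embedding)) embedding$H else t(as.matrix(X))

  repeat {
    ids <- sort(unique(cl[!is.na(cl)]))
    if (length(ids) < 2) break
    cent <- t(sapply(ids, function(k)
      colMeans(coords[which(cl == k), , drop = FALSE])))
    hc <- stats::hclust(stats::dist(cent), method = "average")
    merges <- hc$merge
    sib <- merges[merges[, 1] < 0 & merges[, 2] < 0, , drop = FALSE]
    merged_any <- FALSE
    for (r in seq_len(nrow(sib))) {
      a <- ids[-sib[r, 1]]; b <- ids[-sib[r, 2]]
      nde <- sum(de_genes(X, cl, a, b, ...)$significant)
      if (nde < min_de) {
        cl[cl == b] <- a
        log[[length(log) + 1]] <- list(action = "merge", from = b, to = a,
                                       n_de = nde)
        merged_any <- TRUE
        break  # recompute dendrogram after each merge
      }
    }
    if (!merged_any) break
  }

  if (!is.null(marker_sets)) {
    ann <- annotate_classes(X[, !is.na(cl), drop = FALSE], cl[!is.na(cl)],
                            marker_sets)
    if (is.null(target_class)) {
      cc <- attr(ann, "cell_class")
      target_class <- names(which.max(table(cc)))
    }
    bad <- ann$cluster[ann$class != target_class | ann$doublet]
    for (k in bad) {
      log[[length(log) + 1]] <- list(action = "remove", cluster = k,
                                     class = ann$class[ann$cluster == k],
                                     doublet = ann$doublet[ann$cluster == k])
      cl[cl == k] <- NA
    }
    if (all(is.na(cl))) stop("refinement removed every cluster")
  }
  new_partition(cl, age = partition$age, log = log)
}
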