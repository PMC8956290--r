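#' @importFrom Matrix rowMeans rowSums colMeans colSums t
NULL

# accept either a plain/sparse matrix or a normalize_log() result
.as_mat <- function(X) {
  if (inherits(X, "expression_matrix")) X$X else X
}

#' Filter low-quality cells and rarely detected genes
#'
#' Retains cells detecting at least \code{min_genes_per_cell} genes, then
#' genes detected in at least \code{min_cells_per_gene} of the retained
#' cells — in that order, so gene detection is assessed on the cells that
#' survive.
#'
#' @param C genes x cells count matrix (sparse or dense), nonnegative.
#' @param min_genes_per_cell minimum detected genes per retained cell
#'   (default 700).
#' @param min_cells_per_gene minimum cells detecting a retained gene
#'   (default 10).
#' @return the filtered matrix, with attribute \code{removed} = counts of
#'   dropped cells and genes.
#' @export
filter_cells_genes <- function(C, min_genes_per_cell = 700,
                               min_cells_per_gene = 10) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  detected_per_cell <- Matrix::colSums(C > 0)
  keep_cells <- detected_per_cell >= min_genes_per_cell
  if (!any(keep_cells))
    stop("filtering removed every cell (min_genes_per_cell = ",
         min_genes_per_cell, ")")
  C2 <- C[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(C2 > 0) >= min_cells_per_gene
  out <- C2[keep_genes, , drop = FALSE]
  attr(out, "removed") <- c(cells = sum(!keep_cells),
                            genes = sum(!keep_genes))
  out
}

#' Median-normalize columns and log-transform
#'
#' Scales each cell (column) to a common total — the median of the column
#' sums unless \code{target} is supplied — then applies
#' \eqn{x \mapsto \log(1 + x)}. The median target is recomputed per
#' dataset; a fixed target can be passed to reproduce a specific scaling.
#'
#' @param C filtered genes x cells count matrix; every column total must be
#'   positive.
#' @param target optional fixed normalization total.
#' @return object of class \code{expression_matrix}: list with \code{X}
#'   (sparse genes x cells log-normalized values) and \code{target}.
#' @export
normalize_log <- function(C, target = NULL) {
  cs <- Matrix::colSums(C)
  if (any(cs <= 0))
    stop("zero-total cell encountered; filter cells first")
  if (is.null(target)) target <- stats::median(cs)
  X <- methods::as(Matrix::Matrix(C, sparse = TRUE), "CsparseMatrix")
  X@x <- log1p(X@x * rep.int(target / cs, diff(X@p)))
  structure(list(X = X, target = target), class = "expression_matrix")
}

#' @export
#' @method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$X), "genes x", ncol(x$X),
      "cells, target", signif(x$target, 6), "\n")
  invisible(x)
}

# Maximum-likelihood Gamma shape for a positive sample (scale profiled
# out); Newton iterations on log(s) - digamma(s) = log(mean) - mean(log).
.fit_gamma_shape <- function(x) {
  x <- x[x > 0]
  if (length(x) < 2) stop("cannot fit Gamma shape: too few positive values")
  s <- log(mean(x)) - mean(log(x))
  if (!is.finite(s) || s <= 0)
    stop("Gamma shape fit failed: degenerate library-size distribution")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka initialization
  for (i in 1:50) {
    g <- log(a) - digamma(a) - s
    h <- 1 / a - trigamma(a)
    step <- g / h
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  if (!is.finite(a) || a <= 0)
    stop("Gamma shape fit failed to converge (last value ", a, ")")
  a
}

#' Select highly variable genes under a Gamma-Poisson null
#'
#' For each gene computes the mean \eqn{\mu_m} and coefficient of variation
#' \eqn{CV_m} of its raw UMI counts, and compares the latter to the null
#' \eqn{CV^{null}_m = \sqrt{1/\mu_m + 1/\alpha}} expected from Poisson shot
#' noise plus Gamma-distributed library sizes, where \eqn{\alpha} is the
#' maximum-likelihood Gamma shape fitted to the normalized library sizes
#' \eqn{T_n}. The deviation \eqn{d_m = \log(CV_m / CV^{null}_m)} is
#' thresholded at \code{mean(d) + z_factor * sd(d)} (computed over genes
#' with positive mean and finite \eqn{d}).
#'
#' @param C genes x cells raw count matrix.
#' @param z_factor threshold multiplier on the sd of the deviation scores
#'   (default 0.8).
#' @return object of class \code{hvg_result}: list with \code{table}
#'   (per-gene data.frame: \code{gene}, \code{mean}, \code{cv},
#'   \code{cv_null}, \code{d}, \code{selected}), \code{alpha},
#'   \code{threshold} and \code{z_factor}.
#' @export
select_hvgs <- function(C, z_factor = 0.8) {
  n <- ncol(C)
  mu <- Matrix::rowMeans(C)
  ex2 <- Matrix::rowMeans(C * C)
  sigma2 <- pmax(ex2 - mu^2, 0)          # population variance (1/N)
  cv <- ifelse(mu > 0, sqrt(sigma2) / mu, NA_real_)
  t_n <- Matrix::colSums(C)
  alpha <- .fit_gamma_shape(t_n / mean(t_n))
  cv_null <- ifelse(mu > 0, sqrt(1 / mu + 1 / alpha), NA_real_)
  d <- log(cv / cv_null)                  # -Inf when cv == 0
  usable <- mu > 0 & is.finite(d)
  if (!any(usable)) stop("no expressed genes with finite deviation scores")
  thr <- mean(d[usable]) + z_factor * stats::sd(d[usable])
  selected <- usable & d > thr
  genes <- rownames(C)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(C)))
  structure(list(table = data.frame(gene = genes, mean = mu, cv = cv,
                                    cv_null = cv_null, d = d,
                                    selected = selected,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 alpha = alpha, threshold = thr, z_factor = z_factor),
            class = "hvg_result")
}

#' @export
#' @method print hvg_result
print.hvg_result <- function(x, ...) {
  cat("hvg_result:", sum(x$table$selected), "of", nrow(x$table),
      "genes selected; alpha =", signif(x$alpha, 4), "\n")
  invisible(x)
}

#' Annotate clusters with cell classes and flag putative doublets
#'
#' Scores every cell for each marker set (mean of per-gene z-scored
#' log-expression over the set), averages scores within clusters, labels
#' each cluster with the top-scoring class, and flags clusters whose mean
#' score exceeds \code{doublet_threshold} for two or more classes as
#' doublets. Clusters with no class above threshold are "unassigned".
#'
#' @param X normalized log-expression (matrix or
#'   \code{\link{normalize_log}} result).
#' @param clusters per-cell cluster ids.
#' @param marker_sets named list (GMT-style) mapping class to marker genes.
#' @param doublet_threshold z-score a cluster must exceed to count as
#'   expressing a class (default 0.5).
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{class}, \code{doublet}, plus one score column per class; the
#'   per-cell labels are in attribute \code{cell_class}.
#' @export
annotate_classes <- function(X, clusters, marker_sets,
                             doublet_threshold = 0.5) {
  X <- .as_mat(X)
  if (length(marker_sets) == 0 || any(lengths(marker_sets) == 0))
    stop("empty marker set")
  stopifnot(length(clusters) == ncol(X))
  scores <- sapply(marker_sets, function(genes) {
    genes <- intersect(genes, rownames(X))
    if (length(genes) == 0) return(rep(NA_real_, ncol(X)))
    sub <- as.matrix(X[genes, , drop = FALSE])
    mu <- rowMeans(sub); sdv <- apply(sub, 1, stats::sd)
    sdv[sdv == 0] <- 1
    colMeans((sub - mu) / sdv)
  })
  scores <- as.matrix(scores)
  if (all(is.na(scores))) {
    warning("no marker genes expressed; all clusters unassigned")
    cl <- sort(unique(clusters))
    return(data.frame(cluster = cl, class = "unassigned", doublet = FALSE))
  }
  cl <- sort(unique(clusters))
  mean_scores <- t(sapply(cl, function(k)
    colMeans(scores[clusters == k, , drop = FALSE], na.rm = TRUE)))
  hits <- mean_scores > doublet_threshold
  label <- colnames(scores)[max.col(mean_scores, ties.method = "first")]
  label[rowSums(hits, na.rm = TRUE) == 0] <- "unassigned"
  out <- data.frame(cluster = cl, class = label,
                    doublet = rowSums(hits, na.rm = TRUE) >= 2,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mean_scores))
  attr(out, "cell_class") <- out$class[match(clusters, cl)]
  out
}
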