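# row-wise log-sum-exp of a matrix
.lse_rows <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

#' Solve an entropic (un)balanced optimal-transport coupling between ages
#'
#' Estimates the temporal coupling \eqn{\Pi} between cells measured at two
#' consecutive ages by minimizing
#' \deqn{\langle c, \Pi\rangle - \epsilon H(\Pi)
#'   + \lambda_1 KL(\Pi 1 \,\|\, \hat Q) + \lambda_2 KL(\Pi^T 1 \,\|\, \hat P)}
#' where \eqn{c} is the (squared) Euclidean cost between expression
#' profiles, \eqn{H} the entropy, \eqn{\hat P} the empirical (uniform)
#' distribution over target cells and \eqn{\hat Q} the source distribution
#' rescaled by per-cell growth rates \eqn{g^{\Delta t}} to account for
#' division and death. Solved by stabilized log-domain scaling (Sinkhorn)
#' iterations; with \eqn{\lambda \to \infty} the marginal constraints
#' become exact (balanced transport).
#'
#' The cost matrix is divided by its median positive entry before solving,
#' so \code{eps} is expressed relative to the typical pairwise cost.
#'
#' @param X_i,X_j genes x cells matrices (shared genes, e.g. the common
#'   HVG normalized log-expression) for the source and target ages; cells
#'   x feature matrices are accepted via \code{features_in_rows = FALSE}.
#' @param eps entropic regularization strength (default 0.005).
#' @param lam1,lam2 KL relaxation weights for the source and target
#'   marginals (defaults 1 and 50); \code{Inf} enforces the marginal
#'   exactly.
#' @param g per-source-cell relative growth rates (default 1).
#' @param days_gap time gap in days; the growth rescaling uses
#'   \eqn{g^{days\_gap}}.
#' @param cost "sqeuclidean" (default) or "euclidean".
#' @param normalize_cost divide the cost matrix by its median positive
#'   entry (default TRUE).
#' @param tol stopping tolerance on the change in scaling potentials
#'   (default 1e-8).
#' @param max_iter iteration cap (default 5000); non-convergence is
#'   flagged, not silent.
#' @param features_in_rows set FALSE when inputs are cells x features.
#' @return object of class \code{transport_map}: list with \code{plan}
#'   (source x target, nonnegative), \code{a}, \code{b} (target
#'   marginals), \code{eps}, \code{lam1}, \code{lam2}, \code{g},
#'   \code{cost}, \code{converged}, \code{iterations}.
#' @export
solve_coupling <- function(X_i, X_j, eps = 0.005, lam1 = 1, lam2 = 50,
                           g = NULL, days_gap = 1,
                           cost = c("sqeuclidean", "euclidean"),
                           normalize_cost = TRUE, tol = 1e-8,
                           max_iter = 5000, features_in_rows = TRUE) {
  cost <- match.arg(cost)
  stopifnot(eps > 0, lam1 > 0, lam2 > 0, days_gap >= 0)
  A <- if (features_in_rows) t(as.matrix(.as_mat(X_i))) else
    as.matrix(X_i)
  B <- if (features_in_rows) t(as.matrix(.as_mat(X_j))) else
    as.matrix(X_j)
  n_i <- nrow(A); n_j <- nrow(B)
  C <- outer(rowSums(A^2), rep(1, n_j)) +
    outer(rep(1, n_i), rowSums(B^2)) - 2 * tcrossprod(A, B)
  C[C < 0] <- 0
  if (cost == "euclidean") C <- sqrt(C)
  if (anyNA(C)) stop("NaN in cost matrix")
  if (normalize_cost) {
    med <- stats::median(C[C > 0])
    if (is.finite(med) && med > 0) C <- C / med
  }
  if (is.null(g)) g <- rep(1, n_i)
  stopifnot(length(g) == n_i, all(g > 0))
  a <- g^days_gap
  a <- a / sum(a)                       # growth-rescaled source marginal
  b <- rep(1 / n_j, n_j)                # empirical target marginal

  f1 <- if (is.finite(lam1)) lam1 / (lam1 + eps) else 1
  f2 <- if (is.finite(lam2)) lam2 / (lam2 + eps) else 1
  K <- -C / eps
  log_u <- rep(0, n_i); log_v <- rep(0, n_j)
  log_a <- log(a); log_b <- log(b)
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    log_u_new <- f1 * (log_a - .lse_rows(K + rep(log_v, each = n_i)))
    log_v_new <- f2 * (log_b - .lse_rows(t(K) +
                                           rep(log_u_new, each = n_j)))
    delta <- max(max(abs(log_u_new - log_u)), max(abs(log_v_new - log_v)))
    log_u <- log_u_new; log_v <- log_v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  plan <- exp(K + outer(log_u, log_v, `+`))
  if (!is.null(rownames(A))) rownames(plan) <- rownames(A)
  if (!is.null(rownames(B))) colnames(plan) <- rownames(B)
  if (!converged)
    warning("coupling solver did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  structure(list(plan = plan, a = a, b = b, eps = eps, lam1 = lam1,
                 lam2 = lam2, g = g, days_gap = days_gap, cost = cost,
                 converged = converged, iterations = it),
            class = "transport_map")
}

#' @export
#' @method print transport_map
print.transport_map <- function(x, ...) {
  cat("transport_map:", nrow(x$plan), "x", ncol(x$plan),
      "| eps", x$eps, "| lam", x$lam1, "/", x$lam2,
    "|", if (x$converged) paste0("converged (", x$iterations, " it)")
    else "NOT converged", "\n")
  invisible(x)
}

#' Estimate per-cell growth rates by iterated transport
#'
#' Initializes growth from a marker-based score (logistic map of the
#' difference between proliferation- and apoptosis-signature z-scores,
#' clamped below at 0.2), then alternates: solve the coupling with the
#' current rates, set each source cell's rate to its realized relative
#' mass outflow, and repeat \code{growth_iters} times. Without marker
#' sets the initialization is 1 for every cell; with
#' \code{growth_iters = 0} the initialization is returned unchanged.
#'
#' @param X_i,X_j source/target genes x cells matrices.
#' @param proliferation_markers,apoptosis_markers optional gene sets.
#' @param growth_iters refinement iterations (default 3).
#' @param g_range clamp range for growth rates (default c(0.2, 5)).
#' @param ... passed to \code{\link{solve_coupling}}.
#' @return numeric vector of growth rates (one per source cell) with
#'   attribute \code{history} (rates after each iteration).
#' @export
estimate_growth <- function(X_i, X_j = NULL, proliferation_markers = NULL,
                            apoptosis_markers = NULL, growth_iters = 3,
                            g_range = c(0.2, 5), ...) {
  Xi <- .as_mat(X_i)
  n_i <- ncol(Xi)
  score_of <- function(genes) {
    genes <- intersect(genes, rownames(Xi))
    if (length(genes) == 0) return(rep(0, n_i))
    signature_score(Xi, genes)
  }
  if (is.null(proliferation_markers) && is.null(apoptosis_markers)) {
    g <- rep(1, n_i)
  } else {
    s <- score_of(proliferation_markers) - score_of(apoptosis_markers)
    g <- 2 * stats::plogis(s)           # score 0 -> neutral growth 1
  }
  g <- pmin(pmax(g, g_range[1]), g_range[2])
  history <- list(g)
  if (growth_iters > 0 && !is.null(X_j)) {
    for (i in seq_len(growth_iters)) {
      tm <- solve_coupling(X_i, X_j, g = g, ...)
      realized <- rowSums(tm$plan)
      realized <- realized / mean(realized)   # relative mass change
      g <- pmin(pmax(realized^(1 / max(tm$days_gap, 1)), g_range[1]),
                g_range[2])
      history[[length(history) + 1]] <- g
    }
  }
  attr(g, "history") <- history
  g
}

#' Compose transport maps across ages
#'
#' Long-range couplings are the ordered matrix product of consecutive
#' maps. The product is kept raw (no renormalization); downstream fate
#' and ancestry formulas normalize where their definitions require it.
#'
#' @param maps ordered list of \code{transport_map}s or plain matrices.
#' @return composed \code{transport_map} (with \code{eps} etc. taken from
#'   the first map when available).
#' @export
compose_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  plans <- lapply(maps, function(m)
    if (inherits(m, "transport_map")) m$plan else as.matrix(m))
  for (i in seq_along(plans)[-1])
    if (ncol(plans[[i - 1]]) != nrow(plans[[i]]))
      stop("maps ", i - 1, " and ", i, " are not composable")
  plan <- Reduce(`%*%`, plans)
  first <- maps[[1]]
  meta <- if (inherits(first, "transport_map")) first else
    list(eps = NA, lam1 = NA, lam2 = NA, g = NULL, days_gap = NA,
         cost = NA, converged = NA, iterations = NA)
  structure(list(plan = plan, a = rowSums(plan), b = colSums(plan),
                 eps = meta$eps, lam1 = meta$lam1, lam2 = meta$lam2,
                 g = meta$g, days_gap = meta$days_gap, cost = meta$cost,
                 converged = meta$converged, iterations = meta$iterations),
            class = "transport_map")
}

#' Fate vectors: per-cell probabilities over terminal clusters
#'
#' Sums the (possibly composed) coupling over the cells of each terminal
#' cluster and normalizes per source cell, giving for every cell a
#' probability distribution over terminal types. Cells with zero total
#' transported mass receive a uniform fate with a warning.
#'
#' @param Pi a \code{transport_map} (or matrix) from the source age to
#'   the terminal age.
#' @param terminal_partition \code{cluster_partition} or integer vector
#'   over target cells.
#' @return object of class \code{fate_matrix}: cells x clusters matrix
#'   whose rows sum to 1; cluster ids in \code{colnames}.
#' @export
fate_vectors <- function(Pi, terminal_partition) {
  plan <- if (inherits(Pi, "transport_map")) Pi$plan else as.matrix(Pi)
  cl <- if (inherits(terminal_partition, "cluster_partition"))
    terminal_partition$cluster else terminal_partition
  stopifnot(length(cl) == ncol(plan))
  ok <- !is.na(cl)
  ids <- sort(unique(cl[ok]))
  F <- sapply(ids, function(k)
    rowSums(plan[, which(cl == k), drop = FALSE]))
  F <- matrix(F, nrow = nrow(plan))
  tot <- rowSums(F)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero transported mass; ",
            "assigned uniform fate")
    F[zero, ] <- 1 / length(ids)
    tot[zero] <- 1
  }
  F <- F / tot
  colnames(F) <- ids
  rownames(F) <- rownames(plan)
  structure(F, class = c("fate_matrix", "matrix"))
}

#' Ancestor or descendant distribution of a cluster
#'
#' For a cluster of cells at one end of a coupling, returns the normalized
#' distribution of its transported mass over the cells at the other end:
#' \code{direction = "ancestors"} treats the cluster as target columns and
#' distributes over source cells; \code{"descendants"} treats it as source
#' rows and distributes over target cells.
#'
#' @param Pi \code{transport_map} or matrix (earlier cells x later cells).
#' @param cluster_cells indices (or names) of the cluster's cells at the
#'   relevant end.
#' @param direction "ancestors" or "descendants".
#' @return probability vector over the other end's cells (sums to 1).
#' @export
ancestors_descendants <- function(Pi, cluster_cells,
                                  direction = c("ancestors",
                                                "descendants")) {
  direction <- match.arg(direction)
  plan <- if (inherits(Pi, "transport_map")) Pi$plan else as.matrix(Pi)
  v <- if (direction == "ancestors")
    rowSums(plan[, cluster_cells, drop = FALSE])
  else
    colSums(plan[cluster_cells, , drop = FALSE])
  s <- sum(v)
  if (s == 0) stop("cluster carries no transported mass")
  v / s
}

#' Multipotentiality potential of fate vectors
#'
#' Inverse participation ratio \eqn{P = 1/\sum_\beta f_\beta^2} of a fate
#' vector: 1 for a committed (point-mass) fate, up to the number of
#' terminal types for a maximally uncertain (uniform) fate.
#'
#' @param f a fate vector, or a \code{fate_matrix} / matrix of fate rows.
#' @return scalar, or one potential per row.
#' @export
potential <- function(f) {
  if (is.matrix(f)) return(1 / rowSums(unclass(f)^2))
  1 / sum(f^2)
}
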