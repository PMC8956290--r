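#' Signature score of a gene set per cell
#'
#' Mean of per-gene z-scored normalized log-expression over the set; a
#' rank-based alternative averages the per-gene expression ranks scaled
#' to [0, 1].
#'
#' @param X normalized log-expression (genes x cells).
#' @param gene_set character vector of gene ids; must intersect the
#'   matrix rows.
#' @param method "zscore" (default) or "rank".
#' @return numeric score per cell.
#' @export
signature_score <- function(X, gene_set, method = c("zscore", "rank")) {
  method <- match.arg(method)
  X <- .as_mat(X)
  genes <- intersect(gene_set, rownames(X))
  if (length(genes) == 0)
    stop("gene set has no genes in common with the matrix")
  sub <- as.matrix(X[genes, , drop = FALSE])
  if (method == "zscore") {
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd); sdv[sdv == 0] <- 1
    colMeans((sub - mu) / sdv)
  } else {
    colMeans(t(apply(sub, 1, rank)) / ncol(sub))
  }
}

#' Call putative ipsilateral and contralateral cells
#'
#' A cell is called I when its ipsilateral score lies more than
#' \code{k_sd} standard deviations above the mean across all cells AND
#' its contralateral score more than \code{k_sd} standard deviations
#' below the mean; C is symmetric. All other cells are unassigned (cells
#' that have not declared laterality, or express neither signature).
#'
#' @param ipsi_scores,contra_scores per-cell signature scores.
#' @param k_sd threshold in standard deviations (default 1.5).
#' @return object of class \code{signature_call}: list with \code{call}
#'   (factor I/C/unassigned per cell), the scores, and the thresholds
#'   used.
#' @export
call_laterality <- function(ipsi_scores, contra_scores, k_sd = 1.5) {
  stopifnot(length(ipsi_scores) == length(contra_scores))
  mi <- mean(ipsi_scores); si <- stats::sd(ipsi_scores)
  mc <- mean(contra_scores); sc <- stats::sd(contra_scores)
  is_i <- ipsi_scores > mi + k_sd * si & contra_scores < mc - k_sd * sc
  is_c <- contra_scores > mc + k_sd * sc & ipsi_scores < mi - k_sd * si
  call <- factor(ifelse(is_i, "I", ifelse(is_c, "C", "unassigned")),
                 levels = c("I", "C", "unassigned"))
  structure(list(call = call, ipsi_scores = ipsi_scores,
                 contra_scores = contra_scores, k_sd = k_sd,
                 thresholds = c(ipsi_hi = mi + k_sd * si,
                                ipsi_lo = mi - k_sd * si,
                                contra_hi = mc + k_sd * sc,
                                contra_lo = mc - k_sd * sc)),
            class = "signature_call")
}

#' @export
#' @method print signature_call
print.signature_call <- function(x, ...) {
  print(table(x$call))
  invisible(x)
}

#' Propagate ipsilateral cells to terminal types through transport maps
#'
#' Pushes the mass of the called I-cells forward through the (composed)
#' coupling to the terminal age and reports, per terminal type, the
#' fraction of that type's incoming mass that descends from I-cells.
#'
#' @param calls a \code{\link{call_laterality}} result (or logical/
#'   character vector marking I-cells) over the source cells.
#' @param Pi \code{transport_map} or matrix from the source age to the
#'   terminal age (compose consecutive maps first for long ranges).
#' @param terminal_partition cluster ids over the terminal cells.
#' @return data.frame per terminal type: \code{type}, \code{i_mass}
#'   (normalized descendant mass from I-cells; sums to 1 when any I-cell
#'   exists), \code{total_mass}, \code{i_fraction} (share of the type's
#'   mass that is I-derived).
#' @export
propagate_ipsi <- function(calls, Pi, terminal_partition) {
  is_i <- if (inherits(calls, "signature_call")) calls$call == "I"
          else if (is.character(calls) || is.factor(calls)) calls == "I"
          else as.logical(calls)
  plan <- if (inherits(Pi, "transport_map")) Pi$plan else as.matrix(Pi)
  cl <- if (inherits(terminal_partition, "cluster_partition"))
    terminal_partition$cluster else terminal_partition
  stopifnot(length(is_i) == nrow(plan), length(cl) == ncol(plan))
  ids <- sort(unique(cl[!is.na(cl)]))
  total <- vapply(ids, function(k)
    sum(plan[, which(cl == k), drop = FALSE]), numeric(1))
  i_mass <- vapply(ids, function(k)
    sum(plan[is_i, which(cl == k), drop = FALSE]), numeric(1))
  data.frame(type = ids,
             i_mass = if (sum(i_mass) > 0) i_mass / sum(i_mass) else
               rep(0, length(ids)),
             total_mass = total / sum(total),
             i_fraction = ifelse(total > 0, i_mass / total, 0))
}

#' Differential expression between I-cells and the rest at one age
#'
#' Wilcoxon rank-sum contrast of called (or propagated) ipsilateral cells
#' against all other cells, with fold change computed on linearized
#' expression (\eqn{e^X - 1} means) and Bonferroni correction over tested
#' genes. Significance requires fold change above \code{fc_thresh} (in
#' either direction) and corrected p below \code{p_thresh}.
#'
#' @param X normalized log-expression (genes x cells) at one age.
#' @param is_i logical vector marking I-cells (or a
#'   \code{signature_call}).
#' @param fc_thresh fold-change threshold (default 1.5).
#' @param p_thresh Bonferroni-corrected p threshold (default 5e-5).
#' @return data.frame: \code{gene}, \code{fold_change}, \code{p},
#'   \code{p_bonf}, \code{significant}.
#' @export
de_ipsi <- function(X, is_i, fc_thresh = 1.5, p_thresh = 5e-5) {
  X <- .as_mat(X)
  if (inherits(is_i, "signature_call")) is_i <- is_i$call == "I"
  stopifnot(length(is_i) == ncol(X))
  if (!any(is_i) || all(is_i))
    stop("need both I-cells and background cells")
  A <- as.matrix(X[, is_i, drop = FALSE])
  B <- as.matrix(X[, !is_i, drop = FALSE])
  lin_a <- rowMeans(expm1(A)); lin_b <- rowMeans(expm1(B))
  test <- lin_a > 0 | lin_b > 0
  eps <- 1e-9
  fc <- (lin_a + eps) / (lin_b + eps)
  fc <- pmax(fc, 1 / fc)                 # symmetric fold change >= 1
  p <- rep(NA_real_, nrow(X))
  for (g in which(test))
    p[g] <- suppressWarnings(
      stats::wilcox.test(A[g, ], B[g, ], exact = FALSE)$p.value)
  p[test & !is.finite(p)] <- 1
  p_bonf <- pmin(p * sum(test), 1)
  genes <- rownames(X)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(X)))
  out <- data.frame(gene = genes, fold_change = fc, p = p,
                    p_bonf = p_bonf, stringsAsFactors = FALSE)[test, ]
  out$significant <- out$fold_change > fc_thresh & out$p_bonf < p_thresh
  rownames(out) <- NULL
  out
}
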