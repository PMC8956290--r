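#' Fate-coupling matrix at one age
#'
#' The coupling \eqn{C(\alpha,\beta;t)} between two terminal types is the
#' Pearson correlation, across cells at age t, of their fate
#' probabilities. High coupling means the two fates reside in shared
#' precursors. Types whose fate column has zero variance get \code{NA}
#' (undefined, reported missing rather than 0).
#'
#' @param F cells x types fate matrix (\code{\link{fate_vectors}} result
#'   or plain matrix).
#' @return symmetric types x types matrix of class \code{coupling_matrix}
#'   with unit diagonal where defined; attribute \code{n_cells}.
#' @export
coupling_matrix <- function(F) {
  F <- unclass(F)
  sdv <- apply(F, 2, stats::sd)
  C <- suppressWarnings(stats::cor(F))
  C[sdv == 0, ] <- NA_real_
  C[, sdv == 0] <- NA_real_
  diag(C) <- ifelse(sdv > 0, 1, NA_real_)
  attr(C, "n_cells") <- nrow(F)
  class(C) <- c("coupling_matrix", "matrix")
  C
}

#' Randomization null for fate couplings
#'
#' Permutes every cell's fate vector independently across type labels,
#' recomputes all pairwise couplings, and repeats. This preserves each
#' cell's fate-probability multiset while destroying type identity, giving
#' a null for how large couplings can get by chance.
#'
#' @param F cells x types fate matrix.
#' @param n_perm number of permutations (must be positive).
#' @param seed integer seed.
#' @param quantile_probs per-pair null quantiles to report (default 0.95
#'   and 0.99).
#' @return list: \code{max_abs} (per-permutation maximum absolute
#'   off-diagonal coupling), \code{global_max}, \code{pair_quantiles}
#'   (types x types x quantile array), \code{n_perm}, \code{seed}.
#' @export
coupling_null <- function(F, n_perm = 100, seed = 1L,
                          quantile_probs = c(0.95, 0.99)) {
  if (n_perm <= 0) stop("n_perm must be positive")
  F <- unclass(F)
  n <- nrow(F); k <- ncol(F)
  set.seed(as.integer(seed))
  max_abs <- numeric(n_perm)
  acc <- array(NA_real_, dim = c(k, k, n_perm))
  off <- upper.tri(matrix(0, k, k))
  for (p in seq_len(n_perm)) {
    idx <- vapply(seq_len(n), function(i) sample.int(k), integer(k))
    Fp <- matrix(F[cbind(rep(seq_len(n), each = k), as.vector(idx))],
                 nrow = n, ncol = k, byrow = TRUE)
    Cp <- suppressWarnings(stats::cor(Fp))
    acc[, , p] <- Cp
    max_abs[p] <- max(abs(Cp[off]), na.rm = TRUE)
  }
  pq <- apply(acc, c(1, 2), stats::quantile, probs = quantile_probs,
              na.rm = TRUE)
  list(max_abs = max_abs, global_max = max(max_abs),
       pair_quantiles = aperm(pq, c(2, 3, 1)), n_perm = n_perm,
       seed = as.integer(seed))
}

#' Export a fate-coupling network as an edge list
#'
#' Keeps edges with coupling above the threshold (default 0.2, the level
#' the randomization null never exceeds). Optionally computes a 2-D
#' force-directed layout — intended to be computed once at the earliest
#' age and reused so node positions stay comparable across ages.
#'
#' @param C \code{coupling_matrix}.
#' @param threshold minimum edge weight retained (default 0.2).
#' @param layout_seed if non-NULL, integer seed for a force-directed
#'   (Fruchterman-Reingold) layout returned alongside the edges.
#' @param path optional TSV path for the edge list.
#' @return list: \code{edges} (data.frame type_a, type_b, weight) and
#'   \code{layout} (nodes x 2 matrix, or NULL).
#' @export
export_network <- function(C, threshold = 0.2, layout_seed = NULL,
                           path = NULL) {
  C <- unclass(C)
  k <- ncol(C)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  w <- C[ut]
  keep <- !is.na(w) & w > threshold
  edges <- data.frame(type_a = ut[keep, 1], type_b = ut[keep, 2],
                      weight = w[keep])
  layout <- NULL
  if (!is.null(layout_seed)) {
    g <- igraph::graph_from_data_frame(
      edges[, 1:2], directed = FALSE,
      vertices = data.frame(name = seq_len(k)))
    set.seed(as.integer(layout_seed))
    layout <- igraph::layout_with_fr(
      g, weights = if (nrow(edges)) edges$weight else NULL)
    rownames(layout) <- seq_len(k)
  }
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(edges = edges, layout = layout)
}

# logistic fit y = 1/(1+exp(b0+b1*t)) with jittered restarts; returns
# c(beta0, beta1, rss) or NAs on total failure
.fit_logistic_decay <- function(t, y, n_restarts = 10, seed = 1L) {
  yc <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  lin <- stats::lm(I(log(1 / yc - 1)) ~ t)
  start0 <- c(b0 = unname(stats::coef(lin)[1]),
              b1 = unname(stats::coef(lin)[2]))
  set.seed(as.integer(seed))
  best <- NULL; best_rss <- Inf
  for (r in seq_len(n_restarts)) {
    st <- if (r == 1) start0 else
      start0 * stats::runif(2, 0.5, 1.5) + stats::rnorm(2, sd = 0.5)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(b0 + b1 * t)),
                        start = list(b0 = unname(st[1]),
                                     b1 = unname(st[2])),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) return(c(beta0 = NA_real_, beta1 = NA_real_,
                              rss = NA_real_))
  co <- stats::coef(best)
  c(beta0 = unname(co[[1]]), beta1 = unname(co[[2]]), rss = best_rss)
}

#' Fit logistic decay curves to pairwise coupling time series
#'
#' Models each retained type pair's coupling as
#' \eqn{C(t) = 1/(1 + e^{\beta_0 + \beta_1 t})} over the observed ages
#' plus an anchor point \eqn{C = 0} at \code{terminal_t} (the fate is
#' fully resolved by then), so six data points constrain two parameters
#' on the default 5-age grid. Only pairs whose coupling at the first age
#' exceeds \code{min_first} (the null-derived visualization threshold)
#' are fitted; all-zero or all-missing series are skipped and logged.
#'
#' @param C_series either a list of types x types coupling matrices (one
#'   per age) or a pairs x ages numeric matrix.
#' @param t_grid ages in days matching \code{C_series} (default
#'   0, 1, 3, 6, 11).
#' @param terminal_t anchor age with zero coupling (default 36).
#' @param min_first retention threshold on the first-age coupling
#'   (default 0.2); set to \code{-Inf} to fit everything.
#' @param n_restarts random restarts per pair (default 10).
#' @param seed integer seed for the restarts.
#' @return data.frame: \code{type_a}, \code{type_b} (NA for matrix
#'   input), \code{beta0}, \code{beta1}, \code{rss}, \code{degenerate}
#'   (constant observed series or |beta1| below 1e-3: no decay
#'   detected).
#' @export
fit_coupling_decay <- function(C_series, t_grid = c(0, 1, 3, 6, 11),
                               terminal_t = 36, min_first = 0.2,
                               n_restarts = 10, seed = 1L) {
  if (is.list(C_series)) {
    k <- ncol(C_series[[1]])
    ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    series <- t(sapply(seq_len(nrow(ut)), function(r)
      vapply(C_series, function(C) unclass(C)[ut[r, 1], ut[r, 2]],
             numeric(1))))
    pairs <- ut
  } else {
    series <- as.matrix(C_series)
    pairs <- cbind(rep(NA_integer_, nrow(series)), NA_integer_)
  }
  stopifnot(ncol(series) == length(t_grid))
  out <- data.frame(type_a = pairs[, 1], type_b = pairs[, 2],
                    beta0 = NA_real_, beta1 = NA_real_, rss = NA_real_,
                    degenerate = NA)
  for (r in seq_len(nrow(series))) {
    y <- series[r, ]
    if (all(is.na(y)) || all(y == 0, na.rm = TRUE)) next
    if (!is.na(y[1]) && y[1] <= min_first) next
    tt <- c(t_grid[!is.na(y)], terminal_t)
    yy <- c(y[!is.na(y)], 0)
    fit <- .fit_logistic_decay(tt, yy, n_restarts, seed + r)
    out$beta0[r] <- fit["beta0"]
    out$beta1[r] <- fit["beta1"]
    out$rss[r] <- fit["rss"]
    # degenerate: no decay in the observed series (constant input) or a
    # flat fitted slope
    out$degenerate[r] <- stats::sd(y[!is.na(y)]) < 1e-8 ||
      (is.finite(fit["beta1"]) && abs(fit["beta1"]) < 1e-3)
  }
  out
}

#' Localization of a type's precursors across clusters
#'
#' Precursors of type \eqn{\beta} at an age are the cells whose fate
#' vector is maximized at \eqn{\beta} (ties broken toward the lowest type
#' index). With \eqn{p_k} the fraction of those precursors in cluster k
#' and N the cluster count, localization is
#' \eqn{1 - (1/\sum_k p_k^2)/N}: 0 when precursors spread uniformly,
#' \eqn{1 - 1/N} when they sit in a single cluster.
#'
#' @param F cells x types fate matrix at one age.
#' @param partition \code{cluster_partition} or integer vector over the
#'   same cells.
#' @param type_beta type (column) index.
#' @return scalar localization, or \code{NA} when the type has no
#'   precursors at this age.
#' @export
localization <- function(F, partition, type_beta) {
  F <- unclass(F)
  cl <- if (inherits(partition, "cluster_partition")) partition$cluster
        else partition
  stopifnot(length(cl) == nrow(F))
  ok <- !is.na(cl)
  F <- F[ok, , drop = FALSE]; cl <- cl[ok]
  ids <- sort(unique(cl))
  n_clusters <- length(ids)
  argmax <- max.col(F, ties.method = "first")
  prec <- which(argmax == type_beta)
  if (length(prec) == 0) return(NA_real_)
  p <- as.vector(table(factor(cl[prec], levels = ids))) / length(prec)
  1 - (1 / sum(p^2)) / n_clusters
}

#' Specification time from a localization time series
#'
#' Fits \eqn{Localization(t) = e^{\gamma_0+\gamma_1 t}/(1 +
#' e^{\gamma_0+\gamma_1 t})} to the observed localizations and returns
#' the earliest modeled time at which the fitted curve crosses the
#' specification line \eqn{y(t) = 0.95 (1 - 1/N(t))}, where the cluster
#' count N(t) is step-interpolated between the sampled ages. The step is
#' right-aligned (between two ages the upcoming age's count applies, and
#' beyond the last sampled age the terminal count when supplied): since
#' cluster number grows with age, holding the previous count would let
#' the rising fitted curve clear a stale, lower threshold and declare
#' types specified when no observation exceeds its own age's line. If
#' the curve never crosses by \code{terminal_t} the estimate is censored
#' there.
#'
#' @param localization_series localization values at the sampled ages
#'   (NA allowed; at least 3 usable points required).
#' @param N_series cluster counts at the sampled ages.
#' @param t_grid sampled ages in days.
#' @param terminal_t end of the modeled interval (default 36).
#' @param n_terminal optional cluster count at the terminal age, applied
#'   beyond the last sampled age (defaults to the last \code{N_series}
#'   value).
#' @param level threshold factor on the attainable maximum (default
#'   0.95).
#' @param resolution time step of the crossing search (default 0.01 d).
#' @param n_restarts,seed random restarts for the logistic fit.
#' @return list: \code{tau_sp}, \code{censored}, \code{gamma0},
#'   \code{gamma1}.
#' @export
specification_time <- function(localization_series, N_series, t_grid,
                               terminal_t = 36, n_terminal = NULL,
                               level = 0.95, resolution = 0.01,
                               n_restarts = 10, seed = 1L) {
  ok <- !is.na(localization_series)
  if (sum(ok) < 3) stop("need at least 3 usable localization values")
  t_obs <- t_grid[ok]
  y_obs <- localization_series[ok]
  # same machinery as the decay fit, with flipped sign convention
  fit <- .fit_logistic_decay(t_obs, 1 - y_obs, n_restarts, seed)
  if (!is.finite(fit["beta0"]))
    stop("logistic fit failed for localization series")
  g0 <- fit[["beta0"]]; g1 <- fit[["beta1"]]
  if (is.null(n_terminal)) n_terminal <- N_series[length(N_series)]
  n_fun <- stats::approxfun(c(t_grid, terminal_t),
                            c(N_series, n_terminal),
                            method = "constant", f = 1, rule = 2)
  # the fitted curve interpolates between observations, but a 2-parameter
  # logistic always saturates at 1 and can overshoot a series whose
  # plateau sits below the line; the observed values therefore gate the
  # call — a type is never declared specified before the last sampled age
  # at which its observed localization fell short of its own threshold
  ord <- order(t_obs)
  t_srt <- t_obs[ord]
  y_obs <- level * (1 - 1 / N_series[ok][ord])
  obs_cross <- which(localization_series[ok][ord] >= y_obs)
  search <- function(from, to) {
    tt <- seq(from, to, by = resolution)
    hit <- which(stats::plogis(g0 + g1 * tt) >=
                   level * (1 - 1 / n_fun(tt)))
    if (length(hit)) tt[hit[1]] else NA_real_
  }
  if (length(obs_cross)) {
    j <- obs_cross[1]
    l_srt <- localization_series[ok][ord]
    if (j == 1) {
      tau <- min(t_grid)
    } else {
      # refine within the bracketing interval by interpolating the
      # observed localization against the (step) threshold: the margin
      # below the line at the last failing age sets how far into the
      # interval the crossing lands
      y_at <- level * (1 - 1 / n_fun(t_srt[j] - resolution))
      gap_lo <- y_at - l_srt[j - 1]
      gap_hi <- l_srt[j] - y_obs[j]
      frac <- if (gap_lo + gap_hi <= 0) 1 else gap_lo / (gap_lo + gap_hi)
      tau <- t_srt[j - 1] + frac * (t_srt[j] - t_srt[j - 1])
    }
    list(tau_sp = tau, censored = FALSE, gamma0 = g0, gamma1 = g1)
  } else {
    tau <- search(t_srt[length(t_srt)], terminal_t)
    if (is.na(tau))
      list(tau_sp = terminal_t, censored = TRUE, gamma0 = g0,
           gamma1 = g1)
    else
      list(tau_sp = tau, censored = FALSE, gamma0 = g0, gamma1 = g1)
  }
}

#' Compare within- versus between-subclass fate couplings
#'
#' Splits the off-diagonal couplings by whether the two types share a
#' subclass and tests the difference with a two-sided t-test.
#'
#' @param C \code{coupling_matrix}.
#' @param subclass_labels subclass id per type.
#' @return list: \code{within}, \code{between} (the coupling values),
#'   \code{summary} (medians and IQRs), \code{t}, \code{p_value}.
#' @export
subclass_coupling_test <- function(C, subclass_labels) {
  C <- unclass(C)
  k <- ncol(C)
  stopifnot(length(subclass_labels) == k)
  if (length(unique(subclass_labels)) < 2)
    stop("need at least two subclasses")
  ut <- which(upper.tri(C), arr.ind = TRUE)
  w <- C[ut]
  same <- subclass_labels[ut[, 1]] == subclass_labels[ut[, 2]]
  within <- w[same & !is.na(w)]
  between <- w[!same & !is.na(w)]
  if (length(within) < 2 || length(between) < 2)
    stop("too few defined couplings for the test")
  tt <- stats::t.test(within, between)
  list(within = within, between = between,
       summary = data.frame(
         group = c("within", "between"),
         median = c(stats::median(within), stats::median(between)),
         iqr = c(stats::IQR(within), stats::IQR(between))),
       t = unname(tt$statistic), p_value = tt$p.value)
}
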