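#' Simulate per-cell ground-truth fate vectors along a fate tree
#'
#' Generates the planted ground truth for a synthetic time course. Each cell
#' is sampled at one age and carries a latent destined terminal type (a
#' root-to-leaf path through the tree, drawn with probability proportional
#' to clade sizes). Its fate vector is a product of per-node branch
#' probabilities: before a node's decoupling time both branches keep their
#' baseline (leaf-proportional) probabilities, so the vector is maximally
#' spread; after the node decouples, probability saturates toward the cell's
#' own branch at a rate set by \code{sharpness}. At the terminal age every
#' node is fully resolved and fate vectors are point masses.
#'
#' The commitment weight of node \eqn{v} at age \eqn{t} is
#' \eqn{w_v(t) = 1 - e^{-s (t - \tau_v)}} for \eqn{t > \tau_v} and 0 before,
#' with \eqn{s} = \code{sharpness} and \eqn{\tau_v} the node's decoupling
#' time; the branch probability toward the cell's chosen child is
#' \eqn{(1-w) p_0 + w} and toward the other child \eqn{(1-w)(1-p_0)}. In the
#' \code{sharpness} \eqn{\to 0} limit fate vectors stay uniform over types
#' at every pre-terminal age.
#'
#' Early precursor heterogeneity is largely unrelated to terminal fate:
#' each cell additionally expresses a Dirichlet-weighted mixture of
#' fate-orthogonal "maturation modules" (\code{n_early_modules} of them,
#' weights drawn independently of fate; concentration
#' \code{module_alpha}), scaled overall by the cell's residual fate
#' uncertainty \eqn{\min(1, H(f)/\log 2)} — any cell with an undecided
#' fate split expresses maturation structure fully, terminally committed
#' cells not at all. The module programs are age-specific: a transient
#' state at one age has no transcriptomic counterpart at the next, so
#' early clusters are fate-mixed, fuzzy, and inconsistent across ages
#' (the "nonspecified" regime), and type-specific clusters emerge only
#' as fates commit. The planted cluster label \code{true_state}
#' subdivides each resolved-state pool by dominant module while the
#' pool's mean module weight exceeds 0.5; afterwards it is the resolved
#' fate-tree state (the deepest ancestor whose commitment weight has
#' reached 0.5; leaves at the terminal age).
#'
#' @param tree a \code{\link{make_fate_tree}} result.
#' @param n_cells_per_age integer, cells sampled at each age (recycled
#'   across ages if length 1).
#' @param age_grid ages (days); defaults to the tree's grid.
#' @param sharpness positive rate (1/day) at which fate mass concentrates
#'   after decoupling.
#' @param n_batches batches (replicates) per age; cells are assigned at
#'   random.
#' @param n_early_modules count of transient fate-orthogonal expression
#'   modules per age (default 3).
#' @param module_alpha Dirichlet concentration of the per-cell module
#'   mixture (default 0.7; smaller = more discrete early states).
#' @param seed integer seed.
#'
#' @return Object of class \code{ground_truth}: list with \code{cells} (a
#'   data.frame: \code{cell_id}, \code{age}, \code{batch},
#'   \code{true_state} — planted cluster label, relabelled 1..K within
#'   age —, \code{early_module}, \code{module_weight} (per cell),
#'   \code{destined_type}, \code{lib_factor}, \code{laterality}),
#'   \code{fates} (cells x types matrix, rows sum to 1), \code{potential}
#'   (planted inverse participation ratio per cell), \code{tree},
#'   \code{age_grid}, \code{seed}.
#' @export
simulate_fates <- function(tree, n_cells_per_age, age_grid = tree$age_grid,
                           sharpness = 1.5, n_batches = 2L,
                           n_early_modules = 3L, module_alpha = 0.7,
                           seed = 1L) {
  stopifnot(inherits(tree, "fate_tree"), sharpness >= 0,
            n_early_modules >= 1,
            all(diff(age_grid) > 0))
  set.seed(as.integer(seed))
  n_ages <- length(age_grid)
  n_per <- rep_len(as.integer(n_cells_per_age), n_ages)
  n_types <- tree$n_types
  terminal_age <- age_grid[n_ages]
  half_commit <- log(2) / max(sharpness, 1e-12)  # days to w = 0.5

  base_p <- function(node, child) {
    tree$leaf_count[child] / tree$leaf_count[node]
  }

  total <- sum(n_per)
  fates <- matrix(0, total, n_types)
  age <- numeric(total)
  batch <- integer(total)
  state_node <- integer(total)
  destined <- integer(total)
  module_mix <- matrix(0, total, n_early_modules)

  idx <- 0L
  for (a in seq_len(n_ages)) {
    t <- age_grid[a]
    for (i in seq_len(n_per[a])) {
      idx <- idx + 1L
      age[idx] <- t
      batch[idx] <- sample.int(n_batches, 1L)
      mm <- stats::rgamma(n_early_modules, shape = module_alpha)
      module_mix[idx, ] <- mm / sum(mm)
      # draw the destined path: at each node pick a child by clade size
      chosen <- integer(length(tree$parent))  # chosen child per internal node
      node <- tree$root
      while (!is.null(tree$children[[node]])) {
        ch <- tree$children[[node]]
        pick <- ch[1 + (stats::runif(1) > base_p(node, ch[1]))]
        chosen[node] <- pick
        node <- pick
      }
      destined[idx] <- node
      # fate vector: product of branch probabilities along each leaf's path
      f <- numeric(n_types)
      assign_mass <- function(nd, mass) {
        if (is.null(tree$children[[nd]])) {
          f[nd] <<- mass
          return(invisible())
        }
        tau <- tree$decouple_time[nd]
        w <- if (t >= terminal_age) 1 else if (t > tau)
          1 - exp(-sharpness * (t - tau)) else 0
        for (ch in tree$children[[nd]]) {
          p0 <- base_p(nd, ch)
          # commitment applies only along the cell's own path; off-path
          # clades keep their baseline proportions
          p <- if (chosen[nd] == 0L) p0 else
            (1 - w) * p0 + w * (ch == chosen[nd])
          if (p > 0) assign_mass(ch, mass * p)
        }
      }
      assign_mass(tree$root, 1)
      fates[idx, ] <- f
      # occupied state: descend while commitment has reached half-maximum
      node <- tree$root
      while (!is.null(tree$children[[node]]) &&
             (t >= tree$decouple_time[node] + half_commit ||
                t >= terminal_age))
        node <- chosen[node]
      state_node[idx] <- node
    }
  }

  # per-cell module weight: residual fate uncertainty relative to one
  # binary decision — any cell with an undecided split keeps expressing
  # its maturation module; terminally committed cells shut it off
  ent <- apply(fates, 1, function(f) {
    f <- f[f > 0]; -sum(f * log(f))
  })
  module_weight <- pmin(1, ent / log(2))

  # planted cluster label: each resolved-state pool is subdivided by
  # dominant maturation module while the pool is still multipotent (mean
  # module weight > 0.5); committed pools cluster by state alone
  module <- max.col(module_mix, ties.method = "first")
  true_state <- integer(total)
  for (a in seq_len(n_ages)) {
    sel <- which(age == age_grid[a])
    key <- state_node[sel] * (n_early_modules + 1L)  # numeric label key
    for (s in unique(state_node[sel])) {
      in_pool <- state_node[sel] == s
      if (mean(module_weight[sel][in_pool]) > 0.5)
        key[in_pool] <- key[in_pool] + module[sel][in_pool]
    }
    true_state[sel] <- match(key, sort(unique(key)))
  }

  cells <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(total)),
    age = age, batch = batch, true_state = true_state,
    state_node = state_node, early_module = module,
    module_weight = module_weight, destined_type = destined,
    lib_factor = NA_real_, laterality = "none",
    stringsAsFactors = FALSE)

  structure(list(cells = cells, fates = fates,
                 potential = 1 / rowSums(fates^2),
                 module_mix = module_mix,
                 n_early_modules = as.integer(n_early_modules),
                 module_alpha = module_alpha,
                 tree = tree, age_grid = age_grid,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
#' @method print ground_truth
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$cells), "cells,", x$tree$n_types,
      "types, ages", paste(x$age_grid, collapse = "/"), "\n")
  tab <- tapply(x$cells$true_state, x$cells$age,
                function(s) length(unique(s)))
  cat("planted states per age:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Planted effective-state count per age
#' @param truth a \code{ground_truth}.
#' @return named integer vector, one entry per age.
#' @export
planted_state_counts <- function(truth) {
  vapply(split(truth$cells$true_state, truth$cells$age),
         function(s) length(unique(s)), integer(1))
}
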