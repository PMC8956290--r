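#' Build a random binary fate tree with planted decoupling times
#'
#' Constructs the branching structure used by the synthetic time-course
#' generator. Terminal types are organised into subclasses that form clades:
#' the tree first splits subclasses apart (early decoupling times), then
#' resolves types within each subclass (later times). Each internal node
#' carries a decoupling time, the age (in days) at which the fates of its two
#' descendant clades separate; times are non-decreasing from root to leaves,
#' so restriction is progressive and asynchronous.
#'
#' @param n_types number of terminal types (leaves), at least 2.
#' @param n_subclasses number of subclasses; each is a clade of consecutive
#'   types. Must not exceed \code{n_types}.
#' @param age_grid strictly increasing numeric vector of sampling ages in
#'   days. Decoupling times are placed in \code{[age_grid[1],
#'   age_grid[length(age_grid)-1]]}: everything is resolved before the
#'   terminal age.
#' @param decouple_spread standard deviation (days) of the jitter applied to
#'   depth-scheduled decoupling times.
#' @param seed integer seed; identical seeds give identical trees.
#'
#' @return An object of class \code{fate_tree}: a list with \code{n_types},
#'   \code{parent}, \code{children}, \code{decouple_time} (NA at leaves),
#'   \code{leaf_count}, \code{root}, \code{subclass} (length
#'   \code{n_types}), \code{age_grid} and \code{seed}. Leaves are nodes
#'   \code{1..n_types}; internal nodes follow.
#' @export
make_fate_tree <- function(n_types, n_subclasses = min(8L, n_types),
                           age_grid = c(0, 1, 3, 6, 11, 20),
                           decouple_spread = 1, seed = 1L) {
  stopifnot(n_types >= 2, length(age_grid) >= 2, all(diff(age_grid) > 0),
            decouple_spread >= 0)
  if (n_subclasses > n_types)
    stop("n_subclasses must not exceed n_types")
  set.seed(as.integer(seed))

  n_nodes <- 2L * n_types - 1L
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  decouple_time <- rep(NA_real_, n_nodes)

  # subclasses are clades over consecutive type blocks
  subclass <- rep(seq_len(n_subclasses),
                  times = diff(round(seq(0, n_types, length.out =
                                           n_subclasses + 1L))))

  # The tree is grown FROM its decoupling schedule: n-1 split times,
  # evenly spread (with jitter) over the pre-terminal age range, are
  # processed in order; each splits one randomly chosen unresolved pool.
  # Pools spanning several subclasses split along a subclass boundary
  # (so subclasses stay clades); single-subclass pools split at a random
  # point. Because the splitting pool is drawn uniformly at each event,
  # a type's final separation from its last sibling can fall anywhere in
  # the course - decoupling is progressive and asynchronous.
  t_min <- age_grid[1]
  t_pre <- age_grid[length(age_grid) - 1L]
  times <- seq(t_min, t_pre, length.out = n_types - 1L) +
    stats::rnorm(n_types - 1L, sd = decouple_spread)
  times <- sort(pmin(pmax(times, t_min), t_pre))
  times[1] <- t_min              # coarse structure visible at first age

  next_id <- n_types + 1L
  root <- next_id
  pools <- list(list(node = root, members = seq_len(n_types)))
  for (k in seq_len(n_types - 1L)) {
    pi <- if (length(pools) == 1L) 1L else sample(length(pools), 1L)
    pool <- pools[[pi]]
    pools[[pi]] <- NULL
    m <- pool$members
    decouple_time[pool$node] <- times[k]
    subs <- unique(subclass[m])
    if (length(subs) > 1L) {
      # split along a random subclass boundary
      b <- if (length(subs) == 2L) subs[1] else
        sample(subs[-length(subs)], 1L)
      left <- m[subclass[m] <= b]
    } else {
      left <- m[seq_len(if (length(m) == 2L) 1L else
        sample.int(length(m) - 1L, 1L))]
    }
    right <- setdiff(m, left)
    kids <- integer(2)
    for (side in 1:2) {
      part <- if (side == 1) left else right
      if (length(part) == 1L) {
        kids[side] <- part
      } else {
        next_id <- next_id + 1L
        kids[side] <- next_id
        pools[[length(pools) + 1L]] <- list(node = next_id,
                                            members = part)
      }
    }
    children[[pool$node]] <- kids
    parent[kids] <- pool$node
  }

  # depths and leaf counts
  depth <- rep(NA_real_, n_nodes)
  leaf_count <- integer(n_nodes)
  walk <- function(node, d) {
    depth[node] <<- d
    if (is.null(children[[node]])) {
      leaf_count[node] <<- 1L
      return(1L)
    }
    n <- sum(vapply(children[[node]], function(ch) walk(ch, d + 1),
                    integer(1)))
    leaf_count[node] <<- n
    n
  }
  walk(root, 0)


  structure(list(n_types = as.integer(n_types), parent = parent,
                 children = children, decouple_time = decouple_time,
                 leaf_count = leaf_count, depth = depth, root = root,
                 subclass = subclass, age_grid = age_grid,
                 seed = as.integer(seed)),
            class = "fate_tree")
}

#' @export
#' @method print fate_tree
print.fate_tree <- function(x, ...) {
  cat("fate_tree:", x$n_types, "terminal types,",
      length(unique(x$subclass)), "subclasses\n")
  cat("decouple times:",
      paste(round(sort(x$decouple_time[!is.na(x$decouple_time)]), 2),
            collapse = " "), "\n")
  invisible(x)
}

#' Internal nodes of a fate tree
#' @param tree a \code{fate_tree}.
#' @return integer vector of internal node ids.
#' @keywords internal
tree_internal_nodes <- function(tree) {
  which(!vapply(tree$children, is.null, logical(1)))
}

#' Path from the root to a leaf
#' @keywords internal
tree_path <- function(tree, leaf) {
  path <- leaf
  while (!is.na(tree$parent[path[1]])) path <- c(tree$parent[path[1]], path)
  path
}

#' Planted decoupling time per terminal type
#'
#' The age at which a type's fate separates from its last sibling, i.e. the
#' decoupling time of its immediate parent node. This is the planted
#' analogue of a specification time: after it, no other fate shares the
#' type's branch.
#'
#' @param tree a \code{fate_tree}.
#' @return numeric vector of length \code{n_types}.
#' @export
type_decouple_times <- function(tree) {
  vapply(seq_len(tree$n_types),
         function(l) tree$decouple_time[tree$parent[l]], numeric(1))
}
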