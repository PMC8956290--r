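#' Default pipeline configuration
#'
#' All numeric defaults of the workflow in one overridable list; the
#' configuration is echoed into every run's output manifest.
#'
#' @param ... name = value overrides for any entry.
#' @return named list of parameters: filtering (\code{min_genes_per_cell}
#'   700, \code{min_cells_per_gene} 10), HVG \code{z_factor} 0.8,
#'   clustering (\code{n_neighbors} 30, \code{resolution} 0.5,
#'   \code{min_de} 10), DE thresholds (\code{logfc_thresh} 0.5,
#'   \code{p_thresh} 1e-5), classifier protocol (\code{train_frac} 0.6,
#'   \code{train_cap} 300, \code{max_cluster_error} 0.1, \code{top_n}
#'   500, \code{split_frac} 0.5), transport (\code{eps} 0.005,
#'   \code{lam1} 1, \code{lam2} 50, \code{growth_iters} 3), couplings
#'   (\code{coupling_threshold} 0.2, \code{decay_terminal_t} 36),
#'   specification (\code{spec_level} 0.95), laterality (\code{k_sd}
#'   1.5, \code{fc_thresh} 1.5, \code{bonf_thresh} 5e-5), and the
#'   age-to-day map \code{age_days} (E13/E14/E16/P0/P5/P56 =
#'   0/1/3/6/11/20).
#' @export
default_config <- function(...) {
  cfg <- list(
    min_genes_per_cell = 700, min_cells_per_gene = 10,
    z_factor = 0.8,
    n_neighbors = 30, resolution = 0.5, min_de = 10,
    logfc_thresh = 0.5, p_thresh = 1e-5,
    train_frac = 0.6, train_cap = 300, max_cluster_error = 0.1,
    top_n = 500, split_frac = 0.5,
    eps = 0.005, lam1 = 1, lam2 = 50, growth_iters = 3,
    coupling_threshold = 0.2, decay_terminal_t = 36,
    spec_level = 0.95,
    k_sd = 1.5, fc_thresh = 1.5, bonf_thresh = 5e-5,
    age_days = c(E13 = 0, E14 = 1, E16 = 3, P0 = 6, P5 = 11, P56 = 20),
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full time-course analysis on one dataset
#'
#' Chains every stage of the workflow: filtering and normalization,
#' Gamma-Poisson HVG selection, per-age embedding and graph clustering
#' (with DE-driven merge refinement), consecutive-age entropic transport
#' maps, long-range composition to the terminal age, fate vectors and
#' potentials, fate couplings with a randomization null, cross-age
#' cluster correspondence, and specification times. Intended for
#' synthetic data (where planted truth enables validation) or any
#' dataset in the same layout.
#'
#' @param sim a \code{\link{synth_timecourse}} result, or a list with
#'   \code{counts} (genes x cells) and \code{cells} (data.frame with
#'   \code{age} and \code{batch}).
#' @param config a \code{\link{default_config}} list.
#' @param partition_source "cluster" (run the clustering stages) or
#'   "truth" (use the planted states; synthetic data only) for the
#'   per-age partitions used downstream.
#' @param min_genes_per_cell,min_cells_per_gene optional filter
#'   overrides (defaults from \code{config}; synthetic data uses smaller
#'   panels than real data, so drivers typically lower the cell
#'   threshold).
#' @param stages character subset of
#'   \code{c("cluster", "transport", "fates", "xmap")} to run after
#'   preprocessing.
#' @return list of class \code{timecourse_run} with \code{config},
#'   \code{ages}, \code{hvg}, \code{X} (normalized log matrix),
#'   \code{cells}, per-age \code{partitions} / \code{embeddings} /
#'   \code{diversity}, \code{maps} (consecutive couplings),
#'   \code{fates} (per pre-terminal age), \code{potentials},
#'   \code{couplings}, \code{null}, \code{xmap} (consecutive-age
#'   confusion tables with ARI/NCE), \code{specification} (per-type tau
#'   estimates), and \code{terminal_types} (terminal partition).
#' @export
run_timecourse <- function(sim, config = default_config(),
                           partition_source = c("cluster", "truth"),
                           min_genes_per_cell = config$min_genes_per_cell,
                           min_cells_per_gene = config$min_cells_per_gene,
                           stages = c("cluster", "transport", "fates",
                                      "xmap")) {
  partition_source <- match.arg(partition_source)
  counts <- sim$counts
  cells <- sim$cells
  stopifnot(!is.null(counts), !is.null(cells), ncol(counts) == nrow(cells))

  C <- filter_cells_genes(counts, min_genes_per_cell, min_cells_per_gene)
  cells <- cells[match(colnames(C), cells$cell_id), ]
  norm <- normalize_log(C)
  hvg <- select_hvgs(C, z_factor = config$z_factor)
  hvg_genes <- hvg$table$gene[hvg$table$selected]
  Xh <- norm$X[hvg_genes, , drop = FALSE]

  ages <- sort(unique(cells$age))
  n_ages <- length(ages)
  by_age <- lapply(ages, function(a) which(cells$age == a))
  names(by_age) <- ages

  out <- list(config = config, ages = ages, hvg = hvg, X = norm,
              X_hvg = Xh, cells = cells)

  ## per-age partitions (and embeddings when clustering)
  partitions <- vector("list", n_ages)
  embeddings <- vector("list", n_ages)
  if (partition_source == "truth") {
    for (i in seq_len(n_ages))
      partitions[[i]] <- new_partition(cells$true_state[by_age[[i]]],
                                       age = ages[i], relabel = FALSE)
  } else if ("cluster" %in% stages) {
    for (i in seq_len(n_ages)) {
      idx <- by_age[[i]]
      Xa <- Xh[, idx, drop = FALSE]
      k <- max(2L, min(choose_dim_rmt(Xa), 20L))
      emb <- embed_cells(Xa, batches = cells$batch[idx], k = k,
                         seed = config$seed)
      # a neighbourhood larger than the smallest real cluster forcibly
      # merges types; cap it relative to the age's sample size
      k_nn <- min(config$n_neighbors,
                  max(5L, floor(length(idx) / 15)))
      part <- graph_cluster(emb, n_neighbors = k_nn,
                            resolution = config$resolution,
                            seed = config$seed)
      part <- refine_partition(part, Xa, embedding = emb,
                               min_de = config$min_de,
                               logfc_thresh = config$logfc_thresh,
                               p_thresh = config$p_thresh)
      part$age <- ages[i]
      partitions[[i]] <- part
      embeddings[[i]] <- emb
    }
  }
  names(partitions) <- ages
  out$partitions <- partitions
  out$embeddings <- embeddings
  if (!is.null(partitions[[n_ages]]))
    out$terminal_types <- partitions[[n_ages]]

  if (!is.null(partitions[[1]])) {
    out$diversity <- lapply(seq_len(n_ages), function(i) {
      idx <- by_age[[i]]
      diversity_report(Xh[, idx, drop = FALSE], partitions[[i]],
                       E = embeddings[[i]], age = ages[i],
                       seed = config$seed)
    })
    names(out$diversity) <- ages
  }

  ## consecutive-age transport maps and composed fates
  if ("transport" %in% stages) {
    maps <- vector("list", n_ages - 1L)
    for (i in seq_len(n_ages - 1L)) {
      gap <- ages[i + 1L] - ages[i]
      maps[[i]] <- solve_coupling(Xh[, by_age[[i]], drop = FALSE],
                                  Xh[, by_age[[i + 1L]], drop = FALSE],
                                  eps = config$eps, lam1 = config$lam1,
                                  lam2 = config$lam2, days_gap = gap)
    }
    names(maps) <- paste(ages[-n_ages], ages[-1], sep = "->")
    out$maps <- maps

    term_part <- out$terminal_types
    if (!is.null(term_part)) {
      fates <- vector("list", n_ages - 1L)
      long <- NULL
      for (i in rev(seq_len(n_ages - 1L))) {
        long <- if (is.null(long)) maps[[i]]$plan else
          maps[[i]]$plan %*% long
        fates[[i]] <- fate_vectors(long, term_part)
      }
      names(fates) <- ages[-n_ages]
      out$fates <- fates
      out$potentials <- lapply(fates, potential)
    }
  }

  ## couplings, null threshold, specification times
  if ("fates" %in% stages && !is.null(out$fates)) {
    out$couplings <- lapply(out$fates, coupling_matrix)
    out$null <- coupling_null(out$fates[[1]], n_perm = 100,
                              seed = config$seed)
    n_types_term <- ncol(out$fates[[1]])
    n_series <- vapply(partitions[-n_ages], function(p) p$n_clusters,
                       integer(1))
    t_grid <- ages[-n_ages]
    spec <- lapply(seq_len(n_types_term), function(b) {
      loc <- vapply(seq_len(n_ages - 1L), function(i)
        localization(out$fates[[i]], partitions[[i]], b), numeric(1))
      if (sum(!is.na(loc)) < 3)
        return(list(tau_sp = NA_real_, censored = NA, gamma0 = NA,
                    gamma1 = NA, localization = loc))
      st <- specification_time(loc, n_series, t_grid,
                               terminal_t = config$decay_terminal_t,
                               n_terminal = out$terminal_types$n_clusters,
                               level = config$spec_level,
                               seed = config$seed)
      st$localization <- loc
      st
    })
    out$specification <- data.frame(
      type = seq_len(n_types_term),
      tau_sp = vapply(spec, function(s) s$tau_sp, numeric(1)),
      censored = vapply(spec, function(s) isTRUE(s$censored), logical(1)))
    out$localization <- t(vapply(spec, function(s) s$localization,
                                 numeric(n_ages - 1L)))
  }

  ## consecutive-age supervised correspondence
  if ("xmap" %in% stages && !is.null(partitions[[1]])) {
    xm <- vector("list", n_ages - 1L)
    for (i in seq_len(n_ages - 1L)) {
      ref <- i + 1L; test <- i
      xm[[i]] <- tryCatch(
        map_clusters(Xh[, by_age[[ref]], drop = FALSE],
                     partitions[[ref]],
                     Xh[, by_age[[test]], drop = FALSE],
                     partitions[[test]],
                     seed = config$seed, top_n = config$top_n),
        error = function(e) e)
    }
    names(xm) <- paste(ages[-1], "<-", ages[-n_ages])
    out$xmap <- xm
  }

  class(out) <- "timecourse_run"
  out
}

#' @export
#' @method print timecourse_run
print.timecourse_run <- function(x, ...) {
  cat("timecourse_run over ages:", paste(x$ages, collapse = " "), "\n")
  if (!is.null(x$partitions[[1]]))
    cat("clusters per age:",
        paste(vapply(x$partitions, function(p) p$n_clusters, integer(1)),
              collapse = " "), "\n")
  if (!is.null(x$potentials))
    cat("mean potential per age:",
        paste(round(vapply(x$potentials, mean, numeric(1)), 2),
              collapse = " "), "\n")
  invisible(x)
}

#' Write the main tables of a run to a directory
#'
#' Emits hvg.tsv, clusters.tsv, diversity.tsv, potentials.tsv,
#' couplings_<age>.tsv, confusion_<pair>.tsv, tau_sp.tsv, the coupling
#' network edge list at the earliest age, and a JSON-like manifest of the
#' configuration and seeds.
#'
#' @param run a \code{timecourse_run}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$hvg$table, "hvg.tsv")
  if (!is.null(run$partitions[[1]]))
    wt(data.frame(cell_id = run$cells$cell_id, age = run$cells$age,
                  cluster = unlist(lapply(run$ages, function(a)
                    run$partitions[[as.character(a)]]$cluster))),
       "clusters.tsv")
  if (!is.null(run$diversity))
    wt(do.call(rbind, lapply(run$diversity, function(d)
      data.frame(age = d$age, rao = d$rao, shannon = d$shannon,
                 simpson = d$simpson,
                 classifier_error = d$classifier_error,
                 relative_diameter = d$relative_diameter))),
      "diversity.tsv")
  if (!is.null(run$potentials))
    wt(data.frame(age = rep(as.numeric(names(run$potentials)),
                            lengths(run$potentials)),
                  potential = unlist(run$potentials)), "potentials.tsv")
  if (!is.null(run$couplings)) {
    for (a in names(run$couplings))
      utils::write.table(unclass(run$couplings[[a]]),
                         file.path(dir, paste0("couplings_", a, ".tsv")),
                         sep = "\t", quote = FALSE)
    net <- export_network(run$couplings[[1]],
                          threshold = run$config$coupling_threshold)
    wt(net$edges, "network_edges.tsv")
  }
  if (!is.null(run$specification)) wt(run$specification, "tau_sp.tsv")
  if (!is.null(run$xmap)) {
    for (nm in names(run$xmap))
      if (inherits(run$xmap[[nm]], "confusion_table"))
        utils::write.table(run$xmap[[nm]]$N,
                           file.path(dir, paste0(
                             "confusion_", gsub("[^0-9A-Za-z]+", "_", nm),
                             ".tsv")), sep = "\t", quote = FALSE)
  }
  manifest <- c(
    sprintf("seed\t%s", run$config$seed),
    sprintf("%s\t%s", names(run$config),
            vapply(run$config, function(v) paste(v, collapse = ","),
                   character(1))))
  writeLines(manifest, file.path(dir, "run_manifest.tsv"))
  invisible(dir)
}
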