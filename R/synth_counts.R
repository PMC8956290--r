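#' Simulate UMI counts from planted fates
#'
#' Draws a sparse genes x cells count matrix whose technical noise matches a
#' Gamma-Poisson model: each cell has a library-size factor drawn from a
#' Gamma distribution with shape \code{libsize_shape} (mean 1), and counts
#' are Poisson given the cell's rate vector. Biological structure enters
#' through gene programs: every terminal type owns a block of
#' \code{programs_per_type} genes, and a cell's expected expression is the
#' fate-weighted mixture of type programs plus a shared maturation program
#' for its age plus the cell's transient early-module program (weighted by
#' the module decay recorded in the truth). Program activity fluctuates
#' per cell (Gamma-distributed, unit mean, shape \code{program_shape}), so
#' program genes are genuinely overdispersed relative to the Gamma-Poisson
#' null while background genes are not — making highly-variable-gene
#' recovery testable.
#'
#' @param truth a \code{\link{simulate_fates}} result; its \code{cells}
#'   table gains the drawn \code{lib_factor}.
#' @param n_genes total genes; must accommodate all program blocks.
#' @param programs_per_type genes per terminal-type program (and per
#'   maturation program).
#' @param batch_effect_sd sd of log-normal batch shifts applied, per
#'   (age, batch) replicate, to a random 10\% gene subset. 0 disables.
#' @param libsize_shape Gamma shape of library-size factors.
#' @param mean_depth expected UMI per cell at library factor 1.
#' @param program_amp expression amplitude of program genes relative to the
#'   mean background rate.
#' @param program_shape Gamma shape of per-cell program activity (smaller =
#'   more overdispersion in program genes).
#' @param seed integer seed.
#'
#' @return list of class \code{synth_counts}: \code{counts} (a
#'   \code{dgCMatrix}, genes x cells), \code{gene_ids}, \code{cells} (the
#'   updated truth table), \code{program_genes} (list: per-type and
#'   maturation gene index blocks), \code{params}.
#' @export
simulate_counts <- function(truth, n_genes = 1000L, programs_per_type = 20L,
                            batch_effect_sd = 0, libsize_shape = 3,
                            mean_depth = 2000, program_amp = 8,
                            program_shape = 2, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), libsize_shape > 0,
            mean_depth > 0, program_amp > 0, program_shape > 0)
  set.seed(as.integer(seed))
  n_types <- truth$tree$n_types
  ages <- truth$age_grid
  n_modules <- if (is.null(truth$n_early_modules)) 0L else
    truth$n_early_modules
  n_prog <- (n_types + length(ages) +
               length(ages) * n_modules) * programs_per_type
  if (n_genes < n_prog)
    stop("n_genes (", n_genes, ") smaller than total program genes (",
         n_prog, ")")

  n_cells <- nrow(truth$cells)
  cells <- truth$cells
  cells$lib_factor <- stats::rgamma(n_cells, shape = libsize_shape,
                                    rate = libsize_shape)

  # gene blocks: type programs, then one maturation program per age,
  # then background
  type_prog <- lapply(seq_len(n_types), function(b)
    ((b - 1L) * programs_per_type + 1L):(b * programs_per_type))
  off <- n_types * programs_per_type
  mat_prog <- lapply(seq_along(ages), function(a)
    (off + (a - 1L) * programs_per_type + 1L):(off + a * programs_per_type))
  # module programs are age-specific: block (a, m) is expressed only by
  # cells at age a with weight on module m
  off2 <- off + length(ages) * programs_per_type
  mod_prog <- if (n_modules > 0) lapply(seq_along(ages), function(a)
    lapply(seq_len(n_modules), function(m) {
      o <- off2 + ((a - 1L) * n_modules + (m - 1L)) * programs_per_type
      (o + 1L):(o + programs_per_type)
    })) else list()
  background <- (off2 + length(ages) * n_modules * programs_per_type +
                   1L):n_genes

  base_rate <- stats::rexp(n_genes, rate = 1)
  base_rate <- base_rate / mean(base_rate)           # mean 1
  amp <- program_amp

  # per-(age,batch) multiplicative shifts on a random 10% of genes
  batch_mult <- list()
  if (batch_effect_sd > 0) {
    for (key in unique(paste(cells$age, cells$batch))) {
      m <- rep(1, n_genes)
      hit <- sample.int(n_genes, max(1L, round(0.1 * n_genes)))
      m[hit] <- exp(stats::rnorm(length(hit), sd = batch_effect_sd))
      batch_mult[[key]] <- m
    }
  }

  rate <- matrix(rep(base_rate, n_cells), n_genes, n_cells)
  age_index <- match(cells$age, ages)
  for (u in seq_len(n_cells)) {
    f <- truth$fates[u, ]
    act <- stats::rgamma(n_types, shape = program_shape,
                         rate = program_shape)
    for (b in which(f > 1e-8))
      rate[type_prog[[b]], u] <- rate[type_prog[[b]], u] +
        amp * f[b] * act[b]
    m_act <- stats::rgamma(1, shape = program_shape, rate = program_shape)
    rate[mat_prog[[age_index[u]]], u] <-
      rate[mat_prog[[age_index[u]]], u] + amp * m_act
    if (n_modules > 0) {
      mw <- cells$module_weight[u]
      if (mw > 0.01) {
        mix <- truth$module_mix[u, ]
        blocks <- mod_prog[[age_index[u]]]
        for (m in which(mix > 0.02)) {
          mod_act <- stats::rgamma(1, shape = program_shape,
                                   rate = program_shape)
          rate[blocks[[m]], u] <- rate[blocks[[m]], u] +
            amp * mw * mix[m] * mod_act
        }
      }
    }
    if (batch_effect_sd > 0) {
      key <- paste(cells$age[u], cells$batch[u])
      rate[, u] <- rate[, u] * batch_mult[[key]]
    }
  }
  rate <- sweep(rate, 2, colSums(rate), "/")
  lambda <- sweep(rate, 2, cells$lib_factor * mean_depth, "*")
  counts <- matrix(stats::rpois(length(lambda), lambda), n_genes, n_cells)

  gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  for (b in seq_len(n_types))
    gene_ids[type_prog[[b]]] <- sprintf("Type%02dProg%02d", b,
                                        seq_len(programs_per_type))
  for (a in seq_along(ages))
    gene_ids[mat_prog[[a]]] <- sprintf("MatAge%02dProg%02d", a,
                                       seq_len(programs_per_type))
  for (a in seq_along(mod_prog))
    for (m in seq_along(mod_prog[[a]]))
      gene_ids[mod_prog[[a]][[m]]] <-
        sprintf("Age%02dMod%02dProg%02d", a, m,
                seq_len(programs_per_type))

  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(gene_ids, cells$cell_id)

  structure(list(counts = counts, gene_ids = gene_ids, cells = cells,
                 program_genes = list(type = type_prog, maturation = mat_prog,
                                      module = mod_prog,
                                      background = background),
                 params = list(n_genes = n_genes,
                               programs_per_type = programs_per_type,
                               batch_effect_sd = batch_effect_sd,
                               libsize_shape = libsize_shape,
                               mean_depth = mean_depth,
                               program_amp = program_amp,
                               program_shape = program_shape,
                               seed = as.integer(seed))),
            class = "synth_counts")
}

#' Plant an ipsilateral/contralateral signature into synthetic counts
#'
#' Emulates an early, transient laterality program: a small fraction of
#' early-age cells (the planted ipsilateral lineage, restricted to the
#' terminal types in \code{il_types}) overexpresses the ipsilateral gene
#' set and suppresses the contralateral one; a larger fraction of the
#' remaining early cells carries the mirror-image contralateral signature,
#' so the two scores are anticorrelated and mutually exclusive. The
#' signature is present only at ages up to \code{fade_age}; later ages show
#' no laterality signal. Labels are recorded in the cell table and are
#' consistent with the planted fates (ipsilateral cells are destined to
#' \code{il_types}).
#'
#' @param truth the \code{ground_truth} the counts were simulated from.
#' @param sim a \code{\link{simulate_counts}} result.
#' @param frac_ipsi target fraction of early-age cells labelled ipsilateral
#'   (I); must lie in (0, 0.5).
#' @param ipsi_genes,contra_genes disjoint character vectors of gene ids
#'   (or integer indices) carrying the two signatures.
#' @param fade_age ages strictly greater than this carry no signal.
#' @param il_types terminal types forming the ipsilateral lineage; default
#'   the first subclass clade.
#' @param frac_contra fraction of early cells labelled contralateral
#'   (default 0.8: contralateral is the majority default identity, and a
#'   broadly expressed contralateral signature is what makes the
#'   two-sided SD call rule attainable — the score floor of a cell with
#'   zero signature counts only clears "1.5 SD below the mean" when the
#'   mean is carried by a majority).
#' @param boost mean extra UMI per signature gene in a signature-positive
#'   cell (scaled by the cell's library factor).
#' @param seed integer seed.
#'
#' @return \code{sim} with modified \code{counts}, updated \code{cells}
#'   (column \code{laterality} in \{"I","C","none"\}), and a
#'   \code{laterality} element recording gene sets, \code{il_types} and
#'   \code{fade_age}.
#' @export
plant_laterality <- function(truth, sim, frac_ipsi = 0.1,
                             ipsi_genes, contra_genes, fade_age,
                             il_types = which(truth$tree$subclass == 1L),
                             frac_contra = 0.8, boost = 5, seed = 1L) {
  stopifnot(inherits(sim, "synth_counts"), frac_ipsi > 0, frac_ipsi < 0.5)
  set.seed(as.integer(seed))
  counts <- sim$counts
  if (is.character(ipsi_genes)) ipsi_genes <- match(ipsi_genes, rownames(counts))
  if (is.character(contra_genes)) contra_genes <- match(contra_genes, rownames(counts))
  if (anyNA(ipsi_genes) || anyNA(contra_genes))
    stop("signature genes not found in count matrix")
  if (length(intersect(ipsi_genes, contra_genes)) > 0)
    stop("ipsi and contra gene sets must be disjoint")

  cells <- sim$cells
  early <- which(cells$age <= fade_age)
  if (length(early) == 0) stop("no cells at or before fade_age")

  il_pool <- early[cells$destined_type[early] %in% il_types]
  n_i <- min(length(il_pool), round(frac_ipsi * length(early)))
  i_cells <- sample(il_pool, n_i)
  c_pool <- setdiff(early, i_cells)
  n_c <- min(length(c_pool), round(frac_contra * length(early)))
  c_cells <- sample(c_pool, n_c)

  counts <- as.matrix(counts)
  bump <- function(cols, genes) {
    lam <- outer(rep(boost, length(genes)), cells$lib_factor[cols])
    counts[genes, cols] <<- counts[genes, cols] +
      stats::rpois(length(lam), lam)
  }
  thin <- function(cols, genes) {
    x <- counts[genes, cols]
    counts[genes, cols] <<- stats::rbinom(length(x), as.vector(x), 0.02)
  }
  bump(i_cells, ipsi_genes);  thin(i_cells, contra_genes)
  bump(c_cells, contra_genes); thin(c_cells, ipsi_genes)

  cells$laterality <- "none"
  cells$laterality[i_cells] <- "I"
  cells$laterality[c_cells] <- "C"

  sim$counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix")
  dimnames(sim$counts) <- list(sim$gene_ids, cells$cell_id)
  sim$cells <- cells
  sim$laterality <- list(ipsi_genes = rownames(sim$counts)[ipsi_genes],
                         contra_genes = rownames(sim$counts)[contra_genes],
                         il_types = il_types, fade_age = fade_age,
                         frac_ipsi = frac_ipsi, seed = as.integer(seed))
  sim
}

#' One-call synthetic time course with planted ground truth
#'
#' Convenience wrapper chaining \code{\link{make_fate_tree}},
#' \code{\link{simulate_fates}}, \code{\link{simulate_counts}} and
#' (optionally) \code{\link{plant_laterality}} under a single seed. The
#' defaults define the study conditions used throughout the package's
#' validation: a 5-age course (days 0, 1, 3, 6, 11) plus terminal day 20,
#' types organised in subclass clades, Gamma-Poisson counts with broad
#' library variation, and replicate batches within age.
#'
#' @param n_types,n_subclasses,age_grid,decouple_spread tree parameters.
#' @param n_cells_per_age,sharpness,n_batches fate-simulation parameters.
#' @param n_cells_terminal terminal-age sample size (default twice the
#'   developmental ages: the adult reference is the largest sample).
#' @param n_genes,programs_per_type,batch_effect_sd,libsize_shape count
#'   parameters.
#' @param laterality logical; plant the ipsi/contra module?
#' @param frac_ipsi,fade_age laterality parameters (defaults: 10\% of
#'   cells; the signature is expressed through day 3 — the third
#'   sampled age — and silent afterwards).
#' @param seed master integer seed; all stages derive from it.
#' @return a \code{synth_counts} list, augmented with \code{truth}.
#' @export
synth_timecourse <- function(n_types = 12L, n_subclasses = 4L,
                             age_grid = c(0, 1, 3, 6, 11, 20),
                             decouple_spread = 0.5,
                             n_cells_per_age = 300L,
                             n_cells_terminal = 2L * n_cells_per_age,
                             sharpness = 1.5,
                             n_batches = 2L, n_genes = 800L,
                             programs_per_type = 15L, batch_effect_sd = 0.1,
                             libsize_shape = 3, laterality = FALSE,
                             frac_ipsi = 0.1, fade_age = age_grid[3],
                             seed = 1L) {
  seed <- as.integer(seed)
  tree <- make_fate_tree(n_types, n_subclasses, age_grid, decouple_spread,
                         seed = seed)
  n_cells <- c(rep_len(n_cells_per_age, length(age_grid) - 1L),
               n_cells_terminal)
  truth <- simulate_fates(tree, n_cells, age_grid, sharpness,
                          n_batches, seed = seed + 1L)
  sim <- simulate_counts(truth, n_genes, programs_per_type, batch_effect_sd,
                         libsize_shape, seed = seed + 2L)
  if (laterality) {
    bg <- grep("^Gene", rownames(sim$counts), value = TRUE)
    ip <- utils::tail(bg, 16)[1:8]
    co <- utils::tail(bg, 8)
    # the ipsilateral lineage is the earliest-specified subclass: its
    # types resolve while the signature is still expressed, so the
    # lineage remains transcriptomically trackable after the fade —
    # mirroring laterality being determined in early-specified neurons
    mean_tau <- tapply(type_decouple_times(tree), tree$subclass, mean)
    il <- which(tree$subclass == as.integer(names(which.min(mean_tau))))
    sim <- plant_laterality(truth, sim, frac_ipsi, ip, co, fade_age,
                            il_types = il, boost = 10, seed = seed + 3L)
    truth$cells <- sim$cells
  } else {
    truth$cells <- sim$cells
  }
  sim$truth <- truth
  sim
}
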