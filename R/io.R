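#' Read a 10x-style MTX triplet
#'
#' Loads \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv} from a
#' directory, and \code{cells.tsv} metadata if present.
#'
#' @param dir directory containing the triplet.
#' @return list with \code{counts} (dgCMatrix, genes x cells) and, when
#'   available, \code{cells} (data.frame keyed by barcode).
#' @export
read_tenx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                                header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  out <- list(counts = m)
  meta <- file.path(dir, "cells.tsv")
  if (file.exists(meta))
    out$cells <- utils::read.delim(meta, stringsAsFactors = FALSE)
  out
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param dir output directory (created if absent).
#' @param cells optional per-cell metadata written as \code{cells.tsv}.
#' @return \code{dir}, invisibly.
#' @export
write_tenx <- function(counts, dir, cells = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(cells))
    utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a full synthetic dataset to disk
#'
#' Emits the standard layout consumed by the analysis drivers: the MTX
#' triplet, \code{cells.tsv} (age, batch, planted truth columns),
#' \code{truth_fates.tsv} (per-cell planted fate vectors) and
#' \code{cell_sets.gmt} (one set per planted terminal-age state, plus the
#' planted ipsilateral cells when present).
#'
#' @param sim a \code{\link{simulate_counts}} /
#'   \code{\link{synth_timecourse}} result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_synthdata <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_counts"))
  write_tenx(sim$counts, dir, cells = sim$cells)
  truth <- sim$truth
  if (!is.null(truth)) {
    fates <- as.data.frame(truth$fates)
    names(fates) <- sprintf("type%02d", seq_len(ncol(fates)))
    utils::write.table(cbind(cell_id = truth$cells$cell_id, fates),
                       file.path(dir, "truth_fates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    terminal <- truth$age_grid[length(truth$age_grid)]
    at_term <- truth$cells$age == terminal
    sets <- split(truth$cells$cell_id[at_term],
                  sprintf("type%02d", truth$cells$destined_type[at_term]))
    if (any(truth$cells$laterality == "I"))
      sets$planted_ipsi <- truth$cells$cell_id[truth$cells$laterality == "I"]
    write_gmt(sets, file.path(dir, "cell_sets.gmt"))
    if (!is.null(sim$laterality))
      utils::write.table(
        data.frame(gene = c(sim$laterality$ipsi_genes,
                            sim$laterality$contra_genes),
                   set = rep(c("ipsi", "contra"),
                             c(length(sim$laterality$ipsi_genes),
                               length(sim$laterality$contra_genes)))),
        file.path(dir, "laterality_genes.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a GMT file as a named list of character vectors
#' @param path GMT file path.
#' @return named list; names are set ids, elements are members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a named list of sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
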