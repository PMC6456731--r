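#' Multi-individual UMI count dataset
#'
#' Container for genes x cells UMI count matrices from one or more
#' individuals. All matrices share the same genes, in the same order; cells
#' are never mixed across individuals. Entries are non-negative integers
#' (deduplicated UMI counts); per-cell totals are free to differ across cells
#' and individuals.
#'
#' @param matrices list of genes x cells matrices of non-negative integer
#'   counts, one per individual.
#' @param gene_ids character vector of gene identifiers (length = number of
#'   rows of every matrix). Defaults to the rownames of the first matrix.
#' @param cell_ids list of character vectors of cell barcodes, one per
#'   individual. Defaults to matrix colnames or generated barcodes.
#' @param individual_ids character vector of individual identifiers.
#'
#' @return An object of class `count_dataset`: a list with elements
#'   `matrices`, `gene_ids`, `cell_ids`, `individual_ids`.
#' @export
count_dataset <- function(matrices, gene_ids = NULL, cell_ids = NULL,
                          individual_ids = NULL) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("'matrices' must be a non-empty list of count matrices")
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  G <- nrow(matrices[[1L]])
  L <- length(matrices)
  if (is.null(gene_ids)) gene_ids <- rownames(matrices[[1L]])
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(G))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(L))
  if (is.null(cell_ids)) {
    cell_ids <- lapply(seq_len(L), function(l) {
      cn <- colnames(matrices[[l]])
      if (is.null(cn))
        cn <- paste0(individual_ids[l], "_cell", seq_len(ncol(matrices[[l]])))
      cn
    })
  }
  obj <- structure(
    list(matrices = matrices, gene_ids = as.character(gene_ids),
         cell_ids = lapply(cell_ids, as.character),
         individual_ids = as.character(individual_ids)),
    class = "count_dataset")
  validate_count_dataset(obj)
  obj
}

validate_count_dataset <- function(x) {
  L <- length(x$matrices)
  G <- length(x$gene_ids)
  if (length(x$individual_ids) != L || length(x$cell_ids) != L)
    stop("individual_ids/cell_ids length must match number of matrices")
  for (l in seq_len(L)) {
    m <- x$matrices[[l]]
    if (nrow(m) != G)
      stop(sprintf("matrix %d has %d rows but %d gene ids", l, nrow(m), G))
    if (ncol(m) < 1L)
      stop(sprintf("individual %s has no cells", x$individual_ids[l]))
    if (ncol(m) != length(x$cell_ids[[l]]))
      stop(sprintf("matrix %d: %d columns but %d cell ids", l, ncol(m),
                   length(x$cell_ids[[l]])))
    if (anyNA(m) || any(m < 0) || any(m != floor(m)))
      stop("counts must be non-negative integers")
  }
  invisible(x)
}

#' @export
print.count_dataset <- function(x, ...) {
  cl <- vapply(x$matrices, ncol, integer(1))
  cat(sprintf("count_dataset: %d genes, %d individuals, %d cells total\n",
              length(x$gene_ids), length(x$individual_ids), sum(cl)))
  cat("cells per individual:", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells per individual / in total
#' @param dataset a [count_dataset()].
#' @return `n_cells()` returns the per-individual cell counts;
#'   `n_cells_total()` their sum.
#' @export
n_cells <- function(dataset) vapply(dataset$matrices, ncol, integer(1))

#' @rdname n_cells
#' @export
n_cells_total <- function(dataset) sum(n_cells(dataset))

#' Pool the per-individual matrices into one genes x cells matrix
#' @param dataset a [count_dataset()].
#' @return genes x (total cells) matrix, individuals in order.
#' @export
pooled_counts <- function(dataset) do.call(cbind, dataset$matrices)

#' Merge per-individual count matrices into one dataset
#'
#' Harmonizes the gene universe across individuals by intersecting their gene
#' lists. The merged gene order is the first individual's order restricted to
#' the intersection; every matrix is re-indexed to that order. Cells are
#' never merged across individuals.
#'
#' @param matrices list of genes x cells count matrices, one per individual.
#' @param gene_lists list of character vectors, the gene identifiers of each
#'   matrix in row order.
#' @param cell_ids optional list of per-individual cell barcodes.
#' @param individual_ids optional identifiers for the individuals.
#' @return A [count_dataset()] on the common gene set.
#' @export
merge_individuals <- function(matrices, gene_lists, cell_ids = NULL,
                              individual_ids = NULL) {
  if (length(matrices) != length(gene_lists))
    stop("need one gene list per matrix")
  if (length(matrices) < 1L) stop("need at least one individual")
  common <- Reduce(intersect, gene_lists)
  if (length(common) == 0L)
    stop("no genes shared by all individuals")
  order_ref <- gene_lists[[1L]][gene_lists[[1L]] %in% common]
  matrices <- lapply(seq_along(matrices), function(l) {
    idx <- match(order_ref, gene_lists[[l]])
    m <- matrices[[l]][idx, , drop = FALSE]
    rownames(m) <- order_ref
    m
  })
  count_dataset(matrices, gene_ids = order_ref, cell_ids = cell_ids,
                individual_ids = individual_ids)
}

#' Remove lowly expressed genes
#'
#' A gene is retained iff the fraction of cells, pooled over all individuals,
#' in which it has a strictly positive count is at least `min_cell_fraction`.
#' Genes below the threshold ("expressed in less than that fraction of
#' cells") are dropped; relative gene order is preserved.
#'
#' @param dataset a [count_dataset()].
#' @param min_cell_fraction minimum fraction of pooled cells with count > 0,
#'   in \[0, 1\]. Default 0.01 (genes expressed in fewer than 1% of cells are
#'   removed).
#' @return The filtered [count_dataset()].
#' @export
filter_low_expressed <- function(dataset, min_cell_fraction = 0.01) {
  stopifnot(min_cell_fraction >= 0, min_cell_fraction <= 1)
  pooled <- pooled_counts(dataset)
  frac <- rowMeans(pooled > 0)
  keep <- which(frac >= min_cell_fraction)
  if (length(keep) == 0L)
    stop("all genes removed by expression filter")
  subset_genes(dataset, keep)
}

#' Select highly variable genes
#'
#' Ranks genes by the population standard deviation of their raw counts over
#' all pooled cells and keeps the top `n_genes`. Ties are broken in favour of
#' the gene earlier in the input order; selected genes keep their relative
#' input order.
#'
#' @param dataset a [count_dataset()].
#' @param n_genes number of genes to keep (default 1000). If `n_genes` is at
#'   least the current gene count, the dataset is returned unchanged.
#' @return The reduced [count_dataset()].
#' @export
select_hvg <- function(dataset, n_genes = 1000) {
  stopifnot(n_genes >= 1)
  G <- length(dataset$gene_ids)
  if (n_genes >= G) return(dataset)
  pooled <- pooled_counts(dataset)
  mu <- rowMeans(pooled)
  sd_pop <- sqrt(pmax(rowMeans(pooled^2) - mu^2, 0))
  keep <- sort(order(-sd_pop)[seq_len(n_genes)])  # order() is stable: ties go to earlier genes
  subset_genes(dataset, keep)
}

subset_genes <- function(dataset, idx) {
  dataset$matrices <- lapply(dataset$matrices, function(m) m[idx, , drop = FALSE])
  dataset$gene_ids <- dataset$gene_ids[idx]
  dataset
}

subset_cells <- function(dataset, idx_list) {
  keep <- vapply(idx_list, length, integer(1)) > 0L
  if (!any(keep)) return(NULL)
  structure(
    list(matrices = lapply(which(keep), function(l)
           dataset$matrices[[l]][, idx_list[[l]], drop = FALSE]),
         gene_ids = dataset$gene_ids,
         cell_ids = lapply(which(keep), function(l)
           dataset$cell_ids[[l]][idx_list[[l]]]),
         individual_ids = dataset$individual_ids[keep]),
    class = "count_dataset")
}
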