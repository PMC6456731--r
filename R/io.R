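#' Read a single-individual UMI count matrix
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`"10x-mtx"`}{a directory holding a MatrixMarket coordinate file
#'     (`matrix.mtx`) plus gene and barcode lists (`genes.tsv` or
#'     `features.tsv`, and `barcodes.tsv`), as written by 10x Cell Ranger.}
#'   \item{`"dense"`}{a delimited text table, genes as rows: first column the
#'     gene id, header row the cell barcodes. Comma-separated for `.csv`,
#'     otherwise whitespace/tab.}
#' }
#'
#' @param path directory (`"10x-mtx"`) or file (`"dense"`).
#' @param format `"10x-mtx"` or `"dense"`.
#' @return list with `counts` (genes x cells integer matrix), `gene_ids`,
#'   `cell_ids`.
#' @export
read_counts <- function(path, format = c("10x-mtx", "dense")) {
  format <- match.arg(format)
  if (format == "10x-mtx") read_counts_mtx(path) else read_counts_dense(path)
}

find_10x_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("none of %s found in %s", paste(candidates, collapse = "/"), dir))
}

read_counts_mtx <- function(path) {
  if (!dir.exists(path)) stop(sprintf("input path not found: %s", path))
  mtx <- find_10x_file(path, c("matrix.mtx"))
  genes_f <- find_10x_file(path, c("genes.tsv", "features.tsv"))
  bc_f <- find_10x_file(path, c("barcodes.tsv"))
  m <- Matrix::readMM(mtx)
  genes <- read.table(genes_f, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  barcodes <- read.table(bc_f, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes))
    stop(sprintf("matrix declares %d rows but gene list has %d entries",
                 nrow(m), length(genes)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix declares %d columns but barcode list has %d entries",
                 ncol(m), length(barcodes)))
  m <- as.matrix(m)
  if (anyNA(m) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers")
  dimnames(m) <- list(genes, barcodes)
  list(counts = m, gene_ids = genes, cell_ids = barcodes)
}

read_counts_dense <- function(path) {
  if (!file.exists(path)) stop(sprintf("input path not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers")
  list(counts = m, gene_ids = rownames(m), cell_ids = colnames(m))
}

#' Write a single-individual count matrix
#'
#' Inverse of [read_counts()]; `"10x-mtx"` writes `matrix.mtx`, `genes.tsv`
#' and `barcodes.tsv` into `path` (a directory), `"dense"` writes one
#' delimited table.
#'
#' @param counts genes x cells integer matrix.
#' @param path output directory (`"10x-mtx"`) or file (`"dense"`).
#' @param format `"10x-mtx"` or `"dense"`.
#' @param gene_ids,cell_ids identifiers; default from dimnames.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("10x-mtx", "dense"),
                         gene_ids = rownames(counts),
                         cell_ids = colnames(counts)) {
  format <- match.arg(format)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  if (format == "10x-mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                  "generalMatrix"), "TsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(gene_ids, file.path(path, "genes.tsv"))
    writeLines(cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = gene_ids, counts, check.names = FALSE)
    colnames(tab) <- c("gene", cell_ids)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a clustering result to disk
#'
#' Emits three text artefacts into `dir`:
#' \describe{
#'   \item{`labels.tsv`}{one row per cell: `individual_id`, `cell_id`,
#'     `cluster`, `max_posterior`, `vague_flag` (largest posterior
#'     cluster probability below `vague_threshold`).}
#'   \item{`posterior.tsv`}{the cells x K posterior probability matrix.}
#'   \item{`params.json`}{estimated parameters (alpha, pi, mu, sigma2, ids),
#'     reloadable with [read_params()] for supervised classification.}
#' }
#'
#' @param result a clustering result from [run_mcmc()] or
#'   [supervised_pipeline()].
#' @param dir output directory (created if needed).
#' @param vague_threshold posterior threshold for the vague-cell flag
#'   (default 0.95, strict `<`).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, vague_threshold = 0.95) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  post <- result$posterior
  labs <- data.frame(
    individual_id = rep(result$individual_ids,
                        vapply(result$cell_ids, length, integer(1))),
    cell_id = unlist(result$cell_ids, use.names = FALSE),
    cluster = unlist(result$final_labels, use.names = FALSE),
    max_posterior = apply(post, 1L, max),
    vague_flag = flag_vague_cells(post, vague_threshold))
  write.table(labs, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ptab <- data.frame(individual_id = labs$individual_id,
                     cell_id = labs$cell_id, post, check.names = FALSE)
  colnames(ptab) <- c("individual_id", "cell_id",
                      paste0("cluster", seq_len(ncol(post))))
  write.table(ptab, file.path(dir, "posterior.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_params(result, file.path(dir, "params.json"))
  invisible(dir)
}

#' @rdname write_result
#' @param path file path for the parameter dump (JSON text).
#' @export
write_params <- function(result, path) {
  K <- ncol(result$posterior)
  # arrays flattened column-major; dims are implied by G, L, K
  dump <- list(
    K = K,
    gene_ids = result$gene_ids,
    individual_ids = result$individual_ids,
    alpha_hat = as.numeric(result$alpha_hat),   # G x L x K
    pi_hat = as.numeric(result$pi_hat),         # L x K
    mu_hat = as.numeric(result$mu_hat),         # G x K
    sigma2_hat = as.numeric(result$sigma2_hat))
  jsonlite::write_json(dump, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload a parameter dump as a trained model
#'
#' @param path `params.json` written by [write_result()] / [write_params()].
#' @return A `trained_model` usable with [classify_cells()].
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("input path not found: %s", path))
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  G <- length(d$gene_ids); L <- length(d$individual_ids); K <- d$K
  alpha <- array(as.numeric(unlist(d$alpha_hat)), dim = c(G, L, K))
  structure(
    list(alpha_hat = alpha,
         pi_hat = matrix(as.numeric(unlist(d$pi_hat)), nrow = L, ncol = K),
         mu_hat = matrix(as.numeric(unlist(d$mu_hat)), nrow = G, ncol = K),
         sigma2_hat = matrix(as.numeric(unlist(d$sigma2_hat)), nrow = G, ncol = K),
         K = K, gene_ids = d$gene_ids, individual_ids = d$individual_ids),
    class = "trained_model")
}
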