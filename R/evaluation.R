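#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form),
#' computed from the contingency table. 1 for identical partitions (up to
#' label permutation), approximately 0 for independent labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / denom
}

#' Accuracy under the best one-to-one cluster matching
#'
#' Maximizes, over one-to-one matchings between predicted and true
#' clusters, the fraction of cells whose matched predicted cluster equals
#' the truth; renaming clusters therefore never costs accuracy. Exact
#' optimal assignment for up to 8 clusters (exhaustive over permutations),
#' greedy matching beyond.
#'
#' @param pred,truth label vectors of equal length.
#' @return proportion in \[0, 1\].
#' @export
matched_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must have equal length")
  tab <- unclass(table(pred, truth))
  r <- nrow(tab); s <- ncol(tab)
  m <- max(r, s)
  sq <- matrix(0, m, m)
  sq[seq_len(r), seq_len(s)] <- tab
  best <- if (m <= 8L) {
    perms <- all_permutations(m)
    max(vapply(perms, function(p) sum(sq[cbind(seq_len(m), p)]), numeric(1)))
  } else {
    greedy_assignment_sum(sq)
  }
  best / length(pred)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

greedy_assignment_sum <- function(m) {
  total <- 0
  for (step in seq_len(nrow(m))) {
    idx <- which(m == max(m), arr.ind = TRUE)[1L, ]
    total <- total + m[idx[1L], idx[2L]]
    m[idx[1L], ] <- -1
    m[, idx[2L]] <- -1
  }
  total
}

#' Average proportion of non-overlap (clustering stability)
#'
#' Co-membership stability of a reference clustering against clusterings of
#' perturbed data (e.g. refit after randomly removing genes). For
#' observation o and reduced clustering r, the non-overlap is
#' `1 - |C_full(o) intersect C_r(o)| / |C_full(o)|`, where C(o) is the set
#' of observations sharing o's cluster; APN averages over observations and
#' reductions. 0 means perfectly stable.
#'
#' @param full_labels reference label vector.
#' @param reduced_labels list of label vectors from the perturbed refits,
#'   each the same length as `full_labels`.
#' @return proportion in \[0, 1\].
#' @export
apn <- function(full_labels, reduced_labels) {
  if (!is.list(reduced_labels) || length(reduced_labels) == 0L)
    stop("reduced_labels must be a non-empty list")
  n <- length(full_labels)
  vals <- vapply(reduced_labels, function(red) {
    if (length(red) != n) stop("all label vectors must have equal length")
    # overlap(o) = #{o': same full cluster AND same reduced cluster as o}
    joint <- table(full_labels, red)
    full_sizes <- rowSums(joint)
    per_pair <- joint / full_sizes[row(joint)]  # |intersect| / |C_full|
    mean_nonoverlap <- sum(joint * (1 - per_pair)) / n
    mean_nonoverlap
  }, numeric(1))
  mean(vals)
}

#' Silhouette widths
#'
#' For observation o with mean within-cluster distance a (self excluded)
#' and smallest mean distance to another cluster b, the width is
#' `(b - a) / max(a, b)`. Members of singleton clusters get 0 by
#' convention; a single overall cluster yields all zeros with a warning.
#'
#' @param labels cluster label vector.
#' @param distances symmetric pairwise distance matrix (or `dist` object)
#'   with zero diagonal. For count data, see [proportion_distances()].
#' @return list with `widths` (per observation) and `mean`.
#' @export
silhouette_width <- function(labels, distances) {
  d <- as.matrix(distances)
  n <- length(labels)
  if (nrow(d) != n || ncol(d) != n)
    stop("distance matrix does not match the label vector")
  cl <- unique(labels)
  if (length(cl) < 2L) {
    warning("fewer than 2 clusters: silhouette is 0 by convention")
    return(list(widths = rep(0, n), mean = 0))
  }
  widths <- vapply(seq_len(n), function(o) {
    own <- labels == labels[o]
    n_own <- sum(own)
    if (n_own == 1L) return(0)  # singleton convention
    a <- sum(d[o, own]) / (n_own - 1L)
    b <- min(vapply(cl[cl != labels[o]], function(k)
      mean(d[o, labels == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(widths = widths, mean = mean(widths))
}

#' Euclidean distances between cells on gene-proportion vectors
#'
#' The default geometry for silhouettes on UMI counts: each cell is mapped
#' to its gene-proportion vector (counts / total) and pairwise Euclidean
#' distances are taken.
#'
#' @param dataset a [count_dataset()].
#' @return a `dist` object over all pooled cells.
#' @export
proportion_distances <- function(dataset) {
  pooled <- pooled_counts(dataset)
  props <- t(pooled) / pmax(colSums(pooled), 1)
  dist(props)
}

#' Flag cells with vague cluster assignment
#'
#' A cell is vague when its largest posterior cluster probability is
#' strictly below `threshold`.
#'
#' @param posterior cells x K matrix of posterior probabilities (rows sum
#'   to 1).
#' @param threshold flagging threshold (default 0.95, strict `<`).
#' @return logical vector, one entry per cell.
#' @export
flag_vague_cells <- function(posterior, threshold = 0.95) {
  posterior <- as.matrix(posterior)
  if (anyNA(posterior) || any(posterior < 0) ||
      any(abs(rowSums(posterior) - 1) > 1e-6))
    stop("posterior rows must be probability vectors")
  apply(posterior, 1L, max) < threshold
}

#' Assemble an evaluation report
#'
#' Computes whichever metrics the supplied inputs allow: ARI and matched
#' accuracy need `truth`; APN needs `reduced_labels`; silhouette needs
#' `distances`; vague-cell count needs `posterior`; AIC/BIC need `result`
#' and `dataset`.
#'
#' @param labels predicted label vector (pooled over individuals).
#' @param truth optional true label vector.
#' @param posterior optional cells x K posterior matrix.
#' @param reduced_labels optional list of label vectors from perturbed
#'   refits.
#' @param distances optional pairwise distance matrix for silhouettes.
#' @param result,dataset optional `clustering_result` and its
#'   [count_dataset()] for information criteria.
#' @param vague_threshold threshold for [flag_vague_cells()].
#' @return object of class `evaluation_report` (a named list; absent
#'   metrics are `NA`).
#' @export
evaluation_report <- function(labels, truth = NULL, posterior = NULL,
                              reduced_labels = NULL, distances = NULL,
                              result = NULL, dataset = NULL,
                              vague_threshold = 0.95) {
  rep <- list(ari = NA_real_, accuracy = NA_real_, apn = NA_real_,
              mean_silhouette = NA_real_, aic = NA_real_, bic = NA_real_,
              n_vague = NA_integer_)
  if (!is.null(truth)) {
    rep$ari <- adjusted_rand_index(labels, truth)
    rep$accuracy <- matched_accuracy(labels, truth)
  }
  if (!is.null(reduced_labels)) rep$apn <- apn(labels, reduced_labels)
  if (!is.null(distances))
    rep$mean_silhouette <- silhouette_width(labels, distances)$mean
  if (!is.null(posterior))
    rep$n_vague <- sum(flag_vague_cells(posterior, vague_threshold))
  if (!is.null(result) && !is.null(dataset)) {
    ic <- information_criteria(result, dataset)
    rep$aic <- ic[["AIC"]]
    rep$bic <- ic[["BIC"]]
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  for (nm in names(x))
    if (!is.na(x[[nm]])) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
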