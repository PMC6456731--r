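#' Split a dataset into training and test cells
#'
#' Within each individual independently, `ceiling(train_fraction * C_l)`
#' cells are sampled without replacement into the training set (kept in
#' their original order); the remainder form the test set. The gene
#' universe is unchanged. With `train_fraction = 1` the test set is empty
#' (`NULL`).
#'
#' @param dataset a [count_dataset()].
#' @param train_fraction proportion in (0, 1].
#' @param seed RNG seed for the draw.
#' @return list with `train`, `test` (a [count_dataset()] or `NULL`), and
#'   `train_idx`: per-individual sorted indices of the training cells.
#' @export
split_train_test <- function(dataset, train_fraction, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  set.seed(seed)
  cl <- n_cells(dataset)
  train_idx <- lapply(cl, function(C) {
    n_tr <- min(C, ceiling(train_fraction * C))
    sort(sample.int(C, n_tr))
  })
  test_idx <- lapply(seq_along(cl), function(l)
    setdiff(seq_len(cl[l]), train_idx[[l]]))
  list(train = subset_cells(dataset, train_idx),
       test = subset_cells(dataset, test_idx),
       train_idx = train_idx)
}

#' Fit the mixture on a training subset
#'
#' Runs the full sampler on the training cells and packages the post
#' burn-in aligned posterior means as a reusable model.
#'
#' @param train a [count_dataset()] of training cells.
#' @param config a [sampler_config()].
#' @return object of class `trained_model` with `alpha_hat` (G x L x K),
#'   `pi_hat` (L x K), `K`, `gene_ids`, `individual_ids`, and the full
#'   `result`.
#' @export
fit_training <- function(train, config) {
  res <- run_mcmc(train, config)
  structure(list(alpha_hat = res$alpha_hat, pi_hat = res$pi_hat,
                 mu_hat = res$mu_hat, sigma2_hat = res$sigma2_hat,
                 K = res$K, gene_ids = res$gene_ids,
                 individual_ids = res$individual_ids, result = res),
            class = "trained_model")
}

#' Classify cells in closed form with a trained model
#'
#' Posterior probability that cell x of individual l belongs to cluster k:
#' \deqn{P(z = k \mid x) \propto DM(x \mid \hat\alpha_{\cdot lk})\,
#'   \hat\pi_{lk},} evaluated with the estimated parameters of that cell's
#' own individual. Deterministic: no sampling is involved.
#'
#' @param test a [count_dataset()] whose gene universe equals the model's
#'   `gene_ids` (same order) and whose individuals appeared in training.
#' @param model a `trained_model` from [fit_training()] or [read_params()].
#' @return list with `posterior` (cells x K, rows sum to 1), `labels`
#'   (per-individual argmax, ties to the smallest index), and
#'   `individual_ids`/`cell_ids` aligned to `test`.
#' @export
classify_cells <- function(test, model) {
  if (!identical(as.character(test$gene_ids), as.character(model$gene_ids)))
    stop("test gene universe must match the trained model's gene ids")
  l_map <- match(test$individual_ids, model$individual_ids)
  if (anyNA(l_map))
    stop("test contains individuals absent from the trained model")
  posts <- vector("list", length(test$matrices))
  labels <- vector("list", length(test$matrices))
  for (t in seq_along(test$matrices)) {
    l <- l_map[t]
    w <- cpp_cell_logdm(test$matrices[[t]], alpha_slice(model$alpha_hat, l))
    w <- sweep(w, 2L, log(model$pi_hat[l, ]), "+")
    p <- t(apply(w, 1L, normalize_log_weights))
    if (model$K == 1L) p <- matrix(1, ncol(test$matrices[[t]]), 1L)
    posts[[t]] <- p
    labels[[t]] <- apply(p, 1L, which.max)
  }
  list(posterior = do.call(rbind, posts), labels = labels,
       individual_ids = test$individual_ids, cell_ids = test$cell_ids)
}

#' Supervised pipeline: train on a subset, classify the rest
#'
#' Splits each individual's cells, fits the sampler on the training subset,
#' and assigns the held-out cells in closed form with [classify_cells()].
#' Training cells keep their MCMC labels and posterior frequencies; test
#' cells get the closed-form posteriors. The combined result follows the
#' original cell order. With `train_fraction = 1` this is exactly
#' [run_mcmc()] on the full dataset.
#'
#' @param dataset a [count_dataset()].
#' @param train_fraction proportion of cells per individual used for
#'   training, in (0, 1].
#' @param config a [sampler_config()]; its seed also drives the split.
#' @return object of class `clustering_result` (see [run_mcmc()]) with
#'   extra fields `is_train` (per-individual logical vectors) and `model`
#'   (the `trained_model`).
#' @export
supervised_pipeline <- function(dataset, train_fraction, config) {
  sp <- split_train_test(dataset, train_fraction, seed = config$seed)
  model <- fit_training(sp$train, config)
  res <- model$result
  if (is.null(sp$test)) {
    res$is_train <- lapply(n_cells(dataset), function(C) rep(TRUE, C))
    res$model <- model
    return(res)
  }
  cls <- classify_cells(sp$test, model)

  cl <- n_cells(dataset)
  K <- model$K
  posterior <- matrix(0, sum(cl), K)
  final_labels <- vector("list", length(cl))
  is_train <- vector("list", length(cl))
  offsets <- cumsum(c(0L, cl))
  tr_off <- 0L
  te_row <- 0L
  te_l <- 0L
  for (l in seq_along(cl)) {
    idx_tr <- sp$train_idx[[l]]
    idx_te <- setdiff(seq_len(cl[l]), idx_tr)
    lab <- integer(cl[l])
    n_tr <- length(idx_tr)
    lab[idx_tr] <- res$final_labels[[l]]
    posterior[offsets[l] + idx_tr, ] <-
      res$posterior[tr_off + seq_len(n_tr), , drop = FALSE]
    tr_off <- tr_off + n_tr
    if (length(idx_te)) {
      te_l <- te_l + 1L
      lab[idx_te] <- cls$labels[[te_l]]
      posterior[offsets[l] + idx_te, ] <-
        cls$posterior[te_row + seq_along(idx_te), , drop = FALSE]
      te_row <- te_row + length(idx_te)
    }
    final_labels[[l]] <- lab
    is_train[[l]] <- seq_len(cl[l]) %in% idx_tr
  }
  out <- res
  out$final_labels <- final_labels
  out$posterior <- posterior
  out$cell_ids <- dataset$cell_ids
  out$individual_ids <- dataset$individual_ids
  out$is_train <- is_train
  out$model <- model
  out
}
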