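#' Sampler configuration
#'
#' @param K number of mixture components (cell types). Required.
#' @param n_iter total MCMC sweeps (default 1000).
#' @param burn_in sweeps discarded before posterior summarization
#'   (default 100).
#' @param seed RNG seed; every source of randomness in [run_mcmc()] flows
#'   from it.
#' @param proposal_sd random-walk scale for the Metropolis updates of
#'   log alpha (default 0.1).
#' @param hyper_a,hyper_b shape and rate of the Gamma(a, b) hyper-prior on
#'   the heterogeneity variances sigma2\[i, k\] (default 1, 1: weakly
#'   informative, prior mean 1).
#' @param init_method `"kmeans-proportions"` (k-means on per-cell gene
#'   proportions; default) or `"random"` (uniform labels).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(K, n_iter = 1000, burn_in = 100, seed = 1,
                           proposal_sd = 0.1, hyper_a = 1, hyper_b = 1,
                           init_method = c("kmeans-proportions", "random")) {
  init_method <- match.arg(init_method)
  stopifnot(K >= 1, n_iter > burn_in, burn_in >= 0, proposal_sd > 0,
            hyper_a > 0, hyper_b > 0)
  structure(list(K = as.integer(K), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 proposal_sd = proposal_sd, hyper_a = hyper_a,
                 hyper_b = hyper_b, init_method = init_method),
            class = "sampler_config")
}

#' Initialize the sampler state
#'
#' Seeds the RNG from `config$seed` and builds a full model state: labels
#' (uniform random, or k-means on per-cell gene-proportion vectors pooled
#' across individuals), concentrations from per-cluster mean proportions
#' scaled by the mean per-cell depth (floored at a small positive constant),
#' mixing proportions from within-individual label frequencies (floored and
#' renormalized), mu from the mean of log alpha across individuals and
#' sigma2 at the hyper-prior mean. Any cluster left empty is repaired by
#' reassigning one random cell to it.
#'
#' @param dataset a [count_dataset()].
#' @param config a [sampler_config()].
#' @return object of class `model_state`: list with `labels`, `alpha`
#'   (G x L x K), `pi` (L x K), `mu`, `sigma2` (G x K), `iteration`.
#' @export
initialize_state <- function(dataset, config) {
  set.seed(config$seed)
  K <- config$K
  L <- length(dataset$matrices)
  G <- length(dataset$gene_ids)
  cl <- n_cells(dataset)
  pooled <- pooled_counts(dataset)
  depths <- colSums(pooled)

  if (K == 1L) {
    z_pooled <- rep(1L, sum(cl))
  } else if (config$init_method == "kmeans-proportions") {
    props <- t(pooled) / pmax(depths, 1)
    z_pooled <- tryCatch(
      as.integer(kmeans(props, centers = K, nstart = 5L,
                        iter.max = 25L)$cluster),
      error = function(e) sample.int(K, sum(cl), replace = TRUE))
  } else {
    z_pooled <- sample.int(K, sum(cl), replace = TRUE)
  }
  # repair empty clusters
  for (k in seq_len(K)) {
    if (!any(z_pooled == k)) {
      j <- sample.int(length(z_pooled), 1L)
      z_pooled[j] <- k
      message(sprintf("initialize_state: cluster %d empty, reassigned one cell", k))
    }
  }
  labels <- split_pooled(z_pooled, cl)

  conc <- mean(depths)
  alpha <- array(0, dim = c(G, L, K))
  for (k in seq_len(K)) {
    sel <- z_pooled == k
    pk <- if (any(sel)) rowMeans(pooled[, sel, drop = FALSE] /
                                   rep(pmax(depths[sel], 1), each = G))
          else rep(1 / G, G)
    ak <- pmax(pk * conc, 1e-3)
    for (l in seq_len(L)) alpha[, l, k] <- ak
  }

  pi <- matrix(0, L, K)
  for (l in seq_len(L)) {
    f <- tabulate(labels[[l]], nbins = K) / cl[l]
    f <- pmax(f, 1e-3)
    pi[l, ] <- f / sum(f)
  }

  mu <- matrix(0, G, K)
  for (k in seq_len(K)) mu[, k] <- rowMeans(log(alpha_slice_k(alpha, k)))
  sigma2 <- matrix(config$hyper_a / config$hyper_b, G, K)

  structure(list(labels = labels, alpha = alpha, pi = pi, mu = mu,
                 sigma2 = sigma2, iteration = 0L),
            class = "model_state")
}

split_pooled <- function(z_pooled, cl) {
  ends <- cumsum(cl)
  starts <- ends - cl + 1L
  lapply(seq_along(cl), function(l) z_pooled[starts[l]:ends[l]])
}

# G x L matrix of alpha[, , k]
alpha_slice_k <- function(alpha, k) {
  d <- dim(alpha)
  matrix(alpha[, , k], nrow = d[1L], ncol = d[2L])
}

#' One Gibbs sweep over the cell labels
#'
#' Redraws every z from its full conditional, the categorical distribution
#' proportional to `pi[l, k] * DM(x | alpha[, l, k])`. Cells are
#' conditionally independent given the parameters.
#'
#' @param state a `model_state`.
#' @param dataset the [count_dataset()] being fit.
#' @return updated `model_state`.
#' @export
update_labels <- function(state, dataset) {
  for (l in seq_along(dataset$matrices)) {
    state$labels[[l]] <- cpp_sample_labels(dataset$matrices[[l]],
                                           alpha_slice(state$alpha, l),
                                           log(state$pi[l, ]))
  }
  state
}

#' Metropolis update of the Dirichlet concentrations
#'
#' For each gene, individual and cluster, a random-walk Metropolis step on
#' log alpha targeting its full conditional: the Dirichlet-multinomial
#' likelihood of the cells currently assigned to that (individual, cluster)
#' block times the log-normal prior. Empty blocks fall back to the prior.
#'
#' @inheritParams update_labels
#' @param proposal_sd random-walk scale on the log scale.
#' @return updated `model_state`; acceptance bookkeeping in
#'   `attr(, "alpha_accept")` (accepted / proposed).
#' @export
update_alpha <- function(state, dataset, proposal_sd = 0.1) {
  K <- dim(state$alpha)[3L]
  acc <- 0L
  tot <- 0L
  for (l in seq_along(dataset$matrices)) {
    X <- dataset$matrices[[l]]
    z <- state$labels[[l]]
    for (k in seq_len(K)) {
      Xt <- t(X[, z == k, drop = FALSE])
      up <- cpp_update_alpha_block(Xt, state$alpha[, l, k],
                                   state$mu[, k], state$sigma2[, k],
                                   proposal_sd)
      state$alpha[, l, k] <- up$alpha
      acc <- acc + up$accept
      tot <- tot + nrow(state$mu)
    }
  }
  attr(state, "alpha_accept") <- c(accepted = acc, proposed = tot)
  state
}

#' Update the hyper-parameters mu and sigma2
#'
#' mu\[i, k\] is set to the mean of log alpha\[i, l, k\] over individuals
#' (the closed-form estimator under a noninformative prior). sigma2\[i, k\]
#' takes a Metropolis step on the log scale targeting its conditional:
#' Gamma(a, b) hyper-prior times the normal likelihood of the L values
#' log alpha around mu.
#'
#' @param state a `model_state`.
#' @param config a [sampler_config()] (supplies `hyper_a`, `hyper_b`).
#' @param prop_sd proposal scale for log sigma2.
#' @return updated `model_state`; acceptance fraction in
#'   `attr(, "sigma2_accept")`.
#' @export
update_hyperparams <- function(state, config, prop_sd = 0.5) {
  d <- dim(state$alpha)
  G <- d[1L]; L <- d[2L]; K <- d[3L]
  la <- log(state$alpha)
  for (k in seq_len(K))
    state$mu[, k] <- rowMeans(matrix(la[, , k], nrow = G, ncol = L))

  ss <- matrix(0, G, K)
  for (k in seq_len(K)) {
    lak <- matrix(la[, , k], nrow = G, ncol = L)
    ss[, k] <- rowSums((lak - state$mu[, k])^2)
  }
  cur <- state$sigma2
  logpost <- function(s2)
    dgamma(s2, shape = config$hyper_a, rate = config$hyper_b, log = TRUE) -
      (L / 2) * log(s2) - ss / (2 * s2) + log(s2)  # + Jacobian of log scale
  prop <- cur * exp(matrix(rnorm(G * K, sd = prop_sd), G, K))
  accept <- log(matrix(runif(G * K), G, K)) < (logpost(prop) - logpost(cur))
  state$sigma2[accept] <- prop[accept]
  attr(state, "sigma2_accept") <- mean(accept)
  state
}

#' Conjugate update of the mixing proportions
#'
#' Per individual, pi is redrawn from Dirichlet(1 + n_1, ..., 1 + n_K),
#' the posterior under a symmetric Dirichlet(1) prior given the current
#' cluster occupancies n_k.
#'
#' @param state a `model_state`.
#' @return updated `model_state`.
#' @export
update_pi <- function(state) {
  K <- ncol(state$pi)
  for (l in seq_len(nrow(state$pi))) {
    n <- tabulate(state$labels[[l]], nbins = K)
    g <- rgamma(K, shape = 1 + n, rate = 1)
    state$pi[l, ] <- g / sum(g)
  }
  state
}

# Greedy maximum-overlap matching of cluster labels `cur` onto reference
# labels `ref`; returns perm with perm[k_cur] = k_ref (a permutation).
match_clusters <- function(cur, ref, K) {
  tab <- matrix(0, K, K)
  t0 <- table(factor(cur, levels = seq_len(K)), factor(ref, levels = seq_len(K)))
  tab[, ] <- as.numeric(t0)
  perm <- rep(NA_integer_, K)
  used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    perm[idx[1L]] <- idx[2L]
    used[idx[2L]] <- TRUE
    tab[idx[1L], ] <- -1
    tab[, idx[2L]] <- -1
  }
  left <- which(is.na(perm))
  if (length(left)) perm[left] <- which(!used)
  perm
}

#' Run the full Metropolis-within-Gibbs sampler
#'
#' Iterates label, concentration, hyper-parameter and mixing-proportion
#' updates for `config$n_iter` sweeps, discards `config$burn_in`, and
#' summarizes the retained draws. Label switching across retained sweeps is
#' resolved by greedy maximum-overlap matching of each sweep's partition to
#' the first retained sweep before averaging; parameter estimates are the
#' aligned posterior means. Per-cell posterior probabilities are the
#' aligned assignment frequencies; final labels are their argmax (ties to
#' the smallest cluster index).
#'
#' @param dataset a preprocessed [count_dataset()].
#' @param config a [sampler_config()].
#' @param verbose print progress every 100 sweeps.
#' @return object of class `clustering_result`: per-individual
#'   `final_labels`, pooled `posterior` (cells x K), posterior means
#'   `alpha_hat`, `pi_hat`, `mu_hat`, `sigma2_hat`, traces
#'   `log_posterior_trace` and `log_lik_trace` (length `n_iter`), acceptance
#'   rates, and the identifiers needed to write results.
#' @export
run_mcmc <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(config, "sampler_config"))
  validate_count_dataset(dataset)
  K <- config$K
  L <- length(dataset$matrices)
  G <- length(dataset$gene_ids)
  N <- n_cells_total(dataset)
  cl <- n_cells(dataset)

  state <- initialize_state(dataset, config)
  coef_const <- multinomial_coef_const(dataset)

  post_counts <- matrix(0, N, K)
  alpha_sum <- array(0, dim = c(G, L, K))
  pi_sum <- matrix(0, L, K)
  mu_sum <- matrix(0, G, K)
  sig_sum <- matrix(0, G, K)
  lp_trace <- numeric(config$n_iter)
  ll_trace <- numeric(config$n_iter)
  acc_alpha <- 0
  prop_alpha <- 0
  acc_sigma <- 0
  ref_labels <- NULL
  n_ret <- 0L

  for (it in seq_len(config$n_iter)) {
    state <- update_labels(state, dataset)
    state <- update_alpha(state, dataset, config$proposal_sd)
    aa <- attr(state, "alpha_accept")
    acc_alpha <- acc_alpha + aa["accepted"]
    prop_alpha <- prop_alpha + aa["proposed"]
    state <- update_hyperparams(state, config)
    acc_sigma <- acc_sigma + attr(state, "sigma2_accept")
    state <- update_pi(state)
    state$iteration <- it

    ll <- cpp_loglik_all(dataset, state) + coef_const
    lp <- ll + log_prior_alpha(state$alpha, state$mu, state$sigma2) +
      sum(dgamma(state$sigma2, shape = config$hyper_a,
                 rate = config$hyper_b, log = TRUE))
    ll_trace[it] <- ll
    lp_trace[it] <- lp

    if (it > config$burn_in) {
      z_pooled <- unlist(state$labels, use.names = FALSE)
      if (is.null(ref_labels)) {
        ref_labels <- z_pooled
        perm <- seq_len(K)
      } else {
        perm <- match_clusters(z_pooled, ref_labels, K)
      }
      zp <- perm[z_pooled]
      post_counts[cbind(seq_len(N), zp)] <- post_counts[cbind(seq_len(N), zp)] + 1
      alpha_sum[, , perm] <- alpha_sum[, , perm, drop = FALSE] + state$alpha
      pi_sum[, perm] <- pi_sum[, perm] + state$pi
      mu_sum[, perm] <- mu_sum[, perm] + state$mu
      sig_sum[, perm] <- sig_sum[, perm] + state$sigma2
      n_ret <- n_ret + 1L
    }
    if (verbose && it %% 100L == 0L)
      message(sprintf("sweep %d/%d  log-posterior %.1f", it, config$n_iter, lp))
  }

  posterior <- post_counts / n_ret
  pooled_final <- apply(posterior, 1L, which.max)  # ties -> smallest index
  structure(
    list(final_labels = split_pooled(as.integer(pooled_final), cl),
         posterior = posterior,
         alpha_hat = alpha_sum / n_ret,
         pi_hat = pi_sum / n_ret,
         mu_hat = mu_sum / n_ret,
         sigma2_hat = sig_sum / n_ret,
         log_posterior_trace = lp_trace,
         log_lik_trace = ll_trace,
         accept_rate_alpha = as.numeric(acc_alpha / prop_alpha),
         accept_rate_sigma2 = acc_sigma / config$n_iter,
         K = K, n_iter = config$n_iter, burn_in = config$burn_in,
         n_retained = n_ret, config = config,
         gene_ids = dataset$gene_ids, cell_ids = dataset$cell_ids,
         individual_ids = dataset$individual_ids),
    class = "clustering_result")
}

cpp_loglik_all <- function(dataset, state) {
  ll <- 0
  for (l in seq_along(dataset$matrices))
    ll <- ll + cpp_loglik_assigned(dataset$matrices[[l]],
                                   alpha_slice(state$alpha, l),
                                   as.integer(state$labels[[l]]))
  ll
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: K = %d, %d cells, %d individuals\n",
              x$K, nrow(x$posterior), length(x$individual_ids)))
  cat(sprintf("  %d sweeps (%d burn-in); alpha acceptance %.2f\n",
              x$n_iter, x$burn_in, x$accept_rate_alpha))
  cat("  cluster sizes:",
      paste(tabulate(unlist(x$final_labels), nbins = x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' Information criteria for choosing the number of clusters
#'
#' Uses the best retained joint log likelihood (counts and labels at the
#' sampled parameters, coefficients included) as the plug-in maximized
#' likelihood. The free-parameter count is `G*L*K` concentrations plus
#' `L*(K-1)` mixing proportions.
#'
#' @param result a `clustering_result` from [run_mcmc()].
#' @param dataset the dataset it was fit on.
#' @return named vector `c(AIC =, BIC =)`; lower is better.
#' @export
information_criteria <- function(result, dataset) {
  ret <- seq.int(result$burn_in + 1L, result$n_iter)
  if (length(ret) == 0L) stop("no retained iterations")
  ll <- max(result$log_lik_trace[ret])
  G <- length(result$gene_ids)
  L <- length(result$individual_ids)
  K <- result$K
  P <- G * L * K + L * (K - 1)
  N <- nrow(result$posterior)
  c(AIC = 2 * P - 2 * ll, BIC = P * log(N) - 2 * ll)
}

#' Fit a range of cluster numbers and compare information criteria
#'
#' @param dataset a [count_dataset()].
#' @param k_values integer vector of candidate K.
#' @param config a [sampler_config()]; its `K` is overridden per fit.
#' @param verbose print one line per K.
#' @return data.frame with columns `K`, `AIC`, `BIC`.
#' @export
scan_k <- function(dataset, k_values, config, verbose = FALSE) {
  rows <- lapply(k_values, function(k) {
    cfg <- config
    cfg$K <- as.integer(k)
    res <- run_mcmc(dataset, cfg)
    ic <- information_criteria(res, dataset)
    if (verbose) message(sprintf("K = %d  AIC = %.1f  BIC = %.1f", k,
                                 ic["AIC"], ic["BIC"]))
    data.frame(K = k, AIC = ic[["AIC"]], BIC = ic[["BIC"]])
  })
  do.call(rbind, rows)
}
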