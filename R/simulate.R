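#' Simulation configuration
#'
#' Describes one synthetic multi-individual UMI experiment drawn from the
#' model's own generative process: cluster/gene location parameters mu,
#' per-individual concentrations log-normally dispersed around them with
#' variance sigma2 (the individual-level heterogeneity), per-cell Dirichlet
#' gene probabilities, and multinomial counts at the configured depth.
#'
#' @param G number of genes (default 100).
#' @param K number of cell-type clusters (default 3).
#' @param L number of individuals (default 5).
#' @param cells_per_individual scalar or length-L vector of cell counts
#'   (default 200).
#' @param mu optional G x K matrix of log-scale concentration locations;
#'   when `NULL`, generated by [make_mu()] with `separation`.
#' @param separation cluster separation passed to [make_mu()] when `mu` is
#'   `NULL` (default 2: well-separated signature genes).
#' @param sigma2 individual-level heterogeneity: scalar or G x K matrix of
#'   log-normal variances (default 0.1).
#' @param pi_true L x K mixing proportions (default uniform 1/K).
#' @param depth_model list describing per-cell totals: `list(type =
#'   "fixed", depth = 1000)` or `list(type = "lognormal", median = 1000,
#'   sdlog = 0.3)` (draws rounded up to at least 1).
#' @param seed RNG seed.
#' @param retain_p keep the per-cell Dirichlet probability vectors
#'   (memory-heavy; default FALSE).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(G = 100, K = 3, L = 5,
                              cells_per_individual = 200, mu = NULL,
                              separation = 2, sigma2 = 0.1, pi_true = NULL,
                              depth_model = list(type = "fixed", depth = 1000),
                              seed = 1, retain_p = FALSE) {
  cells <- rep_len(as.integer(cells_per_individual), L)
  stopifnot(G >= 1, K >= 1, L >= 1, all(cells >= 1), all(sigma2 >= 0),
            separation >= 0)
  if (is.null(pi_true)) pi_true <- matrix(1 / K, L, K)
  pi_true <- matrix(pi_true, L, K)
  if (any(pi_true < 0) || any(abs(rowSums(pi_true) - 1) > 1e-8))
    stop("pi_true rows must be probability vectors")
  if (!is.null(mu)) mu <- matrix(mu, G, K)
  structure(list(G = as.integer(G), K = as.integer(K), L = as.integer(L),
                 cells_per_individual = cells, mu = mu,
                 separation = separation, sigma2 = sigma2,
                 pi_true = pi_true, depth_model = depth_model,
                 seed = as.integer(seed), retain_p = isTRUE(retain_p)),
            class = "simulation_config")
}

#' Build cluster location parameters with controlled separation
#'
#' Baseline log-concentrations shared by all clusters (standard normal
#' draws, one per gene) plus a cluster-specific shift of `+separation`
#' applied to a disjoint block of `ceiling(G / (2K))` signature genes per
#' cluster. With `separation = 0` all columns are identical and clusters
#' are indistinguishable.
#'
#' @param G,K numbers of genes and clusters.
#' @param separation non-negative shift applied to signature genes.
#' @return G x K matrix of location parameters.
#' @export
make_mu <- function(G, K, separation) {
  stopifnot(separation >= 0, G >= 1, K >= 1)
  base <- rnorm(G)
  mu <- matrix(base, G, K)
  n_sig <- ceiling(G / (2 * K))
  for (k in seq_len(K)) {
    idx <- ((k - 1) * n_sig + 1):(k * n_sig)
    idx <- idx[idx <= G]
    mu[idx, k] <- mu[idx, k] + separation
  }
  mu
}

#' Simulate a multi-individual UMI dataset from the hierarchical model
#'
#' For each gene, individual and cluster, `alpha = exp(mu + sqrt(sigma2) *
#' eps)` with standard-normal `eps`; each cell draws its cluster from the
#' individual's mixing proportions, its gene-probability vector from
#' Dirichlet(alpha) and its counts from a multinomial at the configured
#' depth. Identical configurations and seeds reproduce bit-identical
#' datasets.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_dataset`: `dataset` (a
#'   [count_dataset()]), `true_labels`, `true_alpha` (G x L x K), `mu`,
#'   `sigma2` (both G x K), and optionally `true_p`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$G; K <- config$K; L <- config$L
  mu <- if (is.null(config$mu)) make_mu(G, K, config$separation) else config$mu
  sigma2 <- matrix(config$sigma2, G, K)

  alpha <- array(0, dim = c(G, L, K))
  for (l in seq_len(L))
    alpha[, l, ] <- exp(mu + sqrt(sigma2) * matrix(rnorm(G * K), G, K))

  matrices <- vector("list", L)
  labels <- vector("list", L)
  probs <- if (config$retain_p) vector("list", L) else NULL
  for (l in seq_len(L)) {
    Cl <- config$cells_per_individual[l]
    z <- sample.int(K, Cl, replace = TRUE, prob = config$pi_true[l, ])
    depths <- draw_depths(config$depth_model, Cl)
    X <- matrix(0, G, Cl)
    if (config$retain_p) P <- matrix(0, G, Cl)
    for (j in seq_len(Cl)) {
      g <- rgamma(G, shape = alpha[, l, z[j]], rate = 1)
      p <- g / sum(g)
      X[, j] <- rmultinom(1L, size = depths[j], prob = p)
      if (config$retain_p) P[, j] <- p
    }
    rownames(X) <- paste0("gene", seq_len(G))
    colnames(X) <- sprintf("ind%d_cell%d", l, seq_len(Cl))
    matrices[[l]] <- X
    labels[[l]] <- z
    if (config$retain_p) probs[[l]] <- P
  }

  structure(list(dataset = count_dataset(matrices),
                 true_labels = labels, true_alpha = alpha,
                 mu = mu, sigma2 = sigma2, true_p = probs,
                 config = config),
            class = "simulated_dataset")
}

draw_depths <- function(depth_model, n) {
  type <- depth_model$type
  if (identical(type, "fixed")) {
    rep(as.integer(depth_model$depth), n)
  } else if (identical(type, "lognormal")) {
    pmax(1L, as.integer(round(rlnorm(n, meanlog = log(depth_model$median),
                                     sdlog = depth_model$sdlog))))
  } else stop(sprintf("unknown depth model '%s'", type))
}

#' Overall individual-level heterogeneity
#'
#' The scalar summary used throughout the simulation studies: the mean of
#' the log-normal variances sigma2\[i, k\] over all genes and clusters.
#' Given a sampled concentration array instead, returns the mean over
#' (gene, cluster) of the empirical variance of log alpha across
#' individuals (requires L >= 2).
#'
#' @param x a sigma2 scalar/matrix, or a G x L x K concentration array.
#' @return scalar heterogeneity level.
#' @export
heterogeneity_level <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    if (d[2L] < 2L) stop("empirical heterogeneity needs at least 2 individuals")
    la <- log(x)
    v <- apply(la, c(1L, 3L), var)
    mean(v)
  } else {
    mean(x)
  }
}

#' Preset simulation designs of the benchmark studies
#'
#' Three reference designs, returned as a [simulation_config()] (every field
#' overridable through `...`):
#' \describe{
#'   \item{`"heterogeneity-sweep"`}{10 individuals with 400 cells each;
#'     clustering difficulty is driven by the heterogeneity level, swept
#'     over `attr(, "sigma2_grid")` = 0.01, 0.1, 0.5, 1.}
#'   \item{`"individuals-sweep"`}{heterogeneity fixed at 0.1; the number of
#'     individuals is swept over `attr(, "L_grid")`.}
#'   \item{`"training-fraction-sweep"`}{10 individuals with 400 cells each
#'     for the supervised mode; training fractions in
#'     `attr(, "train_fractions")` = 0.1 ... 1.}
#' }
#' Desk-scale defaults G = 100, K = 3 apply throughout.
#'
#' @param name one of `"heterogeneity-sweep"`, `"individuals-sweep"`,
#'   `"training-fraction-sweep"`.
#' @param ... overrides passed to [simulation_config()].
#' @return a [simulation_config()] with the sweep grid attached as an
#'   attribute.
#' @export
study_design <- function(name = c("heterogeneity-sweep", "individuals-sweep",
                                  "training-fraction-sweep"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "heterogeneity-sweep" = list(G = 100, K = 3, L = 10,
                                 cells_per_individual = 400, sigma2 = 0.1),
    "individuals-sweep" = list(G = 100, K = 3, L = 10,
                               cells_per_individual = 400, sigma2 = 0.1),
    "training-fraction-sweep" = list(G = 100, K = 3, L = 10,
                                     cells_per_individual = 400,
                                     sigma2 = 0.1))
  over <- list(...)
  base[names(over)] <- over
  cfg <- do.call(simulation_config, base)
  if (name == "heterogeneity-sweep")
    attr(cfg, "sigma2_grid") <- c(0.01, 0.1, 0.5, 1)
  if (name == "individuals-sweep")
    attr(cfg, "L_grid") <- c(2, 5, 10, 20)
  if (name == "training-fraction-sweep")
    attr(cfg, "train_fractions") <- seq(0.1, 1, by = 0.1)
  cfg
}
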