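#' Log Dirichlet-multinomial probability mass
#'
#' Marginal probability of a multinomial count vector whose probability
#' vector has been integrated out against a Dirichlet(alpha) prior:
#' \deqn{P(x \mid \alpha) = \frac{T!}{\prod_i x_i!}
#'   \prod_i \frac{\Gamma(x_i+\alpha_i)}{\Gamma(\alpha_i)}
#'   \frac{\Gamma(|\alpha|)}{\Gamma(T+|\alpha|)},}
#' with \eqn{T = \sum_i x_i} and \eqn{|\alpha| = \sum_i \alpha_i}. Computed
#' entirely through `lgamma`; no factorials are formed, so totals of 1e4 and
#' beyond are safe.
#'
#' @param x non-negative integer count vector.
#' @param alpha strictly positive Dirichlet concentration vector, same length.
#' @param include_coef include the multinomial coefficient
#'   \eqn{T!/\prod x_i!}? It is constant in the cluster index, so cluster
#'   assignment ratios omit it (`FALSE`); full likelihoods include it.
#' @return log probability (scalar).
#' @export
log_dm_pmf <- function(x, alpha, include_coef = TRUE) {
  if (length(x) != length(alpha)) stop("x and alpha must have equal length")
  if (any(alpha <= 0)) stop("all Dirichlet parameters must be > 0")
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integers")
  Tt <- sum(x)
  ll <- sum(lgamma(x + alpha) - lgamma(alpha)) +
    lgamma(sum(alpha)) - lgamma(Tt + sum(alpha))
  if (include_coef) ll <- ll + lgamma(Tt + 1) - sum(lgamma(x + 1))
  ll
}

#' Per-cluster log assignment weights for one cell
#'
#' Entry k is `log pi[individual, k] + log DM(x | alpha[, individual, k])`
#' without the multinomial coefficient (it cancels in the posterior over
#' clusters). Normalizing with [normalize_log_weights()] gives the cell's
#' cluster posterior.
#'
#' @param x count vector for one cell (length G).
#' @param alpha G x L x K array of Dirichlet concentrations.
#' @param pi L x K matrix of mixing proportions.
#' @param individual individual index (1..L).
#' @return length-K vector of log weights (`-Inf` allowed where pi is 0).
#' @export
assignment_log_weights <- function(x, alpha, pi, individual) {
  K <- dim(alpha)[3L]
  stopifnot(individual >= 1, individual <= dim(alpha)[2L])
  vapply(seq_len(K), function(k) {
    log(pi[individual, k]) +
      log_dm_pmf(x, alpha[, individual, k], include_coef = FALSE)
  }, numeric(1))
}

#' Normalize log weights to probabilities
#'
#' Stable softmax: `exp(w - logsumexp(w))`. Invariant to adding a constant
#' to every entry.
#'
#' @param w vector of log weights; at least one entry must be finite.
#' @return probability vector summing to 1.
#' @export
normalize_log_weights <- function(w) {
  m <- max(w)
  if (!is.finite(m)) stop("all log weights are -Inf")
  e <- exp(w - m)
  e / sum(e)
}

#' Joint log likelihood of counts and labels
#'
#' Sum over individuals and cells of the collapsed Dirichlet-multinomial log
#' mass of each cell under its assigned cluster's concentration vector,
#' multinomial coefficients included.
#'
#' @param dataset a [count_dataset()].
#' @param labels list of per-individual integer label vectors in 1..K.
#' @param alpha G x L x K concentration array.
#' @return scalar log likelihood.
#' @export
log_joint <- function(dataset, labels, alpha) {
  K <- dim(alpha)[3L]
  bad <- unlist(labels) < 1 | unlist(labels) > K
  if (any(bad)) stop("labels must lie in 1..K")
  ll <- 0
  for (l in seq_along(dataset$matrices)) {
    X <- dataset$matrices[[l]]
    ll <- ll + cpp_loglik_assigned(X, alpha_slice(alpha, l),
                                   as.integer(labels[[l]])) +
      sum(lgamma(colSums(X) + 1)) - sum(lgamma(X + 1))
  }
  ll
}

# G x K concentration matrix of individual l (robust to G == 1 or K == 1)
alpha_slice <- function(alpha, l) {
  d <- dim(alpha)
  matrix(alpha[, l, ], nrow = d[1L], ncol = d[3L])
}

#' Log-normal prior density of the concentration array
#'
#' For each gene i and cluster k the L concentrations alpha\[i, l, k\] are
#' i.i.d. log-normal LN(mu\[i, k\], sigma2\[i, k\]); this returns the total
#' log density over all (i, l, k).
#'
#' @param alpha G x L x K positive array.
#' @param mu G x K location matrix (mean of log alpha).
#' @param sigma2 G x K positive scale matrix (variance of log alpha).
#' @return scalar log prior density.
#' @export
log_prior_alpha <- function(alpha, mu, sigma2) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  la <- log(alpha)
  L <- dim(alpha)[2L]
  total <- 0
  for (l in seq_len(L)) {
    lal <- la[, l, , drop = TRUE]
    total <- total + sum(-lal - 0.5 * log(2 * pi * sigma2) -
                           (lal - mu)^2 / (2 * sigma2))
  }
  total
}

# Constant multinomial-coefficient term of the full likelihood:
# sum over cells of log T! - sum_i log x_i!.
multinomial_coef_const <- function(dataset) {
  s <- 0
  for (X in dataset$matrices)
    s <- s + sum(lgamma(colSums(X) + 1)) - sum(lgamma(X + 1))
  s
}
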