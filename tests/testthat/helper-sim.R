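# Small fixtures shared across test files; everything is generated in code.

# Hand-built two-individual dataset with known counts.
tiny_dataset <- function() {
  m1 <- matrix(c(0, 5, 2,
                 1, 0, 3,
                 4, 4, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "a3")))
  m2 <- matrix(c(2, 0,
                 0, 1,
                 3, 3), nrow = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("b1", "b2")))
  count_dataset(list(m1, m2))
}

# Quick separable simulation for sampler tests.
quick_sim <- function(G = 60, K = 2, L = 2, C = 100, sigma2 = 0.05,
                      separation = 2.5, seed = 1, depth = 500) {
  simulate_dataset(simulation_config(
    G = G, K = K, L = L, cells_per_individual = C, sigma2 = sigma2,
    separation = separation, seed = seed,
    depth_model = list(type = "fixed", depth = depth)))
}

quick_config <- function(K = 2, n_iter = 120, burn_in = 40, seed = 1, ...) {
  sampler_config(K = K, n_iter = n_iter, burn_in = burn_in, seed = seed, ...)
}

pooled_truth <- function(sim) unlist(sim$true_labels, use.names = FALSE)

ari_vs_truth <- function(result, sim) {
  adjusted_rand_index(unlist(result$final_labels, use.names = FALSE),
                      pooled_truth(sim))
}

# Independent beta-binomial log pmf (two-category Dirichlet-multinomial),
# through lchoose/lbeta rather than the package's lgamma composition.
lbetabinom <- function(x, size, a, b) {
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

# All compositions of total Tt into g non-negative parts.
compositions <- function(Tt, g) {
  if (g == 1L) return(matrix(Tt, 1L, 1L))
  out <- NULL
  for (x1 in 0:Tt) {
    sub <- compositions(Tt - x1, g - 1L)
    out <- rbind(out, cbind(x1, sub))
  }
  unname(out)
}
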