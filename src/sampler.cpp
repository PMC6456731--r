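// Hot paths of the Dirichlet-multinomial mixture sampler.
// All randomness comes from R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every routine reproducible.

#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Per-cell, per-cluster log Dirichlet-multinomial mass (multinomial
// coefficient omitted) for one individual.
// X: genes x cells counts; alpha: genes x K concentrations.
// out(j, k) = sum_{i: x>0} [lg(x+a_ik) - lg(a_ik)] + lg(A_k) - lg(T_j + A_k)
// [[Rcpp::export]]
NumericMatrix cpp_cell_logdm(NumericMatrix X, NumericMatrix alpha) {
  const int G = X.nrow(), C = X.ncol(), K = alpha.ncol();
  NumericVector asum(K);
  NumericMatrix lga(G, K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < G; ++i) {
      s += alpha(i, k);
      lga(i, k) = lgamma(alpha(i, k));
    }
    asum[k] = s;
  }
  NumericMatrix out(C, K);
  for (int j = 0; j < C; ++j) {
    double Tj = 0.0;
    for (int i = 0; i < G; ++i) Tj += X(i, j);
    for (int k = 0; k < K; ++k) {
      double w = lgamma(asum[k]) - lgamma(Tj + asum[k]);
      for (int i = 0; i < G; ++i) {
        double x = X(i, j);
        if (x > 0) w += lgamma(x + alpha(i, k)) - lga(i, k);
      }
      out(j, k) = w;
    }
  }
  return out;
}

// Gibbs draw of cell labels for one individual: z_j ~ Categorical over k of
// pi_k * DM(x_j | alpha_k). Returns 1-based labels.
// [[Rcpp::export]]
IntegerVector cpp_sample_labels(NumericMatrix X, NumericMatrix alpha,
                                NumericVector log_pi) {
  NumericMatrix w = cpp_cell_logdm(X, alpha);
  const int C = w.nrow(), K = w.ncol();
  IntegerVector z(C);
  std::vector<double> p(K);
  for (int j = 0; j < C; ++j) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      p[k] = w(j, k) + log_pi[k];
      if (p[k] > m) m = p[k];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      p[k] = exp(p[k] - m);
      tot += p[k];
    }
    double u = unif_rand() * tot, cum = 0.0;
    int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += p[k];
      if (u <= cum) { pick = k; break; }
    }
    z[j] = pick + 1;
  }
  return z;
}

// Log likelihood (no multinomial coefficient) of one individual's cells at
// their assigned clusters.
// [[Rcpp::export]]
double cpp_loglik_assigned(NumericMatrix X, NumericMatrix alpha,
                           IntegerVector z) {
  const int G = X.nrow(), C = X.ncol(), K = alpha.ncol();
  NumericVector asum(K);
  NumericMatrix lga(G, K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int i = 0; i < G; ++i) {
      s += alpha(i, k);
      lga(i, k) = lgamma(alpha(i, k));
    }
    asum[k] = s;
  }
  double ll = 0.0;
  for (int j = 0; j < C; ++j) {
    const int k = z[j] - 1;
    double Tj = 0.0;
    for (int i = 0; i < G; ++i) Tj += X(i, j);
    ll += lgamma(asum[k]) - lgamma(Tj + asum[k]);
    for (int i = 0; i < G; ++i) {
      double x = X(i, j);
      if (x > 0) ll += lgamma(x + alpha(i, k)) - lga(i, k);
    }
  }
  return ll;
}

// Metropolis-within-Gibbs update of one (individual, cluster) concentration
// block. Random-walk proposal on log alpha_i (symmetric on the log scale;
// the log-normal prior becomes Normal(mu_i, sigma2_i) for theta = log
// alpha_i, absorbing the Jacobian). Xt holds the block's cells as rows
// (cells x genes) so a gene is a contiguous column.
// [[Rcpp::export]]
List cpp_update_alpha_block(NumericMatrix Xt, NumericVector alpha,
                            NumericVector mu, NumericVector sigma2,
                            double prop_sd) {
  const int n = Xt.nrow(), G = Xt.ncol();
  NumericVector a = clone(alpha);
  double asum = 0.0;
  for (int i = 0; i < G; ++i) asum += a[i];

  // depth terms lg(T_j + |alpha|) grouped by unique depth
  std::map<double, int> depth_counts;
  for (int j = 0; j < n; ++j) {
    double Tj = 0.0;
    for (int i = 0; i < G; ++i) Tj += Xt(j, i);
    ++depth_counts[Tj];
  }

  int accept = 0;
  for (int i = 0; i < G; ++i) {
    const double cur = a[i], th = log(cur);
    const double thp = th + norm_rand() * prop_sd;
    const double ap = exp(thp);
    const double asump = asum - cur + ap;
    double d = (-(thp - mu[i]) * (thp - mu[i]) +
                (th - mu[i]) * (th - mu[i])) / (2.0 * sigma2[i]);
    if (n > 0) {
      double s = 0.0;
      int nnz = 0;
      for (int j = 0; j < n; ++j) {
        double x = Xt(j, i);
        if (x > 0) {
          s += lgamma(x + ap) - lgamma(x + cur);
          ++nnz;
        }
      }
      d += s - nnz * (lgamma(ap) - lgamma(cur));
      d += n * (lgamma(asump) - lgamma(asum));
      for (std::map<double, int>::const_iterator it = depth_counts.begin();
           it != depth_counts.end(); ++it)
        d -= it->second *
             (lgamma(it->first + asump) - lgamma(it->first + asum));
    }
    if (log(unif_rand()) < d) {
      a[i] = ap;
      asum = asump;
      ++accept;
    }
  }
  return List::create(_["alpha"] = a, _["accept"] = accept);
}
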