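// Collapsed Gibbs sampler for latent Dirichlet allocation on spot x gene
// count matrices. Uses R's RNG (unif_rand) so runs are reproducible under
// set.seed() from the R wrapper.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerMatrix counts, int K, double alpha, double beta,
                   int n_iter, int burnin, int thin) {
  const int S = counts.nrow();
  const int G = counts.ncol();

  // expand tokens
  long total = 0;
  for (int s = 0; s < S; ++s)
    for (int g = 0; g < G; ++g) total += counts(s, g);
  if (total <= 0) stop("empty count matrix");
  std::vector<int> tok_s(total), tok_g(total), z(total);

  std::vector<double> n_kg((size_t)K * G, 0.0), n_sk((size_t)S * K, 0.0),
      n_k(K, 0.0), n_s(S, 0.0);

  GetRNGstate();
  long t = 0;
  for (int s = 0; s < S; ++s) {
    for (int g = 0; g < G; ++g) {
      int c = counts(s, g);
      for (int r = 0; r < c; ++r) {
        int k = (int)(unif_rand() * K);
        if (k == K) k = K - 1;
        tok_s[t] = s; tok_g[t] = g; z[t] = k;
        n_kg[(size_t)k * G + g] += 1.0;
        n_sk[(size_t)s * K + k] += 1.0;
        n_k[k] += 1.0;
        n_s[s] += 1.0;
        ++t;
      }
    }
  }

  const double Gb = G * beta;
  std::vector<double> p(K);
  int n_samples = 0;
  std::vector<double> theta_acc((size_t)K * G, 0.0),
      omega_acc((size_t)S * K, 0.0);
  NumericVector loglik_trace(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    for (long i = 0; i < total; ++i) {
      const int s = tok_s[i], g = tok_g[i];
      int k = z[i];
      n_kg[(size_t)k * G + g] -= 1.0;
      n_sk[(size_t)s * K + k] -= 1.0;
      n_k[k] -= 1.0;
      double cum = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        cum += (n_sk[(size_t)s * K + kk] + alpha) *
               (n_kg[(size_t)kk * G + g] + beta) / (n_k[kk] + Gb);
        p[kk] = cum;
      }
      const double u = unif_rand() * cum;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      z[i] = k;
      n_kg[(size_t)k * G + g] += 1.0;
      n_sk[(size_t)s * K + k] += 1.0;
      n_k[k] += 1.0;
    }

    // collapsed joint log p(w, z) up to constants shared across sweeps
    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
      for (int g = 0; g < G; ++g)
        ll += R::lgammafn(n_kg[(size_t)k * G + g] + beta);
      ll -= R::lgammafn(n_k[k] + Gb);
    }
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < K; ++k)
        ll += R::lgammafn(n_sk[(size_t)s * K + k] + alpha);
      ll -= R::lgammafn(n_s[s] + K * alpha);
    }
    loglik_trace[it] = ll;

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++n_samples;
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + Gb;
        for (int g = 0; g < G; ++g)
          theta_acc[(size_t)k * G + g] +=
              (n_kg[(size_t)k * G + g] + beta) / denom;
      }
      for (int s = 0; s < S; ++s) {
        const double denom = n_s[s] + K * alpha;
        for (int k = 0; k < K; ++k)
          omega_acc[(size_t)s * K + k] +=
              (n_sk[(size_t)s * K + k] + alpha) / denom;
      }
    }
    if (it % 32 == 0) checkUserInterrupt();
  }
  PutRNGstate();

  if (n_samples == 0) stop("no post-burn-in samples; check n_iter/burnin/thin");

  NumericMatrix theta(K, G), omega(S, K);
  for (int k = 0; k < K; ++k) {
    double rs = 0.0;
    for (int g = 0; g < G; ++g) rs += theta_acc[(size_t)k * G + g];
    for (int g = 0; g < G; ++g)
      theta(k, g) = theta_acc[(size_t)k * G + g] / rs;
  }
  for (int s = 0; s < S; ++s) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) rs += omega_acc[(size_t)s * K + k];
    for (int k = 0; k < K; ++k)
      omega(s, k) = omega_acc[(size_t)s * K + k] / rs;
  }

  return List::create(_["theta"] = theta, _["omega"] = omega,
                      _["loglik_trace"] = loglik_trace,
                      _["n_samples"] = n_samples,
                      _["n_tokens"] = (double)total);
}
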