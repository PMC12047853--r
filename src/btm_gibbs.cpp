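#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the biterm topic model.
//
// Biterms b = (w1, w2) are drawn corpus-wide from topic k with
//   P(z_b = k | z_-b) proportional to
//     (n_k + alpha) * (n_{w1|k} + beta) * (n_{w2|k} + beta [+1 if w1==w2])
//     / ((2 n_k + V beta) * (2 n_k + 1 + V beta))
// where all counts exclude biterm b. Uses R's RNG, so results are
// reproducible under set.seed().
//
// Returns final assignments and counts, count averages over post-burn-in
// samples (taken every `sample_every` sweeps), and optionally the
// per-biterm topic assignment frequencies over all post-burn-in sweeps.

// [[Rcpp::export]]
List btm_gibbs_cpp(IntegerMatrix biterms, int V, int K,
                   double alpha, double beta,
                   int n_iter, int burn_in, int sample_every,
                   bool record_assignments) {
  const int B = biterms.nrow();
  if (B < 1) stop("corpus has no biterms");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  IntegerVector z(B);
  std::vector<double> n_k(K, 0.0);
  std::vector<double> n_wk((size_t)V * K, 0.0); // column-major: w + V*k

  // random initialization
  for (int b = 0; b < B; ++b) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[b] = k;
    n_k[k] += 1.0;
    n_wk[biterms(b, 0) + (size_t)V * k] += 1.0;
    n_wk[biterms(b, 1) + (size_t)V * k] += 1.0;
  }

  std::vector<double> avg_n_k(K, 0.0);
  std::vector<double> avg_n_wk((size_t)V * K, 0.0);
  std::vector<double> assign_freq;
  if (record_assignments) assign_freq.assign((size_t)B * K, 0.0);
  int n_samples = 0;
  long n_freq_sweeps = 0;
  std::vector<double> p(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int b = 0; b < B; ++b) {
      const int w1 = biterms(b, 0), w2 = biterms(b, 1);
      const int old = z[b];
      n_k[old] -= 1.0;
      n_wk[w1 + (size_t)V * old] -= 1.0;
      n_wk[w2 + (size_t)V * old] -= 1.0;

      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        const double nk = n_k[k];
        const double nw1 = n_wk[w1 + (size_t)V * k];
        const double nw2 = n_wk[w2 + (size_t)V * k] + (w1 == w2 ? 1.0 : 0.0);
        const double denom = (2.0 * nk + V * beta) * (2.0 * nk + 1.0 + V * beta);
        p[k] = (nk + alpha) * (nw1 + beta) * (nw2 + beta) / denom;
        total += p[k];
      }
      double u = unif_rand() * total;
      int knew = 0;
      double cum = p[0];
      while (u > cum && knew < K - 1) cum += p[++knew];

      z[b] = knew;
      n_k[knew] += 1.0;
      n_wk[w1 + (size_t)V * knew] += 1.0;
      n_wk[w2 + (size_t)V * knew] += 1.0;
    }
    if (it >= burn_in) {
      if (record_assignments) {
        ++n_freq_sweeps;
        for (int b = 0; b < B; ++b) assign_freq[b + (size_t)B * z[b]] += 1.0;
      }
      if ((it - burn_in) % sample_every == 0) {
        ++n_samples;
        for (int k = 0; k < K; ++k) avg_n_k[k] += n_k[k];
        for (size_t i = 0; i < n_wk.size(); ++i) avg_n_wk[i] += n_wk[i];
      }
    }
  }

  NumericVector out_nk(K), out_avg_nk(K);
  NumericMatrix out_nwk(V, K), out_avg_nwk(V, K);
  for (int k = 0; k < K; ++k) {
    out_nk[k] = n_k[k];
    out_avg_nk[k] = avg_n_k[k] / n_samples;
    for (int w = 0; w < V; ++w) {
      out_nwk(w, k) = n_wk[w + (size_t)V * k];
      out_avg_nwk(w, k) = avg_n_wk[w + (size_t)V * k] / n_samples;
    }
  }
  List out = List::create(
    _["z"] = z, _["n_k"] = out_nk, _["n_wk"] = out_nwk,
    _["avg_n_k"] = out_avg_nk, _["avg_n_wk"] = out_avg_nwk,
    _["n_samples"] = n_samples
  );
  if (record_assignments) {
    NumericMatrix freq(B, K);
    for (int k = 0; k < K; ++k)
      for (int b = 0; b < B; ++b)
        freq(b, k) = assign_freq[b + (size_t)B * k] / (double)n_freq_sweeps;
    out["assign_freq"] = freq;
  }
  return out;
}
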