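#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Tokens are given as parallel 0-based vectors (doc[i], word[i]).  phi and
// theta are integrated out; each token's topic assignment is resampled from
//   P(z_i = k | z_-i, w) ∝ (n_dk + alpha) * (n_kw + beta) / (n_k + V*beta).
//
// Samples at iterations burn_in + thin, burn_in + 2*thin, ... are retained;
// phi/theta posterior means are averaged over those samples.  When track_z is
// true the per-token topic assignment is tallied at *every* post-burn-in
// iteration (used to compare z marginals against exact enumeration).
//
// Uses R's RNG (unif_rand) so set.seed() makes runs reproducible.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int D, int V, int K,
                   double alpha, double beta, int n_iter, int burn_in, int thin,
                   bool track_z) {
  const int N = doc.size();
  const double vb = V * beta;
  IntegerVector z(N);
  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nk(K), nd(D);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk(doc[i], k)++; nkw(k, word[i])++; nk[k]++; nd[doc[i]]++;
  }

  NumericMatrix phi_sum(K, V), theta_sum(D, K);
  NumericMatrix phi_last(K, V), theta_last(D, K);
  NumericMatrix zmarg(track_z ? N : 1, track_z ? K : 1);
  NumericVector loglik(n_iter);
  std::vector<double> cum(K);
  int n_retained = 0;
  double z_iters = 0.0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += (ndk(d, j) + alpha) * (nkw(j, w) + beta) / (nk[j] + vb);
        cum[j] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && cum[k] < u) ++k;
      z[i] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }

    // collapsed joint log P(w, z): Dirichlet-multinomial terms for both blocks
    double ll = K * (lgamma(vb) - V * lgamma(beta)) +
                D * (lgamma(K * alpha) - K * lgamma(alpha));
    for (int k2 = 0; k2 < K; ++k2) {
      ll -= lgamma(nk[k2] + vb);
      for (int w2 = 0; w2 < V; ++w2)
        if (nkw(k2, w2) > 0) ll += lgamma(nkw(k2, w2) + beta) - lgamma(beta);
    }
    for (int d2 = 0; d2 < D; ++d2) {
      ll -= lgamma(nd[d2] + K * alpha);
      for (int k2 = 0; k2 < K; ++k2)
        if (ndk(d2, k2) > 0) ll += lgamma(ndk(d2, k2) + alpha) - lgamma(alpha);
    }
    loglik[it - 1] = ll;

    if (it > burn_in) {
      if (track_z) {
        for (int i = 0; i < N; ++i) zmarg(i, z[i]) += 1.0;
        z_iters += 1.0;
      }
      if ((it - burn_in) % thin == 0) {
        ++n_retained;
        for (int k2 = 0; k2 < K; ++k2)
          for (int w2 = 0; w2 < V; ++w2)
            phi_sum(k2, w2) += (nkw(k2, w2) + beta) / (nk[k2] + vb);
        for (int d2 = 0; d2 < D; ++d2)
          for (int k2 = 0; k2 < K; ++k2)
            theta_sum(d2, k2) += (ndk(d2, k2) + alpha) / (nd[d2] + K * alpha);
      }
    }
    if (it == n_iter) {
      for (int k2 = 0; k2 < K; ++k2)
        for (int w2 = 0; w2 < V; ++w2)
          phi_last(k2, w2) = (nkw(k2, w2) + beta) / (nk[k2] + vb);
      for (int d2 = 0; d2 < D; ++d2)
        for (int k2 = 0; k2 < K; ++k2)
          theta_last(d2, k2) = (ndk(d2, k2) + alpha) / (nd[d2] + K * alpha);
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  if (track_z && z_iters > 0)
    for (int i = 0; i < N; ++i)
      for (int k2 = 0; k2 < K; ++k2) zmarg(i, k2) /= z_iters;

  return List::create(
      _["phi_sum"] = phi_sum, _["theta_sum"] = theta_sum,
      _["n_retained"] = n_retained, _["phi_last"] = phi_last,
      _["theta_last"] = theta_last, _["z_final"] = z, _["loglik"] = loglik,
      _["z_marginals"] = zmarg, _["ndk"] = ndk, _["nkw"] = nkw);
}

// Fold-in Gibbs for one held-out document with phi fixed:
//   P(z_i = k) ∝ phi(k, w_i) * (n_dk + alpha).
// Returns the posterior-mean theta over post-burn-in iterations.
// [[Rcpp::export]]
NumericVector lda_fold_in_cpp(IntegerVector word, NumericMatrix phi,
                              double alpha, int n_iter, int burn_in) {
  const int N = word.size(), K = phi.nrow();
  IntegerVector z(N), ndk(K);
  NumericVector theta(K);
  std::vector<double> cum(K);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k; ndk[k]++;
  }
  int n_samp = 0;
  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      int k = z[i];
      ndk[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += phi(j, word[i]) * (ndk[j] + alpha);
        cum[j] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && cum[k] < u) ++k;
      z[i] = k; ndk[k]++;
    }
    if (it > burn_in) {
      ++n_samp;
      for (int j = 0; j < K; ++j) theta[j] += (ndk[j] + alpha) / (N + K * alpha);
    }
  }
  for (int j = 0; j < K; ++j) theta[j] /= n_samp;
  return theta;
}
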