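#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the standard admixture model on multiallelic diploid
// genotypes (independent allele-frequency prior):
//   P_kl ~ Dirichlet(lambda, ..., lambda)    per-cluster allele frequencies
//   q_i  ~ Dirichlet(alpha, ..., alpha)      per-individual ancestry
//   Z    latent cluster-of-origin of every allele copy
// geno is N x 2L with allele codes 1..A_l and 0 for missing; missing copies
// are skipped everywhere. Returns posterior-mean Q and allele frequencies
// (averaged post burn-in) plus a thinned observed-data log-likelihood trace.
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         double alpha, double lambda, int burn_in, int n_iter,
                         int ll_every) {
  const int N = geno.nrow();
  const int L = n_alleles.size();
  std::vector<int> offset(L, 0);
  int n_allele_total = 0;
  for (int l = 0; l < L; ++l) {
    offset[l] = n_allele_total;
    n_allele_total += n_alleles[l];
  }

  // state
  std::vector<int> Z(N * 2 * L, -1);
  std::vector<double> q(N * K, 1.0 / K);
  std::vector<double> freq(K * n_allele_total, 0.0);
  std::vector<double> cnt(K * n_allele_total);
  std::vector<double> nik(N * K);

  // init Z uniformly at random
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 2 * L; ++c)
      if (geno(i, c) > 0)
        Z[i * 2 * L + c] = (int)std::floor(unif_rand() * K) % K;

  std::vector<double> q_sum(N * K, 0.0), freq_sum(K * n_allele_total, 0.0);
  std::vector<double> ll_trace, ll_iter;
  std::vector<double> wk(K);
  int kept = 0;
  const int total = burn_in + n_iter;

  for (int it = 0; it < total; ++it) {
    // P | Z: Dirichlet(lambda + counts) via gamma draws
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a > 0) {
            int k = Z[i * 2 * L + 2 * l + c];
            cnt[k * n_allele_total + offset[l] + a - 1] += 1.0;
          }
        }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(lambda + cnt[k * n_allele_total + offset[l] + a], 1.0);
          freq[k * n_allele_total + offset[l] + a] = g;
          s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a)
          freq[k * n_allele_total + offset[l] + a] /= s;
      }

    // q | Z: Dirichlet(alpha + n_ik)
    std::fill(nik.begin(), nik.end(), 0.0);
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 2 * L; ++c) {
        int k = Z[i * 2 * L + c];
        if (geno(i, c) > 0 && k >= 0) nik[i * K + k] += 1.0;
      }
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + nik[i * K + k], 1.0);
        q[i * K + k] = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) q[i * K + k] /= s;
    }

    // Z | q, P
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            wk[k] = q[i * K + k] * freq[k * n_allele_total + offset[l] + a - 1];
            s += wk[k];
          }
          double u = unif_rand() * s, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += wk[k];
            if (u <= acc) { pick = k; break; }
          }
          Z[i * 2 * L + 2 * l + c] = pick;
        }

    if (it >= burn_in) {
      for (size_t j = 0; j < q_sum.size(); ++j) q_sum[j] += q[j];
      for (size_t j = 0; j < freq_sum.size(); ++j) freq_sum[j] += freq[j];
      ++kept;
    }
    if (ll_every > 0 && (it % ll_every) == 0) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += q[i * K + k] * freq[k * n_allele_total + offset[l] + a - 1];
            ll += std::log(s);
          }
      ll_trace.push_back(ll);
      ll_iter.push_back(it + 1);
    }
  }

  NumericMatrix Q(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = q_sum[i * K + k] / kept;
  // renormalise away accumulated rounding
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Q(i, k);
    for (int k = 0; k < K; ++k) Q(i, k) /= s;
  }
  NumericVector fmean(K * n_allele_total);
  for (int j = 0; j < K * n_allele_total; ++j) fmean[j] = freq_sum[j] / kept;

  return List::create(_["Q"] = Q, _["freq"] = fmean,
                      _["ll"] = wrap(ll_trace), _["ll_iter"] = wrap(ll_iter));
}
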