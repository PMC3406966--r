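#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele-frequency
// priors: cluster allele frequencies ~ Dirichlet(lambda) per locus, individual
// admixture proportions ~ Dirichlet(alpha) with a scalar alpha updated by a
// Metropolis step under a uniform prior on (0, alpha_max]. Allele-copy
// origins are sampled conditionally each sweep. Uses R's RNG, so results are
// reproducible under set.seed().
//
// a1, a2: n x L matrices of 0-based allele indices, -1 for a missing call
// n_alleles: alleles observed per locus
// Returns posterior-mean q, the mean(lnL) - var(lnL)/2 model log-probability
// estimate, and diagnostics.

static void dirichlet_draw(double *gam, int K, double *out) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(gam[k], 1.0);
    if (out[k] < 1e-300) out[k] = 1e-300;
    tot += out[k];
  }
  for (int k = 0; k < K; ++k) out[k] /= tot;
}

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector n_alleles, int K,
                         int burnin, int iters,
                         double lambda, double alpha0, double alpha_sd,
                         double alpha_max) {
  const int n = a1.nrow(), L = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K larger than the number of individuals");

  // allele frequencies P[l]: K x J_l, admixture Q: n x K
  std::vector<NumericMatrix> P(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, n_alleles[l]);
    for (int k = 0; k < K; ++k) {
      std::vector<double> gam(n_alleles[l], lambda), out(n_alleles[l]);
      dirichlet_draw(gam.data(), n_alleles[l], out.data());
      for (int j = 0; j < n_alleles[l]; ++j) P[l](k, j) = out[j];
    }
  }
  NumericMatrix Q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  // origin labels z per copy
  IntegerMatrix z1(n, L), z2(n, L);
  double alpha = alpha0;
  int alpha_rejects = 0, alpha_steps = 0;

  NumericMatrix q_sum(n, K);
  std::vector<double> lnL_kept;
  lnL_kept.reserve(iters);
  double alpha_sum = 0.0;

  std::vector<double> prob(K);
  // per-sweep count accumulators
  std::vector<std::vector<double>> cntP(L);
  for (int l = 0; l < L; ++l) cntP[l].assign((size_t)K * n_alleles[l], 0.0);
  NumericMatrix m_ik(n, K);

  const int total = burnin + iters;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int l = 0; l < L; ++l)
      std::fill(cntP[l].begin(), cntP[l].end(), 0.0);
    std::fill(m_ik.begin(), m_ik.end(), 0.0);
    double lnL = 0.0;

    // 1. sample origins z, accumulate counts and the data log-likelihood
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) {
        int al[2] = { a1(i, l), a2(i, l) };
        IntegerMatrix::iterator zp[2] = { z1.begin() + i + (size_t)n * l,
                                          z2.begin() + i + (size_t)n * l };
        for (int c = 0; c < 2; ++c) {
          int a = al[c];
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[l](k, a);
            tot += prob[k];
          }
          lnL += std::log(tot);
          double u = R::unif_rand() * tot, acc = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { zk = k; break; }
          }
          *(zp[c]) = zk;
          cntP[l][(size_t)zk * n_alleles[l] + a] += 1.0;
          m_ik(i, zk) += 1.0;
        }
      }
    }

    // 2. sample cluster allele frequencies
    for (int l = 0; l < L; ++l) {
      int J = n_alleles[l];
      std::vector<double> gam(J), out(J);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < J; ++j)
          gam[j] = lambda + cntP[l][(size_t)k * J + j];
        dirichlet_draw(gam.data(), J, out.data());
        for (int j = 0; j < J; ++j) P[l](k, j) = out[j];
      }
    }

    // 3. sample admixture proportions
    double sum_log_q = 0.0;
    for (int i = 0; i < n; ++i) {
      std::vector<double> gam(K), out(K);
      for (int k = 0; k < K; ++k) gam[k] = alpha + m_ik(i, k);
      dirichlet_draw(gam.data(), K, out.data());
      for (int k = 0; k < K; ++k) {
        Q(i, k) = out[k];
        sum_log_q += std::log(out[k]);
      }
    }

    // 4. Metropolis update of alpha (uniform prior on (0, alpha_max])
    if (K > 1) {
      double prop = alpha + R::norm_rand() * alpha_sd;
      ++alpha_steps;
      if (prop <= 0.0 || prop > alpha_max) {
        ++alpha_rejects;
      } else {
        double ll_cur = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                        (alpha - 1.0) * sum_log_q;
        double ll_prop = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                         (prop - 1.0) * sum_log_q;
        if (std::log(R::unif_rand()) < ll_prop - ll_cur) alpha = prop;
        else ++alpha_rejects;
      }
    }

    if (sweep >= burnin) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += Q(i, k);
      lnL_kept.push_back(lnL);
      alpha_sum += alpha;
    }
  }

  NumericMatrix q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = q_sum(i, k) / iters;

  double mean_lnL = 0.0;
  for (double v : lnL_kept) mean_lnL += v;
  mean_lnL /= lnL_kept.size();
  double var_lnL = 0.0;
  for (double v : lnL_kept) var_lnL += (v - mean_lnL) * (v - mean_lnL);
  var_lnL = lnL_kept.size() > 1 ? var_lnL / (lnL_kept.size() - 1) : 0.0;

  return List::create(
    _["q"] = q,
    _["lnP"] = mean_lnL - var_lnL / 2.0,
    _["mean_lnL"] = mean_lnL,
    _["var_lnL"] = var_lnL,
    _["alpha"] = alpha_sum / iters,
    _["alpha_reject_rate"] = alpha_steps ? (double)alpha_rejects / alpha_steps
                                         : NA_REAL);
}
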