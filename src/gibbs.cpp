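#include <Rcpp.h>
using namespace Rcpp;

// Admixture-model Gibbs sampler for co-dominant diploid genotypes.
//
// a1, a2: n x m integer allele codes (1-based per locus, 0 = missing copy).
// Sweep order: (i) allele-copy origins Z | P, Q; (ii) allele frequencies
// P | Z ~ Dirichlet(lambda + counts); (iii) admixture proportions
// Q | Z ~ Dirichlet(alpha + counts).  The log-likelihood of the current
// (Q, P) state is accumulated during the Z sweep, where the mixture
// denominators are already in hand.
//
// Uses R's RNG throughout, so results are reproducible under set.seed().

static void rdirichlet_row(double *out, const double *shape, int K) {
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(shape[k], 1.0);
    // guard against underflow to an all-zero row
    if (out[k] < 1e-300) out[k] = 1e-300;
    s += out[k];
  }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// log density (up to a constant) of all Q rows under symmetric
// Dirichlet(alpha), as a function of alpha
static double alpha_logpost(double alpha, int n, int K, double sumLogQ) {
  return n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
    (alpha - 1.0) * sumLogQ;
}

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix a1, IntegerMatrix a2, int K,
                         int burnin, int iters, double alpha, double lambda,
                         IntegerVector nAlleles, bool inferAlpha = true,
                         double alphaPropSd = 0.025, double alphaMax = 10.0) {
  const int n = a1.nrow(), m = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (iters < 1) stop("need at least one main iteration");

  // state
  NumericMatrix Q(n, K);
  std::vector<NumericMatrix> P(m);
  IntegerMatrix Z1(n, m), Z2(n, m);

  // init from the priors
  std::vector<double> shape(std::max(K, 64)), tmp(std::max(K, 64));
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) shape[k] = alpha;
    rdirichlet_row(tmp.data(), shape.data(), K);
    for (int k = 0; k < K; ++k) Q(i, k) = tmp[k];
  }
  for (int l = 0; l < m; ++l) {
    int J = nAlleles[l];
    NumericMatrix Pl(K, J);
    for (int k = 0; k < K; ++k) {
      std::vector<double> sh(J, lambda), out(J);
      rdirichlet_row(out.data(), sh.data(), J);
      for (int j = 0; j < J; ++j) Pl(k, j) = out[j];
    }
    P[l] = Pl;
  }

  // accumulators (post burn-in means)
  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(m);
  for (int l = 0; l < m; ++l) Psum[l] = NumericMatrix(K, nAlleles[l]);
  NumericVector lnLtrace(iters);
  double alphaSum = 0.0;

  std::vector<double> pr(K);

  for (int t = 0; t < burnin + iters; ++t) {
    // (i) Z | P, Q  (and log-likelihood of the current state)
    double lnL = 0.0;
    for (int l = 0; l < m; ++l) {
      NumericMatrix &Pl = P[l];
      for (int i = 0; i < n; ++i) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy ? a2(i, l) : a1(i, l);
          IntegerMatrix &Z = copy ? Z2 : Z1;
          if (a == 0) { Z(i, l) = 0; continue; }
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            pr[k] = Q(i, k) * Pl(k, a - 1);
            s += pr[k];
          }
          lnL += std::log(s);
          double u = unif_rand() * s, cum = 0.0;
          int z = K;
          for (int k = 0; k < K; ++k) {
            cum += pr[k];
            if (u <= cum) { z = k + 1; break; }
          }
          Z(i, l) = z;
        }
      }
    }

    // (ii) P | Z
    for (int l = 0; l < m; ++l) {
      int J = nAlleles[l];
      std::vector<double> cnt((size_t)K * J, 0.0);
      for (int i = 0; i < n; ++i) {
        int a = a1(i, l), z = Z1(i, l);
        if (a > 0 && z > 0) cnt[(size_t)(z - 1) * J + (a - 1)] += 1.0;
        a = a2(i, l); z = Z2(i, l);
        if (a > 0 && z > 0) cnt[(size_t)(z - 1) * J + (a - 1)] += 1.0;
      }
      NumericMatrix &Pl = P[l];
      std::vector<double> sh(J), out(J);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < J; ++j) sh[j] = lambda + cnt[(size_t)k * J + j];
        rdirichlet_row(out.data(), sh.data(), J);
        for (int j = 0; j < J; ++j) Pl(k, j) = out[j];
      }
    }

    // (iii) Q | Z
    double sumLogQ = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) shape[k] = alpha;
      for (int l = 0; l < m; ++l) {
        if (Z1(i, l) > 0) shape[Z1(i, l) - 1] += 1.0;
        if (Z2(i, l) > 0) shape[Z2(i, l) - 1] += 1.0;
      }
      rdirichlet_row(tmp.data(), shape.data(), K);
      for (int k = 0; k < K; ++k) {
        Q(i, k) = tmp[k];
        sumLogQ += std::log(tmp[k]);
      }
    }

    // (iv) optional random-walk Metropolis update of alpha
    if (inferAlpha && K > 1) {
      double prop = alpha + R::norm_rand() * alphaPropSd;
      if (prop > 0.0 && prop < alphaMax) {
        double logr = alpha_logpost(prop, n, K, sumLogQ) -
          alpha_logpost(alpha, n, K, sumLogQ);
        if (logr >= 0.0 || unif_rand() < std::exp(logr)) alpha = prop;
      }
    }

    if (t >= burnin) {
      lnLtrace[t - burnin] = lnL;
      alphaSum += alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < m; ++l) {
        NumericMatrix &Pl = P[l], &Ps = Psum[l];
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < nAlleles[l]; ++j) Ps(k, j) += Pl(k, j);
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= iters;
  List Pout(m);
  for (int l = 0; l < m; ++l) {
    NumericMatrix &Ps = Psum[l];
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < nAlleles[l]; ++j) Ps(k, j) /= iters;
    Pout[l] = Ps;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout, _["lnL"] = lnLtrace,
                      _["alphaHat"] = alphaSum / iters);
}
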