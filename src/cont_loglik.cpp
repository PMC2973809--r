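#include <Rcpp.h>
using namespace Rcpp;

// Time-quadrature Gaussian-mixture log-likelihood of pairwise snapshot
// observations under a single-harmonic mean-trajectory model, with its
// analytic gradient.  The per-observation likelihood is
//   (1/T) int_0^T N(x_a; mu_a(t), s_a) N(x_b; mu_b(t), s_b) dt,
// approximated by a uniform K-point rule (trapezoid on a periodic
// integrand, i.e. equal weights), evaluated with log-sum-exp.
//
// Parameters per gene: mu0 (baseline), A (amplitude), phi (phase),
// sigma (noise sd).  ia/ib are 1-based gene indices per observation.
// The gradient is returned packed as (mu0, A, phi, sigma).
// [[Rcpp::export]]
List cont_loglik_cpp(NumericVector mu0, NumericVector A, NumericVector phi,
                     NumericVector sigma, IntegerVector ia, IntegerVector ib,
                     NumericVector xa, NumericVector xb, int K, double period,
                     bool want_grad) {
  const int N = mu0.size();
  const int M = ia.size();
  const double w = 2.0 * M_PI / period;
  const double logK = std::log((double)K);
  const double log2pi = std::log(2.0 * M_PI);

  // mu[i + k*N]: mean of gene i at grid time k
  std::vector<double> mu(N * K), cosang(N * K), sinang(N * K);
  for (int k = 0; k < K; ++k) {
    double t = period * (double)k / (double)K;
    for (int i = 0; i < N; ++i) {
      double ang = w * t + phi[i];
      double c = std::cos(ang), s = std::sin(ang);
      cosang[i + k * N] = c;
      sinang[i + k * N] = s;
      mu[i + k * N] = mu0[i] + A[i] * c;
    }
  }

  std::vector<double> lk(K), za(K), zb(K);
  NumericVector grad(want_grad ? 4 * N : 0);
  double total = 0.0;

  for (int r = 0; r < M; ++r) {
    int a = ia[r] - 1, b = ib[r] - 1;
    double sa = sigma[a], sb = sigma[b];
    double inva = 1.0 / sa, invb = 1.0 / sb;
    double lognorm = -std::log(sa) - std::log(sb) - log2pi;
    double mx = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double da = (xa[r] - mu[a + k * N]) * inva;
      double db = (xb[r] - mu[b + k * N]) * invb;
      za[k] = da;
      zb[k] = db;
      double l = -0.5 * (da * da + db * db) + lognorm;
      lk[k] = l;
      if (l > mx) mx = l;
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(lk[k] - mx);
    total += mx + std::log(sum) - logK;

    if (want_grad) {
      double ga_mu0 = 0, ga_A = 0, ga_phi = 0, ga_sig = 0;
      double gb_mu0 = 0, gb_A = 0, gb_phi = 0, gb_sig = 0;
      for (int k = 0; k < K; ++k) {
        double wk = std::exp(lk[k] - mx) / sum;
        // d l / d mu_a = za/sa ; d mu_a/d mu0 = 1, /dA = cos, /dphi = -A sin
        double dmu_a = za[k] * inva;
        double dmu_b = zb[k] * invb;
        ga_mu0 += wk * dmu_a;
        ga_A += wk * dmu_a * cosang[a + k * N];
        ga_phi += wk * dmu_a * (-A[a] * sinang[a + k * N]);
        ga_sig += wk * (za[k] * za[k] - 1.0) * inva;
        gb_mu0 += wk * dmu_b;
        gb_A += wk * dmu_b * cosang[b + k * N];
        gb_phi += wk * dmu_b * (-A[b] * sinang[b + k * N]);
        gb_sig += wk * (zb[k] * zb[k] - 1.0) * invb;
      }
      grad[a] += ga_mu0;
      grad[N + a] += ga_A;
      grad[2 * N + a] += ga_phi;
      grad[3 * N + a] += ga_sig;
      grad[b] += gb_mu0;
      grad[N + b] += gb_A;
      grad[2 * N + b] += gb_phi;
      grad[3 * N + b] += gb_sig;
    }
  }

  if (want_grad) {
    return List::create(_["loglik"] = total, _["grad"] = grad);
  }
  return List::create(_["loglik"] = total);
}
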