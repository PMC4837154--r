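// Compiled transcriptions of the two sequential belief-update filters.
// These mirror the exported R step functions exactly (the test suite enforces
// equality to machine precision); they exist because model inversion needs
// ~10^3-10^4 likelihood evaluations per fit, each a full pass over a block.

#include <Rcpp.h>
using namespace Rcpp;

static const double OMEGA_CLAMP = 1e-12;
static const double LOG2PI = 1.8378770664093454836;

static inline double norm_logpdf(double x, double m, double v) {
  double d = x - m;
  return -0.5 * (LOG2PI + std::log(v)) - d * d / (2.0 * v);
}

static inline double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// ---------------------------------------------------------------------------
// HGF

struct HgfOut {
  int invalid_at;     // 0 = ok, else 1-based trial of first invalid update
  double total_surprise;
};

// Runs the filter; if store != nullptr, writes per-trial internals into the
// provided 11-column matrix (mu1 sigma1 mu2 sigma2 alpha1 eps1 eps2 delta2
// w2t r2t surprise). mu1_out (if non-null) receives the mu1 trajectory.
static HgfOut hgf_run(const double* obs, int T,
                      double mu0_1, double sigma0_1, double s,
                      double mu0_2, double sigma0_2, double eta,
                      double* store, double* mu1_out) {
  double mu1 = mu0_1, sigma1 = sigma0_1, mu2 = mu0_2, sigma2 = sigma0_2;
  double total = 0.0;
  for (int t = 0; t < T; ++t) {
    double o = obs[t];
    double p_mu1 = mu1, p_sigma1 = sigma1, p_mu2 = mu2, p_sigma2 = sigma2;
    double E = std::exp(p_mu2);
    double g = p_sigma1 + E;
    double n_sigma1 = 1.0 / (1.0 / s + 1.0 / g);
    double alpha1 = n_sigma1 / s;
    double eps1 = alpha1 * (o - p_mu1);
    double n_mu1 = p_mu1 + eps1;
    double w2t = E / g;
    double r2t = (E - p_sigma1) / g;
    double delta2 = (n_sigma1 + eps1 * eps1) / g - 1.0;
    double prec2 = 1.0 / (p_sigma2 + eta) + 0.5 * w2t * (w2t + r2t * delta2);
    if (!std::isfinite(prec2) || prec2 <= 0.0) {
      HgfOut out; out.invalid_at = t + 1; out.total_surprise = R_PosInf;
      return out;
    }
    double n_sigma2 = 1.0 / prec2;
    double eps2 = 0.5 * n_sigma2 * w2t * delta2;
    double n_mu2 = p_mu2 + eps2;

    double g_post = p_sigma1 + std::exp(n_mu2);
    double F = -0.5 * std::log(s) -
               (n_sigma1 + (o - n_mu1) * (o - n_mu1)) / (2.0 * s) -
               0.5 * std::log(g_post) -
               (n_sigma1 + (n_mu1 - p_mu1) * (n_mu1 - p_mu1)) / (2.0 * g_post) -
               0.5 * std::log(p_sigma2 + eta) -
               (n_sigma2 + (n_mu2 - p_mu2) * (n_mu2 - p_mu2)) /
                 (2.0 * (p_sigma2 + eta)) -
               0.5 * LOG2PI + 1.0 + 0.5 * std::log(n_sigma1 * n_sigma2);
    if (!std::isfinite(F)) {
      HgfOut out; out.invalid_at = t + 1; out.total_surprise = R_PosInf;
      return out;
    }
    mu1 = n_mu1; sigma1 = n_sigma1; mu2 = n_mu2; sigma2 = n_sigma2;
    total += -F;
    if (store) {
      store[t + 0L * T] = mu1;    store[t + 1L * T] = sigma1;
      store[t + 2L * T] = mu2;    store[t + 3L * T] = sigma2;
      store[t + 4L * T] = alpha1; store[t + 5L * T] = eps1;
      store[t + 6L * T] = eps2;   store[t + 7L * T] = delta2;
      store[t + 8L * T] = w2t;    store[t + 9L * T] = r2t;
      store[t + 10L * T] = -F;
    }
    if (mu1_out) mu1_out[t] = mu1;
  }
  HgfOut out; out.invalid_at = 0; out.total_surprise = total;
  return out;
}

// [[Rcpp::export]]
List cpp_hgf_filter(NumericVector obs, double mu0_1, double sigma0_1,
                    double s, double mu0_2, double sigma0_2, double eta) {
  int T = obs.size();
  NumericMatrix store(T, 11);
  HgfOut res = hgf_run(obs.begin(), T, mu0_1, sigma0_1, s, mu0_2, sigma0_2,
                       eta, store.begin(), nullptr);
  return List::create(_["internals"] = store,
                      _["total_surprise"] = res.total_surprise,
                      _["invalid_at"] = res.invalid_at);
}

// [[Rcpp::export]]
double cpp_hgf_loglik(NumericVector obs, NumericVector resp,
                      double mu0_1, double sigma0_1, double s,
                      double mu0_2, double sigma0_2, double eta,
                      double sigma_r) {
  int T = obs.size();
  std::vector<double> mu1(T);
  HgfOut res = hgf_run(obs.begin(), T, mu0_1, sigma0_1, s, mu0_2, sigma0_2,
                       eta, nullptr, mu1.data());
  if (res.invalid_at != 0) return R_NegInf;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += norm_logpdf(resp[t], mu1[t], sigma_r);
  return std::isfinite(ll) ? ll : R_NegInf;
}

// obs_matrix: T x N, one block per column; returns summed total surprise
// (+Inf if any block hits an invalid update).
// [[Rcpp::export]]
double cpp_hgf_total_surprise(NumericMatrix obs, double mu0_1,
                              double sigma0_1, double s, double mu0_2,
                              double sigma0_2, double eta) {
  int T = obs.nrow(), N = obs.ncol();
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    HgfOut res = hgf_run(&obs(0, n), T, mu0_1, sigma0_1, s, mu0_2, sigma0_2,
                         eta, nullptr, nullptr);
    if (res.invalid_at != 0) return R_PosInf;
    total += res.total_surprise;
  }
  return total;
}

// ---------------------------------------------------------------------------
// CPM

struct CpmOut {
  int invalid_at;
  double total_surprise;
};

// store: 8-column matrix (mu1 sigma1 mu2 alpha1 eps1 eps2 omega surprise)
static CpmOut cpm_run(const double* obs, int T,
                      double mu0_1, double sigma0_1, double s,
                      double w1, double w2, double h, double a,
                      double* store, double* mu1_out) {
  double mu1 = mu0_1, sigma1 = sigma0_1;
  double h_c = std::min(std::max(h, OMEGA_CLAMP), 1.0 - OMEGA_CLAMP);
  double mu2 = std::log(h_c / (1.0 - h_c)) / a;
  double total = 0.0;
  for (int t = 0; t < T; ++t) {
    double o = obs[t];
    double l_stay = norm_logpdf(o, mu1, sigma1 + w1 + s);
    double l_change = norm_logpdf(o, 0.0, s + w2);
    double omega, surprise;
    if (h == 0.0) {
      omega = 0.0; surprise = -l_stay;
    } else if (h == 1.0) {
      omega = 1.0; surprise = -l_change;
    } else {
      double ls = l_stay + std::log1p(-h), lc = l_change + std::log(h);
      omega = 1.0 / (1.0 + std::exp(ls - lc));
      surprise = -logsumexp2(ls, lc);
    }
    double n_sigma1 = 1.0 / ((1.0 - omega) / (sigma1 + w1) + 1.0 / s);
    double alpha1 = n_sigma1 / s;
    double eps1 = alpha1 * (o - mu1);
    double n_mu1 = mu1 + eps1;
    double om_c = std::min(std::max(omega, OMEGA_CLAMP), 1.0 - OMEGA_CLAMP);
    double n_mu2 = std::log(om_c / (1.0 - om_c)) / a;
    double eps2 = n_mu2 - mu2;
    if (!std::isfinite(n_mu1) || !std::isfinite(surprise)) {
      CpmOut out; out.invalid_at = t + 1; out.total_surprise = R_PosInf;
      return out;
    }
    mu1 = n_mu1; sigma1 = n_sigma1; mu2 = n_mu2;
    total += surprise;
    if (store) {
      store[t + 0L * T] = mu1;    store[t + 1L * T] = sigma1;
      store[t + 2L * T] = mu2;    store[t + 3L * T] = alpha1;
      store[t + 4L * T] = eps1;   store[t + 5L * T] = eps2;
      store[t + 6L * T] = omega;  store[t + 7L * T] = surprise;
    }
    if (mu1_out) mu1_out[t] = mu1;
  }
  CpmOut out; out.invalid_at = 0; out.total_surprise = total;
  return out;
}

// [[Rcpp::export]]
List cpp_cpm_filter(NumericVector obs, double mu0_1, double sigma0_1,
                    double s, double w1, double w2, double h, double a) {
  int T = obs.size();
  NumericMatrix store(T, 8);
  CpmOut res = cpm_run(obs.begin(), T, mu0_1, sigma0_1, s, w1, w2, h, a,
                       store.begin(), nullptr);
  return List::create(_["internals"] = store,
                      _["total_surprise"] = res.total_surprise,
                      _["invalid_at"] = res.invalid_at);
}

// [[Rcpp::export]]
double cpp_cpm_loglik(NumericVector obs, NumericVector resp,
                      double mu0_1, double sigma0_1, double s,
                      double w1, double w2, double h, double a,
                      double sigma_r) {
  int T = obs.size();
  std::vector<double> mu1(T);
  CpmOut res = cpm_run(obs.begin(), T, mu0_1, sigma0_1, s, w1, w2, h, a,
                       nullptr, mu1.data());
  if (res.invalid_at != 0) return R_NegInf;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += norm_logpdf(resp[t], mu1[t], sigma_r);
  return std::isfinite(ll) ? ll : R_NegInf;
}

// [[Rcpp::export]]
double cpp_cpm_total_surprise(NumericMatrix obs, double mu0_1,
                              double sigma0_1, double s, double w1,
                              double w2, double h, double a) {
  int T = obs.nrow(), N = obs.ncol();
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    CpmOut res = cpm_run(&obs(0, n), T, mu0_1, sigma0_1, s, w1, w2, h, a,
                         nullptr, nullptr);
    if (res.invalid_at != 0) return R_PosInf;
    total += res.total_surprise;
  }
  return total;
}
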