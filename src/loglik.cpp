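#include <Rcpp.h>
using namespace Rcpp;

// Effort-discounting choice likelihood, evaluated in the unconstrained
// (logit-transformed) parameter space used by the hierarchical fitter.
//
// Parameter vector layout: K entries first (1 or 2), then beta entries
// (1 or 2).  Natural scale: K = 1.5 * sigmoid(x), beta = 4 * sigmoid(y).
// family: 1 = linear, 2 = hyperbolic, 3 = parabolic.
// recip: 1 = self, 2 = other.  rest option is worth 1 undiscounted credit.

static const double K_BOUND = 1.5;
static const double B_BOUND = 4.0;
static const double REST = 1.0;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double softplus(double z) {
  // log(1 + exp(z)), overflow-safe
  if (z > 35.0) return z;
  if (z < -35.0) return 0.0;
  return std::log1p(std::exp(z));
}

struct ParamsNat {
  double K[2];    // self, other
  double beta[2];
  double dKdx[2]; // chain factors w.r.t. transformed coords
  double dBdy[2];
  int k_idx[2];   // position in x of the K used for recip 1/2
  int b_idx[2];
};

static ParamsNat expand_params(const NumericVector &x, bool k2, bool b2) {
  ParamsNat p;
  int nk = k2 ? 2 : 1;
  for (int r = 0; r < 2; ++r) {
    int ik = k2 ? r : 0;
    int ib = b2 ? r : 0;
    double sk = sigmoid(x[ik]);
    double sb = sigmoid(x[nk + ib]);
    p.K[r] = K_BOUND * sk;
    p.beta[r] = B_BOUND * sb;
    p.dKdx[r] = K_BOUND * sk * (1.0 - sk);
    p.dBdy[r] = B_BOUND * sb * (1.0 - sb);
    p.k_idx[r] = ik;
    p.b_idx[r] = nk + ib;
  }
  return p;
}

static inline double value_diff(int family, double K, double E, double R,
                                double *dVdK) {
  double V;
  switch (family) {
  case 1: V = R - K * E; *dVdK = -E; break;
  case 2: {
    double d = 1.0 + K * E;
    V = R / d; *dVdK = -R * E / (d * d); break;
  }
  default: V = R - K * E * E; *dVdK = -E * E; break;
  }
  return V - REST;
}

// [[Rcpp::export]]
double nll_map_cpp(NumericVector x, IntegerVector choice, NumericVector E,
                   NumericVector R, IntegerVector recip, int family,
                   bool k2, bool b2, NumericVector mu, NumericVector sigma2,
                   bool use_prior) {
  ParamsNat p = expand_params(x, k2, b2);
  int n = choice.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    int r = recip[i] - 1;
    double dVdK;
    double dv = value_diff(family, p.K[r], E[i], R[i], &dVdK);
    double z = p.beta[r] * dv;
    // -log p(chosen): softplus(-z) if work chosen, softplus(z) if rest
    nll += choice[i] ? softplus(-z) : softplus(z);
  }
  if (use_prior)
    for (int j = 0; j < x.size(); ++j) {
      double d = x[j] - mu[j];
      nll += 0.5 * d * d / sigma2[j];
    }
  return nll;
}

// [[Rcpp::export]]
NumericVector nll_map_grad_cpp(NumericVector x, IntegerVector choice,
                               NumericVector E, NumericVector R,
                               IntegerVector recip, int family, bool k2,
                               bool b2, NumericVector mu, NumericVector sigma2,
                               bool use_prior) {
  ParamsNat p = expand_params(x, k2, b2);
  int n = choice.size();
  NumericVector g(x.size());
  for (int i = 0; i < n; ++i) {
    int r = recip[i] - 1;
    double dVdK;
    double dv = value_diff(family, p.K[r], E[i], R[i], &dVdK);
    double z = p.beta[r] * dv;
    double pw = sigmoid(z);
    double resid = (choice[i] ? 1.0 : 0.0) - pw; // d loglik / d z
    // d nll = -(c - p) dz
    g[p.k_idx[r]] -= resid * p.beta[r] * dVdK * p.dKdx[r];
    g[p.b_idx[r]] -= resid * dv * p.dBdy[r];
  }
  if (use_prior)
    for (int j = 0; j < x.size(); ++j)
      g[j] += (x[j] - mu[j]) / sigma2[j];
  return g;
}

// Log-likelihood of one subject's data under S parameter draws given in the
// transformed space (rows of X); used for Monte-Carlo group evidence.
// [[Rcpp::export]]
NumericVector loglik_draws_cpp(NumericMatrix X, IntegerVector choice,
                               NumericVector E, NumericVector R,
                               IntegerVector recip, int family, bool k2,
                               bool b2) {
  int S = X.nrow(), n = choice.size();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    NumericVector xs = X(s, _);
    ParamsNat p = expand_params(xs, k2, b2);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      int r = recip[i] - 1;
      double dVdK;
      double dv = value_diff(family, p.K[r], E[i], R[i], &dVdK);
      double z = p.beta[r] * dv;
      ll -= choice[i] ? softplus(-z) : softplus(z);
    }
    out[s] = ll;
  }
  return out;
}
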