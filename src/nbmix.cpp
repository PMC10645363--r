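#include <Rcpp.h>
using namespace Rcpp;

// Negative Binomial mixture kernels used by the SVI loop.
//
// Parameterisation (mean/size): for count x with mean mu and size r,
//   log f(x) = lgamma(x+r) - lgamma(r) - lgamma(x+1)
//            + r*log(r) - (x+r)*log(r+mu) + x*log(mu)
// with mu[n,i,k] = rho[n] * theta[i] * C[k,i], where C[k,i] is the expected
// copy number of segment i in cluster k (in [1, H], hence mu > 0).

// Per-cell, per-cluster component log-densities summed over segments:
// L[n,k] = sum_i log f(x[n,i] | mu[n,i,k], r[i]).
// [[Rcpp::export]]
NumericMatrix nb_component_logdens_cpp(const NumericMatrix& X,
                                       const NumericVector& rho,
                                       const NumericVector& theta,
                                       const NumericVector& size,
                                       const NumericMatrix& C) {
  const int N = X.nrow(), I = X.ncol(), K = C.nrow();
  NumericMatrix L(N, K);
  std::vector<double> logtheta(I), logC(K * I);
  for (int i = 0; i < I; ++i) logtheta[i] = std::log(theta[i]);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < I; ++i) logC[k + K * i] = std::log(C(k, i));
  for (int i = 0; i < I; ++i) {
    const double r = size[i], logr = std::log(r);
    const double lgr = R::lgammafn(r);
    for (int n = 0; n < N; ++n) {
      const double x = X(n, i);
      const double cst = R::lgammafn(x + r) - lgr - R::lgammafn(x + 1.0)
                       + r * logr;
      const double base = rho[n] * theta[i];
      const double logbase = std::log(rho[n]) + logtheta[i];
      for (int k = 0; k < K; ++k) {
        const double mu = base * C(k, i);
        L(n, k) += cst - (x + r) * std::log(r + mu)
                 + x * (logbase + logC[k + K * i]);
      }
    }
  }
  return L;
}

// Gradients of weight * sum_n sum_k W[n,k] * sum_i log f(x[n,i]|mu,r)
// with respect to C (expected copies), log(theta) and log(size).
// W are the (fixed) posterior responsibilities; this is the expected
// complete-data gradient that equals the marginal-likelihood gradient.
// [[Rcpp::export]]
List nb_component_grad_cpp(const NumericMatrix& X,
                           const NumericVector& rho,
                           const NumericVector& theta,
                           const NumericVector& size,
                           const NumericMatrix& C,
                           const NumericMatrix& W,
                           const double weight) {
  const int N = X.nrow(), I = X.ncol(), K = C.nrow();
  NumericMatrix gC(K, I);
  NumericVector gLogTheta(I), gLogSize(I);
  for (int i = 0; i < I; ++i) {
    const double r = size[i], logr = std::log(r);
    const double dgr = R::digamma(r);
    double acc_th = 0.0, acc_r = 0.0;
    for (int n = 0; n < N; ++n) {
      const double x = X(n, i);
      const double base = rho[n] * theta[i];
      const double dg_x = R::digamma(x + r) - dgr;
      for (int k = 0; k < K; ++k) {
        const double w = W(n, k);
        if (w <= 0) continue;
        const double mu = base * C(k, i);
        const double rpmu = r + mu;
        // d log f / d mu = x/mu - (x+r)/(r+mu)
        const double dmu = (x > 0 ? x / mu : 0.0) - (x + r) / rpmu;
        gC(k, i) += w * dmu * base;
        acc_th += w * dmu * mu;             // d/d log theta = dmu * mu
        // d log f / d r, times r for the log-size gradient
        acc_r += w * r * (dg_x + logr - std::log(rpmu)
                          + 1.0 - (x + r) / rpmu);
      }
    }
    gLogTheta[i] = weight * acc_th;
    gLogSize[i] = weight * acc_r;
  }
  if (weight != 1.0)
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < I; ++i) gC(k, i) *= weight;
  return List::create(_["gC"] = gC, _["gLogTheta"] = gLogTheta,
                      _["gLogSize"] = gLogSize);
}
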