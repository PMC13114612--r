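// Sequential selective-scan recurrence (forward and reverse-mode backward).
// Matrices are K x (d_state * d_inner) with the state index fastest, matching
// the R-side layout; A is passed as a flat d_state * d_inner vector.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".scan_forward")]]
List scan_forward(const NumericMatrix& u, const NumericMatrix& Delta,
                  const NumericMatrix& Bmat, const NumericMatrix& Cmat,
                  const NumericVector& Avec, const bool euler) {
  const int K = u.nrow(), di = u.ncol();
  const int m = Avec.size();        // d_state * d_inner
  const int ds = m / di;
  NumericMatrix y(K, di), Hmat(K, m), Abarmat(K, m);
  std::vector<double> h(m, 0.0);
  for (int k = 0; k < K; ++k) {
    for (int d = 0; d < di; ++d) {
      const double dd = Delta(k, d), uk = u(k, d);
      double acc = 0.0;
      for (int n = 0; n < ds; ++n) {
        const int idx = d * ds + n;
        const double a = Avec[idx];
        const double abar = std::exp(dd * a);
        const double bbar = euler ? dd * Bmat(k, idx)
                                  : (abar - 1.0) / a * Bmat(k, idx);
        const double hv = abar * h[idx] + bbar * uk;
        h[idx] = hv;
        Hmat(k, idx) = hv;
        Abarmat(k, idx) = abar;
        acc += Cmat(k, idx) * hv;
      }
      y(k, d) = acc;
    }
  }
  return List::create(_["y"] = y, _["Hmat"] = Hmat, _["Abarmat"] = Abarmat);
}

// [[Rcpp::export(name = ".scan_backward")]]
List scan_backward(const NumericMatrix& dy, const NumericMatrix& u,
                   const NumericMatrix& Delta, const NumericMatrix& Bmat,
                   const NumericMatrix& Cmat, const NumericVector& Avec,
                   const bool euler, const NumericMatrix& Hmat,
                   const NumericMatrix& Abarmat) {
  const int K = u.nrow(), di = u.ncol();
  const int m = Avec.size();
  const int ds = m / di;
  NumericMatrix du(K, di), dDelta(K, di), dBmat(K, m), dCmat(K, m);
  NumericVector dA(m);
  std::vector<double> dh(m, 0.0);
  for (int k = K - 1; k >= 0; --k) {
    for (int d = 0; d < di; ++d) {
      const double dd = Delta(k, d), uk = u(k, d), dyk = dy(k, d);
      double du_acc = 0.0, dDelta_acc = 0.0;
      for (int n = 0; n < ds; ++n) {
        const int idx = d * ds + n;
        const double a = Avec[idx];
        const double abar = Abarmat(k, idx);
        const double hk = Hmat(k, idx);
        const double hkm1 = (k > 0) ? Hmat(k - 1, idx) : 0.0;
        const double B = Bmat(k, idx);
        dCmat(k, idx) = dyk * hk;
        double dhv = dh[idx] + Cmat(k, idx) * dyk;
        double dAbar = dhv * hkm1;
        const double dBbar = dhv * uk;
        double bbar_coef;
        if (euler) {
          bbar_coef = dd;
          dDelta_acc += dBbar * B;
        } else {
          bbar_coef = (abar - 1.0) / a;
          dAbar += dBbar * B / a;
          dA[idx] -= dBbar * B * (abar - 1.0) / (a * a);
        }
        dBmat(k, idx) = dBbar * bbar_coef;
        du_acc += dhv * bbar_coef * B;
        dDelta_acc += dAbar * a * abar;
        dA[idx] += dAbar * dd * abar;
        dh[idx] = dhv * abar;
      }
      du(k, d) = du_acc;
      dDelta(k, d) = dDelta_acc;
    }
  }
  return List::create(_["du"] = du, _["dDelta"] = dDelta,
                      _["dBmat"] = dBmat, _["dCmat"] = dCmat, _["dA"] = dA);
}
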