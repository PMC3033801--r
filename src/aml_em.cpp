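#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for the two-sided contamination mixture
//   (1 - alpha) N(0,1) + alpha * 0.5 [N(zeta,1) + N(-zeta,1)]
// run independently on every column of Z (one (alpha, zeta) start per
// column), maximizing the log-likelihood ratio against N(0,1):
//   lambda(alpha, zeta) =
//     sum_j log[(1-alpha) + (alpha/2)(e^{z zeta} + e^{-z zeta}) e^{-zeta^2/2}].
// Each iteration makes one pass over the column, computing the objective and
// the E-step responsibilities together; monotonicity of the objective is
// checked at every iterate.
// [[Rcpp::export]]
List aml_em_cpp(NumericMatrix Z, NumericVector alpha0, NumericVector zeta0,
                int max_iter, double tol) {
  const int P = Z.nrow(), B = Z.ncol();
  NumericVector alpha(B), zeta(B), ll(B);
  IntegerVector iters(B);
  LogicalVector converged(B);
  for (int b = 0; b < B; ++b) {
    const double* z = &Z(0, 0) + (size_t)b * P;
    double a = alpha0[b], zt = zeta0[b];
    double llb = R_NegInf;
    int it_count = 0;
    bool conv = false;
    for (int it = 0; it <= max_iter; ++it) {
      const double h = zt * zt / 2.0;
      double ll_cur = 0.0, sum_r = 0.0, sum_zr = 0.0;
      for (int j = 0; j < P; ++j) {
        double e = z[j] * zt;
        // factor out m >= 0 so no exponential overflows
        double m = std::max(std::fabs(e) - h, 0.0);
        double w0 = (1.0 - a) * std::exp(-m);
        double wp = 0.5 * a * std::exp(e - h - m);
        double wm = 0.5 * a * std::exp(-e - h - m);
        double tot = w0 + wp + wm;
        ll_cur += std::log(tot) + m;
        sum_r += (wp + wm) / tot;
        sum_zr += z[j] * (wp - wm) / tot;
      }
      if (it > 0) {
        if (ll_cur < llb - 1e-6)
          stop("EM decreased the objective (iteration %d)", it);
        if (std::fabs(ll_cur - llb) < tol) {
          llb = ll_cur;
          conv = true;
          break;
        }
        it_count = it;
      }
      llb = ll_cur;
      if (it == max_iter) break;
      // M-step
      a = std::min(std::max(sum_r / P, 0.0), 1.0);
      zt = (sum_r > 0.0) ? std::max(sum_zr / sum_r, 0.0) : 0.0;
    }
    alpha[b] = a;
    zeta[b] = zt;
    ll[b] = llb;
    iters[b] = it_count;
    converged[b] = conv;
  }
  return List::create(_["alpha"] = alpha, _["zeta"] = zeta,
                      _["lambda"] = ll, _["iters"] = iters,
                      _["converged"] = converged);
}
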