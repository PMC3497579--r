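#include <Rcpp.h>
using namespace Rcpp;

// Transition matrix of the linear birth-death process with equal per-gene
// birth and death rate lambda over a branch of length t, parameterised by
// alpha = lambda * t / (1 + lambda * t):
//   P(c | s, t) = sum_{j=0}^{min(s,c)} C(s,j) C(s+c-j-1, s-1)
//                 alpha^(s+c-2j) (1-2*alpha)^j
// Terms are accumulated as signed magnitudes via lgamma so that sizes up to
// a few hundred stay finite; (1-2*alpha) may be negative when lambda*t > 1.
// Row s = 0 is absorbing (extinct families cannot regenerate).

// [[Rcpp::export]]
NumericMatrix bd_trans_matrix_cpp(int smax, double alpha) {
  NumericMatrix P(smax + 1, smax + 1);
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0,1)");
  P(0, 0) = 1.0;
  if (alpha == 0.0) {
    for (int s = 1; s <= smax; ++s) P(s, s) = 1.0;
    return P;
  }
  const double la = std::log(alpha);
  const double onem2a = 1.0 - 2.0 * alpha;
  const double labs = (onem2a == 0.0) ? R_NegInf : std::log(std::fabs(onem2a));
  const bool neg = onem2a < 0.0;
  for (int s = 1; s <= smax; ++s) {
    for (int c = 0; c <= smax; ++c) {
      const int jmax = std::min(s, c);
      double acc = 0.0;
      for (int j = 0; j <= jmax; ++j) {
        if (onem2a == 0.0 && j > 0) break;
        double lmag = Rf_lchoose(s, j) + Rf_lchoose(s + c - j - 1, s - 1)
          + (s + c - 2 * j) * la + (j > 0 ? j * labs : 0.0);
        double term = std::exp(lmag);
        if (neg && (j % 2 == 1)) term = -term;
        acc += term;
      }
      P(s, c) = std::max(acc, 0.0);
    }
  }
  return P;
}
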