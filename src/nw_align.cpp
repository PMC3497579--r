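#include <Rcpp.h>
using namespace Rcpp;

// Seed-weighted global (Needleman-Wunsch) alignment score with affine gaps.
// Bases are integer-encoded 1..5 = A,C,G,U,N; N (5) never matches.
// A match scores `match * seed_mult` when the seed condition holds for the
// aligned pair (both positions seed-marked, or either if both_seed = false),
// otherwise `match`. Mismatches score `mismatch` regardless of seed marks.
// A gap of length L scores gap_open + L * gap_ext (open charged once).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
double nw_score_cpp(IntegerVector a, IntegerVector b,
                    LogicalVector aseed, LogicalVector bseed,
                    double match, double mismatch,
                    double gap_open, double gap_ext,
                    double seed_mult, bool both_seed) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // M: a[i] aligned to b[j]; X: gap in b (a[i] vs -); Y: gap in a (- vs b[j]).
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1), Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = gap_open + gap_ext * j;
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF; Y[0] = NEG_INF;
    X[0] = gap_open + gap_ext * i;
    for (int j = 1; j <= m; ++j) {
      double sub;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 5) {
        bool seeded = both_seed ? (aseed[i - 1] && bseed[j - 1])
                                : (aseed[i - 1] || bseed[j - 1]);
        sub = seeded ? match * seed_mult : match;
      } else {
        sub = mismatch;
      }
      double best_prev = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = best_prev + sub;
      X[j] = std::max(Mp[j] + gap_open + gap_ext,
                      std::max(Xp[j] + gap_ext, Yp[j] + gap_open + gap_ext));
      Y[j] = std::max(M[j - 1] + gap_open + gap_ext,
                      std::max(Y[j - 1] + gap_ext, X[j - 1] + gap_open + gap_ext));
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// All-vs-all upper-triangle score matrix over integer-encoded sequences.
// [[Rcpp::export]]
NumericMatrix nw_score_matrix_cpp(List seqs, List seeds,
                                  double match, double mismatch,
                                  double gap_open, double gap_ext,
                                  double seed_mult, bool both_seed) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> sq(n);
  std::vector<LogicalVector> sd(n);
  for (int i = 0; i < n; ++i) {
    sq[i] = as<IntegerVector>(seqs[i]);
    sd[i] = as<LogicalVector>(seeds[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = nw_score_cpp(sq[i], sq[j], sd[i], sd[j], match, mismatch,
                              gap_open, gap_ext, seed_mult, both_seed);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
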