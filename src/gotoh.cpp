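// Affine-gap global alignment (Gotoh) with a deterministic traceback, and a
// profile-profile variant used by the progressive multiple aligner.
//
// Gap cost convention: a gap run of length L costs gap_open + (L-1) *
// gap_extend (both parameters are penalties, i.e. negative numbers in the
// defaults). Traceback tie-break prefers, in order: diagonal, up (gap in b),
// left (gap in a).

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

inline double subst(char x, char y, double match, double mismatch) {
  if (x == y && x != 'N') return match;
  return mismatch;
}

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b, double match,
                     double mismatch, double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // state matrices: M ends in substitution, X ends with gap in b (consumes
  // a), Y ends with gap in a (consumes b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double d = std::max(M(i - 1, j - 1),
                          std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      if (d > NEG) M(i, j) = d + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                         std::max(X(i - 1, j) + gap_extend,
                                  Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                         std::max(Y(i, j - 1) + gap_extend,
                                  X(i, j - 1) + gap_open));
    }
  }

  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback; state 0 = M, 1 = X, 2 = Y, preference order M, X, Y
  int state = (M(n, m) == best) ? 0 : (X(n, m) == best ? 1 : 2);
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double need = M(i, j) - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) == need) state = 0;
      else if (X(i, j) == need) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      double cur = X(i, j);
      --i;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (X(i, j) + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      double cur = Y(i, j);
      --j;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (Y(i, j) + gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
}

// Profile columns are frequency vectors over rows A,C,G,T (rows 0-3), N
// (row 4) and gap (row 5). Substitution score between two columns is the
// expected pair score over non-gap, non-N frequencies; gaps and N score 0.
// Returns the merge path as integers: 0 diagonal, 1 consume-A column (gap
// inserted into B), 2 consume-B column (gap inserted into A).
// [[Rcpp::export]]
IntegerVector profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                                double match, double mismatch,
                                double gap_open, double gap_extend) {
  int n = pa.ncol(), m = pb.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x) {
        double fa = pa(x, i - 1);
        if (fa == 0.0) continue;
        for (int y = 0; y < 4; ++y) {
          double fb = pb(y, j - 1);
          if (fb == 0.0) continue;
          s += fa * fb * (x == y ? match : mismatch);
        }
      }
      double d = std::max(M(i - 1, j - 1),
                          std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      if (d > NEG) M(i, j) = d + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                         std::max(X(i - 1, j) + gap_extend,
                                  Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                         std::max(Y(i, j - 1) + gap_extend,
                                  X(i, j - 1) + gap_open));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  int state = (M(n, m) == best) ? 0 : (X(n, m) == best ? 1 : 2);
  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      double s = 0.0;
      for (int x = 0; x < 4; ++x) {
        double fa = pa(x, i - 1);
        if (fa == 0.0) continue;
        for (int y = 0; y < 4; ++y) {
          double fb = pb(y, j - 1);
          if (fb == 0.0) continue;
          s += fa * fb * (x == y ? match : mismatch);
        }
      }
      double need = M(i, j) - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) == need) state = 0;
      else if (X(i, j) == need) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(1);
      double cur = X(i, j);
      --i;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (X(i, j) + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      path.push_back(2);
      double cur = Y(i, j);
      --j;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (Y(i, j) + gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
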