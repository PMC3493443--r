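#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two profiles given the precomputed
// column-vs-column score matrix S (na x nb). End gaps are charged. The
// first residue of a gap costs open + extend, each further residue extend.
// Tie-break: diagonal > up (gap in B) > left (gap in A).
// Returns the optimal score and the traceback path (1 = diagonal,
// 2 = consume a profile-A column, 3 = consume a profile-B column).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix S, double open, double extend) {
  const int na = S.nrow(), nb = S.ncol();
  const double NEG = -1e30;
  // three DP layers: M (match), X (gap in B, moving down), Y (gap in A)
  NumericMatrix M(na + 1, nb + 1), X(na + 1, nb + 1), Y(na + 1, nb + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= na; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -open - extend * i;
  }
  for (int j = 1; j <= nb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -open - extend * j;
  }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double d = std::max(M(i - 1, j - 1),
                          std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + S(i - 1, j - 1);
      X(i, j) = std::max(std::max(M(i - 1, j), Y(i - 1, j)) - open - extend,
                         X(i - 1, j) - extend);
      Y(i, j) = std::max(std::max(M(i, j - 1), X(i, j - 1)) - open - extend,
                         Y(i, j - 1) - extend);
    }
  }
  double best = std::max(M(na, nb), std::max(X(na, nb), Y(na, nb)));
  // traceback
  std::vector<int> path;
  int i = na, j = nb;
  int state; // 0 = M, 1 = X, 2 = Y ; prefer diagonal > up > left
  if (M(na, nb) >= X(na, nb) && M(na, nb) >= Y(na, nb)) state = 0;
  else if (X(na, nb) >= Y(na, nb)) state = 1;
  else state = 2;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(1);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - prev) < eps) state = 0;
      else if (std::abs(X(i, j) - prev) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(2);
      double cur = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - open - extend - cur) < eps) state = 0;
      else if (std::abs(X(i, j) - extend - cur) < eps) state = 1;
      else state = 2;
    } else {
      path.push_back(3);
      double cur = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - open - extend - cur) < eps) state = 0;
      else if (std::abs(Y(i, j) - extend - cur) < eps) state = 2;
      else state = 1;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
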