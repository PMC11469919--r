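#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-score matrix C (rows: positions of a, cols: positions of b).
// A gap of length L costs open + extend * L; end gaps are penalized.
// Deterministic tie-break: match/mismatch (M) preferred over gap-in-a (X,
// consumes b) preferred over gap-in-b (Y, consumes a), both when choosing
// the traceback start state and at every step.
//
// Returned path codes: 1 = diagonal, 2 = gap in a, 3 = gap in b.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix C, double gap_open, double gap_extend) {
  const int n = C.nrow(), m = C.ncol();
  const double go = gap_open + gap_extend, ge = gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // state trace: which predecessor state (0=M,1=X,2=Y) maximized each cell
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; Y(0, j) = NEG_INF;
    X(0, j) = -(gap_open + ge * j);
    tX(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; X(i, 0) = NEG_INF;
    Y(i, 0) = -(gap_open + ge * i);
    tY(i, 0) = 2;
  }

  // pick best with priority M > X > Y at ties
  auto best3 = [](double m_, double x_, double y_, int &arg) {
    double b = m_; arg = 0;
    if (x_ > b) { b = x_; arg = 1; }
    if (y_ > b) { b = y_; arg = 2; }
    return b;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int a;
      double b = best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), a);
      M(i, j) = b + C(i - 1, j - 1); tM(i, j) = a;
      b = best3(M(i, j - 1) - go, X(i, j - 1) - ge, Y(i, j - 1) - go, a);
      X(i, j) = b; tX(i, j) = a;
      b = best3(M(i - 1, j) - go, X(i - 1, j) - go, Y(i - 1, j) - ge, a);
      Y(i, j) = b; tY(i, j) = a;
    }
  }

  int state;
  double score = best3(M(n, m), X(n, m), Y(n, m), state);

  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(1);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      path.push_back(2);
      state = tX(i, j); --j;
    } else {
      path.push_back(3);
      state = tY(i, j); --i;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
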