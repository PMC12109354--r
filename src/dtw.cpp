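#include <Rcpp.h>
using namespace Rcpp;

// Distance-only DTW with squared-difference local cost and the classic
// unconstrained (step up / left / diagonal) recursion. Two rolling rows keep
// memory at O(m) so full 4 s epochs at 2 kHz (8000 x 8000 cells) stay cheap.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = x[0] - y[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    double d0 = x[i] - y[0];
    cur[0] = d0 * d0 + prev[0];
    for (int j = 1; j < m; ++j) {
      double d = x[i] - y[j];
      double best = prev[j];                       // up
      if (prev[j - 1] < best) best = prev[j - 1];  // diagonal
      if (cur[j - 1] < best) best = cur[j - 1];    // left
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Full cumulative matrix plus backtraced optimal path, for inputs small
// enough to hold the n x m matrix. Backtrace tie-break: diagonal, then up,
// then left (the distance is unaffected, only the reported path).
// [[Rcpp::export]]
List dtw_full_cpp(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  NumericMatrix C(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double d = x[i] - y[j];
      d *= d;
      if (i == 0 && j == 0)
        C(i, j) = d;
      else if (i == 0)
        C(i, j) = d + C(i, j - 1);
      else if (j == 0)
        C(i, j) = d + C(i - 1, j);
      else {
        double best = C(i - 1, j - 1);
        if (C(i - 1, j) < best) best = C(i - 1, j);
        if (C(i, j - 1) < best) best = C(i, j - 1);
        C(i, j) = d + best;
      }
    }
  // backtrace from (n, m) to (1, 1)
  std::vector<int> pa, pb;
  int i = n - 1, j = m - 1;
  pa.push_back(i + 1);
  pb.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0)
      --j;
    else if (j == 0)
      --i;
    else {
      double diag = C(i - 1, j - 1), up = C(i - 1, j), left = C(i, j - 1);
      if (diag <= up && diag <= left) {
        --i;
        --j;
      } else if (up <= left)
        --i;
      else
        --j;
    }
    pa.push_back(i + 1);
    pb.push_back(j + 1);
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["distance"] = C(n - 1, m - 1), _["cumulative"] = C,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}

static double bf_rec(const NumericVector& x, const NumericVector& y, int i,
                     int j) {
  double d = x[i] - y[j];
  d *= d;
  if (i == 0 && j == 0) return d;
  double best = R_PosInf, c;
  if (i > 0 && j > 0) {
    c = bf_rec(x, y, i - 1, j - 1);
    if (c < best) best = c;
  }
  if (i > 0) {
    c = bf_rec(x, y, i - 1, j);
    if (c < best) best = c;
  }
  if (j > 0) {
    c = bf_rec(x, y, i, j - 1);
    if (c < best) best = c;
  }
  return d + best;
}

// Exhaustive recursive enumeration of every monotone alignment path: an
// independent oracle for the dynamic-programming kernels. Exponential; the
// R wrapper guards n + m <= 20.
// [[Rcpp::export]]
double brute_force_dtw_cpp(NumericVector x, NumericVector y) {
  return bf_rec(x, y, x.size() - 1, y.size() - 1);
}
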