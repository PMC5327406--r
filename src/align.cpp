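#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman on integer-encoded sequences (1-based codes into
// the score matrix). Tie-break in the traceback: diagonal > up (gap in target)
// > left (gap in query). Best cell: maximal score, then smallest query index,
// then smallest target index, so results are deterministic.
//
// States: M (diagonal), X (consumes query, "up"), Y (consumes target, "left").

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector t, NumericMatrix S,
              double gap_open, double gap_extend, bool traceback = true) {
  const int n = q.size(), m = t.size();
  const double NEG = -1e18;
  if (!traceback) {
    // score-only fast path: rolling rows, no traceback state
    std::vector<double> Mrow(m + 1, 0.0), Xrow(m + 1, NEG), Yrow(m + 1, NEG),
        Mprev(m + 1, 0.0), Xprev(m + 1, NEG), Yprev(m + 1, NEG);
    double best = 0.0;
    const int nrow = S.nrow();
    std::vector<double> Sflat(S.begin(), S.end());  // column-major
    for (int i = 1; i <= n; ++i) {
      std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
      Mrow[0] = 0.0; Xrow[0] = NEG; Yrow[0] = NEG;
      const size_t qoff = (size_t)(q[i - 1] - 1);
      for (int j = 1; j <= m; ++j) {
        double x = std::max(Mprev[j] - gap_open - gap_extend,
                            Xprev[j] - gap_extend);
        double y = std::max(Mrow[j - 1] - gap_open - gap_extend,
                            Yrow[j - 1] - gap_extend);
        double prev = std::max(std::max(Mprev[j - 1], Xprev[j - 1]),
                               std::max(Yprev[j - 1], 0.0));
        double val = prev + Sflat[(size_t)(t[j - 1] - 1) * nrow + qoff];
        if (val < 0.0) val = 0.0;
        Mrow[j] = val; Xrow[j] = x; Yrow[j] = y;
        if (val > best) best = val;
      }
    }
    return List::create(_["score"] = best,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0,
                        _["q_aln"] = IntegerVector(0),
                        _["t_aln"] = IntegerVector(0));
  }
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // traceback codes per state: 0 none/stop, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((n + 1) * (m + 1), 0);
    tbX.assign((n + 1) * (m + 1), 0);
    tbY.assign((n + 1) * (m + 1), 0);
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int diag = (i - 1) * (m + 1) + (j - 1);
      const int up = (i - 1) * (m + 1) + j;
      const int left = i * (m + 1) + (j - 1);
      // X: gap in target (consume query)
      double xo = M[up] - gap_open - gap_extend;
      double xe = X[up] - gap_extend;
      if (xo >= xe) { X[idx] = xo; if (traceback) tbX[idx] = 1; }
      else          { X[idx] = xe; if (traceback) tbX[idx] = 2; }
      // Y: gap in query (consume target)
      double yo = M[left] - gap_open - gap_extend;
      double ye = Y[left] - gap_extend;
      if (yo >= ye) { Y[idx] = yo; if (traceback) tbY[idx] = 1; }
      else          { Y[idx] = ye; if (traceback) tbY[idx] = 3; }
      // M: diagonal extension; tie-break M > X > Y; restart if no positive
      // predecessor (local floor)
      double sc = S(qi, t[j - 1] - 1);
      double vm = M[diag], vx = X[diag], vy = Y[diag];
      double prev; unsigned char code;
      if (vm >= vx && vm >= vy) { prev = vm; code = 1; }
      else if (vx >= vy)        { prev = vx; code = 2; }
      else                      { prev = vy; code = 3; }
      if (prev <= 0.0) { prev = 0.0; code = 0; }
      double val = prev + sc;
      if (val <= 0.0) { val = 0.0; code = 0; }
      M[idx] = val;
      if (traceback) tbM[idx] = code;
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0,
                        _["q_aln"] = IntegerVector(0),
                        _["t_aln"] = IntegerVector(0));
  }
  // traceback from (bi, bj) in state M
  std::vector<int> qa, ta;  // 0 encodes a gap
  int i = bi, j = bj; int state = 1;
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 1) {
      unsigned char code = tbM[idx];
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j;
      if (code == 0) break;
      state = code;
    } else if (state == 2) {
      unsigned char code = tbX[idx];
      qa.push_back(q[i - 1]); ta.push_back(0);
      --i;
      state = code;
    } else {
      unsigned char code = tbY[idx];
      qa.push_back(0); ta.push_back(t[j - 1]);
      --j;
      state = code;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["t_start"] = j, _["t_end"] = bj,
                      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                      _["t_aln"] = IntegerVector(ta.begin(), ta.end()));
}

// Best suffix(a)-prefix(b) overlap of length >= min_overlap: maximise
// identity, then overlap length. Returns c(length, matches) or c(0, 0).
// [[Rcpp::export(name = ".best_overlap")]]
IntegerVector best_overlap(std::string a, std::string b, int min_overlap) {
  const int na = a.size(), nb = b.size();
  const int maxL = std::min(na, nb);
  int bestL = 0, bestM = 0;
  double bestId = -1.0;
  for (int L = min_overlap; L <= maxL; ++L) {
    int matches = 0;
    const char* pa = a.data() + (na - L);
    for (int k = 0; k < L; ++k) if (pa[k] == b[k]) ++matches;
    double id = (double)matches / L;
    if (id > bestId || (id == bestId && L > bestL)) {
      bestId = id; bestL = L; bestM = matches;
    }
  }
  return IntegerVector::create(bestL, bestM);
}

// Hamming mismatch count between equal-length strings.
// [[Rcpp::export(name = ".hamming")]]
int hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int d = 0;
  for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
  return d;
}
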