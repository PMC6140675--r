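#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) with full traceback.
//
// Gap of length L costs gap_open + L * gap_extend. Three-state DP:
//   M  - alignment ends in a substitution column
//   Ix - alignment ends consuming a query residue against a gap ("up")
//   Iy - alignment ends consuming a subject residue against a gap ("left")
// Ties are broken deterministically: diagonal > up > left, and among equal
// cell maxima the smallest (i, j) in row-major order wins.
//
// q and s are 0-based indices into the rows/columns of `mat`.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;  // cost of opening a length-1 gap

  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG);
  std::vector<double> Iy((n + 1) * (m + 1), NEG);
  // predecessor codes: M: 0 = local start, 1 = diag from M, 2 = diag from Ix,
  // 3 = diag from Iy; Ix/Iy: 1 = open (from M), 2 = extend
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pIx((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pIy((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * (m + 1) + j;
      const int cd = (i - 1) * (m + 1) + (j - 1);
      const int cu = (i - 1) * (m + 1) + j;
      const int cl = i * (m + 1) + (j - 1);

      // Ix: consume query residue i (gap in subject)
      double open_x = M[cu] - go, ext_x = Ix[cu] - gap_extend;
      if (open_x >= ext_x) { Ix[c] = open_x; pIx[c] = 1; }
      else { Ix[c] = ext_x; pIx[c] = 2; }

      // Iy: consume subject residue j (gap in query)
      double open_y = M[cl] - go, ext_y = Iy[cl] - gap_extend;
      if (open_y >= ext_y) { Iy[c] = open_y; pIy[c] = 1; }
      else { Iy[c] = ext_y; pIy[c] = 2; }

      // M: substitution, predecessor preference diag-M > diag-Ix > diag-Iy
      const double sub = mat(q[i - 1], s[j - 1]);
      double v = 0.0; unsigned char p = 0;
      if (M[cd] + sub > v) { v = M[cd] + sub; p = 1; }
      if (Ix[cd] + sub > v) { v = Ix[cd] + sub; p = 2; }
      if (Iy[cd] + sub > v) { v = Iy[cd] + sub; p = 3; }
      M[c] = v; pM[c] = p;

      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_aln"] = IntegerVector(0),
                        _["s_aln"] = IntegerVector(0),
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }

  // traceback from (bi, bj) in state M; a zero-valued M cell is the local start
  std::vector<int> qa, sa;  // 0-based residue index, or -1 for a gap
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  while (true) {
    const int c = i * (m + 1) + j;
    if (state == 0) {
      if (M[c] <= 0.0) break;
      const unsigned char p = pM[c];  // p > 0 whenever M[c] > 0
      qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
      --i; --j;
      state = (p == 1) ? 0 : (p == 2) ? 1 : 2;
    } else if (state == 1) {
      const unsigned char p = pIx[c];
      qa.push_back(q[i - 1]); sa.push_back(-1);
      --i;
      state = (p == 1) ? 0 : 1;
    } else {
      const unsigned char p = pIy[c];
      qa.push_back(-1); sa.push_back(s[j - 1]);
      --j;
      state = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(_["score"] = best,
                      _["q_aln"] = wrap(qa), _["s_aln"] = wrap(sa),
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj);
}
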