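#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of a sequence against itself with the
// near-diagonal band j - i < band excluded, affine gaps (gap of length L
// costs gap_open + gap_ext * L). Only the strictly upper region j > i is
// scanned; masked positions are excluded entirely. Used by
// detect_internal_repeats() to locate homologous intra-sequence regions.
//
// codes: 0-based indices into the rows/cols of submat.
// Returns best score and the traceback as paired 1-based indices
// (0 = gap on that side).
// [[Rcpp::export]]
List self_align_cpp(IntegerVector codes, NumericMatrix submat, int band,
                    double gap_open, double gap_ext, LogicalVector mask) {
  const int n = codes.size();
  const double NEG = -1e18;
  // state matrices, (n+1) x (n+1), 1-based over residues
  std::vector<double> M((n + 1) * (n + 1), NEG);
  std::vector<double> Ix((n + 1) * (n + 1), NEG);
  std::vector<double> Iy((n + 1) * (n + 1), NEG);
  // traceback: 0 none, 1 from M, 2 from Ix, 3 from Iy, 4 local start
  std::vector<unsigned char> tM((n + 1) * (n + 1), 0);
  std::vector<unsigned char> tIx((n + 1) * (n + 1), 0);
  std::vector<unsigned char> tIy((n + 1) * (n + 1), 0);
  #define IDX(i, j) ((i) * (n + 1) + (j))

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = i + band; j <= n; ++j) {
      bool ok = !mask[i - 1] && !mask[j - 1];
      if (!ok) continue;
      // match state
      double s = submat(codes[i - 1], codes[j - 1]);
      double m0 = 0.0; unsigned char tb = 4;
      double vM = M[IDX(i - 1, j - 1)];
      double vIx = Ix[IDX(i - 1, j - 1)];
      double vIy = Iy[IDX(i - 1, j - 1)];
      if (vM > m0) { m0 = vM; tb = 1; }
      if (vIx > m0) { m0 = vIx; tb = 2; }
      if (vIy > m0) { m0 = vIy; tb = 3; }
      M[IDX(i, j)] = s + m0;
      tM[IDX(i, j)] = tb;
      // Ix: gap in the second copy (consume i)
      double openx = M[IDX(i - 1, j)] - gap_open - gap_ext;
      double extx = Ix[IDX(i - 1, j)] - gap_ext;
      if (openx >= extx) { Ix[IDX(i, j)] = openx; tIx[IDX(i, j)] = 1; }
      else { Ix[IDX(i, j)] = extx; tIx[IDX(i, j)] = 2; }
      // Iy: gap in the first copy (consume j)
      double openy = M[IDX(i, j - 1)] - gap_open - gap_ext;
      double exty = Iy[IDX(i, j - 1)] - gap_ext;
      if (openy >= exty) { Iy[IDX(i, j)] = openy; tIy[IDX(i, j)] = 1; }
      else { Iy[IDX(i, j)] = exty; tIy[IDX(i, j)] = 3; }
      if (M[IDX(i, j)] > best) { best = M[IDX(i, j)]; bi = i; bj = j; }
    }
  }

  std::vector<int> ai, aj;
  if (bi > 0) {
    int i = bi, j = bj, state = 1; // start in M at the best cell
    while (i > 0 && j > 0) {
      if (state == 1) {
        unsigned char tb = tM[IDX(i, j)];
        ai.push_back(i); aj.push_back(j);
        --i; --j;
        if (tb == 4) break;
        state = tb;
      } else if (state == 2) {
        unsigned char tb = tIx[IDX(i, j)];
        ai.push_back(i); aj.push_back(0);
        --i;
        state = tb;
      } else {
        unsigned char tb = tIy[IDX(i, j)];
        ai.push_back(0); aj.push_back(j);
        --j;
        state = tb;
      }
    }
    std::reverse(ai.begin(), ai.end());
    std::reverse(aj.begin(), aj.end());
  }
  #undef IDX
  return List::create(Named("score") = best,
                      Named("ai") = wrap(ai),
                      Named("aj") = wrap(aj));
}
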