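#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap convention throughout: a gap of length k costs open + k * extend
// (NCBI BLAST convention, so open=11/extend=1 reproduces blastp defaults).

// Local (Smith-Waterman) alignment over a precomputed cell-score matrix S
// (rows = query positions, cols = subject positions). Returns the optimal
// local score and the 1-based inclusive coordinates of the best-scoring
// segment pair. Linear memory: rolling rows with start-origin propagation.
// [[Rcpp::export]]
List cpp_local_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double og = gap_open + gap_extend; // cost of opening a length-1 gap

  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<int> oHprev(n + 1, 0), oHcur(n + 1, 0);
  std::vector<int> oFprev(n + 1, 0), oFcur(n + 1, 0);

  double best = 0.0;
  int bi = 0, bj = 0, borigin = 0;

  for (int i = 1; i <= m; ++i) {
    double E = NEG;
    int oE = 0;
    Hcur[0] = 0.0; Fcur[0] = NEG; oHcur[0] = 0; oFcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (move along subject), row-local
      double e_open = Hcur[j - 1] - og, e_ext = E - gap_extend;
      if (e_open >= e_ext) { E = e_open; oE = oHcur[j - 1]; }
      else                 { E = e_ext; }
      // F: gap in subject (move along query)
      double f_open = Hprev[j] - og, f_ext = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; oFcur[j] = oHprev[j]; }
      else                 { Fcur[j] = f_ext;  oFcur[j] = oFprev[j]; }
      // H
      double diag = Hprev[j - 1] + S(i - 1, j - 1);
      int odiag = Hprev[j - 1] > 0.0 ? oHprev[j - 1] : ((i - 1) * (n + 1) + (j - 1));
      double h = diag; int oh = odiag;
      if (E > h) { h = E; oh = oE; }
      if (Fcur[j] > h) { h = Fcur[j]; oh = oFcur[j]; }
      if (h <= 0.0) { h = 0.0; oh = 0; }
      Hcur[j] = h; oHcur[j] = oh;
      if (h > best) { best = h; bi = i; bj = j; borigin = oh; }
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
    std::swap(oHprev, oHcur); std::swap(oFprev, oFcur);
  }

  int qs = borigin / (n + 1) + 1, ss = borigin % (n + 1) + 1;
  if (best <= 0.0) { qs = ss = bi = bj = 0; }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = bi,
                      _["s_start"] = ss, _["s_end"] = bj);
}

// Global (Needleman-Wunsch/Gotoh) alignment over a precomputed cell-score
// matrix, end gaps penalized. Returns the move path from the top-left:
// 1 = diagonal (consume row+col), 2 = consume row only (gap in columns'
// sequence), 3 = consume col only.
// [[Rcpp::export]]
IntegerVector cpp_global_path(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e30;
  const double og = gap_open + gap_extend;

  std::vector<double> H((m + 1) * (n + 1)), E((m + 1) * (n + 1)), F((m + 1) * (n + 1));
  std::vector<unsigned char> tH((m + 1) * (n + 1)), tE((m + 1) * (n + 1)), tF((m + 1) * (n + 1));
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  H[at(0, 0)] = 0.0; E[at(0, 0)] = NEG; F[at(0, 0)] = NEG;
  for (int j = 1; j <= n; ++j) {
    E[at(0, j)] = -(gap_open + j * gap_extend);
    H[at(0, j)] = E[at(0, j)];
    F[at(0, j)] = NEG;
    tH[at(0, j)] = 3; tE[at(0, j)] = 2; // extend
  }
  for (int i = 1; i <= m; ++i) {
    F[at(i, 0)] = -(gap_open + i * gap_extend);
    H[at(i, 0)] = F[at(i, 0)];
    E[at(i, 0)] = NEG;
    tH[at(i, 0)] = 2; tF[at(i, 0)] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e_open = H[at(i, j - 1)] - og, e_ext = E[at(i, j - 1)] - gap_extend;
      if (e_open >= e_ext) { E[at(i, j)] = e_open; tE[at(i, j)] = 1; }
      else                 { E[at(i, j)] = e_ext;  tE[at(i, j)] = 2; }
      double f_open = H[at(i - 1, j)] - og, f_ext = F[at(i - 1, j)] - gap_extend;
      if (f_open >= f_ext) { F[at(i, j)] = f_open; tF[at(i, j)] = 1; }
      else                 { F[at(i, j)] = f_ext;  tF[at(i, j)] = 2; }
      double diag = H[at(i - 1, j - 1)] + S(i - 1, j - 1);
      double h = diag; unsigned char t = 1;
      if (F[at(i, j)] > h) { h = F[at(i, j)]; t = 2; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; t = 3; }
      H[at(i, j)] = h; tH[at(i, j)] = t;
    }
  }

  // traceback
  std::vector<int> rev;
  int i = m, j = n;
  int state = 0; // 0 = H, 2 = in F run, 3 = in E run
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tH[at(i, j)];
      if (t == 1 && i > 0 && j > 0) { rev.push_back(1); --i; --j; }
      else if (t == 2) { state = 2; }
      else { state = 3; }
    } else if (state == 2) {
      unsigned char t = tF[at(i, j)];
      rev.push_back(2); --i;
      state = (t == 1) ? 0 : 2;
    } else {
      unsigned char t = tE[at(i, j)];
      rev.push_back(3); --j;
      state = (t == 1) ? 0 : 3;
    }
  }
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  return path;
}
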