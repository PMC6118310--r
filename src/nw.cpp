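// Global (Needleman-Wunsch) protein alignment with affine gap penalties
// (Gotoh three-state recursion). Scoring convention matches EMBOSS needle /
// Biostrings: the first residue of a gap costs gap_open + gap_ext, each
// further residue gap_ext. Tie-break is deterministic: match/mismatch is
// preferred over a gap in B, which is preferred over a gap in A.
#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// a, b: 0-based indices into the substitution matrix; -1 = unknown residue
// (scored as the matrix minimum). Returns counts and, if traceback, the
// aligned index rows (-1 for gap positions).
struct NWCounts {
  double score;
  int n_columns, n_ungapped, n_identical;
};

// flat scoring table with an extra "unknown" row/column at index K holding
// the matrix minimum
static std::vector<double> flatten_submat(const NumericMatrix &submat,
                                          int &K) {
  K = submat.nrow();
  double smin = submat(0, 0);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      if (submat(i, j) < smin) smin = submat(i, j);
  std::vector<double> S((K + 1) * (K + 1), smin);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) S[i * (K + 1) + j] = submat(i, j);
  return S;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_ext, bool traceback) {
  const int n = a.size(), m = b.size();
  int K;
  std::vector<double> S = flatten_submat(submat, K);
  const int Kw = K + 1;
  auto sub = [&](int ai, int bj) {
    return S[(ai < 0 ? K : ai) * Kw + (bj < 0 ? K : bj)];
  };

  const double og = gap_open + gap_ext;  // cost of the first gap residue
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: predecessor state (0=M,1=X,2=Y) per state per cell
  std::vector<uint8_t> tM, tX, tY;
  if (true) {
    tM.assign((n + 1) * W, 0);
    tX.assign((n + 1) * W, 0);
    tY.assign((n + 1) * W, 0);
  }

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {  // X: a_i aligned to gap (gap in B)
    X[i * W] = -(og + (i - 1) * gap_ext);
    tX[i * W] = 1;
  }
  tX[1 * W] = 0;
  for (int j = 1; j <= m; ++j) {  // Y: gap in A
    Y[j] = -(og + (j - 1) * gap_ext);
    tY[j] = 2;
  }
  tY[1] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: consume a_i and b_j
      double best = M[d];
      uint8_t st = 0;
      if (X[d] > best) { best = X[d]; st = 1; }
      if (Y[d] > best) { best = Y[d]; st = 2; }
      M[c] = best + sub(a[i - 1], b[j - 1]);
      tM[c] = st;
      // X: consume a_i, gap in B
      best = M[u] - og; st = 0;
      if (X[u] - gap_ext > best) { best = X[u] - gap_ext; st = 1; }
      if (Y[u] - og > best) { best = Y[u] - og; st = 2; }
      X[c] = best; tX[c] = st;
      // Y: consume b_j, gap in A
      best = M[l] - og; st = 0;
      if (X[l] - og > best) { best = X[l] - og; st = 1; }
      if (Y[l] - gap_ext > best) { best = Y[l] - gap_ext; st = 2; }
      Y[c] = best; tY[c] = st;
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // walk back, counting columns
  int i = n, j = m, n_col = 0, n_ungapped = 0, n_ident = 0;
  std::vector<int> ra, rb;  // aligned rows as source indices, -1 = gap
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    ++n_col;
    if (state == 0) {
      ++n_ungapped;
      if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++n_ident;
      if (traceback) { ra.push_back(i - 1); rb.push_back(j - 1); }
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      if (traceback) { ra.push_back(i - 1); rb.push_back(-1); }
      state = tX[c];
      --i;
    } else {
      if (traceback) { ra.push_back(-1); rb.push_back(j - 1); }
      state = tY[c];
      --j;
    }
  }

  List out = List::create(
      _["score"] = score, _["n_columns"] = n_col,
      _["n_ungapped"] = n_ungapped, _["n_identical"] = n_ident);
  if (traceback) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    out["row_a"] = IntegerVector(ra.begin(), ra.end());
    out["row_b"] = IntegerVector(rb.begin(), rb.end());
  }
  return out;
}

// counts-only Gotoh without traceback matrices: two rolling rows per state,
// columns/ungapped/identical tracked alongside the scores so no walk-back
// is needed.
static NWCounts nw_counts(const int *a, int n, const int *b, int m,
                          const std::vector<double> &S, int K,
                          double gap_open, double gap_ext) {
  const double og = gap_open + gap_ext;
  const int Kw = K + 1;
  struct Cell {
    double s;
    int col, ug, id;
  };
  const Cell dead = {NEG_INF, 0, 0, 0};
  std::vector<Cell> Mp(m + 1, dead), Xp(m + 1, dead), Yp(m + 1, dead),
      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = {0.0, 0, 0, 0};
  for (int j = 1; j <= m; ++j)
    Yp[j] = {-(og + (j - 1) * gap_ext), j, 0, 0};
  for (int i = 1; i <= n; ++i) {
    Mc[0] = dead;
    Yc[0] = dead;
    Xc[0] = {-(og + (i - 1) * gap_ext), i, 0, 0};
    const int ai = a[i - 1] < 0 ? K : a[i - 1];
    const double *Srow = &S[ai * Kw];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] < 0 ? K : b[j - 1];
      // M from diagonal predecessors
      Cell best = Mp[j - 1];
      if (Xp[j - 1].s > best.s) best = Xp[j - 1];
      if (Yp[j - 1].s > best.s) best = Yp[j - 1];
      best.s += Srow[bj];
      best.col += 1;
      best.ug += 1;
      if (ai < K && ai == bj) best.id += 1;
      Mc[j] = best;
      // X from above (gap in b)
      Cell bx = Mp[j];
      bx.s -= og;
      if (Xp[j].s - gap_ext > bx.s) { bx = Xp[j]; bx.s -= gap_ext; }
      if (Yp[j].s - og > bx.s) { bx = Yp[j]; bx.s -= og; }
      bx.col += 1;
      Xc[j] = bx;
      // Y from left (gap in a)
      Cell by = Mc[j - 1];
      by.s -= og;
      if (Xc[j - 1].s - og > by.s) { by = Xc[j - 1]; by.s -= og; }
      if (Yc[j - 1].s - gap_ext > by.s) { by = Yc[j - 1]; by.s -= gap_ext; }
      by.col += 1;
      Yc[j] = by;
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }
  Cell fin = Mp[m];
  if (Xp[m].s > fin.s) fin = Xp[m];
  if (Yp[m].s > fin.s) fin = Yp[m];
  return {fin.s, fin.col, fin.ug, fin.id};
}

// Batched scorer: proteins is a list of integer encodings; idx_a/idx_b are
// 1-based indices into it, one row per pair. Returns a matrix with columns
// score, n_columns, n_ungapped, n_identical.
// [[Rcpp::export(name = ".nw_score_pairs_cpp")]]
NumericMatrix nw_score_pairs_cpp(List proteins, IntegerVector idx_a,
                                 IntegerVector idx_b, NumericMatrix submat,
                                 double gap_open, double gap_ext) {
  int K;
  std::vector<double> S = flatten_submat(submat, K);
  const int np = idx_a.size();
  NumericMatrix out(np, 4);
  std::vector<IntegerVector> seqs(proteins.size());
  for (int i = 0; i < proteins.size(); ++i)
    seqs[i] = as<IntegerVector>(proteins[i]);
  for (int p = 0; p < np; ++p) {
    const IntegerVector &a = seqs[idx_a[p] - 1];
    const IntegerVector &b = seqs[idx_b[p] - 1];
    NWCounts c = nw_counts(a.begin(), a.size(), b.begin(), b.size(), S, K,
                           gap_open, gap_ext);
    out(p, 0) = c.score;
    out(p, 1) = c.n_columns;
    out(p, 2) = c.n_ungapped;
    out(p, 3) = c.n_identical;
  }
  return out;
}
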