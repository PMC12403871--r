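// Exhaustive enumeration of nested RNA secondary structures with sound
// branch-and-bound pruning. Serves as the independent reference for the
// dynamic-programming folder: it walks every structure (positions are taken
// left to right, each either unpaired or opening a pair), accumulates loop
// energies as pairs close, and discards a branch only when an admissible
// lower bound on any completion is already no better than the best energy
// found. The minimum returned is therefore exact under the supplied tables;
// pruning can be switched off entirely to verify its soundness on short
// inputs.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct EnumCtx {
  int n;
  int minloop;
  std::vector<int> s;                  // bases 1..4
  std::vector<std::vector<int>> ptm;   // pair type or 0
  const double *stack;                 // 6x6 column-major
  const double *hairpin;
  const double *bulge;
  const double *internal_;             // (side_max+1)^2 column-major
  int int_dim;
  double ml_a, ml_b, ml_c;
  double Erun;
  double best;
  bool use_bound;
  std::vector<int> cur_pair;           // current partner per position (-1 none)
  std::vector<int> best_pair;
  double ws_out[7];                    // min stack with this pair outer
  // admissible interval bound (relax_bound) and move ordering
  std::vector<std::vector<double>> RB;
  std::vector<std::vector<double>> Cl;
  std::vector<std::vector<int>> order; // pair partners of p, most promising first
  // frame stack
  std::vector<int> I, J, nchild, c1, d1, unp;
  int top;
};

// Admissible relaxation: a closed-subtree score G(i,j) that keeps helix
// stacking, hairpin and multibranch terms exact but floors every bulge and
// internal loop at the smallest finite penalty in the tables (jmin). Every
// term in G is <= the corresponding term of the full model, so the minimum
// of G over structures on an interval is a true lower bound on the energy
// achievable there. The recursion is written independently of the
// production folder, and pruning soundness is additionally verified by
// comparing pruned against unpruned enumeration in the test suite.
static void relax_bound(EnumCtx &C) {
  int n = C.n;
  double jmin = 1e18;
  for (int L = 0; L <= n; L++) {
    if (R_finite(C.bulge[L])) jmin = std::min(jmin, C.bulge[L]);
  }
  for (int a = 0; a <= n; a++)
    for (int b = 0; a + b <= n && b <= n; b++) {
      double v = C.internal_[a + C.int_dim * b];
      if (R_finite(v)) jmin = std::min(jmin, v);
    }
  if (jmin > 1e17 || jmin < 0) jmin = 0;

  // G: lower bound for the subtree closed by pair (i,j)
  // WMr/WM2r: >= 1 / >= 2 multiloop branches over [i,j] (ml_b per branch)
  C.Cl.assign(n, std::vector<double>(n, 1e18));
  std::vector<std::vector<double>> WMr(n, std::vector<double>(n, 1e18));
  std::vector<std::vector<double>> WM2r(n, std::vector<double>(n, 1e18));
  C.RB.assign(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> R(n, std::vector<double>(n, 0.0));
  for (int d = 1; d < n; d++) {
    for (int i = 0; i + d < n; i++) {
      int j = i + d;
      if (C.ptm[i][j] && d > C.minloop) {
        double e = C.hairpin[j - i - 1];
        if (C.ptm[i + 1][j - 1])
          e = std::min(e, C.stack[(C.ptm[i][j] - 1) + 6 * (C.ptm[i + 1][j - 1] - 1)] +
                              C.Cl[i + 1][j - 1]);
        // single branch behind a bulge/internal junction (floored at jmin)
        for (int k = i + 1; k < j; k++)
          for (int l = k + C.minloop + 1; l < j; l++)
            if (C.Cl[k][l] < 1e17 && !(k == i + 1 && l == j - 1))
              e = std::min(e, jmin + C.Cl[k][l]);
        if (d >= 2 && WM2r[i + 1][j - 1] < 1e17)
          e = std::min(e, C.ml_a + C.ml_b + WM2r[i + 1][j - 1]);
        C.Cl[i][j] = e;
      }
      double wm2 = (j - 1 >= i) ? WM2r[i][j - 1] : 1e18;
      double wm = (j - 1 >= i) ? WMr[i][j - 1] : 1e18;
      for (int k = i + 1; k <= j; k++) {
        if (C.Cl[k][j] < 1e17 && WMr[i][k - 1] < 1e17)
          wm2 = std::min(wm2, WMr[i][k - 1] + C.Cl[k][j] + C.ml_b);
      }
      // the first branch of a collection may start anywhere in [i, j]
      for (int k = i; k <= j; k++)
        if (C.Cl[k][j] < 1e17)
          wm = std::min(wm, C.Cl[k][j] + C.ml_b);
      wm = std::min(wm, wm2);
      WM2r[i][j] = wm2;
      WMr[i][j] = wm;
      // external-style content over [i,j]: helices side by side, no charge
      double r = R[i + 1 <= j ? i + 1 : i][j];
      if (i + 1 > j) r = 0.0;
      for (int l = i + C.minloop + 1; l <= j; l++) {
        if (C.Cl[i][l] < 1e17) {
          double rest = (l + 1 <= j) ? R[l + 1][j] : 0.0;
          r = std::min(r, C.Cl[i][l] + rest);
        }
      }
      R[i][j] = std::min(0.0, r);
      C.RB[i][j] = R[i][j];
    }
  }
  // most promising pairing partner first, so the incumbent drops early
  C.order.assign(n, {});
  for (int p = 0; p < n; p++) {
    std::vector<int> qs;
    for (int q = p + C.minloop + 1; q < n; q++)
      if (C.ptm[p][q]) qs.push_back(q);
    std::stable_sort(qs.begin(), qs.end(), [&](int a, int b) {
      return C.Cl[p][a] < C.Cl[p][b];
    });
    C.order[p] = qs;
  }
}

// lower bound on the energy still achievable from the current DFS node:
// accumulated energy, the relaxed bound of every un-enumerated gap (up to
// the innermost closing position and between nested closing positions),
// and the best possible closing term of each open pair.
static double node_bound(EnumCtx &C, int p) {
  double b = C.Erun;
  int lo = p;
  for (int t = C.top; t >= 0; t--) {
    b += std::min(0.0, C.ws_out[C.ptm[C.I[t]][C.J[t]]]);
    int hi = C.J[t] - 1;
    if (lo <= hi) b += C.RB[lo][hi];
    lo = C.J[t] + 1;
  }
  if (lo <= C.n - 1) b += C.RB[lo][C.n - 1];
  return b;
}

void dfs(EnumCtx &C, int p) {
  if (C.top >= 0 && p == C.J[C.top]) {
    int t = C.top;
    int i = C.I[t], j = C.J[t], nc = C.nchild[t];
    double e;
    if (nc == 0) {
      e = C.hairpin[j - i - 1];
    } else if (nc == 1) {
      int l1 = C.c1[t] - i - 1, l2 = j - C.d1[t] - 1;
      if (l1 == 0 && l2 == 0)
        e = C.stack[(C.ptm[i][j] - 1) + 6 * (C.ptm[C.c1[t]][C.d1[t]] - 1)];
      else if (l1 == 0 || l2 == 0)
        e = C.bulge[l1 + l2];
      else
        e = C.internal_[l1 + C.int_dim * l2];
    } else {
      e = C.ml_a + C.ml_b * (nc + 1) + C.ml_c * C.unp[t];
    }
    int si = C.I[t], sj = C.J[t], snc = C.nchild[t], sc1 = C.c1[t],
        sd1 = C.d1[t], sunp = C.unp[t];
    C.Erun += e;
    C.top = t - 1;
    if (C.top >= 0) {
      int pt_ = C.top;
      int oc1 = C.c1[pt_], od1 = C.d1[pt_];
      C.nchild[pt_]++;
      if (C.nchild[pt_] == 1) { C.c1[pt_] = i; C.d1[pt_] = j; }
      dfs(C, p + 1);
      C.nchild[pt_]--;
      C.c1[pt_] = oc1; C.d1[pt_] = od1;
    } else {
      dfs(C, p + 1);
    }
    C.top = t;
    C.I[t] = si; C.J[t] = sj; C.nchild[t] = snc; C.c1[t] = sc1;
    C.d1[t] = sd1; C.unp[t] = sunp;
    C.Erun -= e;
    return;
  }
  if (p == C.n) {
    if (C.Erun < C.best) { C.best = C.Erun; C.best_pair = C.cur_pair; }
    return;
  }
  if (C.use_bound && node_bound(C, p) >= C.best) return;
  int limit = (C.top >= 0) ? C.J[C.top] : C.n;
  // p opens a pair (p, q), most promising partner first
  for (int q : C.order[p]) {
    if (q >= limit) continue;
    C.top++;
    int t = C.top;
    C.I[t] = p; C.J[t] = q; C.nchild[t] = 0;
    C.c1[t] = -1; C.d1[t] = -1; C.unp[t] = 0;
    C.cur_pair[p] = q; C.cur_pair[q] = p;
    dfs(C, p + 1);
    C.cur_pair[p] = -1; C.cur_pair[q] = -1;
    C.top--;
  }
  // p unpaired
  if (C.top >= 0) C.unp[C.top]++;
  dfs(C, p + 1);
  if (C.top >= 0) C.unp[C.top]--;
}

int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

} // namespace

// [[Rcpp::export]]
List enum_mfe_cpp(IntegerVector seq, NumericMatrix stackE,
                    NumericVector hairpinE, NumericVector bulgeE,
                    NumericMatrix internalE, double ml_a, double ml_b,
                    double ml_c, int minloop, bool use_bound) {
  EnumCtx C;
  C.n = seq.size();
  C.minloop = minloop;
  C.s.assign(seq.begin(), seq.end());
  C.ptm.assign(C.n, std::vector<int>(C.n, 0));
  for (int i = 0; i < C.n; i++)
    for (int j = i + minloop + 1; j < C.n; j++)
      C.ptm[i][j] = pair_type(C.s[i], C.s[j]);
  C.stack = stackE.begin();
  C.hairpin = hairpinE.begin();
  C.bulge = bulgeE.begin();
  C.internal_ = internalE.begin();
  C.int_dim = internalE.nrow();
  C.ml_a = ml_a; C.ml_b = ml_b; C.ml_c = ml_c;
  C.Erun = 0.0;
  C.best = 0.0;
  C.use_bound = use_bound;
  C.cur_pair.assign(C.n, -1);
  C.best_pair.assign(C.n, -1);
  for (int p = 1; p <= 6; p++) {
    double m = 0.0;
    for (int q = 1; q <= 6; q++)
      m = std::min(m, C.stack[(p - 1) + 6 * (q - 1)]);
    C.ws_out[p] = m;
  }
  relax_bound(C);
  C.I.assign(C.n + 1, 0); C.J.assign(C.n + 1, 0);
  C.nchild.assign(C.n + 1, 0); C.c1.assign(C.n + 1, 0);
  C.d1.assign(C.n + 1, 0); C.unp.assign(C.n + 1, 0);
  C.top = -1;
  dfs(C, 0);
  return List::create(Named("dg") = C.best,
                      Named("pairs") = IntegerVector(C.best_pair.begin(),
                                                     C.best_pair.end()));
}
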