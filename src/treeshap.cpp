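#include <Rcpp.h>
using namespace Rcpp;

// Interventional (background-marginalised) Shapley attributions for a tree
// ensemble, exact by construction.
//
// For one explained row x, one background row z and one tree, every leaf
// reachable under some coalition partitions the unique features on its
// root path into: features where only x satisfies the path conditions
// (set A, |A| = a), features where only z satisfies them (set B, |B| = b),
// and features where both do (irrelevant). The leaf is reached iff all of
// A is in the coalition and none of B is, a conjunction game whose Shapley
// values have the closed form
//   phi_i = +v_L * (a-1)! b! / (a+b)!   for i in A
//   phi_i = -v_L * a! (b-1)! / (a+b)!   for i in B.
// Summing over leaves, trees and background rows gives attributions that
// satisfy the efficiency identity sum_j phi_j = f(x) - mean_z f(z) exactly.

static const int MAXPATH = 64;
static double factorial_tab[MAXPATH + 1];

static void init_factorials() {
  factorial_tab[0] = 1.0;
  for (int i = 1; i <= MAXPATH; ++i)
    factorial_tab[i] = factorial_tab[i - 1] * i;
}

struct Ensemble {
  const int *feature;       // -1 for leaf
  const double *split;
  const int *yes, *no;      // 0-based global node ids
  const double *value;      // leaf value at leaves
};

struct Walker {
  const Ensemble &ens;
  const double *x, *z;      // one row each, length d
  double *phi;              // output, length d
  // per-feature path state: bit 1 = x satisfies all conditions so far,
  // bit 2 = z does; only meaningful while feature is on the current path
  std::vector<char> state;
  std::vector<int> seen;    // occurrence count of feature on current path
  std::vector<int> pathFeats;
  int a, b;

  Walker(const Ensemble &e, const double *x_, const double *z_, double *phi_,
         int d)
      : ens(e), x(x_), z(z_), phi(phi_), state(d, 0), seen(d, 0), a(0), b(0) {
    pathFeats.reserve(MAXPATH);
  }

  void descend(int node) {
    int f = ens.feature[node];
    if (f < 0) {  // leaf
      double v = ens.value[node];
      if (a == 0 && b == 0) return;           // no divergent features
      int tot = a + b;
      if (tot > MAXPATH) Rcpp::stop("path too deep");
      double wpos = 0.0, wneg = 0.0;
      if (a > 0)
        wpos = factorial_tab[a - 1] * factorial_tab[b] / factorial_tab[tot];
      if (b > 0)
        wneg = factorial_tab[a] * factorial_tab[b - 1] / factorial_tab[tot];
      for (size_t i = 0; i < pathFeats.size(); ++i) {
        int pf = pathFeats[i];
        if (state[pf] == 1) phi[pf] += v * wpos;
        else if (state[pf] == 2) phi[pf] -= v * wneg;
      }
      return;
    }
    double t = ens.split[node];
    bool xgoesYes = x[f] < t, zgoesYes = z[f] < t;
    for (int branch = 0; branch < 2; ++branch) {
      bool isYes = (branch == 0);
      int child = isYes ? ens.yes[node] : ens.no[node];
      bool xok = (xgoesYes == isYes), zok = (zgoesYes == isYes);
      char oldState = state[f];
      char effOld = seen[f] ? oldState : (char)3;  // fresh feature: both ok
      char newState = (char)((effOld & (xok ? 1 : 0)) |
                             (effOld & (zok ? 2 : 0)));
      if (newState == 0) continue;  // unreachable under any coalition
      // push
      bool fresh = (seen[f] == 0);
      if (fresh) pathFeats.push_back(f);
      seen[f]++;
      // update divergence counters
      if (effOld == 3) { if (newState == 1) ++a; else if (newState == 2) ++b; }
      else if (effOld == 1 && newState != 1) { /* impossible: 1 -> 1 or 0 */ }
      state[f] = newState;
      descend(child);
      // pop
      state[f] = oldState;
      seen[f]--;
      if (fresh) pathFeats.pop_back();
      if (effOld == 3) { if (newState == 1) --a; else if (newState == 2) --b; }
    }
  }
};

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(IntegerVector feature, NumericVector split,
                           IntegerVector yes, IntegerVector no,
                           NumericVector value, IntegerVector roots,
                           NumericMatrix X, NumericMatrix Z) {
  init_factorials();
  int n = X.nrow(), d = X.ncol(), m = Z.nrow();
  if (Z.ncol() != d) stop("background dimension mismatch");
  Ensemble ens{feature.begin(), split.begin(), yes.begin(), no.begin(),
               value.begin()};
  NumericMatrix out(n, d);
  std::vector<double> xrow(d), zrow(d), phi(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xrow[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int bz = 0; bz < m; ++bz) {
      for (int j = 0; j < d; ++j) zrow[j] = Z(bz, j);
      Walker w(ens, xrow.data(), zrow.data(), phi.data(), d);
      for (int r = 0; r < roots.size(); ++r) w.descend(roots[r]);
    }
    for (int j = 0; j < d; ++j) out(i, j) = phi[j] / m;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
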