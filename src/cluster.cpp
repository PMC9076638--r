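// Cluster-based permutation engine: per-cell t statistics under sign-flip
// (one-sample) or group-label permutation, with 4-connected supra-threshold
// clustering on the frequency x time grid and a max-cluster-statistic null.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Label 4-connected clusters of same-signed supra-threshold cells.
// t is a column-major [nf x nt] map; lab receives labels (0 = background);
// mass/extent receive the per-cluster summed t and cell count.
static void label_map(const std::vector<double>& t, int nf, int nt,
                      double thr, std::vector<int>& lab,
                      std::vector<double>& mass, std::vector<int>& extent) {
  int n = nf * nt;
  lab.assign(n, 0);
  mass.clear();
  extent.clear();
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0 || std::fabs(t[i]) <= thr || !R_finite(t[i])) continue;
    ++next;
    double sgn = t[i] > 0 ? 1.0 : -1.0;
    double m = 0.0;
    int cnt = 0;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      m += t[c]; ++cnt;
      int f = c % nf, ti = c / nf;
      int nb[4]; int k = 0;
      if (f > 0)      nb[k++] = c - 1;
      if (f < nf - 1) nb[k++] = c + 1;
      if (ti > 0)     nb[k++] = c - nf;
      if (ti < nt - 1) nb[k++] = c + nf;
      for (int j = 0; j < k; ++j) {
        int u = nb[j];
        if (lab[u] == 0 && R_finite(t[u]) && std::fabs(t[u]) > thr &&
            ((t[u] > 0 ? 1.0 : -1.0) == sgn)) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
    mass.push_back(m);
    extent.push_back(cnt);
  }
}

// One-sample t per cell given per-subject signs (+1/-1).
static void t_onesample(const NumericMatrix& X, const NumericVector& ss,
                        const std::vector<double>& sgn,
                        std::vector<double>& t) {
  int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += sgn[i] * X(i, j);
    double m = s / n;
    double v = (ss[j] - n * m * m) / (n - 1);
    t[j] = v > 0 ? m / std::sqrt(v / n) : 0.0;
  }
}

// Pooled-variance two-sample t per cell given a 0/1 group assignment.
static void t_twosample(const NumericMatrix& X, const std::vector<int>& g,
                        std::vector<double>& t) {
  int n = X.nrow(), p = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += g[i];
  int n0 = n - n1;
  for (int j = 0; j < p; ++j) {
    double s0 = 0, s1 = 0, q0 = 0, q1 = 0;
    for (int i = 0; i < n; ++i) {
      double x = X(i, j);
      if (g[i]) { s1 += x; q1 += x * x; } else { s0 += x; q0 += x * x; }
    }
    double m0 = s0 / n0, m1 = s1 / n1;
    double sp2 = ((q0 - n0 * m0 * m0) + (q1 - n1 * m1 * m1)) / (n - 2);
    double se = std::sqrt(sp2 * (1.0 / n0 + 1.0 / n1));
    t[j] = se > 0 ? (m0 - m1) / se : 0.0;
  }
}

static double max_cluster_stat(const std::vector<double>& t, int nf, int nt,
                               double thr, bool use_extent) {
  std::vector<int> lab, extent;
  std::vector<double> mass;
  label_map(t, nf, nt, thr, lab, mass, extent);
  double mx = 0.0;
  for (size_t k = 0; k < mass.size(); ++k) {
    double v = use_extent ? (double)extent[k] : std::fabs(mass[k]);
    if (v > mx) mx = v;
  }
  return mx;
}

// [[Rcpp::export]]
List cluster_perm_cpp(NumericMatrix X, int nf, int nt, double thr,
                      int nperm, bool use_extent, IntegerVector groups) {
  int n = X.nrow(), p = X.ncol();
  bool twogroup = groups.size() == n;

  NumericVector ss(p);
  if (!twogroup)
    for (int j = 0; j < p; ++j) {
      double q = 0;
      for (int i = 0; i < n; ++i) q += X(i, j) * X(i, j);
      ss[j] = q;
    }

  std::vector<double> tobs(p);
  std::vector<double> ones(n, 1.0);
  std::vector<int> g(n);
  if (twogroup) {
    for (int i = 0; i < n; ++i) g[i] = groups[i];
    t_twosample(X, g, tobs);
  } else {
    t_onesample(X, ss, ones, tobs);
  }

  std::vector<int> lab, extent;
  std::vector<double> mass;
  label_map(tobs, nf, nt, thr, lab, mass, extent);

  NumericVector nullmax(nperm);
  std::vector<double> tp(p);
  std::vector<double> sgn(n);
  for (int b = 0; b < nperm; ++b) {
    if (twogroup) {
      std::vector<int> gp(g);
      for (int i = n - 1; i > 0; --i) {           // Fisher-Yates, R RNG
        int j = (int)std::floor(unif_rand() * (i + 1));
        std::swap(gp[i], gp[j]);
      }
      t_twosample(X, gp, tp);
    } else {
      for (int i = 0; i < n; ++i) sgn[i] = unif_rand() < 0.5 ? -1.0 : 1.0;
      t_onesample(X, ss, sgn, tp);
    }
    nullmax[b] = max_cluster_stat(tp, nf, nt, thr, use_extent);
  }

  NumericMatrix tmap(nf, nt);
  IntegerMatrix labmat(nf, nt);
  for (int j = 0; j < p; ++j) { tmap[j] = tobs[j]; labmat[j] = lab[j]; }

  return List::create(
    _["t"] = tmap, _["labels"] = labmat,
    _["mass"] = NumericVector(mass.begin(), mass.end()),
    _["extent"] = IntegerVector(extent.begin(), extent.end()),
    _["null_max"] = nullmax);
}
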