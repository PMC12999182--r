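#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All estimators here implement the KSG fixed-epsilon scheme under the
// Chebyshev (maximum) norm: for each sample, epsilon is the distance to its
// k-th nearest neighbour in the full joint space (self excluded), and
// neighbour counts in the projected spaces use the strict inequality
// distance < epsilon:
//   I(A; B | C) = psi(k) + < psi(nC+1) - psi(nAC+1) - psi(nBC+1) >.
// An empty conditioning block makes nC = N - 1 for every sample, reducing the
// expression to the plain KSG mutual information.

static inline double cheb(const double *m, int d, int n, int i, int j) {
  double dd = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = std::fabs(m[c * n + i] - m[c * n + j]);
    if (v > dd) dd = v;
  }
  return dd;
}

// Streaming evaluation, O(n) memory: used for single estimates at large n.
static double cmi_stream(const double *a, int da, const double *b, int db,
                         const double *c, int dc, int n, int k) {
  std::vector<double> dAC(n), dBC(n), dC(n), buf(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double vc = dc ? cheb(c, dc, n, i, j) : 0.0;
      double va = cheb(a, da, n, i, j); if (vc > va) va = vc;
      double vb = cheb(b, db, n, i, j); if (vc > vb) vb = vc;
      dC[j] = vc; dAC[j] = va; dBC[j] = vb;
      buf[j] = va > vb ? va : vb;
    }
    buf[i] = R_PosInf;
    std::vector<double> tmp(buf);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nC = 0, nAC = 0, nBC = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dC[j] < eps) ++nC;
      if (dAC[j] < eps) ++nAC;
      if (dBC[j] < eps) ++nBC;
    }
    acc += R::digamma(nC + 1.0) - R::digamma(nAC + 1.0) - R::digamma(nBC + 1.0);
  }
  return R::digamma((double)k) + acc / n;
}

// [[Rcpp::export]]
double cmi_knn_cpp(NumericMatrix a, NumericMatrix b, NumericMatrix c, int k) {
  const int n = a.nrow();
  if (b.nrow() != n || (c.ncol() > 0 && c.nrow() != n))
    stop("blocks must share the sample count");
  if (k < 1 || k >= n) stop("k must be in [1, N-1]");
  return cmi_stream(a.begin(), a.ncol(), b.begin(), b.ncol(),
                    c.begin(), c.ncol(), n, k);
}

static void pairwise(const double *m, int d, int n, std::vector<double> &out) {
  out.assign((size_t)n * n, 0.0);
  for (int c = 0; c < d; ++c) {
    const double *col = m + (size_t)c * n;
    for (int i = 0; i < n; ++i) {
      double xi = col[i];
      double *row = out.data() + (size_t)i * n;
      for (int j = 0; j < i; ++j) {
        double v = std::fabs(xi - col[j]);
        if (v > row[j]) { row[j] = v; out[(size_t)j * n + i] = v; }
      }
    }
  }
}

// Evaluate one CMI from precomputed pairwise distance matrices, with optional
// permutations pa / pb (0-based) applied to the A and B blocks.
static double cmi_from_dist(const std::vector<double> &DA,
                            const std::vector<double> &DB,
                            const std::vector<double> &DC, bool hasC,
                            int n, int k, const int *pa, const int *pb,
                            const std::vector<double> &psi_tab) {
  std::vector<double> dAC(n), dBC(n), dC(n);
  std::vector<int> ident;
  if (!pa || !pb) {
    ident.resize(n);
    for (int i = 0; i < n; ++i) ident[i] = i;
    if (!pa) pa = ident.data();
    if (!pb) pb = ident.data();
  }
  std::vector<double> heap(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *ra = DA.data() + (size_t)pa[i] * n;
    const double *rb = DB.data() + (size_t)pb[i] * n;
    const double *rc = hasC ? DC.data() + (size_t)i * n : nullptr;
    // max-heap of the k smallest joint distances (self excluded)
    int hs = 0;
    for (int j = 0; j < n; ++j) {
      double vc = rc ? rc[j] : 0.0;
      double va = ra[pa[j]]; if (vc > va) va = vc;
      double vb = rb[pb[j]]; if (vc > vb) vb = vc;
      dC[j] = vc; dAC[j] = va; dBC[j] = vb;
      if (j == i) continue;
      double dj = va > vb ? va : vb;
      if (hs < k) {
        heap[hs++] = dj;
        if (hs == k) std::make_heap(heap.begin(), heap.end());
      } else if (dj < heap[0]) {
        std::pop_heap(heap.begin(), heap.end());
        heap[k - 1] = dj;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    const double eps = heap[0];
    int nC = 0, nAC = 0, nBC = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dC[j] < eps) ++nC;
      if (dAC[j] < eps) ++nAC;
      if (dBC[j] < eps) ++nBC;
    }
    acc += psi_tab[nC + 1] - psi_tab[nAC + 1] - psi_tab[nBC + 1];
  }
  return R::digamma((double)k) + acc / n;
}

static std::vector<double> digamma_table(int n) {
  std::vector<double> t(n + 1);
  t[0] = 0.0;
  for (int i = 1; i <= n; ++i) t[i] = R::digamma((double)i);
  return t;
}

// Score every column of W as candidate B against fixed target A and
// conditioning C, sharing the pairwise distances of A and C across candidates.
// [[Rcpp::export]]
NumericVector cmi_knn_score_cpp(NumericMatrix a, NumericMatrix w,
                                NumericMatrix c, int k) {
  const int n = a.nrow();
  const int nc = w.ncol();
  if (w.nrow() != n || (c.ncol() > 0 && c.nrow() != n))
    stop("blocks must share the sample count");
  if (k < 1 || k >= n) stop("k must be in [1, N-1]");
  std::vector<double> DA, DB, DC;
  pairwise(a.begin(), a.ncol(), n, DA);
  const bool hasC = c.ncol() > 0;
  if (hasC) pairwise(c.begin(), c.ncol(), n, DC);
  const std::vector<double> psi = digamma_table(n);
  NumericVector out(nc);
  for (int q = 0; q < nc; ++q) {
    pairwise(w.begin() + (size_t)q * n, 1, n, DB);
    out[q] = cmi_from_dist(DA, DB, DC, hasC, n, k, nullptr, nullptr, psi);
  }
  return out;
}

// Observed CMI plus ns shuffle-null replicates in one pass. perm_a / perm_b
// are n x ns 1-based index matrices (supplied from R, so all randomness is
// under the caller's seed) permuting the target block and the candidate.
// Returns c(observed, null_1..null_ns).
// [[Rcpp::export]]
NumericVector cmi_knn_null_cpp(NumericMatrix a, NumericMatrix b, NumericMatrix c,
                               int k, IntegerMatrix perm_a, IntegerMatrix perm_b) {
  const int n = a.nrow();
  const int ns = perm_a.ncol();
  if (perm_b.ncol() != ns || perm_a.nrow() != n || perm_b.nrow() != n)
    stop("permutation matrices must be n x ns");
  if (k < 1 || k >= n) stop("k must be in [1, N-1]");
  std::vector<double> DA, DB, DC;
  pairwise(a.begin(), a.ncol(), n, DA);
  pairwise(b.begin(), b.ncol(), n, DB);
  const bool hasC = c.ncol() > 0;
  if (hasC) pairwise(c.begin(), c.ncol(), n, DC);
  const std::vector<double> psi = digamma_table(n);
  NumericVector out(ns + 1);
  out[0] = cmi_from_dist(DA, DB, DC, hasC, n, k, nullptr, nullptr, psi);
  std::vector<int> pa(n), pb(n);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < n; ++i) {
      pa[i] = perm_a(i, s) - 1;
      pb[i] = perm_b(i, s) - 1;
    }
    out[s + 1] = cmi_from_dist(DA, DB, DC, hasC, n, k, pa.data(), pb.data(), psi);
  }
  return out;
}
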