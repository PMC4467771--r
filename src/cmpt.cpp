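// Cluster-mass permutation core: pointwise t maps, spatiotemporal flood-fill
// clustering, and permutation nulls of the maximum |cluster mass|.
//
// Point layout: maps are channels x time flattened column-major
// (point = ch + nCh * t), matching R's matrix layout. Epoch matrices are
// points x epochs. Clustering connects same channel at adjacent samples and
// neighboring channels at the same sample, restricted to columns >= startCol
// (the post-stimulus window).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// two-sample pooled-variance t per point from group-A sums and fixed totals
static inline double t_two(double sA, double qA, double S, double Q,
                           int nA, int nB) {
  double mA = sA / nA;
  double mB = (S - sA) / nB;
  double ssA = qA - sA * sA / nA;
  double ssB = (Q - qA) - (S - sA) * (S - sA) / nB;
  double sp2 = (ssA + ssB) / (nA + nB - 2);
  double diff = mA - mB;
  // zero pooled variance: no evidence if means agree, else a saturated t
  if (sp2 <= 0) return diff == 0 ? 0.0 : (diff > 0 ? 1e9 : -1e9);
  return diff / std::sqrt(sp2 * (1.0 / nA + 1.0 / nB));
}

// flood-fill over supra-threshold points of one sign; returns cluster masses
// and (optionally) labels membership 1..K in 'member'
static void clusters_one_sign(const double *t, int nCh, int nT, int startCol,
                              const int *adjIdx, const int *adjPtr,
                              double thresh, bool positive,
                              std::vector<double> &masses, int *member,
                              int labelOffset) {
  int nPts = nCh * nT;
  std::vector<char> supra(nPts, 0);
  for (int c = startCol; c < nT; ++c)
    for (int ch = 0; ch < nCh; ++ch) {
      int p = ch + nCh * c;
      supra[p] = positive ? (t[p] > thresh) : (t[p] < -thresh);
    }
  std::vector<char> seen(nPts, 0);
  std::vector<int> stack;
  for (int c = startCol; c < nT; ++c)
    for (int ch = 0; ch < nCh; ++ch) {
      int p0 = ch + nCh * c;
      if (!supra[p0] || seen[p0]) continue;
      double mass = 0.0;
      int label = labelOffset + (int)masses.size() + 1;
      stack.clear();
      stack.push_back(p0);
      seen[p0] = 1;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        mass += t[p];
        if (member) member[p] = label;
        int pc = p % nCh, pt = p / nCh;
        // temporal neighbors
        if (pt - 1 >= startCol) {
          int q = p - nCh;
          if (supra[q] && !seen[q]) { seen[q] = 1; stack.push_back(q); }
        }
        if (pt + 1 < nT) {
          int q = p + nCh;
          if (supra[q] && !seen[q]) { seen[q] = 1; stack.push_back(q); }
        }
        // spatial neighbors
        for (int a = adjPtr[pc]; a < adjPtr[pc + 1]; ++a) {
          int q = adjIdx[a] + nCh * pt;
          if (supra[q] && !seen[q]) { seen[q] = 1; stack.push_back(q); }
        }
      }
      masses.push_back(mass);
    }
}

static double max_abs_mass(const double *t, int nCh, int nT, int startCol,
                           const int *adjIdx, const int *adjPtr,
                           double thresh) {
  std::vector<double> masses;
  clusters_one_sign(t, nCh, nT, startCol, adjIdx, adjPtr, thresh, true,
                    masses, nullptr, 0);
  clusters_one_sign(t, nCh, nT, startCol, adjIdx, adjPtr, thresh, false,
                    masses, nullptr, 0);
  double m = 0.0;
  for (double x : masses) if (std::fabs(x) > m) m = std::fabs(x);
  return m;
}

// [[Rcpp::export]]
NumericVector cppTmapTwo(NumericMatrix X, LogicalVector isA) {
  int nPts = X.nrow(), n = X.ncol();
  int nA = 0;
  for (int j = 0; j < n; ++j) if (isA[j]) ++nA;
  int nB = n - nA;
  NumericVector t(nPts);
  std::vector<double> S(nPts, 0.0), Q(nPts, 0.0), sA(nPts, 0.0), qA(nPts, 0.0);
  for (int j = 0; j < n; ++j) {
    const double *col = &X(0, j);
    bool a = isA[j];
    for (int p = 0; p < nPts; ++p) {
      double v = col[p];
      S[p] += v; Q[p] += v * v;
      if (a) { sA[p] += v; qA[p] += v * v; }
    }
  }
  for (int p = 0; p < nPts; ++p)
    t[p] = t_two(sA[p], qA[p], S[p], Q[p], nA, nB);
  return t;
}

// [[Rcpp::export]]
NumericVector cppTmapPaired(NumericMatrix D) {
  int nPts = D.nrow(), n = D.ncol();
  NumericVector t(nPts);
  for (int p = 0; p < nPts; ++p) {
    double s = 0.0, q = 0.0;
    for (int j = 0; j < n; ++j) { double v = D(p, j); s += v; q += v * v; }
    double m = s / n;
    double var = (q - n * m * m) / (n - 1);
    t[p] = var > 0 ? m / std::sqrt(var / n)
                   : (m == 0 ? 0.0 : (m > 0 ? 1e9 : -1e9));
  }
  return t;
}

// [[Rcpp::export]]
List cppClusters(NumericVector tmap, int nCh, int nT, IntegerVector adjIdx,
                 IntegerVector adjPtr, double thresh, int startCol) {
  IntegerVector member(nCh * nT, 0);
  std::vector<double> massPos, massNeg;
  clusters_one_sign(REAL(tmap), nCh, nT, startCol, adjIdx.begin(),
                    adjPtr.begin(), thresh, true, massPos, INTEGER(member), 0);
  clusters_one_sign(REAL(tmap), nCh, nT, startCol, adjIdx.begin(),
                    adjPtr.begin(), thresh, false, massNeg, INTEGER(member),
                    (int)massPos.size());
  NumericVector masses(massPos.size() + massNeg.size());
  for (size_t i = 0; i < massPos.size(); ++i) masses[i] = massPos[i];
  for (size_t i = 0; i < massNeg.size(); ++i)
    masses[massPos.size() + i] = massNeg[i];
  return List::create(_["membership"] = member, _["masses"] = masses);
}

// [[Rcpp::export]]
double cppMaxMassTwo(NumericMatrix X, LogicalVector isA, int nCh, int nT,
                     IntegerVector adjIdx, IntegerVector adjPtr,
                     double thresh, int startCol) {
  NumericVector t = cppTmapTwo(X, isA);
  return max_abs_mass(REAL(t), nCh, nT, startCol, adjIdx.begin(),
                      adjPtr.begin(), thresh);
}

// Permutation null for the single-participant (two unbalanced samples) test:
// random re-partitions of the pooled epochs into groups of the original
// sizes. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
NumericVector cppNullMaxSingle(NumericMatrix X, int nA, int nCh, int nT,
                               IntegerVector adjIdx, IntegerVector adjPtr,
                               double thresh, int nperm, int startCol) {
  int nPts = X.nrow(), n = X.ncol();
  std::vector<double> S(nPts, 0.0), Q(nPts, 0.0);
  for (int j = 0; j < n; ++j) {
    const double *col = &X(0, j);
    for (int p = 0; p < nPts; ++p) {
      double v = col[p];
      S[p] += v; Q[p] += v * v;
    }
  }
  int nB = n - nA;
  std::vector<int> idx(n);
  std::vector<double> sA(nPts), qA(nPts), t(nPts);
  NumericVector out(nperm);
  for (int j = 0; j < n; ++j) idx[j] = j;
  for (int r = 0; r < nperm; ++r) {
    // partial Fisher-Yates: first nA entries form group A
    for (int j = 0; j < nA; ++j) {
      int k = j + (int)(unif_rand() * (n - j));
      if (k >= n) k = n - 1;
      std::swap(idx[j], idx[k]);
    }
    std::fill(sA.begin(), sA.end(), 0.0);
    std::fill(qA.begin(), qA.end(), 0.0);
    for (int j = 0; j < nA; ++j) {
      const double *col = &X(0, idx[j]);
      for (int p = 0; p < nPts; ++p) {
        double v = col[p];
        sA[p] += v; qA[p] += v * v;
      }
    }
    for (int p = 0; p < nPts; ++p)
      t[p] = t_two(sA[p], qA[p], S[p], Q[p], nA, nB);
    out[r] = max_abs_mass(t.data(), nCh, nT, startCol, adjIdx.begin(),
                          adjPtr.begin(), thresh);
  }
  return out;
}

// Permutation null for the group (paired) test: random sign flips of the
// participant difference maps.
// [[Rcpp::export]]
NumericVector cppNullMaxGroup(NumericMatrix D, int nCh, int nT,
                              IntegerVector adjIdx, IntegerVector adjPtr,
                              double thresh, int nperm, int startCol) {
  int nPts = D.nrow(), n = D.ncol();
  // sum of squares per point is sign-invariant
  std::vector<double> Q(nPts, 0.0);
  for (int j = 0; j < n; ++j)
    for (int p = 0; p < nPts; ++p) Q[p] += D(p, j) * D(p, j);
  std::vector<double> s(nPts), t(nPts);
  std::vector<int> eps(n);
  NumericVector out(nperm);
  for (int r = 0; r < nperm; ++r) {
    for (int j = 0; j < n; ++j) eps[j] = unif_rand() < 0.5 ? -1 : 1;
    std::fill(s.begin(), s.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double *col = &D(0, j);
      if (eps[j] > 0)
        for (int p = 0; p < nPts; ++p) s[p] += col[p];
      else
        for (int p = 0; p < nPts; ++p) s[p] -= col[p];
    }
    for (int p = 0; p < nPts; ++p) {
      double m = s[p] / n;
      double var = (Q[p] - n * m * m) / (n - 1);
      t[p] = var > 0 ? m / std::sqrt(var / n)
                     : (m == 0 ? 0.0 : (m > 0 ? 1e9 : -1e9));
    }
    out[r] = max_abs_mass(t.data(), nCh, nT, startCol, adjIdx.begin(),
                          adjPtr.begin(), thresh);
  }
  return out;
}
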