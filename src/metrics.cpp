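#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double xlogx(double x) { return x > 0.0 ? x * std::log(x) : 0.0; }

// Weighted NODF (0-100). For every unordered pair of rows (and of columns),
// the member with the strictly larger marginal total is "richer"; the pair
// scores 100 * (#cells where the poorer value is > 0 and < the richer's
// corresponding value) / (#nonzero cells of the poorer member). Pairs with
// tied marginal totals score 0. The statistic is the mean over all row
// pairs and column pairs combined.
// Mean pair score over all unordered pairs of the `n` length-`len`
// contiguous vectors starting at `X` (column-major slices).
static double nodfPairSum(const double* X, int n, int len,
                          const std::vector<double>& tot) {
  double acc = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    const double* cj = X + (size_t)j * len;
    for (int l = j + 1; l < n; ++l) {
      if (tot[j] == tot[l]) continue;
      const double* cu = tot[j] > tot[l] ? cj : X + (size_t)l * len;
      const double* cv = tot[j] > tot[l] ? X + (size_t)l * len : cj;
      int cnt = 0, nz = 0;
      for (int i = 0; i < len; ++i) {
        const double pv = cv[i];
        if (pv > 0.0) {
          ++nz;
          if (pv < cu[i]) ++cnt;
        }
      }
      if (nz > 0) acc += 100.0 * cnt / nz;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double wnodf_cpp(NumericMatrix a) {
  const int nr = a.nrow(), nc = a.ncol();
  const double* A = &a(0, 0);
  std::vector<double> rt(nr, 0.0), ct(nc, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double* cj = A + (size_t)j * nr;
    double s = 0.0;
    for (int i = 0; i < nr; ++i) {
      s += cj[i];
      rt[i] += cj[i];
    }
    ct[j] = s;
  }
  const double npairs = 0.5 * nr * (nr - 1) + 0.5 * nc * (nc - 1);
  if (npairs <= 0) return 0.0;
  // transpose so row slices are contiguous too
  std::vector<double> T((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) T[(size_t)i * nc + j] = A[(size_t)j * nr + i];
  double acc = nodfPairSum(T.data(), nr, nc, rt);
  acc += nodfPairSum(A, nc, nr, ct);
  return acc / npairs;
}

// Entropy (nats) of the cell distribution p = A / m for an integer matrix
// stored densely, via sum(a log a).
static double entropyOf(const std::vector<double>& A, double m) {
  double s = 0.0;
  for (double v : A) s += xlogx(v);
  return std::log(m) - s / m;
}

// Greedy concentration heuristic for the minimum-entropy matrix with the
// given marginals: repeatedly place min(remaining row, remaining column)
// in the cell of the currently largest remaining marginals.
static void greedyMin(const std::vector<double>& rs,
                      const std::vector<double>& cs,
                      std::vector<double>& A, int nr, int nc) {
  std::vector<double> rr(rs), cc(cs);
  for (;;) {
    int bi = -1, bj = -1;
    double bri = 0.0, bcj = 0.0;
    for (int i = 0; i < nr; ++i)
      if (rr[i] > bri) { bri = rr[i]; bi = i; }
    for (int j = 0; j < nc; ++j)
      if (cc[j] > bcj) { bcj = cc[j]; bj = j; }
    if (bi < 0 || bj < 0) break;
    const double v = std::min(bri, bcj);
    A[bi + (size_t)bj * nr] += v;
    rr[bi] -= v;
    cc[bj] -= v;
  }
}

// Even-distribution heuristic for the maximum-entropy matrix: start from
// the continuous expectation r_i c_j / m, keep the floors, then distribute
// the remaining units by largest fractional remainder while preserving the
// integer marginals.
static void largestRemainderMax(const std::vector<double>& rs,
                                const std::vector<double>& cs, double m,
                                std::vector<double>& A, int nr, int nc) {
  std::vector<double> rrem(nr), crem(nc);
  std::vector<double> frac((size_t)nr * nc);
  for (int i = 0; i < nr; ++i) rrem[i] = rs[i];
  for (int j = 0; j < nc; ++j) crem[j] = cs[j];
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double e = rs[i] * cs[j] / m;
      const double f = std::floor(e);
      A[i + (size_t)j * nr] = f;
      rrem[i] -= f;
      crem[j] -= f;
      frac[i + (size_t)j * nr] = e - f;
    }
  std::vector<size_t> ord(frac.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return frac[a] > frac[b]; });
  for (size_t k : ord) {
    const int i = (int)(k % nr), j = (int)(k / nr);
    if (rrem[i] >= 1.0 && crem[j] >= 1.0) {
      A[k] += 1.0;
      rrem[i] -= 1.0;
      crem[j] -= 1.0;
    }
  }
  // Repair pass: any residual needs are matched greedily (the remainder
  // matrix is a feasible transportation problem).
  for (int i = 0; i < nr; ++i) {
    while (rrem[i] >= 1.0) {
      int bj = -1;
      for (int j = 0; j < nc; ++j)
        if (crem[j] >= 1.0) { bj = j; break; }
      if (bj < 0) break;
      const double t = std::min(rrem[i], crem[bj]);
      A[i + (size_t)bj * nr] += t;
      rrem[i] -= t;
      crem[bj] -= t;
    }
  }
}

// Branched variant of the greedy concentration heuristic for tiny
// matrices: at every step the block min(row remainder, column remainder)
// may be placed at any combination of the two largest remaining rows and
// columns, and the best resulting sum(a log a) is kept. Each placement
// zeroes a row or column, so recursion depth is at most nr + nc.
static void branchMinRec(std::vector<double>& rr, std::vector<double>& cc,
                         double sum, double& bestSum) {
  int r1 = -1, r2 = -1, c1 = -1, c2 = -1;
  for (int i = 0; i < (int)rr.size(); ++i) {
    if (rr[i] <= 0) continue;
    if (r1 < 0 || rr[i] > rr[r1]) { r2 = r1; r1 = i; }
    else if (r2 < 0 || rr[i] > rr[r2]) r2 = i;
  }
  for (int j = 0; j < (int)cc.size(); ++j) {
    if (cc[j] <= 0) continue;
    if (c1 < 0 || cc[j] > cc[c1]) { c2 = c1; c1 = j; }
    else if (c2 < 0 || cc[j] > cc[c2]) c2 = j;
  }
  if (r1 < 0 || c1 < 0) {
    if (sum > bestSum) bestSum = sum;
    return;
  }
  const int ri[2] = {r1, r2}, cj[2] = {c1, c2};
  for (int a = 0; a < 2; ++a) {
    if (ri[a] < 0) continue;
    for (int b = 0; b < 2; ++b) {
      if (cj[b] < 0) continue;
      const int i = ri[a], j = cj[b];
      const double v = std::min(rr[i], cc[j]);
      rr[i] -= v; cc[j] -= v;
      branchMinRec(rr, cc, sum + xlogx(v), bestSum);
      rr[i] += v; cc[j] += v;
    }
  }
}

// Change in sum(a log a) from moving `t` units around the rectangle
// (i,j) -> (i,l), (k,l) -> (k,j).
static inline double moveDelta(double aij, double akl, double ail, double akj,
                               double t) {
  return xlogx(aij - t) + xlogx(akl - t) + xlogx(ail + t) + xlogx(akj + t) -
         (xlogx(aij) + xlogx(akl) + xlogx(ail) + xlogx(akj));
}

// 2x2 swap refinement. direction = +1 maximizes entropy (unit moves,
// decreasing sum(a log a)); direction = -1 minimizes entropy (endpoint
// moves, since entropy is concave along a rectangle transfer the optimum
// of a concentration move lies at the full transfer). Candidate cells are
// the positive cells, optionally capped to the `maxCells` most deviant
// from the continuous expectation (used for large matrices).
static void swapRefine(std::vector<double>& A, int nr, int nc,
                       const std::vector<double>& rs,
                       const std::vector<double>& cs, double m, int direction,
                       int maxIter, int maxCells, bool filterDonors,
                       int kicks = 0) {
  // Track the best state seen; with kicks > 0 the search may walk through
  // a bounded number of non-improving moves to escape shallow local
  // optima (deterministic: always the least-bad non-reversing move).
  std::vector<double> bestA(A);
  auto score = [&](const std::vector<double>& X) {
    double s = 0.0;
    for (double v : X) s += xlogx(v);
    return direction > 0 ? -s : s;  // larger is better
  };
  double cur = score(A), best = cur;
  size_t prev1 = (size_t)-1, prev2 = (size_t)-1;
  for (int iter = 0; iter < maxIter; ++iter) {
    std::vector<std::pair<double, size_t>> cells;
    for (size_t k = 0; k < A.size(); ++k) {
      if (A[k] <= 0.0) continue;
      const int i = (int)(k % nr), j = (int)(k / nr);
      const double dev = A[k] - rs[i] * cs[j] / m;
      // On large matrices only over-represented cells are useful donors
      // for maximization; small matrices scan every positive cell.
      if (filterDonors && direction > 0 && dev < 0.2) continue;
      cells.push_back(std::make_pair(std::fabs(dev), k));
    }
    if ((int)cells.size() > maxCells) {
      std::stable_sort(cells.begin(), cells.end(),
                       [](const std::pair<double, size_t>& a,
                          const std::pair<double, size_t>& b) {
                         return a.first > b.first;
                       });
      cells.resize(maxCells);
    }
    bool found = false;
    double bestGain = 0.0;
    size_t bk1 = 0, bk2 = 0;
    double bestT = 0.0;
    const int ncell = (int)cells.size();
    for (int a = 0; a < ncell; ++a) {
      const size_t k1 = cells[a].second;
      const int i = (int)(k1 % nr), j = (int)(k1 / nr);
      for (int b = a + 1; b < ncell; ++b) {
        const size_t k2 = cells[b].second;
        const int k = (int)(k2 % nr), l = (int)(k2 / nr);
        if (i == k || j == l) continue;
        const size_t kil = (size_t)i + (size_t)l * nr;
        const size_t kkj = (size_t)k + (size_t)j * nr;
        // skip the exact reversal of the previous (kick) move
        if ((kil == prev1 && kkj == prev2) || (kil == prev2 && kkj == prev1))
          continue;
        const double aij = A[k1], akl = A[k2];
        const double ail = A[kil], akj = A[kkj];
        double t, d;
        if (direction > 0) {
          t = 1.0;
          d = -moveDelta(aij, akl, ail, akj, t);  // want sum(a log a) down
        } else {
          t = std::min(aij, akl);
          d = moveDelta(aij, akl, ail, akj, t);  // want sum(a log a) up
        }
        if (!found || d > bestGain) {
          found = true;
          bestGain = d;
          bk1 = k1;
          bk2 = k2;
          bestT = t;
        }
      }
    }
    if (!found) break;
    if (bestGain <= 1e-10) {
      if (kicks <= 0) break;
      --kicks;
    }
    const int i = (int)(bk1 % nr), j = (int)(bk1 / nr);
    const int k = (int)(bk2 % nr), l = (int)(bk2 / nr);
    A[bk1] -= bestT;
    A[bk2] -= bestT;
    A[i + (size_t)l * nr] += bestT;
    A[k + (size_t)j * nr] += bestT;
    prev1 = bk1;
    prev2 = bk2;
    cur += bestGain;
    if (cur > best + 1e-12) {
      best = cur;
      bestA = A;
    }
  }
  A = bestA;
}

// Minimum and maximum achievable entropy (nats) of an integer matrix with
// the given row and column totals, by the heuristics above. Returns
// c(h_min, h_max).
// [[Rcpp::export]]
NumericVector h2_extremes_cpp(NumericVector rowTotals, NumericVector colTotals) {
  const int nr = rowTotals.size(), nc = colTotals.size();
  std::vector<double> rs(rowTotals.begin(), rowTotals.end());
  std::vector<double> cs(colTotals.begin(), colTotals.end());
  double m = 0.0;
  for (double v : rs) m += v;
  if (m <= 0.0) stop("matrix total must be positive");
  const bool small = (size_t)nr * nc <= 256;

  std::vector<double> Amin((size_t)nr * nc, 0.0);
  greedyMin(rs, cs, Amin, nr, nc);
  if (small) swapRefine(Amin, nr, nc, rs, cs, m, -1, 500, 10000, false, 12);
  double hmin = entropyOf(Amin, m);
  if (nr + nc <= 8) {
    // tiny matrices: the single greedy trajectory can stall in a local
    // optimum; branch over the two largest rows/columns at every step
    std::vector<double> rr(rs), cc(cs);
    double bestSum = -1.0;
    branchMinRec(rr, cc, 0.0, bestSum);
    const double hBranch = std::log(m) - bestSum / m;
    if (hBranch < hmin) hmin = hBranch;
  }

  std::vector<double> Amax((size_t)nr * nc, 0.0);
  largestRemainderMax(rs, cs, m, Amax, nr, nc);
  swapRefine(Amax, nr, nc, rs, cs, m, +1, small ? 500 : 50,
             small ? 10000 : 64, !small, small ? 12 : 0);

  return NumericVector::create(hmin, entropyOf(Amax, m));
}
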