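// Maximal information coefficient via the MINE grid search.
//
// Heuristic mode follows the ApproxMaxMI scheme: one axis is mass-
// equipartitioned, the other optimised by dynamic programming over clump
// boundaries (runs of x-consecutive points sharing a y-row; x-ties are never
// split), with the clump count capped at c * max_bins via superclumps.
// Exhaustive mode enumerates every admissible cut placement between distinct
// consecutive order statistics on both axes; it is the test oracle for
// small n.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -1e300;

// mass-equipartition of a sorted value vector into at most q bins; equal
// values always share a bin. Returns bin id per sorted position.
static std::vector<int> equipartition_sorted(const std::vector<double>& v, int q) {
  int n = (int)v.size();
  std::vector<int> assign(n, 0);
  int i = 0, curr = 0;
  double share = 0.0;
  double desired = (double)n / q;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    int s = j - i;
    double grow = std::fabs(share + s - desired);
    double stay = std::fabs(share - desired);
    if (share != 0.0 && grow >= stay && curr < q - 1) {
      ++curr;
      share = 0.0;
      int left = q - curr;
      desired = (double)(n - i) / left;
    }
    for (int t = i; t < j; ++t) assign[t] = curr;
    share += s;
    i = j;
  }
  return assign;
}

// DP over clumps: points sorted by the optimised axis, Q = row id per point
// (0..q-1). Returns best[l] = max I (bits) over partitions into <= l bins,
// for l = 2..L.
static std::vector<double> optimize_axis(const std::vector<double>& xs,
                                         const std::vector<int>& Q,
                                         int q, int L, int khat) {
  int n = (int)xs.size();
  // tie groups on the optimised axis
  std::vector<int> gstart;
  for (int i = 0; i < n;) {
    gstart.push_back(i);
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    i = j;
  }
  gstart.push_back(n);
  int ng = (int)gstart.size() - 1;
  std::vector<int> glabel(ng);
  for (int g = 0; g < ng; ++g) {
    int lab = Q[gstart[g]];
    for (int t = gstart[g] + 1; t < gstart[g + 1]; ++t)
      if (Q[t] != lab) { lab = -1; break; }
    glabel[g] = lab;
  }
  // clumps: maximal runs of groups with one shared row label
  std::vector<int> cstart;
  for (int g = 0; g < ng; ++g) {
    if (g == 0 || glabel[g] == -1 || glabel[g - 1] == -1 ||
        glabel[g] != glabel[g - 1])
      cstart.push_back(gstart[g]);
  }
  cstart.push_back(n);
  int k = (int)cstart.size() - 1;

  // cap the DP size: merge clumps into at most khat superclumps by mass
  std::vector<int> bstart;
  if (k > khat && khat >= 2) {
    bstart.push_back(0);
    double share = 0.0;
    double desired = (double)n / khat;
    int made = 0;
    for (int cidx = 0; cidx < k; ++cidx) {
      int s = cstart[cidx + 1] - cstart[cidx];
      double grow = std::fabs(share + s - desired);
      double stay = std::fabs(share - desired);
      if (share != 0.0 && grow >= stay && made < khat - 1) {
        bstart.push_back(cstart[cidx]);
        ++made;
        share = 0.0;
        desired = (double)(n - cstart[cidx]) / (khat - made);
      }
      share += s;
    }
    bstart.push_back(n);
  } else {
    bstart = cstart;
  }
  int kk = (int)bstart.size() - 1;

  // prefix row counts over superclumps
  std::vector<std::vector<double> > cum(kk + 1, std::vector<double>(q, 0.0));
  std::vector<double> np(kk + 1, 0.0);
  for (int t = 1; t <= kk; ++t) {
    cum[t] = cum[t - 1];
    np[t] = np[t - 1];
    for (int i = bstart[t - 1]; i < bstart[t]; ++i) {
      cum[t][Q[i]] += 1.0;
      np[t] += 1.0;
    }
  }
  double N = (double)n;

  // additive per-bin contribution to H(P) - H(P,Q) for the bin made of
  // superclumps (s, t]
  struct Contrib {
    const std::vector<std::vector<double> >& cum;
    const std::vector<double>& np;
    double N;
    int q;
    double operator()(int s, int t) const {
      double nb = np[t] - np[s];
      if (nb <= 0.0) return NEG_INF;
      double val = 0.0;
      for (int r = 0; r < q; ++r) {
        double nbr = cum[t][r] - cum[s][r];
        if (nbr > 0.0) val += (nbr / N) * (std::log(nbr / N) / std::log(2.0));
      }
      val -= (nb / N) * (std::log(nb / N) / std::log(2.0));
      return val;
    }
  } contrib = {cum, np, N, q};

  int Lc = std::min(L, kk);
  std::vector<std::vector<double> > F(kk + 1,
                                      std::vector<double>(Lc + 1, NEG_INF));
  for (int t = 1; t <= kk; ++t) F[t][1] = contrib(0, t);
  for (int l = 2; l <= Lc; ++l) {
    for (int t = l; t <= kk; ++t) {
      double best = NEG_INF;
      for (int s = l - 1; s < t; ++s) {
        if (F[s][l - 1] <= NEG_INF / 2) continue;
        double v = F[s][l - 1] + contrib(s, t);
        if (v > best) best = v;
      }
      F[t][l] = best;
    }
  }

  double HQ = 0.0;
  for (int r = 0; r < q; ++r) {
    double nr = cum[kk][r];
    if (nr > 0.0) HQ -= (nr / N) * (std::log(nr / N) / std::log(2.0));
  }

  std::vector<double> best(L + 1, 0.0);
  double running = 0.0;
  for (int l = 2; l <= L; ++l) {
    double v = 0.0;
    if (l <= Lc && F[kk][l] > NEG_INF / 2) v = HQ + F[kk][l];
    if (v > running) running = v;
    best[l] = running > 0.0 ? running : 0.0;
  }
  return best;
}

// prepare one orientation: equipartition `rows` axis values, return row id
// per point after sorting by the `cols` axis
static void orient(const NumericVector& colv, const NumericVector& rowv,
                   int q, std::vector<double>& xs, std::vector<int>& Q) {
  int n = colv.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  // sort by row axis, equipartition
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return rowv[a] < rowv[b]; });
  std::vector<double> sortedrow(n);
  for (int i = 0; i < n; ++i) sortedrow[i] = rowv[idx[i]];
  std::vector<int> rowbin_sorted = equipartition_sorted(sortedrow, q);
  std::vector<int> rowbin(n);
  for (int i = 0; i < n; ++i) rowbin[idx[i]] = rowbin_sorted[i];
  // sort by column axis
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return colv[a] < colv[b]; });
  xs.resize(n);
  Q.resize(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = colv[idx[i]];
    Q[i] = rowbin[idx[i]];
  }
}

// [[Rcpp::export(name = ".mine_heuristic")]]
double mine_heuristic(NumericVector x, NumericVector y, int B, int c) {
  int n = x.size();
  double mic = 0.0;
  for (int o = 0; o < 2; ++o) {
    const NumericVector& colv = (o == 0) ? x : y;
    const NumericVector& rowv = (o == 0) ? y : x;
    int qmax = B / 2;
    for (int q = 2; q <= qmax; ++q) {
      int L = B / q;
      if (L < 2) break;
      std::vector<double> xs;
      std::vector<int> Q;
      orient(colv, rowv, q, xs, Q);
      int khat = std::max(2, c * L);
      std::vector<double> best = optimize_axis(xs, Q, q, L, khat);
      for (int l = 2; l <= L; ++l) {
        double norm = std::log((double)std::min(l, q)) / std::log(2.0);
        double v = best[l] / norm;
        if (v > mic) mic = v;
      }
    }
  }
  return std::min(mic, 1.0);
}

// [[Rcpp::export(name = ".mine_heuristic_cv")]]
double mine_heuristic_cv(NumericVector x, NumericVector y, int nx, int ny) {
  // best normalised MI for the single grid dimension (nx, ny): try both
  // orientations (equipartition rows = y optimise x, and the transpose)
  double best = 0.0;
  for (int o = 0; o < 2; ++o) {
    const NumericVector& colv = (o == 0) ? x : y;
    const NumericVector& rowv = (o == 0) ? y : x;
    int q = (o == 0) ? ny : nx;
    int L = (o == 0) ? nx : ny;
    std::vector<double> xs;
    std::vector<int> Q;
    orient(colv, rowv, q, xs, Q);
    std::vector<double> b = optimize_axis(xs, Q, q, L, 1 << 30);
    if (b[L] > best) best = b[L];
  }
  double norm = std::log((double)std::min(nx, ny)) / std::log(2.0);
  return std::min(best / norm, 1.0);
}

// ---------- exhaustive enumeration ----------

// positions (in sorted order) after which a cut may fall: boundaries between
// distinct consecutive order statistics
static std::vector<int> cut_candidates(const std::vector<double>& sorted) {
  std::vector<int> pos;
  for (int i = 0; i + 1 < (int)sorted.size(); ++i)
    if (sorted[i] != sorted[i + 1]) pos.push_back(i);
  return pos;
}

struct ExhaustiveState {
  int n, nx, ny;
  std::vector<int> px, py;          // each point's position in x/y order
  std::vector<int> candx, candy;    // admissible cut positions
  std::vector<int> cutx, cuty;      // current cut selections
  double best;
  long long evals, max_evals;
};

static void eval_table(ExhaustiveState& st) {
  int nx = (int)st.cutx.size() + 1, ny = (int)st.cuty.size() + 1;
  std::vector<double> tab(nx * ny, 0.0);
  for (int i = 0; i < st.n; ++i) {
    int cx = 0;
    for (int cpos : st.cutx)
      if (cpos < st.px[i]) ++cx;
    int cy = 0;
    for (int cpos : st.cuty)
      if (cpos < st.py[i]) ++cy;
    tab[cx * ny + cy] += 1.0;
  }
  double N = st.n, I = 0.0;
  std::vector<double> rs(nx, 0.0), cs(ny, 0.0);
  for (int a = 0; a < nx; ++a)
    for (int b = 0; b < ny; ++b) {
      rs[a] += tab[a * ny + b];
      cs[b] += tab[a * ny + b];
    }
  for (int a = 0; a < nx; ++a)
    for (int b = 0; b < ny; ++b) {
      double p = tab[a * ny + b];
      if (p > 0.0)
        I += (p / N) * (std::log(p * N / (rs[a] * cs[b])) / std::log(2.0));
    }
  if (I > st.best) st.best = I;
  ++st.evals;
}

static void rec_y(ExhaustiveState& st, int start, int left) {
  if (st.evals > st.max_evals)
    stop("exhaustive MIC enumeration exceeds the evaluation budget; reduce n or the resolution bound");
  if (left == 0) {
    eval_table(st);
    return;
  }
  for (int i = start; i <= (int)st.candy.size() - left; ++i) {
    st.cuty.push_back(st.candy[i]);
    rec_y(st, i + 1, left - 1);
    st.cuty.pop_back();
  }
}

static void rec_x(ExhaustiveState& st, int start, int left, int ycuts) {
  if (left == 0) {
    if (ycuts == 0)
      eval_table(st);
    else
      rec_y(st, 0, ycuts);
    return;
  }
  for (int i = start; i <= (int)st.candx.size() - left; ++i) {
    st.cutx.push_back(st.candx[i]);
    rec_x(st, i + 1, left - 1, ycuts);
    st.cutx.pop_back();
  }
}

static double exhaustive_best_I(NumericVector x, NumericVector y, int nx,
                                int ny, long long max_evals) {
  int n = x.size();
  ExhaustiveState st;
  st.n = n;
  st.nx = nx;
  st.ny = ny;
  std::vector<int> idx(n);
  std::vector<double> sx(n), sy(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return x[a] < x[b]; });
  st.px.resize(n);
  for (int i = 0; i < n; ++i) {
    st.px[idx[i]] = i;
    sx[i] = x[idx[i]];
  }
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return y[a] < y[b]; });
  st.py.resize(n);
  for (int i = 0; i < n; ++i) {
    st.py[idx[i]] = i;
    sy[i] = y[idx[i]];
  }
  st.candx = cut_candidates(sx);
  st.candy = cut_candidates(sy);
  int xcuts = std::min(nx - 1, (int)st.candx.size());
  int ycuts = std::min(ny - 1, (int)st.candy.size());
  st.best = 0.0;
  st.evals = 0;
  st.max_evals = max_evals;
  rec_x(st, 0, xcuts, ycuts);
  return st.best;
}

// [[Rcpp::export(name = ".mine_exhaustive_cv")]]
double mine_exhaustive_cv(NumericVector x, NumericVector y, int nx, int ny) {
  double I = exhaustive_best_I(x, y, nx, ny, 200000000LL);
  double norm = std::log((double)std::min(nx, ny)) / std::log(2.0);
  return std::min(I / norm, 1.0);
}

// [[Rcpp::export(name = ".mine_exhaustive")]]
double mine_exhaustive(NumericVector x, NumericVector y, int B) {
  double mic = 0.0;
  for (int nx = 2; nx <= B / 2; ++nx) {
    for (int ny = 2; (long long)nx * ny <= B; ++ny) {
      double v = mine_exhaustive_cv(x, y, nx, ny);
      if (v > mic) mic = v;
    }
  }
  return std::min(mic, 1.0);
}
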