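#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average-rank (midrank) assignment used by the Spearman statistic.
// v: values, idx: scratch index buffer, r: output ranks (1-based, ties averaged).
static void rank_average(const std::vector<double> &v, std::vector<int> &idx,
                         std::vector<double> &r) {
  const int n = (int)v.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    const double avg = 0.5 * (double)(i + j) + 1.0;
    for (int t = i; t <= j; ++t) r[idx[t]] = avg;
    i = j + 1;
  }
}

static double pearson(const std::vector<double> &x, const std::vector<double> &y) {
  const int n = (int)x.size();
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  if (sxx <= 0.0 || syy <= 0.0) return 0.0;
  double rho = sxy / std::sqrt(sxx * syy);
  if (rho > 1.0) rho = 1.0;
  if (rho < -1.0) rho = -1.0;
  return rho;
}

// Per-voxel Spearman rank correlation of a and b over a centered (2w+1)^3 cube.
// Voxels whose window does not fit entirely inside the volume, or where either
// window is constant (zero variance), get 0. If mask is given, only voxels with
// mask == TRUE are evaluated (others stay 0).
// [[Rcpp::export]]
NumericVector cpp_windowed_spearman(NumericVector a, NumericVector b,
                                    IntegerVector dims, int w,
                                    Nullable<LogicalVector> mask = R_NilValue) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int m = 2 * w + 1;
  const int M = m * m * m;
  NumericVector out(a.size());
  const bool use_mask = mask.isNotNull();
  LogicalVector msk;
  if (use_mask) msk = mask.get();
  std::vector<double> va(M), vb(M), ra(M), rb(M);
  std::vector<int> idx(M);

  for (int k = w; k < d3 - w; ++k) {
    for (int j = w; j < d2 - w; ++j) {
      for (int i = w; i < d1 - w; ++i) {
        const R_xlen_t c =
            (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
        if (use_mask && !msk[c]) continue;
        int t = 0;
        double amin = R_PosInf, amax = R_NegInf;
        double bmin = R_PosInf, bmax = R_NegInf;
        for (int dk = -w; dk <= w; ++dk) {
          for (int dj = -w; dj <= w; ++dj) {
            R_xlen_t base = (R_xlen_t)(i - w) +
                            (R_xlen_t)d1 * ((R_xlen_t)(j + dj) +
                                            (R_xlen_t)d2 * (k + dk));
            for (int di = 0; di < m; ++di, ++t) {
              const double av = a[base + di], bv = b[base + di];
              va[t] = av; vb[t] = bv;
              if (av < amin) amin = av;
              if (av > amax) amax = av;
              if (bv < bmin) bmin = bv;
              if (bv > bmax) bmax = bv;
            }
          }
        }
        if (amin == amax || bmin == bmax) continue;  // zero variance -> 0
        rank_average(va, idx, ra);
        rank_average(vb, idx, rb);
        out[c] = pearson(ra, rb);
      }
    }
  }
  return out;
}

// Connected-component labelling of a 3D logical mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels are 1..n in
// first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector labels(n);
  std::vector<int> ndi, ndj, ndk;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        ndi.push_back(di); ndj.push_back(dj); ndk.push_back(dk);
      }
  const int nn = (int)ndi.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int i = (int)(c % d1);
      const int j = (int)((c / d1) % d2);
      const int k = (int)(c / ((R_xlen_t)d1 * d2));
      for (int q = 0; q < nn; ++q) {
        const int ii = i + ndi[q], jj = j + ndj[q], kk = k + ndk[q];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        const R_xlen_t cc =
            (R_xlen_t)ii + (R_xlen_t)d1 * ((R_xlen_t)jj + (R_xlen_t)d2 * kk);
        if (mask[cc] && labels[cc] == 0) {
          labels[cc] = next;
          stack.push_back(cc);
        }
      }
    }
  }
  return labels;
}

// 26-neighbourhood binary dilation, `iter` passes.
// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims, int iter = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iter; ++it) {
    LogicalVector nxt = clone(cur);
    for (R_xlen_t c = 0; c < n; ++c) {
      if (!cur[c]) continue;
      const int i = (int)(c % d1);
      const int j = (int)((c / d1) % d2);
      const int k = (int)(c / ((R_xlen_t)d1 * d2));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
              continue;
            nxt[(R_xlen_t)ii +
                (R_xlen_t)d1 * ((R_xlen_t)jj + (R_xlen_t)d2 * kk)] = true;
          }
    }
    cur = nxt;
  }
  return cur;
}

// 1D convolution along one axis (1, 2 or 3) with replicate-edge padding;
// kernel has odd length and is applied centered.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector v, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int r = ((int)kernel.size() - 1) / 2;
  NumericVector out(v.size());
  const int dlen = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        const int pos = (axis == 1) ? i : (axis == 2) ? j : k;
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = pos + t;
          if (p < 0) p = 0;
          if (p >= dlen) p = dlen - 1;
          const int ii = (axis == 1) ? p : i;
          const int jj = (axis == 2) ? p : j;
          const int kk = (axis == 3) ? p : k;
          acc += kernel[t + r] *
                 v[(R_xlen_t)ii +
                   (R_xlen_t)d1 * ((R_xlen_t)jj + (R_xlen_t)d2 * kk)];
        }
        out[(R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k)] = acc;
      }
    }
  }
  return out;
}
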