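#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Convolve every contiguous line of length len with kernel k (reflecting
// boundaries); lines are stored back-to-back in a.
static void conv_lines(const double *a, double *b, int len, R_xlen_t nline,
                       const std::vector<double> &k) {
  int h = ((int)k.size() - 1) / 2;
  for (R_xlen_t l = 0; l < nline; ++l) {
    const double *src = a + l * len;
    double *dst = b + l * len;
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      if (i >= h && i + h < len) { // interior: no boundary checks
        const double *s = src + i - h;
        for (int t = 0; t < (int)k.size(); ++t) acc += k[t] * s[t];
      } else {
        for (int t = -h; t <= h; ++t) {
          int j = i + t;
          if (j < 0) j = -j - 1; // reflect
          if (j >= len) j = 2 * len - j - 1;
          acc += k[t + h] * src[j];
        }
      }
      dst[i] = acc;
    }
  }
}

// Cyclic rotation of a d0 x d1 x d2 array: output has dims (d1, d2, d0).
static void rotate_dims(const double *a, double *b, int d0, int d1, int d2) {
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      const double *src = a + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
      double *dst = b + j;
      R_xlen_t stride = (R_xlen_t)d1 * d2;
      for (int i = 0; i < d0; ++i)
        dst[(R_xlen_t)d1 * k + stride * i] = src[i];
    }
}

// Separable 3-D Gaussian smoothing with reflecting boundaries.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector x, IntegerVector dims,
                           NumericVector k1, NumericVector k2,
                           NumericVector k3) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (nvox != x.size()) stop("dims do not match volume");
  std::vector<double> a(x.begin(), x.end()), b(nvox);
  std::vector<double> kk1(k1.begin(), k1.end()),
      kk2(k2.begin(), k2.end()), kk3(k3.begin(), k3.end());
  // convolve along the (contiguous) first axis, then rotate dims so each
  // axis becomes contiguous in turn; three rotations restore the layout
  conv_lines(a.data(), b.data(), nx, nvox / nx, kk1);
  rotate_dims(b.data(), a.data(), nx, ny, nz); // dims now (ny, nz, nx)
  conv_lines(a.data(), b.data(), ny, nvox / ny, kk2);
  rotate_dims(b.data(), a.data(), ny, nz, nx); // dims now (nz, nx, ny)
  conv_lines(a.data(), b.data(), nz, nvox / nz, kk3);
  rotate_dims(b.data(), a.data(), nz, nx, ny); // back to (nx, ny, nz)
  return NumericVector(a.begin(), a.end());
}

// Connected components of a 3-D binary volume; connectivity 6, 18 or 26.
// Returns integer labels (0 = background) with cluster sizes as an attribute.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector mask, IntegerVector dims,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (nvox != mask.size()) stop("dims do not match volume");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        if (connectivity == 6 && d > 1) continue;
        if (connectivity == 18 && d > 2) continue;
        nb.push_back({dx, dy, dz});
      }

  IntegerVector lab(nvox, 0);
  std::vector<int> sizes;
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t v0 = 0; v0 < nvox; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++cur;
    int sz = 0;
    lab[v0] = cur;
    q.push(v0);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      ++sz;
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (auto &o : nb) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * yy + (R_xlen_t)nx * ny * zz;
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          q.push(w);
        }
      }
    }
    sizes.push_back(sz);
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// Two-sample t statistics on resampled group assignments. mode 0 draws the
// first surrogate group without replacement (label permutation); mode 1 draws
// both groups independently with replacement from the pooled sample. Uses the
// R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_resample_t(NumericVector x, int n1, int iterations,
                             int mode) {
  int n = x.size(), n2 = n - n1;
  NumericVector out(iterations);
  std::vector<int> idx(n);
  GetRNGstate();
  for (int b = 0; b < iterations; ++b) {
    double s1 = 0, ss1 = 0, s2 = 0, ss2 = 0;
    if (mode == 0) {
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = 0; i < n1; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(idx[i], idx[j]);
      }
      for (int i = 0; i < n1; ++i) { double v = x[idx[i]]; s1 += v; ss1 += v * v; }
      for (int i = n1; i < n; ++i) { double v = x[idx[i]]; s2 += v; ss2 += v * v; }
    } else {
      for (int i = 0; i < n1; ++i) {
        int j = (int)(unif_rand() * n); if (j >= n) j = n - 1;
        double v = x[j]; s1 += v; ss1 += v * v;
      }
      for (int i = 0; i < n2; ++i) {
        int j = (int)(unif_rand() * n); if (j >= n) j = n - 1;
        double v = x[j]; s2 += v; ss2 += v * v;
      }
    }
    double m1 = s1 / n1, m2 = s2 / n2;
    double v1 = (ss1 - n1 * m1 * m1) / (n1 - 1);
    double v2 = (ss2 - n2 * m2 * m2) / (n2 - 1);
    double sp = ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2);
    double se = std::sqrt(sp * (1.0 / n1 + 1.0 / n2));
    out[b] = se > 0 ? (m1 - m2) / se : 0.0;
  }
  PutRNGstate();
  return out;
}
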