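#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fast non-local means (Buades et al.): each pixel becomes a weighted mean of
// search-window pixels, weights exp(-d2/h^2) with d2 the mean squared patch
// difference. One integral image of squared differences per window offset
// makes the patch distance O(1) per pixel.

// [[Rcpp::export(name = ".nlm_denoise_cpp")]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double h, int patch, int search) {
  const int H = img.nrow(), W = img.ncol();
  const int pr = patch / 2;        // patch radius (patch odd)
  const int sr = search / 2;       // search radius
  const int pad = pr + sr;
  const int PH = H + 2 * pad, PW = W + 2 * pad;

  // reflect-padded copy
  std::vector<double> P(static_cast<size_t>(PH) * PW);
  auto refl = [](int v, int n) {
    while (v < 0 || v >= n) { if (v < 0) v = -v - 1; if (v >= n) v = 2 * n - 1 - v; }
    return v;
  };
  for (int i = 0; i < PH; ++i) {
    int si = refl(i - pad, H);
    for (int j = 0; j < PW; ++j)
      P[static_cast<size_t>(i) * PW + j] = img(si, refl(j - pad, W));
  }

  std::vector<double> acc(static_cast<size_t>(H) * W, 0.0);
  std::vector<double> wsum(static_cast<size_t>(H) * W, 0.0);
  // integral image of squared differences, (PH+1) x (PW+1)
  std::vector<double> S(static_cast<size_t>(PH + 1) * (PW + 1), 0.0);
  const double h2 = h * h;
  const double npatch = static_cast<double>(patch) * patch;

  for (int dy = -sr; dy <= sr; ++dy) {
    for (int dx = -sr; dx <= sr; ++dx) {
      if (dy == 0 && dx == 0) continue;
      // integral of (P(i,j) - P(i+dy, j+dx))^2 over valid region
      for (int i = 0; i < PH; ++i) {
        double row = 0.0;
        const double *a = &P[static_cast<size_t>(i) * PW];
        const bool ok_i = (i + dy >= 0 && i + dy < PH);
        const double *b = ok_i ? &P[static_cast<size_t>(i + dy) * PW] : nullptr;
        double *s1 = &S[static_cast<size_t>(i + 1) * (PW + 1)];
        const double *s0 = &S[static_cast<size_t>(i) * (PW + 1)];
        s1[0] = 0.0;
        for (int j = 0; j < PW; ++j) {
          double d = 0.0;
          if (ok_i && j + dx >= 0 && j + dx < PW) d = a[j] - b[j + dx];
          row += d * d;
          s1[j + 1] = s0[j + 1] + row;
        }
      }
      const size_t SW = PW + 1;
      for (int y = 0; y < H; ++y) {
        const int ci = y + pad; // centre in padded coords
        for (int x = 0; x < W; ++x) {
          const int cj = x + pad;
          const int r0 = ci - pr, r1 = ci + pr + 1;
          const int c0 = cj - pr, c1 = cj + pr + 1;
          double d2 = S[static_cast<size_t>(r1) * SW + c1]
                    - S[static_cast<size_t>(r0) * SW + c1]
                    - S[static_cast<size_t>(r1) * SW + c0]
                    + S[static_cast<size_t>(r0) * SW + c0];
          d2 /= npatch;
          double w = std::exp(-d2 / h2);
          const size_t o = static_cast<size_t>(y) * W + x;
          acc[o] += w * P[static_cast<size_t>(ci + dy) * PW + (cj + dx)];
          wsum[o] += w;
        }
      }
    }
  }

  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      const size_t o = static_cast<size_t>(y) * W + x;
      // self weight 1 (maximum possible weight)
      double v = (acc[o] + img(y, x)) / (wsum[o] + 1.0);
      out(y, x) = v;
    }
  return out;
}
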