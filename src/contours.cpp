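#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Border following after Suzuki & Abe (1985): raster scan, trace every outer
// and hole border of the 8-connected foreground, recording the containment
// hierarchy. Foreground pixels are 1, background 0. The image frame acts as
// border number 1 (a hole border), so top-level borders get parent 0.

// clockwise 8-neighbourhood in screen coordinates (y grows downward):
// E, SE, S, SW, W, NW, N, NE
static const int DJ[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DI[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline int dir_index(int di, int dj) {
  for (int k = 0; k < 8; ++k)
    if (DI[k] == di && DJ[k] == dj) return k;
  return -1; // unreachable for 8-adjacent offsets
}

// [[Rcpp::export(name = ".trace_borders_cpp")]]
List trace_borders_cpp(IntegerMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  // working copy with border labels; int to hold +/- NBD
  std::vector<int> f(static_cast<size_t>(H) * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      f[static_cast<size_t>(i) * W + j] = bin(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return f[static_cast<size_t>(i) * W + j];
  };
  auto set = [&](int i, int j, int v) {
    f[static_cast<size_t>(i) * W + j] = v;
  };

  std::vector< std::vector< std::pair<int,int> > > borders; // (i, j) runs
  std::vector<int> parent;  // parent NBD (1 = frame)
  std::vector<int> is_hole; // border type
  // NBD 1 = frame
  parent.push_back(0);
  is_hole.push_back(1);
  int NBD = 1;

  for (int i = 0; i < H; ++i) {
    int LNBD = 1;
    for (int j = 0; j < W; ++j) {
      int fij = at(i, j);
      if (fij == 0) continue;

      int i2 = -1, j2 = -1, border_is_hole = -1;
      if (fij == 1 && at(i, j - 1) == 0) {
        border_is_hole = 0;          // outer border start
        i2 = i; j2 = j - 1;
      } else if (fij >= 1 && at(i, j + 1) == 0) {
        border_is_hole = 1;          // hole border start
        i2 = i; j2 = j + 1;
        if (fij > 1) LNBD = fij;
      }

      if (border_is_hole >= 0) {
        ++NBD;
        // parent from the last border met on this row (Suzuki & Abe Table 1)
        int b2 = LNBD - 1; // 0-based into parent/is_hole
        int par = (is_hole[b2] == border_is_hole) ? parent[b2] : LNBD;
        parent.push_back(par);
        is_hole.push_back(border_is_hole);

        std::vector< std::pair<int,int> > pts;
        // step 3.1: clockwise search around (i,j) from (i2,j2)
        int s = dir_index(i2 - i, j2 - j);
        int i1 = -1, j1 = -1;
        for (int k = 0; k < 8; ++k) {
          int d = (s + k) & 7;
          if (at(i + DI[d], j + DJ[d]) != 0) { i1 = i + DI[d]; j1 = j + DJ[d]; break; }
        }
        if (i1 < 0) {
          // isolated pixel
          set(i, j, -NBD);
          pts.emplace_back(i, j);
        } else {
          int i3 = i, j3 = j;
          i2 = i1; j2 = j1;
          for (;;) {
            // step 3.3: counterclockwise search around (i3,j3) starting
            // after (i2,j2); note whether east neighbour examined as zero
            int sd = dir_index(i2 - i3, j2 - j3);
            int i4 = -1, j4 = -1;
            bool east_zero = false;
            for (int k = 1; k <= 8; ++k) {
              int d = (sd - k) & 7;
              int ni = i3 + DI[d], nj = j3 + DJ[d];
              if (at(ni, nj) != 0) { i4 = ni; j4 = nj; break; }
              if (d == 0) east_zero = true; // east neighbour, value 0
            }
            // step 3.4: mark
            int cur = at(i3, j3);
            if (east_zero) set(i3, j3, -NBD);
            else if (cur == 1) set(i3, j3, NBD);
            pts.emplace_back(i3, j3);
            // step 3.5: termination back at the start
            if (i4 == i && j4 == j && i3 == i1 && j3 == j1) break;
            i2 = i3; j2 = j3;
            i3 = i4; j3 = j4;
          }
        }
        borders.push_back(std::move(pts));
      }

      int fnow = at(i, j);
      if (fnow != 1) LNBD = fnow > 0 ? fnow : -fnow;
    }
  }

  const int n = static_cast<int>(borders.size());
  List contours(n);
  IntegerVector par_out(n), hole_out(n);
  LogicalVector touches(n);
  for (int b = 0; b < n; ++b) {
    const auto &pts = borders[b];
    IntegerMatrix m(static_cast<int>(pts.size()), 2);
    bool tb = false;
    for (size_t k = 0; k < pts.size(); ++k) {
      int pi = pts[k].first, pj = pts[k].second;
      m(static_cast<int>(k), 0) = pj; // x = column, 0-based
      m(static_cast<int>(k), 1) = pi; // y = row
      if (pi == 0 || pi == H - 1 || pj == 0 || pj == W - 1) tb = true;
    }
    contours[b] = m;
    // NBD of border b is b + 2; parent NBD 1 (frame) reported as 0
    int p = parent[b + 1];
    par_out[b] = (p <= 1) ? 0 : p - 1; // 1-based contour id of parent
    hole_out[b] = is_hole[b + 1];
    touches[b] = tb;
  }
  return List::create(_["vertices"] = contours,
                      _["parent"] = par_out,
                      _["is_hole"] = hole_out,
                      _["touches_border"] = touches);
}

// 8-connected labelling of foreground pixels plus first moments per label,
// used for interior-pixel centroids and enclosed-pixel areas.
// [[Rcpp::export(name = ".label_regions_cpp")]]
List label_regions_cpp(IntegerMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::vector<double> cnt, sx, sy;
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!bin(i, j) || lab(i, j)) continue;
      ++next;
      cnt.push_back(0); sx.push_back(0); sy.push_back(0);
      stack.clear();
      stack.push_back(i * W + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p / W, pj = p % W;
        cnt[next - 1] += 1; sx[next - 1] += pj; sy[next - 1] += pi;
        for (int k = 0; k < 8; ++k) {
          int ni = pi + DI[k], nj = pj + DJ[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (bin(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni * W + nj);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = lab,
                      _["count"] = NumericVector(cnt.begin(), cnt.end()),
                      _["sum_x"] = NumericVector(sx.begin(), sx.end()),
                      _["sum_y"] = NumericVector(sy.begin(), sy.end()));
}
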