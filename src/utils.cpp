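#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exhaustive integer block matching of every frame against frame 0.
// Returns a T x 2 matrix of global (drow, dcol) displacements, each the
// per-axis median over the per-block best matches (minimum mean absolute
// difference). Blocks whose search window leaves the frame at a given
// shift skip that shift.
// [[Rcpp::export]]
NumericMatrix bm_motion_cpp(NumericVector frames, int block, int radius,
                            int stride) {
  IntegerVector dims = frames.attr("dim");
  const int H = dims[0], W = dims[1], T = dims[2];
  const double *f = frames.begin();
  NumericMatrix disp(T, 2);

  std::vector<int> r0s, c0s;
  for (int r0 = 0; r0 + block <= H; r0 += stride) r0s.push_back(r0);
  for (int c0 = 0; c0 + block <= W; c0 += stride) c0s.push_back(c0);

  std::vector<double> drs, dcs;
  for (int t = 1; t < T; ++t) {
    const double *cur = f + (size_t)H * W * t;
    drs.clear(); dcs.clear();
    for (int r0 : r0s) for (int c0 : c0s) {
      double best = R_PosInf;
      int bdr = 0, bdc = 0;
      for (int dr = -radius; dr <= radius; ++dr) {
        if (r0 + dr < 0 || r0 + dr + block > H) continue;
        for (int dc = -radius; dc <= radius; ++dc) {
          if (c0 + dc < 0 || c0 + dc + block > W) continue;
          double sad = 0.0;
          for (int c = 0; c < block && sad < best * block * block; ++c) {
            const double *pr = f   + (size_t)H * (c0 + c)      + r0;
            const double *pc = cur + (size_t)H * (c0 + dc + c) + r0 + dr;
            for (int r = 0; r < block; ++r)
              sad += std::abs(pr[r] - pc[r]);
          }
          double mad = sad / (block * block);
          if (mad < best) { best = mad; bdr = dr; bdc = dc; }
        }
      }
      if (R_finite(best)) { drs.push_back(bdr); dcs.push_back(bdc); }
    }
    auto med = [](std::vector<double> &v) {
      if (v.empty()) return 0.0;
      std::sort(v.begin(), v.end());
      size_t n = v.size();
      return n % 2 ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
    };
    disp(t, 0) = med(drs);
    disp(t, 1) = med(dcs);
  }
  return disp;
}

// 8-connected labeling of a logical matrix. Background is 0, components
// are numbered 1..k in raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    if (!mask(r, c) || lab(r, c)) continue;
    ++next;
    stack.push_back(r + H * c);
    lab(r, c) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p % H, pc = p / H;
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        int nr = pr + dr, nc = pc + dc;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (mask(nr, nc) && !lab(nr, nc)) {
          lab(nr, nc) = next;
          stack.push_back(nr + H * nc);
        }
      }
    }
  }
  return lab;
}
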