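#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Separable Gaussian blur with symmetric-reflect boundary (d c b a | a b c d)
// and kernel truncated at 4*sigma (radius = ceil(4*sigma)).

static inline int reflect_idx(int i, int n) {
  // fold i into [0, n) by symmetric reflection with edge repetition
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass (along rows within each column); reflected indices are
  // precomputed once and each line is copied into a padded buffer so the
  // inner loop is a contiguous dot product
  {
    std::vector<int> ridx(H + 2 * r);
    for (int i = 0; i < H + 2 * r; ++i) ridx[i] = reflect_idx(i - r, H);
    std::vector<double> buf(H + 2 * r);
    for (int c = 0; c < W; ++c) {
      const double* col = &img(0, c);
      for (int i = 0; i < H + 2 * r; ++i) buf[i] = col[ridx[i]];
      for (int rr = 0; rr < H; ++rr) {
        double acc = 0.0;
        const double* b = &buf[rr];
        for (int i = 0; i <= 2 * r; ++i) acc += k[i] * b[i];
        tmp(rr, c) = acc;
      }
    }
  }
  // horizontal pass
  {
    std::vector<int> cidx(W + 2 * r);
    for (int i = 0; i < W + 2 * r; ++i) cidx[i] = reflect_idx(i - r, W);
    std::vector<double> buf(W + 2 * r);
    for (int rr = 0; rr < H; ++rr) {
      for (int i = 0; i < W + 2 * r; ++i) buf[i] = tmp(rr, cidx[i]);
      for (int c = 0; c < W; ++c) {
        double acc = 0.0;
        const double* b = &buf[c];
        for (int i = 0; i <= 2 * r; ++i) acc += k[i] * b[i];
        out(rr, c) = acc;
      }
    }
  }
  return out;
}

// Weighted DBSCAN on a pixel grid with manhattan metric.
// weight(r,c) > 0 marks an input point with that sample weight. A point is
// CORE iff the weight sum over all points at manhattan distance <= eps
// (itself included) is >= min_weight. Clusters are density-connected core
// sets; border points join the nearest core point (manhattan distance, ties
// broken toward the lowest cluster id). Labels 1..K ordered by the row-major
// position (0-based row, col) of each cluster's first member pixel; 0 = noise
// or background.

// [[Rcpp::export(name = ".dbscan_grid_cpp")]]
IntegerMatrix dbscan_grid_cpp(const NumericMatrix& w, double eps,
                              double min_weight) {
  const int H = w.nrow(), W = w.ncol();
  const int R = (int)std::floor(eps);
  // neighborhood offsets (incl. self), sorted by manhattan distance
  std::vector<std::array<int, 3>> offs; // {dist, dr, dc}
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc) {
      int d = std::abs(dr) + std::abs(dc);
      if ((double)d <= eps) offs.push_back({d, dr, dc});
    }
  std::sort(offs.begin(), offs.end());

  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<char> core(H * (size_t)W, 0);

  // core test
  for (int rr = 0; rr < H; ++rr)
    for (int c = 0; c < W; ++c) {
      if (w(rr, c) <= 0) continue;
      double s = 0.0;
      for (auto& o : offs) {
        int nr = rr + o[1], nc = c + o[2];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        double wv = w(nr, nc);
        if (wv > 0) s += wv;
      }
      if (s >= min_weight) core[(size_t)c * H + rr] = 1;
    }

  // BFS over core points, row-major seed order (row outer, col inner)
  int K = 0;
  for (int rr = 0; rr < H; ++rr)
    for (int c = 0; c < W; ++c) {
      size_t idx = (size_t)c * H + rr;
      if (!core[idx] || lab(rr, c) != 0) continue;
      ++K;
      std::queue<std::pair<int, int>> q;
      lab(rr, c) = K;
      q.push({rr, c});
      while (!q.empty()) {
        auto p = q.front();
        q.pop();
        for (auto& o : offs) {
          if (o[0] == 0) continue;
          int nr = p.first + o[1], nc = p.second + o[2];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (core[(size_t)nc * H + nr] && lab(nr, nc) == 0) {
            lab(nr, nc) = K;
            q.push({nr, nc});
          }
        }
      }
    }

  // border points: nearest core within eps; tie -> lowest cluster id
  for (int rr = 0; rr < H; ++rr)
    for (int c = 0; c < W; ++c) {
      if (w(rr, c) <= 0 || core[(size_t)c * H + rr]) continue;
      int bestd = R + 1, bestlab = 0;
      for (auto& o : offs) {
        if (o[0] > bestd) break; // offs sorted by distance
        int nr = rr + o[1], nc = c + o[2];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (!core[(size_t)nc * H + nr]) continue;
        int l = lab(nr, nc);
        if (o[0] < bestd || (o[0] == bestd && l < bestlab)) {
          bestd = o[0];
          bestlab = l;
        }
      }
      if (bestlab > 0) lab(rr, c) = bestlab;
    }

  // relabel so ids follow row-major order of each cluster's first member
  if (K > 0) {
    std::vector<long> firstpos(K + 1, -1);
    long pos = 0;
    for (int rr = 0; rr < H; ++rr)
      for (int c = 0; c < W; ++c, ++pos) {
        int l = lab(rr, c);
        if (l > 0 && firstpos[l] < 0) firstpos[l] = pos;
      }
    std::vector<int> ord;
    for (int l = 1; l <= K; ++l)
      if (firstpos[l] >= 0) ord.push_back(l);
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return firstpos[a] < firstpos[b];
    });
    std::vector<int> remap(K + 1, 0);
    for (size_t i = 0; i < ord.size(); ++i) remap[ord[i]] = (int)i + 1;
    for (int i = 0; i < H * W; ++i)
      if (lab[i] > 0) lab[i] = remap[lab[i]];
  }
  return lab;
}

// Connected components of a logical mask (8- or 4-connectivity), labels
// 1..K in row-major discovery order of each component's first pixel.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask,
                                   int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<std::pair<int, int>> offs;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if (connectivity == 4 && std::abs(dr) + std::abs(dc) != 1) continue;
      offs.push_back({dr, dc});
    }
  int K = 0;
  for (int rr = 0; rr < H; ++rr)
    for (int c = 0; c < W; ++c) {
      if (!mask(rr, c) || lab(rr, c) != 0) continue;
      ++K;
      std::queue<std::pair<int, int>> q;
      lab(rr, c) = K;
      q.push({rr, c});
      while (!q.empty()) {
        auto p = q.front();
        q.pop();
        for (auto& o : offs) {
          int nr = p.first + o.first, nc = p.second + o.second;
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = K;
            q.push({nr, nc});
          }
        }
      }
    }
  return lab;
}
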