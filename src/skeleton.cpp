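// Binary skeletonization (Zhang-Suen thinning) and extraction of the
// longest geodesic path through an 8-connected skeleton (double BFS sweep).

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m(clone(mask));
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return m(i, j) != 0 ? 1 : 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j),     p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({i, j});
        }
      }
      for (auto& k : kill) m(k.first, k.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

static std::vector<int> bfs_far(const IntegerMatrix& m, int start,
                                std::vector<int>& parent) {
  int H = m.nrow(), W = m.ncol();
  std::vector<int> dist((std::size_t)H * W, -1);
  parent.assign((std::size_t)H * W, -1);
  std::queue<int> qq;
  dist[start] = 0;
  qq.push(start);
  while (!qq.empty()) {
    int p = qq.front(); qq.pop();
    int i = p % H, j = p / H;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (!m(ii, jj)) continue;
        int pn = ii + H * jj;
        if (dist[pn] >= 0) continue;
        dist[pn] = dist[p] + 1;
        parent[pn] = p;
        qq.push(pn);
      }
    }
  }
  return dist;
}

// [[Rcpp::export]]
IntegerMatrix cpp_skeleton_longest_path(IntegerMatrix skel) {
  int H = skel.nrow(), W = skel.ncol();
  int start = -1;
  for (int j = 0; j < W && start < 0; ++j)
    for (int i = 0; i < H; ++i)
      if (skel(i, j)) { start = i + H * j; break; }
  if (start < 0) return IntegerMatrix(0, 2);
  std::vector<int> parent;
  std::vector<int> d1 = bfs_far(skel, start, parent);
  int u = start;
  for (std::size_t p = 0; p < d1.size(); ++p)
    if (d1[p] > d1[u]) u = (int)p;
  std::vector<int> d2 = bfs_far(skel, u, parent);
  int v = u;
  for (std::size_t p = 0; p < d2.size(); ++p)
    if (d2[p] > d2[v]) v = (int)p;
  std::vector<int> path;
  for (int p = v; p >= 0; p = parent[p]) path.push_back(p);
  IntegerMatrix out(path.size(), 2);
  for (std::size_t k = 0; k < path.size(); ++k) {
    out(k, 0) = path[k] % H + 1; // row, 1-based
    out(k, 1) = path[k] / H + 1; // col, 1-based
  }
  return out;
}
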