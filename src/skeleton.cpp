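#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// All routines use (row, col) indexing on integer 0/1 matrices and the
// 8-connected foreground convention.

static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

inline int at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

//' Count 8-connected foreground neighbours of every pixel.
//'
//' @param img integer 0/1 matrix.
//' @return integer matrix of neighbour counts (0 outside the foreground too).
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix nbr_count8(const IntegerMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int s = 0;
      for (int k = 0; k < 8; ++k) s += at(img, r + DR[k], c + DC[k]);
      out(r, c) = s;
    }
  return out;
}

// number of 0->1 transitions in the ordered 8-neighbourhood ring
static int transitions(const IntegerMatrix& m, int r, int c) {
  int t = 0;
  for (int k = 0; k < 8; ++k) {
    int a = at(m, r + DR[k], c + DC[k]);
    int b = at(m, r + DR[(k + 1) % 8], c + DC[(k + 1) % 8]);
    if (a == 0 && b == 1) ++t;
  }
  return t;
}

// is the foreground of the 3x3 ring around (r,c), excluding (r,c) itself,
// a single 8-connected set? (used for redundant-pixel removal)
static bool ring_connected(const IntegerMatrix& m, int r, int c) {
  int pix[8];
  int n = 0;
  for (int k = 0; k < 8; ++k) pix[k] = at(m, r + DR[k], c + DC[k]);
  for (int k = 0; k < 8; ++k) n += pix[k];
  if (n == 0) return true;
  // BFS over the 8 ring positions, adjacency = 8-adjacency of the cells
  int seen[8] = {0,0,0,0,0,0,0,0};
  std::queue<int> q;
  for (int k = 0; k < 8; ++k) if (pix[k]) { q.push(k); seen[k] = 1; break; }
  int cnt = 0;
  while (!q.empty()) {
    int k = q.front(); q.pop(); ++cnt;
    int rk = r + DR[k], ck = c + DC[k];
    for (int j = 0; j < 8; ++j) {
      if (!pix[j] || seen[j]) continue;
      int rj = r + DR[j], cj = c + DC[j];
      if (std::abs(rk - rj) <= 1 && std::abs(ck - cj) <= 1) {
        seen[j] = 1; q.push(j);
      }
    }
  }
  return cnt == n;
}

//' Zhang-Suen thinning with a redundant-pixel cleanup pass.
//'
//' Iterative two-subfield thinning to a 1-pixel-wide skeleton, followed by
//' sequential removal (fixed raster order) of non-endpoint simple pixels so
//' that staircase artifacts do not masquerade as junctions. Idempotent on
//' its own output.
//'
//' @param img integer 0/1 matrix.
//' @return thinned integer 0/1 matrix.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix thin_skeleton(const IntegerMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) m(r, c) = m(r, c) != 0 ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          int B = 0;
          for (int k = 0; k < 8; ++k) B += at(m, r + DR[k], c + DC[k]);
          if (B < 2 || B > 6) continue;
          if (transitions(m, r, c) != 1) continue;
          // ring order: 0=N,1=NE,2=E,3=SE,4=S,5=SW,6=W,7=NW
          int P2 = at(m, r - 1, c), P4 = at(m, r, c + 1),
              P6 = at(m, r + 1, c), P8 = at(m, r, c - 1);
          if (sub == 0) {
            if (P2 * P4 * P6 != 0) continue;
            if (P4 * P6 * P8 != 0) continue;
          } else {
            if (P2 * P4 * P8 != 0) continue;
            if (P2 * P6 * P8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      for (size_t i = 0; i < kill.size(); ++i) m(kill[i].first, kill[i].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }

  // sequential cleanup: drop pixels whose removal leaves the local ring
  // connected and which are not endpoints; removes staircase "fake junctions"
  changed = true;
  while (changed) {
    changed = false;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        if (!m(r, c)) continue;
        int B = 0;
        for (int k = 0; k < 8; ++k) B += at(m, r + DR[k], c + DC[k]);
        if (B < 2) continue;              // keep endpoints / isolated pixels
        // removable iff the neighbours remain one 8-connected set without
        // this pixel: straight-path interiors (opposite neighbours) and real
        // junctions (>=2 separated arms) fail this; staircase corners pass
        if (!ring_connected(m, r, c)) continue;
        m(r, c) = 0;
        changed = true;
      }
  }
  return m;
}

//' Label 8-connected foreground components.
//'
//' @param img integer 0/1 matrix.
//' @return integer matrix of component labels, 0 = background.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label8(const IntegerMatrix& img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int r0 = 0; r0 < nr; ++r0)
    for (int c0 = 0; c0 < nc; ++c0) {
      if (img(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int k = 0; k < 8; ++k) {
          int r = p.first + DR[k], c = p.second + DC[k];
          if (r < 0 || c < 0 || r >= nr || c >= nc) continue;
          if (img(r, c) == 0 || lab(r, c) != 0) continue;
          lab(r, c) = next;
          q.push(std::make_pair(r, c));
        }
      }
    }
  return lab;
}
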