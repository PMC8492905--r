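#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Pixel-grid helpers shared by segmentation, FAZ detection and
// skeletonization. All grids are logical matrices in R's column-major
// layout; indices below are 0-based (row r, column c).

static inline int idx(int r, int c, int nr) { return r + c * nr; }

// Label connected components of a binary image.
// connectivity: 4 or 8. Returns an integer matrix of labels (0 = background),
// labels are 1..k in discovery order (deterministic raster scan).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& img, int connectivity) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc2 = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (img(rr, cc2) && !lab(rr, cc2)) {
            lab(rr, cc2) = next;
            q.push(std::make_pair(rr, cc2));
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation by an arbitrary structuring element given as offset lists.
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalMatrix dilate_cpp(const LogicalMatrix& img, const IntegerVector& dr,
                         const IntegerVector& dc) {
  const int nr = img.nrow(), nc = img.ncol(), nk = dr.size();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      for (int k = 0; k < nk; ++k) {
        int rr = r + dr[k], cc2 = c + dc[k];
        if (rr >= 0 && rr < nr && cc2 >= 0 && cc2 < nc) out(rr, cc2) = true;
      }
    }
  }
  return out;
}

// Hysteresis growth: keep weak-mask pixels 8-connected to a strong seed.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalMatrix hysteresis_cpp(const LogicalMatrix& strong,
                             const LogicalMatrix& weak) {
  const int nr = strong.nrow(), nc = strong.ncol();
  LogicalMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (strong(r, c)) {
        out(r, c) = true;
        q.push(std::make_pair(r, c));
      }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = p.first + dr[k], cc2 = p.second + dc[k];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      if (weak(rr, cc2) && !out(rr, cc2)) {
        out(rr, cc2) = true;
        q.push(std::make_pair(rr, cc2));
      }
    }
  }
  return out;
}

// Guo-Hall thinning to 1-px-wide centerlines, followed by a conservative
// staircase cleanup that removes a pixel from any remaining 2x2 block when
// doing so cannot break 8-connectivity (the pixel is simple).
static inline bool getpx(const std::vector<char>& m, int r, int c, int nr,
                         int nc) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
  return m[idx(r, c, nr)] != 0;
}

// neighbours in circular order p2..p9 starting north, clockwise
static void neigh(const std::vector<char>& m, int r, int c, int nr, int nc,
                  int p[8]) {
  p[0] = getpx(m, r - 1, c, nr, nc);
  p[1] = getpx(m, r - 1, c + 1, nr, nc);
  p[2] = getpx(m, r, c + 1, nr, nc);
  p[3] = getpx(m, r + 1, c + 1, nr, nc);
  p[4] = getpx(m, r + 1, c, nr, nc);
  p[5] = getpx(m, r + 1, c - 1, nr, nc);
  p[6] = getpx(m, r, c - 1, nr, nc);
  p[7] = getpx(m, r - 1, c - 1, nr, nc);
}

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(const LogicalMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<char> m(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) m[idx(r, c, nr)] = img(r, c) ? 1 : 0;

  // Guo-Hall (1989) two-subiteration thinning. With p[] in circular order
  // N, NE, E, SE, S, SW, W, NW (= P2..P9 of the paper):
  //   C  = !P2&(P3|P4) + !P4&(P5|P6) + !P6&(P7|P8) + !P8&(P9|P2)
  //   N1 = (P9|P2) + (P3|P4) + (P5|P6) + (P7|P8)
  //   N2 = (P2|P3) + (P4|P5) + (P6|P7) + (P8|P9)
  // delete iff C == 1, 2 <= min(N1,N2) <= 3, and the pass-specific
  // condition ((P6|P7|!P9)&P8 for one pass, (P2|P3|!P5)&P4 for the other)
  // is zero.
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m[idx(r, c, nr)]) continue;
          int p[8];
          neigh(m, r, c, nr, nc, p);
          const int P2 = p[0], P3 = p[1], P4 = p[2], P5 = p[3];
          const int P6 = p[4], P7 = p[5], P8 = p[6], P9 = p[7];
          int C = (!P2 && (P3 || P4)) + (!P4 && (P5 || P6)) +
                  (!P6 && (P7 || P8)) + (!P8 && (P9 || P2));
          if (C != 1) continue;
          int N1 = (P9 || P2) + (P3 || P4) + (P5 || P6) + (P7 || P8);
          int N2 = (P2 || P3) + (P4 || P5) + (P6 || P7) + (P8 || P9);
          int N = N1 < N2 ? N1 : N2;
          if (N < 2 || N > 3) continue;
          int mcond = (pass == 0) ? ((P6 || P7 || !P9) && P8)
                                  : ((P2 || P3 || !P5) && P4);
          if (mcond != 0) continue;
          kill.push_back(idx(r, c, nr));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m[kill[k]] = 0;
    }
  }

  // staircase cleanup: delete simple pixels participating in a 2x2 block.
  // Simplicity is tested with the Yokoi connectivity number for 8-connected
  // foreground: C = sum over 4-neighbour slots k of
  //   q_k - q_k * q_{k+1} * q_{k+2}   (q = background, circular order);
  // a pixel with C == 1 (and more than one foreground neighbour, so
  // endpoints are preserved) can be removed without changing topology.
  bool again = true;
  while (again) {
    again = false;
    for (int c = 0; c < nc - 1; ++c) {
      for (int r = 0; r < nr - 1; ++r) {
        if (!(getpx(m, r, c, nr, nc) && getpx(m, r + 1, c, nr, nc) &&
              getpx(m, r, c + 1, nr, nc) && getpx(m, r + 1, c + 1, nr, nc)))
          continue;
        const int rs[4] = {r, r + 1, r + 1, r};
        const int cs[4] = {c, c + 1, c, c + 1};
        for (int t = 0; t < 4; ++t) {
          int p[8];
          neigh(m, rs[t], cs[t], nr, nc, p);
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2) continue;  // endpoint or isolated: keep
          int C = 0;
          for (int k = 0; k < 8; k += 2) {
            int q0 = 1 - p[k], q1 = 1 - p[(k + 1) % 8], q2 = 1 - p[(k + 2) % 8];
            C += q0 - q0 * q1 * q2;
          }
          if (C != 1) continue;
          m[idx(rs[t], cs[t], nr)] = 0;
          again = true;
          break;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = m[idx(r, c, nr)] != 0;
  return out;
}
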