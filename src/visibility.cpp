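#include <Rcpp.h>
using namespace Rcpp;

// Line-of-sight on a unit-tile grid. A tile is a unit square; walls are
// whole tiles. A target tile is visible from an observer tile iff each of
// the target's 4 corners is connected by a wall-free segment to at least
// one of the observer's 4 corners. A segment is blocked by a wall square
// when its intersection with the closed square has positive length, so
// segments grazing exactly along a wall edge count as blocked, while a
// touch at a single corner point does not.

static const double EPS = 1e-9;

// Liang-Barsky clip of segment (x1,y1)-(x2,y2) against closed unit box at
// (wx,wy); returns true when the overlap has positive length.
static bool segment_blocked_by(double x1, double y1, double x2, double y2,
                               double wx, double wy) {
  double t0 = 0.0, t1 = 1.0;
  double d, lo, hi, ta, tb, tmp;

  d = x2 - x1; lo = wx; hi = wx + 1.0;
  if (std::fabs(d) < EPS) {
    if (x1 < lo - EPS || x1 > hi + EPS) return false;
  } else {
    ta = (lo - x1) / d; tb = (hi - x1) / d;
    if (ta > tb) { tmp = ta; ta = tb; tb = tmp; }
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }

  d = y2 - y1; lo = wy; hi = wy + 1.0;
  if (std::fabs(d) < EPS) {
    if (y1 < lo - EPS || y1 > hi + EPS) return false;
  } else {
    ta = (lo - y1) / d; tb = (hi - y1) / d;
    if (ta > tb) { tmp = ta; ta = tb; tb = tmp; }
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }

  return (t1 - t0) > EPS;
}

static bool segment_hits_wall(double x1, double y1, double x2, double y2,
                         const std::vector<double>& wx,
                         const std::vector<double>& wy) {
  double bx0 = std::min(x1, x2) - 1.0, bx1 = std::max(x1, x2) + 1.0;
  double by0 = std::min(y1, y2) - 1.0, by1 = std::max(y1, y2) + 1.0;
  for (size_t i = 0; i < wx.size(); ++i) {
    if (wx[i] < bx0 || wx[i] > bx1 || wy[i] < by0 || wy[i] > by1) continue;
    if (segment_blocked_by(x1, y1, x2, y2, wx[i], wy[i])) return true;
  }
  return false;
}

// One direction: every target corner must see >= 1 observer corner.
static bool covers(int ox, int oy, int tx, int ty,
                   const std::vector<double>& wx,
                   const std::vector<double>& wy) {
  static const int dx[4] = {0, 1, 0, 1};
  static const int dy[4] = {0, 0, 1, 1};
  for (int tc = 0; tc < 4; ++tc) {
    bool seen = false;
    for (int oc = 0; oc < 4 && !seen; ++oc) {
      if (ox + dx[oc] == tx + dx[tc] && oy + dy[oc] == ty + dy[tc]) {
        seen = true; // shared corner point
      } else if (!segment_hits_wall(ox + dx[oc], oy + dy[oc],
                                    tx + dx[tc], ty + dy[tc], wx, wy)) {
        seen = true;
      }
    }
    if (!seen) return false;
  }
  return true;
}

// Tile-pair visibility, symmetrized so that "b visible from a" iff
// "a visible from b".
static bool tile_visible(int ox, int oy, int tx, int ty,
                         const std::vector<double>& wx,
                         const std::vector<double>& wy) {
  return covers(ox, oy, tx, ty, wx, wy) && covers(tx, ty, ox, oy, wx, wy);
}

// [[Rcpp::export(name = ".vis_matrix_cpp")]]
LogicalMatrix vis_matrix_cpp(IntegerVector from_x, IntegerVector from_y,
                             IntegerVector to_x, IntegerVector to_y,
                             IntegerVector wall_x, IntegerVector wall_y) {
  int nf = from_x.size(), nt = to_x.size();
  std::vector<double> wx(wall_x.begin(), wall_x.end());
  std::vector<double> wy(wall_y.begin(), wall_y.end());
  LogicalMatrix out(nf, nt);
  for (int i = 0; i < nf; ++i) {
    for (int j = 0; j < nt; ++j) {
      if (from_x[i] == to_x[j] && from_y[i] == to_y[j]) {
        out(i, j) = true;
      } else {
        out(i, j) = tile_visible(from_x[i], from_y[i], to_x[j], to_y[j],
                                 wx, wy);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".segment_free_cpp")]]
bool segment_free_cpp(double x1, double y1, double x2, double y2,
                      IntegerVector wall_x, IntegerVector wall_y) {
  std::vector<double> wx(wall_x.begin(), wall_x.end());
  std::vector<double> wy(wall_y.begin(), wall_y.end());
  return !segment_hits_wall(x1, y1, x2, y2, wx, wy);
}
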