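#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Geometry helpers: flat-top hexagons with circumradius (side) s.
// A point p is inside the hexagon centred at c, shrunk by `margin`, iff its
// distance to every edge line is at least `margin`. For a flat-top hexagon
// the apothem is a = s*sqrt(3)/2 and the six half-plane tests reduce, by
// symmetry, to two inequalities on (|dx|, |dy|).
// ---------------------------------------------------------------------------

static const double SQRT3_2 = 0.86602540378443864676;

static inline bool in_hex(double dx, double dy, double s, double margin) {
  const double a = SQRT3_2 * s - margin;
  const double qx = std::fabs(dx), qy = std::fabs(dy);
  return (qy <= a) && (SQRT3_2 * qx + 0.5 * qy <= a);
}

static int which_hex(double x, double y, const NumericMatrix& centers,
                     double s, double margin) {
  for (int h = 0; h < centers.nrow(); ++h) {
    if (in_hex(x - centers(h, 0), y - centers(h, 1), s, margin)) return h;
  }
  return -1;
}

// [[Rcpp::export]]
IntegerVector cpp_hex_member(NumericMatrix pts, NumericMatrix centers,
                             double s, double margin) {
  const int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int h = which_hex(pts(i, 0), pts(i, 1), centers, s, margin);
    out[i] = (h < 0) ? NA_INTEGER : h + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uniform-bin spatial hash over points, rebuilt per use. Bin size is chosen
// by the caller (>= the largest interaction distance) so all partners of a
// point lie in its 3x3 bin neighbourhood.
// ---------------------------------------------------------------------------

struct SpatialHash {
  double x0, y0, cell;
  int nx, ny;
  std::vector< std::vector<int> > bins;

  SpatialHash(double xmin, double ymin, double xmax, double ymax, double cs) {
    cell = cs > 0 ? cs : 1.0;
    x0 = xmin - cell; y0 = ymin - cell;
    nx = std::max(1, (int)std::ceil((xmax - x0) / cell) + 2);
    ny = std::max(1, (int)std::ceil((ymax - y0) / cell) + 2);
    // guard against degenerate/huge grids
    if ((double)nx * (double)ny > 4e7) stop("spatial hash too large");
    bins.assign((size_t)nx * ny, std::vector<int>());
  }
  inline int bx(double x) const {
    int i = (int)std::floor((x - x0) / cell);
    return std::min(std::max(i, 0), nx - 1);
  }
  inline int by(double y) const {
    int j = (int)std::floor((y - y0) / cell);
    return std::min(std::max(j, 0), ny - 1);
  }
  inline void insert(int id, double x, double y) {
    bins[(size_t)by(y) * nx + bx(x)].push_back(id);
  }
  template <typename F>
  inline void neighbours(double x, double y, F fun) const {
    int i0 = bx(x), j0 = by(y);
    for (int j = std::max(0, j0 - 1); j <= std::min(ny - 1, j0 + 1); ++j)
      for (int i = std::max(0, i0 - 1); i <= std::min(nx - 1, i0 + 1); ++i) {
        const std::vector<int>& b = bins[(size_t)j * nx + i];
        for (size_t k = 0; k < b.size(); ++k) fun(b[k]);
      }
  }
};

static void bbox_of(const std::vector<double>& xs, const std::vector<double>& ys,
                    double& xmin, double& ymin, double& xmax, double& ymax) {
  xmin = ymin = R_PosInf; xmax = ymax = R_NegInf;
  for (size_t i = 0; i < xs.size(); ++i) {
    if (xs[i] < xmin) xmin = xs[i];
    if (xs[i] > xmax) xmax = xs[i];
    if (ys[i] < ymin) ymin = ys[i];
    if (ys[i] > ymax) ymax = ys[i];
  }
  if (!R_FINITE(xmin)) { xmin = ymin = 0; xmax = ymax = 1; }
}

// ---------------------------------------------------------------------------
// Disk packing inside one hexagon: contact-distance growth from spiral seeds.
// Children are placed at exactly distance d from a frontier disk, first
// feasible among n_angles directions (random base rotation per attempt drawn
// from the pre-generated uniform stream u, consumed cyclically).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_pack_hex(NumericMatrix seeds, double cx, double cy, double s,
                           double d, double margin, int n_angles,
                           NumericVector u) {
  std::vector<double> xs, ys;
  for (int i = 0; i < seeds.nrow(); ++i) {
    xs.push_back(seeds(i, 0));
    ys.push_back(seeds(i, 1));
  }
  const double d2 = d * d * (1.0 - 1e-12);
  const double a = SQRT3_2 * s;
  SpatialHash hash(cx - a - d, cy - a - d, cx + a + d, cy + a + d, d);
  for (size_t i = 0; i < xs.size(); ++i) hash.insert((int)i, xs[i], ys[i]);

  std::vector<int> queue;
  for (size_t i = 0; i < xs.size(); ++i) queue.push_back((int)i);
  size_t qi = 0, ui = 0;
  const size_t un = u.size() > 0 ? (size_t)u.size() : 1;

  while (qi < queue.size()) {
    const int p = queue[qi++];
    bool placed = true;
    while (placed) {
      placed = false;
      const double base = 2.0 * M_PI * (u.size() > 0 ? u[ui++ % un] : 0.0);
      for (int k = 0; k < n_angles; ++k) {
        const double th = base + 2.0 * M_PI * k / n_angles;
        const double x = xs[p] + d * std::cos(th);
        const double y = ys[p] + d * std::sin(th);
        if (!in_hex(x - cx, y - cy, s, margin)) continue;
        bool free_site = true;
        hash.neighbours(x, y, [&](int j) {
          if (!free_site) return;
          const double ddx = xs[j] - x, ddy = ys[j] - y;
          if (ddx * ddx + ddy * ddy < d2) free_site = false;
        });
        if (free_site) {
          xs.push_back(x); ys.push_back(y);
          const int id = (int)xs.size() - 1;
          hash.insert(id, x, y);
          queue.push_back(id);
          placed = true;
          break;
        }
      }
    }
  }

  NumericMatrix out((int)xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise disk overlap audit (hashed). Returns the maximum penetration
// depth (ri + rj - dist), 0 if none.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_max_overlap(NumericMatrix xy, NumericVector r) {
  const int n = xy.nrow();
  if (n < 2) return 0.0;
  double rmax = 0.0;
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = xy(i, 0); ys[i] = xy(i, 1);
    if (r[i] > rmax) rmax = r[i];
  }
  double xmin, ymin, xmax, ymax;
  bbox_of(xs, ys, xmin, ymin, xmax, ymax);
  SpatialHash hash(xmin, ymin, xmax, ymax, std::max(2.0 * rmax, 1e-9));
  for (int i = 0; i < n; ++i) hash.insert(i, xs[i], ys[i]);
  double worst = 0.0;
  for (int i = 0; i < n; ++i) {
    hash.neighbours(xs[i], ys[i], [&](int j) {
      if (j <= i) return;
      const double dx = xs[j] - xs[i], dy = ys[j] - ys[i];
      const double dist = std::sqrt(dx * dx + dy * dy);
      const double pen = r[i] + r[j] - dist;
      if (pen > worst) worst = pen;
    });
  }
  return worst;
}

// ---------------------------------------------------------------------------
// Position-based relaxation of overlapping disks. Deterministic sorted-id
// sweep; immobile disks never move. Returns corrected positions, the
// residual max overlap and iterations used.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_resolve_disks(NumericMatrix xy, NumericVector r, NumericVector w,
                       int max_iter, double tol) {
  const int n = xy.nrow();
  std::vector<double> xs(n), ys(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    xs[i] = xy(i, 0); ys[i] = xy(i, 1);
    if (r[i] > rmax) rmax = r[i];
  }
  int it = 0;
  double worst = R_PosInf;
  for (it = 0; it < max_iter && n > 1; ++it) {
    double xmin, ymin, xmax, ymax;
    bbox_of(xs, ys, xmin, ymin, xmax, ymax);
    SpatialHash hash(xmin, ymin, xmax, ymax, std::max(2.0 * rmax, 1e-9));
    for (int i = 0; i < n; ++i) hash.insert(i, xs[i], ys[i]);
    worst = 0.0;
    for (int i = 0; i < n; ++i) {
      hash.neighbours(xs[i], ys[i], [&](int j) {
        if (j <= i) return;
        double dx = xs[j] - xs[i], dy = ys[j] - ys[i];
        double dist = std::sqrt(dx * dx + dy * dy);
        double pen = r[i] + r[j] - dist;
        if (pen <= 0) return;
        if (pen > worst) worst = pen;
        double nxv, nyv;
        if (dist > 1e-12) { nxv = dx / dist; nyv = dy / dist; }
        else { nxv = 1.0; nyv = 0.0; } // coincident centres: fixed direction
        double wi = w[i], wj = w[j];
        double wsum = wi + wj;
        if (wsum <= 0) return;
        xs[i] -= nxv * pen * wi / wsum; ys[i] -= nyv * pen * wi / wsum;
        xs[j] += nxv * pen * wj / wsum; ys[j] += nyv * pen * wj / wsum;
      });
    }
    if (worst < tol) { ++it; break; }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return List::create(_["xy"] = out, _["max_overlap"] = (n > 1 ? worst : 0.0),
                      _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// Joint-constrained mechanical step.
//
// Reduced-coordinate skeleton: each septum joins nodes (a, b). Its two
// boundary sub-segments are rods of length rod_len anchored one at each
// node (revolute joint: the rod endpoint coincides with its node), both
// directed along the a->b axis and laterally offset by +/- rod_off
// (side-by-side pair). Relative sliding of the pair along the shared axis
// (prismatic joint) is the free telescoping of the septum, bounded by the
// node-distance window [Lmin, Lmax].
//
// One step = n_iter position-based relaxation sweeps of:
//   (1) septum length window projection on node pairs,
//   (2) node(triad disk)-disk contacts,
//   (3) disk-disk contacts,
//   (4) disk-rod contacts (reaction applied to the rod's anchor node).
// Pinned nodes and immobile disks never move.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mech_step(NumericMatrix nodes, LogicalVector pinned, double node_r,
                   IntegerMatrix septa, double Lmin, double Lmax,
                   double rod_len, double rod_halfw, double rod_off,
                   NumericMatrix disks, NumericVector dr, NumericVector dw,
                   int n_iter) {
  const int nn = nodes.nrow(), ns = septa.nrow(), nd = disks.nrow();
  std::vector<double> nx_(nn), ny_(nn), dx_(nd), dy_(nd);
  for (int i = 0; i < nn; ++i) { nx_[i] = nodes(i, 0); ny_[i] = nodes(i, 1); }
  double rmax = node_r;
  for (int i = 0; i < nd; ++i) {
    dx_[i] = disks(i, 0); dy_[i] = disks(i, 1);
    if (dr[i] > rmax) rmax = dr[i];
  }
  const double reach = rod_halfw + std::fabs(rod_off) + rmax; // rod contact band

  // node corrections are accumulated per sweep and applied as the average
  // over contributing constraints (Jacobi style): a node engaged by many
  // contacts settles at a force-balance compromise instead of summing
  // full sequential corrections, which would amplify without bound
  std::vector<double> nax(nn), nay(nn);
  std::vector<int> ncnt(nn);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(nax.begin(), nax.end(), 0.0);
    std::fill(nay.begin(), nay.end(), 0.0);
    std::fill(ncnt.begin(), ncnt.end(), 0);
    // (1) septum length window
    for (int sId = 0; sId < ns; ++sId) {
      const int a = septa(sId, 0) - 1, b = septa(sId, 1) - 1;
      double ddx = nx_[b] - nx_[a], ddy = ny_[b] - ny_[a];
      double dist = std::sqrt(ddx * ddx + ddy * ddy);
      if (dist < 1e-12) continue;
      double target = dist;
      if (dist < Lmin) target = Lmin;
      else if (dist > Lmax) target = Lmax;
      if (target == dist) continue;
      const double wa = pinned[a] ? 0.0 : 1.0, wb = pinned[b] ? 0.0 : 1.0;
      const double wsum = wa + wb;
      if (wsum <= 0) continue;
      const double corr = (dist - target) / dist;
      if (wa > 0) { nax[a] += ddx * corr * wa / wsum;
                    nay[a] += ddy * corr * wa / wsum; ncnt[a]++; }
      if (wb > 0) { nax[b] -= ddx * corr * wb / wsum;
                    nay[b] -= ddy * corr * wb / wsum; ncnt[b]++; }
    }

    // spatial hash over disks for (2)-(4)
    double xmin, ymin, xmax, ymax;
    bbox_of(dx_, dy_, xmin, ymin, xmax, ymax);
    const double cs = std::max(2.0 * rmax, std::max(reach, 1e-9));
    SpatialHash hash(std::min(xmin, -1.0), std::min(ymin, -1.0),
                     xmax + 1.0, ymax + 1.0, cs);
    for (int i = 0; i < nd; ++i) hash.insert(i, dx_[i], dy_[i]);

    // (2) triad-node disks vs agent disks
    for (int i = 0; i < nn; ++i) {
      hash.neighbours(nx_[i], ny_[i], [&](int j) {
        double ddx = dx_[j] - nx_[i], ddy = dy_[j] - ny_[i];
        double dist = std::sqrt(ddx * ddx + ddy * ddy);
        double pen = node_r + dr[j] - dist;
        if (pen <= 0 || dist < 1e-12) return;
        double wi = pinned[i] ? 0.0 : 1.0, wj = dw[j];
        double wsum = wi + wj;
        if (wsum <= 0) return;
        double nxv = ddx / dist, nyv = ddy / dist;
        if (wi > 0) { nax[i] -= nxv * pen * wi / wsum;
                      nay[i] -= nyv * pen * wi / wsum; ncnt[i]++; }
        dx_[j] += nxv * pen * wj / wsum; dy_[j] += nyv * pen * wj / wsum;
      });
    }

    // (3) disk-disk
    for (int i = 0; i < nd; ++i) {
      hash.neighbours(dx_[i], dy_[i], [&](int j) {
        if (j <= i) return;
        double ddx = dx_[j] - dx_[i], ddy = dy_[j] - dy_[i];
        double dist = std::sqrt(ddx * ddx + ddy * ddy);
        double pen = dr[i] + dr[j] - dist;
        if (pen <= 0 || dist < 1e-12) return;
        double wi = dw[i], wj = dw[j];
        double wsum = wi + wj;
        if (wsum <= 0) return;
        double nxv = ddx / dist, nyv = ddy / dist;
        dx_[i] -= nxv * pen * wi / wsum; dy_[i] -= nyv * pen * wi / wsum;
        dx_[j] += nxv * pen * wj / wsum; dy_[j] += nyv * pen * wj / wsum;
      });
    }

    // (4) rods vs disks; reaction moves the rod's anchor node
    for (int sId = 0; sId < ns; ++sId) {
      const int a = septa(sId, 0) - 1, b = septa(sId, 1) - 1;
      double axv = nx_[b] - nx_[a], ayv = ny_[b] - ny_[a];
      double dist = std::sqrt(axv * axv + ayv * ayv);
      if (dist < 1e-12) continue;
      axv /= dist; ayv /= dist;
      const double nxn = -ayv, nyn = axv; // lateral normal
      const double len = std::min(rod_len, dist);
      for (int side = 0; side < 2; ++side) {
        const int anchor = side == 0 ? a : b;
        const double sgn = side == 0 ? 1.0 : -1.0;
        const double px = nx_[anchor] + sgn * nxn * rod_off;
        const double py = ny_[anchor] + sgn * nyn * rod_off;
        const double qx = px + sgn * axv * len;
        const double qy = py + sgn * ayv * len;
        // walk hash bins along the rod
        const int nsamp = std::max(2, (int)std::ceil(len / cs) + 1);
        std::vector<int> seen;
        for (int t = 0; t < nsamp; ++t) {
          const double f = (double)t / (nsamp - 1);
          hash.neighbours(px + (qx - px) * f, py + (qy - py) * f, [&](int j) {
            for (size_t z = 0; z < seen.size(); ++z) if (seen[z] == j) return;
            seen.push_back(j);
            // closest point on segment pq to disk j
            double vx = qx - px, vy = qy - py;
            double L2 = vx * vx + vy * vy;
            double tt = L2 > 1e-18
              ? ((dx_[j] - px) * vx + (dy_[j] - py) * vy) / L2 : 0.0;
            tt = std::min(1.0, std::max(0.0, tt));
            double cxp = px + vx * tt, cyp = py + vy * tt;
            double ddx = dx_[j] - cxp, ddy = dy_[j] - cyp;
            double dd = std::sqrt(ddx * ddx + ddy * ddy);
            double pen = dr[j] + rod_halfw - dd;
            if (pen <= 0 || dd < 1e-12) return;
            double wn = pinned[anchor] ? 0.0 : 1.0, wd = dw[j];
            double wsum = wn + wd;
            if (wsum <= 0) return;
            double nxv = ddx / dd, nyv = ddy / dd;
            dx_[j] += nxv * pen * wd / wsum; dy_[j] += nyv * pen * wd / wsum;
            if (wn > 0) { nax[anchor] -= nxv * pen * wn / wsum;
                          nay[anchor] -= nyv * pen * wn / wsum;
                          ncnt[anchor]++; }
          });
        }
      }
    }
    for (int i = 0; i < nn; ++i) {
      if (ncnt[i] > 0) {
        nx_[i] += nax[i] / ncnt[i];
        ny_[i] += nay[i] / ncnt[i];
      }
    }
  }

  NumericMatrix on(nn, 2), od(nd, 2);
  for (int i = 0; i < nn; ++i) { on(i, 0) = nx_[i]; on(i, 1) = ny_[i]; }
  for (int i = 0; i < nd; ++i) { od(i, 0) = dx_[i]; od(i, 1) = dy_[i]; }
  return List::create(_["nodes"] = on, _["disks"] = od);
}

// ---------------------------------------------------------------------------
// Replication site search. Parents are processed in the supplied order; for
// each, candidate sites at distance d in n_angles directions (random base
// rotation from u) are tested for patch membership (inside some hexagon
// with `margin`) and for clearance against all colliding disks, including
// sites already accepted this sweep. First feasible site wins.
// Returns parallel vectors: parent row index, site coords, hexagon id.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_find_sites(NumericMatrix parents, IntegerVector order,
                    NumericMatrix coll_xy, NumericVector coll_r,
                    NumericMatrix centers, double s, double margin,
                    double d, double site_r, int n_angles, NumericVector u) {
  const int nc = coll_xy.nrow();
  std::vector<double> xs, ys, rs;
  xs.reserve(nc + order.size()); ys.reserve(nc + order.size());
  double rmax = site_r;
  for (int i = 0; i < nc; ++i) {
    xs.push_back(coll_xy(i, 0)); ys.push_back(coll_xy(i, 1));
    rs.push_back(coll_r[i]);
    if (coll_r[i] > rmax) rmax = coll_r[i];
  }
  double xmin, ymin, xmax, ymax;
  bbox_of(xs, ys, xmin, ymin, xmax, ymax);
  SpatialHash hash(xmin - d, ymin - d, xmax + d, ymax + d,
                   std::max(site_r + rmax, 1e-9));
  for (size_t i = 0; i < xs.size(); ++i) hash.insert((int)i, xs[i], ys[i]);

  std::vector<int> out_parent, out_hex;
  std::vector<double> out_x, out_y;
  size_t ui = 0;
  const size_t un = u.size() > 0 ? (size_t)u.size() : 1;

  for (int oi = 0; oi < order.size(); ++oi) {
    const int p = order[oi] - 1;
    const double base = 2.0 * M_PI * (u.size() > 0 ? u[ui++ % un] : 0.0);
    for (int k = 0; k < n_angles; ++k) {
      const double th = base + 2.0 * M_PI * k / n_angles;
      const double x = parents(p, 0) + d * std::cos(th);
      const double y = parents(p, 1) + d * std::sin(th);
      const int h = which_hex(x, y, centers, s, margin);
      if (h < 0) continue;
      bool ok = true;
      hash.neighbours(x, y, [&](int j) {
        if (!ok) return;
        const double ddx = xs[j] - x, ddy = ys[j] - y;
        const double need = site_r + rs[j];
        if (ddx * ddx + ddy * ddy < need * need * (1.0 - 1e-12)) ok = false;
      });
      if (ok) {
        out_parent.push_back(p + 1);
        out_x.push_back(x); out_y.push_back(y);
        out_hex.push_back(h + 1);
        xs.push_back(x); ys.push_back(y); rs.push_back(site_r);
        hash.insert((int)xs.size() - 1, x, y);
        break;
      }
    }
  }
  return List::create(_["parent"] = wrap(out_parent), _["x"] = wrap(out_x),
                      _["y"] = wrap(out_y), _["hex"] = wrap(out_hex));
}

// ---------------------------------------------------------------------------
// Phagocytosis matching: each Kupffer cell (processed in `order`) claims the
// nearest unclaimed dead agent within `radius`; each dead agent is claimed
// at most once. Returns, per Kupffer cell, the 1-based dead index or 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_match_phago(NumericMatrix kc, IntegerVector order,
                              NumericMatrix dead, double radius) {
  const int nk = kc.nrow(), ndd = dead.nrow();
  IntegerVector out(nk, 0);
  if (ndd == 0 || nk == 0) return out;
  std::vector<double> xs(ndd), ys(ndd);
  for (int i = 0; i < ndd; ++i) { xs[i] = dead(i, 0); ys[i] = dead(i, 1); }
  double xmin, ymin, xmax, ymax;
  bbox_of(xs, ys, xmin, ymin, xmax, ymax);
  SpatialHash hash(xmin, ymin, xmax, ymax, std::max(radius, 1e-9));
  for (int i = 0; i < ndd; ++i) hash.insert(i, xs[i], ys[i]);
  std::vector<bool> claimed(ndd, false);
  const double r2 = radius * radius;
  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi] - 1;
    int best = -1; double bd = R_PosInf;
    hash.neighbours(kc(i, 0), kc(i, 1), [&](int j) {
      if (claimed[j]) return;
      const double ddx = xs[j] - kc(i, 0), ddy = ys[j] - kc(i, 1);
      const double dd = ddx * ddx + ddy * ddy;
      if (dd <= r2 && dd < bd) { bd = dd; best = j; }
    });
    if (best >= 0) { claimed[best] = true; out[i] = best + 1; }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Collagen deposition site selection. Depositing myofibroblasts are
// processed in the supplied order. Anchors (triads, septum sample points,
// existing collagen) within `reach` of the cell offer one candidate site
// each: on the anchor surface along the anchor->cell direction. The valid
// candidate nearest to the cell wins; the new deposit immediately becomes a
// collider and an anchor for subsequent deposits in the same sweep.
// ---------------------------------------------------------------------------

// Colliders flagged "soft" (live/dead cells, which the tissue mechanics can
// push aside) may be penetrated by up to soft_budget; "hard" colliders
// (existing collagen, portal triads) must not be overlapped at all.
// [[Rcpp::export]]
List cpp_collagen_sites(NumericMatrix mf, IntegerVector order,
                        NumericMatrix anchor_xy, NumericVector anchor_r,
                        IntegerVector anchor_type, IntegerVector anchor_id,
                        NumericMatrix coll_xy, NumericVector coll_r,
                        LogicalVector coll_soft, double soft_budget,
                        NumericMatrix rods, double rod_clear,
                        NumericMatrix centers, double s, double margin,
                        double reach, double site_r, double tol) {
  std::vector<double> axs, ays, ars;
  std::vector<int> aty, aid;
  for (int i = 0; i < anchor_xy.nrow(); ++i) {
    axs.push_back(anchor_xy(i, 0)); ays.push_back(anchor_xy(i, 1));
    ars.push_back(anchor_r[i]); aty.push_back(anchor_type[i]);
    aid.push_back(anchor_id[i]);
  }
  std::vector<double> cxs, cys, crs;
  std::vector<bool> csoft;
  double rmax = site_r;
  for (int i = 0; i < coll_xy.nrow(); ++i) {
    cxs.push_back(coll_xy(i, 0)); cys.push_back(coll_xy(i, 1));
    crs.push_back(coll_r[i]);
    csoft.push_back(coll_soft[i]);
    if (coll_r[i] > rmax) rmax = coll_r[i];
  }
  double xmin, ymin, xmax, ymax;
  bbox_of(axs, ays, xmin, ymin, xmax, ymax);
  SpatialHash ahash(xmin - reach, ymin - reach, xmax + reach, ymax + reach,
                    std::max(reach, 1e-9));
  for (size_t i = 0; i < axs.size(); ++i) ahash.insert((int)i, axs[i], ays[i]);
  double cxmin, cymin, cxmax, cymax;
  bbox_of(cxs, cys, cxmin, cymin, cxmax, cymax);
  SpatialHash chash(std::min(cxmin, xmin) - 1, std::min(cymin, ymin) - 1,
                    std::max(cxmax, xmax) + 1, std::max(cymax, ymax) + 1,
                    std::max(2.0 * rmax, 1e-9));
  for (size_t i = 0; i < cxs.size(); ++i) chash.insert((int)i, cxs[i], cys[i]);

  std::vector<int> out_mf, out_ty, out_id;
  std::vector<double> out_x, out_y;
  const double reach2 = reach * reach;
  int n_new = 0;

  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi] - 1;
    const double mx = mf(i, 0), my = mf(i, 1);
    double bestd = R_PosInf, bx = 0, by = 0;
    int bty = 0, bid = 0;
    bool found = false;
    ahash.neighbours(mx, my, [&](int j) {
      const double vx = mx - axs[j], vy = my - ays[j];
      const double av2 = vx * vx + vy * vy;
      if (av2 > reach2 || av2 < 1e-18) return;
      const double av = std::sqrt(av2);
      const double x = axs[j] + vx / av * (ars[j] + site_r);
      const double y = ays[j] + vy / av * (ars[j] + site_r);
      if (which_hex(x, y, centers, s, margin) < 0) return;
      // keep clear of the septal boundary sub-segments (distance to the
      // rod segment, so rings around triad nodes remain admissible)
      for (int rr = 0; rr < rods.nrow(); ++rr) {
        const double px = rods(rr, 0), py = rods(rr, 1);
        const double qx2 = rods(rr, 2), qy2 = rods(rr, 3);
        const double vx2 = qx2 - px, vy2 = qy2 - py;
        const double L2 = vx2 * vx2 + vy2 * vy2;
        double tt = L2 > 1e-18 ? ((x - px) * vx2 + (y - py) * vy2) / L2 : 0.0;
        tt = std::min(1.0, std::max(0.0, tt));
        const double ddx = x - (px + vx2 * tt), ddy = y - (py + vy2 * tt);
        if (ddx * ddx + ddy * ddy < rod_clear * rod_clear) return;
      }
      bool ok = true;
      chash.neighbours(x, y, [&](int c) {
        if (!ok) return;
        const double ddx = cxs[c] - x, ddy = cys[c] - y;
        double need = site_r + crs[c] - tol;
        if (csoft[c]) need -= soft_budget;
        if (need > 0 && ddx * ddx + ddy * ddy < need * need) ok = false;
      });
      if (!ok) return;
      const double dcell = (x - mx) * (x - mx) + (y - my) * (y - my);
      if (dcell < bestd) {
        bestd = dcell; bx = x; by = y; bty = aty[j]; bid = aid[j];
        found = true;
      }
    });
    if (found) {
      out_mf.push_back(i + 1);
      out_x.push_back(bx); out_y.push_back(by);
      out_ty.push_back(bty); out_id.push_back(bid);
      ++n_new;
      cxs.push_back(bx); cys.push_back(by); crs.push_back(site_r);
      csoft.push_back(false);
      chash.insert((int)cxs.size() - 1, bx, by);
      axs.push_back(bx); ays.push_back(by); ars.push_back(site_r);
      aty.push_back(3); aid.push_back(-n_new); // new-deposit anchor (negative
                                               // marker: remapped by caller)
      ahash.insert((int)axs.size() - 1, bx, by);
    }
  }
  return List::create(_["mf"] = wrap(out_mf), _["x"] = wrap(out_x),
                      _["y"] = wrap(out_y), _["anchor_type"] = wrap(out_ty),
                      _["anchor_id"] = wrap(out_id));
}
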