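#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Piecewise-linear inversion of a gridded forward map
// (mua[i], musp[j]) -> (rd0[i,j], rd1[i,j]).
// Each grid cell is split into two triangles in (rd0, rd1) space and the
// parameter values are interpolated barycentrically; queries outside the
// forward gamut are clamped to the nearest point on the gamut boundary and
// flagged. Exact (to machine precision) at grid nodes.

struct Tri {
  double x1, y1, x2, y2, x3, y3;  // forward-space vertices
  double a1, b1, a2, b2, a3, b3;  // parameter values at the vertices
};

static inline bool bary(const Tri &t, double px, double py, double &l1,
                        double &l2, double &l3) {
  const double d =
      (t.y2 - t.y3) * (t.x1 - t.x3) + (t.x3 - t.x2) * (t.y1 - t.y3);
  if (std::fabs(d) < 1e-300) return false;
  l1 = ((t.y2 - t.y3) * (px - t.x3) + (t.x3 - t.x2) * (py - t.y3)) / d;
  l2 = ((t.y3 - t.y1) * (px - t.x3) + (t.x1 - t.x3) * (py - t.y3)) / d;
  l3 = 1.0 - l1 - l2;
  const double eps = -1e-9;
  return l1 >= eps && l2 >= eps && l3 >= eps;
}

// [[Rcpp::export]]
List cpp_invert_table(NumericMatrix rd0, NumericMatrix rd1, NumericVector ax,
                      NumericVector ay, NumericVector q0, NumericVector q1) {
  const int nx = ax.size(), ny = ay.size(), nq = q0.size();
  const int ncell = (nx - 1) * (ny - 1);
  std::vector<Tri> tris(2 * ncell);
  std::vector<double> bx0(2 * ncell), bx1(2 * ncell), by0(2 * ncell),
      by1(2 * ncell);

  int c = 0;
  for (int j = 0; j + 1 < ny; ++j) {
    for (int i = 0; i + 1 < nx; ++i) {
      // corners A=(i,j) B=(i+1,j) C=(i+1,j+1) D=(i,j+1)
      const double Ax = rd0(i, j), Ay = rd1(i, j);
      const double Bx = rd0(i + 1, j), By = rd1(i + 1, j);
      const double Cx = rd0(i + 1, j + 1), Cy = rd1(i + 1, j + 1);
      const double Dx = rd0(i, j + 1), Dy = rd1(i, j + 1);
      Tri t1 = {Ax, Ay, Bx, By, Cx, Cy,
                ax[i], ay[j], ax[i + 1], ay[j], ax[i + 1], ay[j + 1]};
      Tri t2 = {Ax, Ay, Cx, Cy, Dx, Dy,
                ax[i], ay[j], ax[i + 1], ay[j + 1], ax[i], ay[j + 1]};
      for (int k = 0; k < 2; ++k) {
        const Tri &t = (k == 0) ? t1 : t2;
        tris[c] = t;
        bx0[c] = std::min(t.x1, std::min(t.x2, t.x3));
        bx1[c] = std::max(t.x1, std::max(t.x2, t.x3));
        by0[c] = std::min(t.y1, std::min(t.y2, t.y3));
        by1[c] = std::max(t.y1, std::max(t.y2, t.y3));
        ++c;
      }
    }
  }

  // boundary chain of the grid (gamut hull approximation for clamping)
  std::vector<int> bi, bj;
  for (int i = 0; i < nx; ++i) { bi.push_back(i); bj.push_back(0); }
  for (int j = 1; j < ny; ++j) { bi.push_back(nx - 1); bj.push_back(j); }
  for (int i = nx - 2; i >= 0; --i) { bi.push_back(i); bj.push_back(ny - 1); }
  for (int j = ny - 2; j >= 1; --j) { bi.push_back(0); bj.push_back(j); }
  const int nb = static_cast<int>(bi.size());

  // uniform bin index over the forward gamut for O(1) point location
  const int NB = 64;
  double gx0 = R_PosInf, gx1 = R_NegInf, gy0 = R_PosInf, gy1 = R_NegInf;
  for (int t = 0; t < 2 * ncell; ++t) {
    gx0 = std::min(gx0, bx0[t]); gx1 = std::max(gx1, bx1[t]);
    gy0 = std::min(gy0, by0[t]); gy1 = std::max(gy1, by1[t]);
  }
  const double sx = (gx1 > gx0) ? NB / (gx1 - gx0) : 0.0;
  const double sy = (gy1 > gy0) ? NB / (gy1 - gy0) : 0.0;
  std::vector<std::vector<int> > bins(NB * NB);
  for (int t = 0; t < 2 * ncell; ++t) {
    int ix0 = std::max(0, std::min(NB - 1, (int)((bx0[t] - gx0) * sx)));
    int ix1 = std::max(0, std::min(NB - 1, (int)((bx1[t] - gx0) * sx)));
    int iy0 = std::max(0, std::min(NB - 1, (int)((by0[t] - gy0) * sy)));
    int iy1 = std::max(0, std::min(NB - 1, (int)((by1[t] - gy0) * sy)));
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        bins[ix * NB + iy].push_back(t);
  }

  NumericVector out_a(nq), out_b(nq);
  LogicalVector oob(nq);

  for (int q = 0; q < nq; ++q) {
    const double px = q0[q], py = q1[q];
    if (!R_finite(px) || !R_finite(py)) {
      out_a[q] = NA_REAL;
      out_b[q] = NA_REAL;
      oob[q] = true;
      continue;
    }
    bool hit = false;
    double l1, l2, l3;
    std::vector<int> empty;
    const bool inBox = px >= gx0 && px <= gx1 && py >= gy0 && py <= gy1;
    const std::vector<int> &cand = inBox
      ? bins[std::max(0, std::min(NB - 1, (int)((px - gx0) * sx))) * NB +
             std::max(0, std::min(NB - 1, (int)((py - gy0) * sy)))]
      : empty;
    for (size_t c = 0; c < cand.size(); ++c) {
      const int t = cand[c];
      if (px < bx0[t] || px > bx1[t] || py < by0[t] || py > by1[t]) continue;
      if (bary(tris[t], px, py, l1, l2, l3)) {
        out_a[q] = l1 * tris[t].a1 + l2 * tris[t].a2 + l3 * tris[t].a3;
        out_b[q] = l1 * tris[t].b1 + l2 * tris[t].b2 + l3 * tris[t].b3;
        oob[q] = false;
        hit = true;
        break;
      }
    }
    if (!hit) {
      // Distinguish a genuinely out-of-gamut query from one that fell into
      // a fold gap of the noisy triangulated surface: test against the
      // boundary polygon of the grid image (ray casting). Interior gap
      // queries are resolved by nearest-edge interpolation and NOT flagged.
      bool inside = false;
      for (int e = 0; e < nb; ++e) {
        const int i1 = bi[e], j1 = bj[e];
        const int i2 = bi[(e + 1) % nb], j2 = bj[(e + 1) % nb];
        const double x1 = rd0(i1, j1), y1 = rd1(i1, j1);
        const double x2 = rd0(i2, j2), y2 = rd1(i2, j2);
        if ((y1 > py) != (y2 > py)) {
          const double xint = x1 + (py - y1) / (y2 - y1) * (x2 - x1);
          if (px < xint) inside = !inside;
        }
      }
      double best = R_PosInf, besta = NA_REAL, bestb = NA_REAL;
      if (inside) {
        // nearest point on any triangle edge near the query
        for (int t = 0; t < 2 * ncell; ++t) {
          if (px < bx0[t] - 0.02 || px > bx1[t] + 0.02 ||
              py < by0[t] - 0.02 || py > by1[t] + 0.02)
            continue;
          const double vx[3] = {tris[t].x1, tris[t].x2, tris[t].x3};
          const double vy[3] = {tris[t].y1, tris[t].y2, tris[t].y3};
          const double va[3] = {tris[t].a1, tris[t].a2, tris[t].a3};
          const double vb[3] = {tris[t].b1, tris[t].b2, tris[t].b3};
          for (int e = 0; e < 3; ++e) {
            const int f = (e + 1) % 3;
            const double dx = vx[f] - vx[e], dy = vy[f] - vy[e];
            const double len2 = dx * dx + dy * dy;
            double tt =
                len2 > 0 ? ((px - vx[e]) * dx + (py - vy[e]) * dy) / len2
                         : 0.0;
            if (tt < 0.0) tt = 0.0;
            if (tt > 1.0) tt = 1.0;
            const double cx = vx[e] + tt * dx, cy = vy[e] + tt * dy;
            const double d2 =
                (px - cx) * (px - cx) + (py - cy) * (py - cy);
            if (d2 < best) {
              best = d2;
              besta = va[e] + tt * (va[f] - va[e]);
              bestb = vb[e] + tt * (vb[f] - vb[e]);
            }
          }
        }
      }
      if (inside && R_finite(besta)) {
        out_a[q] = besta;
        out_b[q] = bestb;
        oob[q] = false;
      } else {
        // clamp to nearest point on the boundary chain
        for (int e = 0; e < nb; ++e) {
          const int i1 = bi[e], j1 = bj[e];
          const int i2 = bi[(e + 1) % nb], j2 = bj[(e + 1) % nb];
          const double x1 = rd0(i1, j1), y1 = rd1(i1, j1);
          const double x2 = rd0(i2, j2), y2 = rd1(i2, j2);
          const double dx = x2 - x1, dy = y2 - y1;
          const double len2 = dx * dx + dy * dy;
          double tt =
              len2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / len2 : 0.0;
          if (tt < 0.0) tt = 0.0;
          if (tt > 1.0) tt = 1.0;
          const double cx = x1 + tt * dx, cy = y1 + tt * dy;
          const double d2 =
              (px - cx) * (px - cx) + (py - cy) * (py - cy);
          if (d2 < best) {
            best = d2;
            besta = ax[i1] + tt * (ax[i2] - ax[i1]);
            bestb = ay[j1] + tt * (ay[j2] - ay[j1]);
          }
        }
        out_a[q] = besta;
        out_b[q] = bestb;
        oob[q] = true;
      }
    }
  }

  return List::create(_["mua"] = out_a, _["musp"] = out_b, _["oob"] = oob);
}
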