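// Canopy light interception kernels.
//
// Projection mode: for each dome direction the scene's facet sample points
// are projected onto a plane perpendicular to the beam and binned into a 2D
// grid. Within each grid cell, points are walked in depth order; each run of
// points belonging to one leaf covers a fraction of the cell and intercepts
// that fraction of the remaining beam power; the beam is attenuated by
// (1 - cover * (1 - transmittance)) per layer (first-order scattering only:
// reflected flux is counted as lost). The periodic field is emulated by
// replicating occluders on a 3x3 tiling of the scene tile; interception is
// credited from the central replica only.
//
// Monte Carlo mode: reverse path tracing against explicit parallelogram
// facets; rays are spawned from the dome sources in proportion to source
// flux, transmitted rays continue straight through (refraction treated as
// transmittance), reflected flux terminates as lost.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <random>
using namespace Rcpp;

// [[Rcpp::export]]
List trace_projection_cpp(NumericMatrix pts,        // n x 3 sample points
                          IntegerVector leaf_of_pt, // 0-based leaf index
                          NumericVector wt_pt,      // facet area share per point (m2)
                          NumericMatrix nrm_pt,     // n x 3 facet normal per point
                          NumericMatrix dirs,       // m x 3 unit vectors toward source
                          NumericVector flux,       // horizontal irradiance per source
                          int n_leaf,
                          double absorptance, double reflectance, double transmittance,
                          double cell, double lx, double ly, bool tile) {
  const int n = pts.nrow();
  const int m = dirs.nrow();
  NumericVector leaf_abs(n_leaf); // absorbed power (W) per leaf
  double tot_abs = 0.0, tot_ref = 0.0;

  const int t0 = tile ? -1 : 0, t1 = tile ? 1 : 0;
  const int n_tiles = (t1 - t0 + 1) * (t1 - t0 + 1);
  const double cell2 = cell * cell;

  std::vector<double> px(n), py(n), pd(n), pw(n);
  const size_t cap = (size_t)n * n_tiles;
  std::vector<int> cellidx(cap), ekey(cap), order(cap);
  std::vector<double> edepth(cap), ew(cap);
  std::vector<char> erec(cap);
  std::vector<int> cnt;

  for (int s = 0; s < m; ++s) {
    double ux = dirs(s, 0), uy = dirs(s, 1), uz = dirs(s, 2);
    double f = flux[s];
    if (f <= 0.0 || uz <= 1e-9) continue;
    double fb = f / uz; // beam flux density perpendicular to the ray
    // basis perpendicular to u
    double e1x, e1y, e1z;
    if (std::abs(uz) < 0.999) { // e1 = u x z normalized
      double nx = uy, ny = -ux, nz = 0.0;
      double nn = std::sqrt(nx * nx + ny * ny);
      e1x = nx / nn; e1y = ny / nn; e1z = nz;
    } else {
      e1x = 1.0; e1y = 0.0; e1z = 0.0;
    }
    double e2x = uy * e1z - uz * e1y;
    double e2y = uz * e1x - ux * e1z;
    double e2z = ux * e1y - uy * e1x;

    // central-tile projections and grid bounds
    double minx = 1e300, maxx = -1e300, miny = 1e300, maxy = -1e300;
    for (int i = 0; i < n; ++i) {
      double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
      double a = x * e1x + y * e1y + z * e1z;
      double b = x * e2x + y * e2y + z * e2z;
      px[i] = a; py[i] = b;
      pd[i] = -(x * ux + y * uy + z * uz); // larger = farther from the sun
      double ct = std::abs(nrm_pt(i, 0) * ux + nrm_pt(i, 1) * uy + nrm_pt(i, 2) * uz);
      pw[i] = wt_pt[i] * ct;
      if (a < minx) minx = a; if (a > maxx) maxx = a;
      if (b < miny) miny = b; if (b > maxy) maxy = b;
    }
    int nx_c = std::max(1, (int)std::ceil((maxx - minx) / cell) + 1);
    int ny_c = std::max(1, (int)std::ceil((maxy - miny) / cell) + 1);
    long ncell = (long)nx_c * ny_c;

    // entries: cell, depth, key (leaf + tile * n_leaf), weight, receiver flag
    size_t ne = 0;
    int tl = 0;
    for (int tx = t0; tx <= t1; ++tx) {
      for (int ty = t0; ty <= t1; ++ty, ++tl) {
        bool central = (tx == 0 && ty == 0);
        // projected offset of the tile shift (z component is 0)
        double oa = tx * lx * e1x + ty * ly * e1y;
        double ob = tx * lx * e2x + ty * ly * e2y;
        double od = -(tx * lx * ux + ty * ly * uy);
        // skip tiles whose shifted point cloud cannot reach the grid
        if (maxx + oa < minx || minx + oa >= minx + nx_c * cell ||
            maxy + ob < miny || miny + ob >= miny + ny_c * cell)
          continue;
        for (int i = 0; i < n; ++i) {
          double a = px[i] + oa, b = py[i] + ob;
          if (a < minx || a >= minx + nx_c * cell || b < miny || b >= miny + ny_c * cell)
            continue;
          int cx = (int)((a - minx) / cell);
          int cy = (int)((b - miny) / cell);
          cellidx[ne] = cx + nx_c * cy;
          edepth[ne] = pd[i] + od;
          ew[ne] = pw[i];
          ekey[ne] = leaf_of_pt[i] + tl * n_leaf;
          erec[ne] = central ? 1 : 0;
          ++ne;
        }
      }
    }

    // counting sort by cell
    cnt.assign(ncell + 1, 0);
    for (size_t i = 0; i < ne; ++i) cnt[cellidx[i] + 1]++;
    for (long c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
    {
      std::vector<int> pos(cnt.begin(), cnt.end() - 1);
      for (size_t i = 0; i < ne; ++i) order[pos[cellidx[i]]++] = (int)i;
    }

    // per-cell depth ordering (insertion sort: runs are short) and
    // layered attenuation
    for (long c = 0; c < ncell; ++c) {
      int lo = cnt[c], hi = cnt[c + 1];
      if (lo >= hi) continue;
      for (int a = lo + 1; a < hi; ++a) {
        int v = order[a];
        double dv = edepth[v];
        int b = a - 1;
        while (b >= lo && edepth[order[b]] > dv) { order[b + 1] = order[b]; --b; }
        order[b + 1] = v;
      }
      double trans = 1.0;
      int i = lo;
      while (i < hi && trans > 1e-12) {
        int key = ekey[order[i]];
        double wsum = 0.0;
        bool rec = erec[order[i]];
        int j = i;
        while (j < hi && ekey[order[j]] == key) { wsum += ew[order[j]]; ++j; }
        double q = wsum / cell2;
        if (q > 1.0) q = 1.0;
        double pint = fb * cell2 * q * trans;
        if (rec) {
          int leaf = key % n_leaf;
          leaf_abs[leaf] += absorptance * pint;
          tot_abs += absorptance * pint;
          tot_ref += reflectance * pint;
        }
        trans *= (1.0 - q * (1.0 - transmittance));
        i = j;
      }
    }
  }
  return List::create(_["leaf_absorbed_w"] = leaf_abs,
                      _["absorbed_w"] = tot_abs,
                      _["reflected_w"] = tot_ref);
}

struct Hit { double s; int facet; };

// [[Rcpp::export]]
List trace_montecarlo_cpp(NumericMatrix f0,  // nf x 3 facet origin corner
                          NumericMatrix fe,  // nf x 3 edge along length
                          NumericMatrix fw,  // nf x 3 edge along width
                          IntegerVector leaf_of_facet, // 0-based
                          NumericMatrix dirs, NumericVector flux,
                          int n_leaf,
                          double absorptance, double reflectance, double transmittance,
                          int n_rays, int max_bounces,
                          double x0, double y0, double x1, double y1, double ztop,
                          double lx, double ly, bool tile, int seed) {
  const int nf = f0.nrow();
  const int m = dirs.nrow();
  NumericVector leaf_abs(n_leaf);
  double tot_abs = 0.0, tot_ref = 0.0;
  double area = (x1 - x0) * (y1 - y0);
  double total_flux = 0.0;
  for (int s = 0; s < m; ++s) if (dirs(s, 2) > 1e-9) total_flux += flux[s];
  if (total_flux <= 0.0 || n_rays < 1)
    return List::create(_["leaf_absorbed_w"] = leaf_abs,
                        _["absorbed_w"] = 0.0, _["reflected_w"] = 0.0,
                        _["incident_w"] = 0.0);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // precompute facet normals and inverse-matrix style solve terms
  const int t0i = tile ? -1 : 0, t1i = tile ? 1 : 0;

  for (int s = 0; s < m; ++s) {
    double uz = dirs(s, 2);
    if (uz <= 1e-9 || flux[s] <= 0.0) continue;
    int nr = std::max(1, (int)std::llround((double)n_rays * flux[s] / total_flux));
    double dx = -dirs(s, 0), dy = -dirs(s, 1), dz = -uz; // propagation direction
    // expand the spawn rectangle so oblique rays can still enter the scene
    double tg = ztop / uz;
    double ex0 = x0 - std::max(0.0, dx * tg);
    double ex1 = x1 - std::min(0.0, dx * tg);
    double ey0 = y0 - std::max(0.0, dy * tg);
    double ey1 = y1 - std::min(0.0, dy * tg);
    double rect_area = (ex1 - ex0) * (ey1 - ey0);
    double pray = flux[s] * rect_area / nr; // horizontal irradiance basis
    for (int r = 0; r < nr; ++r) {
      // spawn above the scene over the (expanded) plot rectangle
      double ox = ex0 + unif(rng) * (ex1 - ex0);
      double oy = ey0 + unif(rng) * (ey1 - ey0);
      double oz = ztop;
      double p = pray;
      double smin_prev = 0.0;
      for (int b = 0; b <= max_bounces && p > 1e-12 * pray; ++b) {
        // nearest intersection over facets and tile replicas
        double smin = 1e300; int fhit = -1;
        for (int tx = t0i; tx <= t1i; ++tx) {
          for (int ty = t0i; ty <= t1i; ++ty) {
            double sx = ox - tx * lx, sy = oy - ty * ly;
            for (int fi = 0; fi < nf; ++fi) {
              // solve s*d = f0 + a*e + b*w - o
              double ax = fe(fi, 0), ay = fe(fi, 1), az = fe(fi, 2);
              double bx = fw(fi, 0), by = fw(fi, 1), bz = fw(fi, 2);
              // normal
              double nx = ay * bz - az * by;
              double ny = az * bx - ax * bz;
              double nz = ax * by - ay * bx;
              double denom = dx * nx + dy * ny + dz * nz;
              if (std::abs(denom) < 1e-14) continue;
              double rx = f0(fi, 0) - sx, ry = f0(fi, 1) - sy, rz = f0(fi, 2) - oz;
              double sdist = (rx * nx + ry * ny + rz * nz) / denom;
              if (sdist <= smin_prev + 1e-9 || sdist >= smin) continue;
              // barycentric-style coordinates on the parallelogram
              double hx = sx + sdist * dx - f0(fi, 0);
              double hy = sy + sdist * dy - f0(fi, 1);
              double hz = oz + sdist * dz - f0(fi, 2);
              // project onto edges (edges need not be orthogonal)
              double ee = ax * ax + ay * ay + az * az;
              double ww = bx * bx + by * by + bz * bz;
              double ewd = ax * bx + ay * by + az * bz;
              double he = hx * ax + hy * ay + hz * az;
              double hw = hx * bx + hy * by + hz * bz;
              double det = ee * ww - ewd * ewd;
              if (det <= 0) continue;
              double aa = (he * ww - hw * ewd) / det;
              double bb = (hw * ee - he * ewd) / det;
              if (aa < 0 || aa > 1 || bb < 0 || bb > 1) continue;
              smin = sdist; fhit = fi;
            }
          }
        }
        if (fhit < 0) break; // escapes to the ground or sky
        leaf_abs[leaf_of_facet[fhit]] += absorptance * p;
        tot_abs += absorptance * p;
        tot_ref += reflectance * p;
        p *= transmittance; // continue straight through the leaf
        smin_prev = smin;
      }
    }
  }
  return List::create(_["leaf_absorbed_w"] = leaf_abs,
                      _["absorbed_w"] = tot_abs,
                      _["reflected_w"] = tot_ref,
                      _["incident_w"] = total_flux * area);
}
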