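// Voxel-volume measurement support: iso-surface area by marching tetrahedra
// (6-tetrahedra Kuhn decomposition of each voxel cube), sub-pixel iso-contours
// of 2D masks by marching squares, separable Gaussian smoothing, and 2D
// connected-component labeling.  Arrays are column-major (R layout).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <map>
#include <queue>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dims, NumericVector spacing,
                   double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, bit order (x, y, z)
  const int cx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // 6 tetrahedra around the main diagonal v0-v7
  const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                          {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;
  double px[8], py[8], pz[8], fv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          fv[c] = field[idx3(i + cx[c], j + cy[c], k + cz[c], nx, ny)];
          px[c] = (i + cx[c]) * sx;
          py[c] = (j + cy[c]) * sy;
          pz[c] = (k + cz[c]) * sz;
          if (fv[c] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0, nout = 0, iin[4], iout[4];
          for (int c = 0; c < 4; ++c) {
            in[c] = fv[T[c]] > iso;
            if (in[c]) iin[nin++] = T[c]; else iout[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int a, int b, double* p) {
            double t0 = (iso - fv[a]) / (fv[b] - fv[a]);
            p[0] = px[a] + t0 * (px[b] - px[a]);
            p[1] = py[a] + t0 * (py[b] - py[a]);
            p[2] = pz[a] + t0 * (pz[b] - pz[a]);
          };
          auto tri_area = [](const double* a, const double* b, const double* c2) {
            double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
            double w[3] = {c2[0] - a[0], c2[1] - a[1], c2[2] - a[2]};
            double cr[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                            u[0] * w[1] - u[1] * w[0]};
            return 0.5 * std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
          };
          double p0[3], p1[3], p2[3], p3[3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? iin[0] : iout[0];
            const int* oth = (nin == 1) ? iout : iin;
            interp(apex, oth[0], p0);
            interp(apex, oth[1], p1);
            interp(apex, oth[2], p2);
            area += tri_area(p0, p1, p2);
          } else {  // 2 in, 2 out -> quad
            interp(iin[0], iout[0], p0);
            interp(iin[0], iout[1], p1);
            interp(iin[1], iout[1], p2);
            interp(iin[1], iout[0], p3);
            area += tri_area(p0, p1, p2);
            area += tri_area(p0, p2, p3);
          }
        }
      }
  return area;
}

// separable Gaussian filter (zero extension), sigma in voxel units per axis
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector field, IntegerVector dims,
                               NumericVector sigma) {
  const int nd = dims.size();
  std::vector<int> n(dims.begin(), dims.end());
  int total = 1;
  for (int d = 0; d < nd; ++d) total *= n[d];
  std::vector<double> a(field.begin(), field.end()), b(total);

  for (int d = 0; d < nd; ++d) {
    double sg = sigma[d];
    if (sg <= 0) continue;
    int rad = (int)std::ceil(3.0 * sg);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (sg * sg));
      sum += ker[t + rad];
    }
    for (double& kv : ker) kv /= sum;
    // stride for axis d
    int stride = 1;
    for (int e = 0; e < d; ++e) stride *= n[e];
    int len = n[d];
    int nlines = total / len;
    for (int line = 0; line < nlines; ++line) {
      // base index of this line: decompose line index over the other axes
      int rem = line, base = 0, mul = 1;
      for (int e = 0; e < nd; ++e) {
        if (e == d) { mul *= n[e]; continue; }
        int sz = n[e];
        int coord = rem % sz;
        rem /= sz;
        base += coord * mul;
        mul *= n[e];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int u = -rad; u <= rad; ++u) {
          int tu = t + u;
          if (tu < 0 || tu >= len) continue;
          acc += ker[u + rad] * a[base + tu * stride];
        }
        b[base + t * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// 4-connected components of a 2D logical mask; returns integer label matrix
// [[Rcpp::export]]
IntegerMatrix cpp_components2d(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      std::queue<std::pair<int, int>> q;
      q.push({i, j});
      lab(i, j) = next;
      while (!q.empty()) {
        auto [ci, cj] = q.front();
        q.pop();
        const int di[4] = {1, -1, 0, 0};
        const int dj[4] = {0, 0, 1, -1};
        for (int t = 0; t < 4; ++t) {
          int ni = ci + di[t], nj = cj + dj[t];
          if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push({ni, nj});
          }
        }
      }
    }
  return lab;
}

// Marching-squares iso-contours of a 2D field; returns a list of closed
// polygons (n x 2, in pixel coordinates, 0-based, x = row index).  Segment
// endpoints lie on pixel-grid edges with linear interpolation; loops are
// chained by shared edge identity.
// [[Rcpp::export]]
List cpp_ms_contours(NumericMatrix field, double iso) {
  const int nx = field.nrow(), ny = field.ncol();
  // edge id: horizontal edge between (i,j)-(i+1,j): id = 2*(i + nx*j)
  //          vertical  edge between (i,j)-(i,j+1): id = 2*(i + nx*j) + 1
  auto hedge = [&](int i, int j) { return 2 * (i + nx * j); };
  auto vedge = [&](int i, int j) { return 2 * (i + nx * j) + 1; };
  std::map<long long, std::vector<long long>> adj;  // edge id -> connected edge ids
  auto link = [&](long long a, long long b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
      double f00 = field(i, j), f10 = field(i + 1, j), f01 = field(i, j + 1),
             f11 = field(i + 1, j + 1);
      int c = (f00 > iso) | ((f10 > iso) << 1) | ((f11 > iso) << 2) |
              ((f01 > iso) << 3);
      if (c == 0 || c == 15) continue;
      long long eB = hedge(i, j);       // bottom: (i,j)-(i+1,j)
      long long eT = hedge(i, j + 1);   // top
      long long eL = vedge(i, j);       // left: (i,j)-(i,j+1)
      long long eR = vedge(i + 1, j);   // right
      switch (c) {
        case 1: case 14: link(eB, eL); break;
        case 2: case 13: link(eB, eR); break;
        case 4: case 11: link(eT, eR); break;
        case 8: case 7:  link(eT, eL); break;
        case 3: case 12: link(eL, eR); break;
        case 6: case 9:  link(eB, eT); break;
        case 5: case 10: {
          double center = 0.25 * (f00 + f10 + f01 + f11);
          bool cin = center > iso;
          if ((c == 5) == cin) { link(eB, eR); link(eT, eL); }
          else { link(eB, eL); link(eT, eR); }
          break;
        }
      }
    }
  // positions of crossing points on edges
  auto edge_pos = [&](long long id, double& xo, double& yo) {
    int v = id & 1;
    long long cellid = id >> 1;
    int i = (int)(cellid % nx), j = (int)(cellid / nx);
    if (!v) {
      double fa = field(i, j), fb = field(i + 1, j);
      double t = (iso - fa) / (fb - fa);
      xo = i + t;
      yo = j;
    } else {
      double fa = field(i, j), fb = field(i, j + 1);
      double t = (iso - fa) / (fb - fa);
      xo = i;
      yo = j + t;
    }
  };
  std::map<long long, bool> used;
  std::vector<NumericMatrix> loops;
  for (auto& kv : adj) {
    if (used[kv.first]) continue;
    if (kv.second.size() != 2) { used[kv.first] = true; continue; }
    // walk the loop
    std::vector<long long> path;
    long long start = kv.first, cur = start, prev = -1;
    bool closed = false;
    while (true) {
      path.push_back(cur);
      used[cur] = true;
      auto& nb = adj[cur];
      if (nb.size() != 2) break;
      long long nxt = (nb[0] == prev) ? nb[1] : nb[0];
      prev = cur;
      cur = nxt;
      if (cur == start) { closed = true; break; }
      if (used[cur]) break;
    }
    if (!closed || path.size() < 3) continue;
    NumericMatrix pm(path.size(), 2);
    for (size_t k = 0; k < path.size(); ++k) {
      double xo, yo;
      edge_pos(path[k], xo, yo);
      pm(k, 0) = xo;
      pm(k, 1) = yo;
    }
    loops.push_back(pm);
  }
  List out(loops.size());
  for (size_t k = 0; k < loops.size(); ++k) out[k] = loops[k];
  return out;
}

// Label voxels of a periodic box by nearest cell center (minimum-image metric)
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix centers, NumericVector box,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = centers.nrow();
  const double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  IntegerVector lab(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * hx, y = (j + 0.5) * hy, z = (k + 0.5) * hz;
        double best = 1e300;
        int bi = 0;
        for (int c = 0; c < N; ++c) {
          double dx = std::fabs(x - centers(c, 0));
          if (dx > 0.5 * box[0]) dx = box[0] - dx;
          double dy = std::fabs(y - centers(c, 1));
          if (dy > 0.5 * box[1]) dy = box[1] - dy;
          double dz = std::fabs(z - centers(c, 2));
          if (dz > 0.5 * box[2]) dz = box[2] - dz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) { best = d2; bi = c; }
        }
        lab[i + nx * (j + ny * (size_t)k)] = bi + 1;
      }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), grid step s
static void edt1d(const std::vector<double>& f, std::vector<double>& d, double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double sq = q * s;
    while (true) {
      double sv = v[k] * s;
      double inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
      if (inter <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = inter;
      z[k + 1] = 1e300;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = q * s;
    while (z[k + 1] < sq) ++k;
    double sv = v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// squared Euclidean distance (physical units) from each foreground voxel to
// the nearest background voxel center; background gets 0
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nd = dims.size();
  std::vector<int> n(dims.begin(), dims.end());
  int total = 1;
  for (int d = 0; d < nd; ++d) total *= n[d];
  std::vector<double> a(total);
  for (int i = 0; i < total; ++i) a[i] = mask[i] ? 1e300 : 0.0;
  for (int d = 0; d < nd; ++d) {
    int stride = 1;
    for (int e = 0; e < d; ++e) stride *= n[e];
    int len = n[d];
    int nlines = total / len;
    std::vector<double> line(len), out(len);
    for (int li = 0; li < nlines; ++li) {
      int rem = li, base = 0, mul = 1;
      for (int e = 0; e < nd; ++e) {
        if (e == d) { mul *= n[e]; continue; }
        int coord = rem % n[e];
        rem /= n[e];
        base += coord * mul;
        mul *= n[e];
      }
      for (int t = 0; t < len; ++t) line[t] = a[base + t * stride];
      edt1d(line, out, spacing[d]);
      for (int t = 0; t < len; ++t) a[base + t * stride] = out[t];
    }
  }
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = dims;
  return res;
}
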