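// Periodic Voronoi tessellation of cell centers, convex-polyhedron clipping,
// 3D shape measurement, the quadratic surface/volume energy and its analytic
// gradient, plane slicing into 2D polygons, and the largest inscribed sphere.
//
// Geometry conventions: the box is [0, Lx) x [0, Ly) x [0, Lz), periodic in
// all three axes.  Each Voronoi cell is built around its (wrapped) center by
// incremental half-space clipping against the perpendicular bisectors of the
// 27 periodic images of all other centers, processed in order of increasing
// distance with the standard closure bound (a generator at distance d can cut
// the cell only if d/2 < max vertex distance).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <map>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// Convex polyhedron as vertices + oriented faces (outward), with the
// generating neighbor of each face (cell index, image position).
struct Poly {
  std::vector<Vec3> verts;
  std::vector<std::vector<int>> faces;
  std::vector<int> face_cell;     // 0-based neighbor cell index, -1 for the seed cube
  std::vector<Vec3> face_gen;     // generator image position of that face
};

static const double CLIP_EPS = 1e-10;

// Clip poly by half-space n.x <= d (n unit); returns false if nothing was cut.
static bool clip_poly(Poly& P, const Vec3& n, double d, int gen_cell,
                      const Vec3& gen_pos, double eps_scale) {
  const int nv = (int)P.verts.size();
  std::vector<double> s(nv);
  std::vector<int> side(nv);
  const double eps = CLIP_EPS * eps_scale;
  bool any_out = false, any_in = false;
  for (int i = 0; i < nv; ++i) {
    s[i] = dot(n, P.verts[i]) - d;
    side[i] = (s[i] > eps) ? 1 : ((s[i] < -eps) ? -1 : 0);
    if (side[i] > 0) any_out = true;
    if (side[i] < 0) any_in = true;
  }
  if (!any_out) return false;
  if (!any_in) stop("degenerate geometry: clipping plane removes entire cell");

  std::vector<int> remap(nv, -1);
  Poly Q;
  Q.verts.reserve(nv + 8);
  for (int i = 0; i < nv; ++i) {
    if (side[i] <= 0) {
      remap[i] = (int)Q.verts.size();
      Q.verts.push_back(P.verts[i]);
    }
  }
  // crossing vertex cache keyed by undirected old-vertex edge
  std::map<std::pair<int, int>, int> xing;
  auto cross_vertex = [&](int a, int b) -> int {
    std::pair<int, int> key = (a < b) ? std::make_pair(a, b) : std::make_pair(b, a);
    auto it = xing.find(key);
    if (it != xing.end()) return it->second;
    double t = s[a] / (s[a] - s[b]);
    Vec3 v = P.verts[a] + (P.verts[b] - P.verts[a]) * t;
    int idx = (int)Q.verts.size();
    Q.verts.push_back(v);
    xing[key] = idx;
    return idx;
  };

  std::vector<int> cap;  // vertices lying on the new plane
  auto cap_add = [&](int qidx) {
    if (std::find(cap.begin(), cap.end(), qidx) == cap.end()) cap.push_back(qidx);
  };

  for (size_t f = 0; f < P.faces.size(); ++f) {
    const std::vector<int>& ring = P.faces[f];
    std::vector<int> nr;
    const int m = (int)ring.size();
    for (int k = 0; k < m; ++k) {
      int u = ring[k], w = ring[(k + 1) % m];
      if (side[u] <= 0) {
        nr.push_back(remap[u]);
        if (side[u] == 0) cap_add(remap[u]);
      }
      if ((side[u] < 0 && side[w] > 0) || (side[u] > 0 && side[w] < 0)) {
        int xv = cross_vertex(u, w);
        nr.push_back(xv);
        cap_add(xv);
      }
    }
    // drop consecutive duplicates
    std::vector<int> clean;
    for (int v : nr)
      if (clean.empty() || clean.back() != v) clean.push_back(v);
    if (clean.size() > 1 && clean.front() == clean.back()) clean.pop_back();
    if (clean.size() >= 3) {
      Q.faces.push_back(clean);
      Q.face_cell.push_back(P.face_cell[f]);
      Q.face_gen.push_back(P.face_gen[f]);
    }
  }

  if (cap.size() >= 3) {
    // order cap vertices around the plane; outward normal must equal n
    Vec3 cent(0, 0, 0);
    for (int v : cap) cent = cent + Q.verts[v];
    cent = cent * (1.0 / cap.size());
    Vec3 a = std::fabs(n.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
    Vec3 e1 = cross(n, a);
    e1 = e1 * (1.0 / norm(e1));
    Vec3 e2 = cross(n, e1);
    std::vector<std::pair<double, int>> ang;
    ang.reserve(cap.size());
    for (int v : cap) {
      Vec3 r = Q.verts[v] - cent;
      ang.push_back(std::make_pair(std::atan2(dot(r, e2), dot(r, e1)), v));
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> ring;
    for (auto& p : ang) ring.push_back(p.second);
    // orientation: ensure outward (along n)
    Vec3 u = Q.verts[ring[1]] - Q.verts[ring[0]];
    Vec3 w = Q.verts[ring[2]] - Q.verts[ring[0]];
    if (dot(cross(u, w), n) < 0) std::reverse(ring.begin(), ring.end());
    Q.faces.push_back(ring);
    Q.face_cell.push_back(gen_cell);
    Q.face_gen.push_back(gen_pos);
  }
  P = std::move(Q);
  return true;
}

static Poly seed_cube(const Vec3& c, double h) {
  Poly P;
  for (int i = 0; i < 8; ++i) {
    P.verts.push_back(Vec3(c.x + ((i & 1) ? h : -h), c.y + ((i & 2) ? h : -h),
                           c.z + ((i & 4) ? h : -h)));
  }
  int F[6][4] = {{0, 2, 6, 4}, {1, 5, 7, 3}, {0, 4, 5, 1},
                 {2, 3, 7, 6}, {0, 1, 3, 2}, {4, 6, 7, 5}};
  for (int f = 0; f < 6; ++f) {
    P.faces.push_back({F[f][0], F[f][1], F[f][2], F[f][3]});
    P.face_cell.push_back(-1);
    P.face_gen.push_back(c);  // placeholder
  }
  return P;
}

struct Candidate {
  double d2;
  Vec3 p;
  int cell;
};

// Build the Voronoi cell of center i.  centers must be wrapped into the box.
static Poly build_cell(int i, const std::vector<Vec3>& cen, const Vec3& L) {
  const int N = (int)cen.size();
  const Vec3 c = cen[i];
  double Lmin = std::min(L.x, std::min(L.y, L.z));
  double vmean = (L.x * L.y * L.z) / N;
  double rc = 3.0 * std::cbrt(vmean);
  const double coincident = 1e-9 * Lmin;

  for (int attempt = 0; attempt < 8; ++attempt) {
    std::vector<Candidate> cand;
    cand.reserve(64);
    double rc2 = rc * rc;
    for (int j = 0; j < N; ++j) {
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            if (j == i && ox == 0 && oy == 0 && oz == 0) continue;
            Vec3 p(cen[j].x + ox * L.x, cen[j].y + oy * L.y, cen[j].z + oz * L.z);
            Vec3 r = p - c;
            double d2 = dot(r, r);
            if (d2 < rc2) cand.push_back({d2, p, j});
          }
    }
    std::sort(cand.begin(), cand.end(),
              [](const Candidate& a, const Candidate& b) { return a.d2 < b.d2; });
    if (!cand.empty() && cand[0].d2 < coincident * coincident)
      stop("degenerate geometry: coincident cell centers (distance %g)",
           std::sqrt(cand[0].d2));

    Poly P = seed_cube(c, rc);
    double Rmax2 = 3.0 * rc * rc;
    for (const Candidate& q : cand) {
      if (q.d2 * 0.25 > Rmax2) break;
      Vec3 n = q.p - c;
      double dlen = norm(n);
      n = n * (1.0 / dlen);
      double d = dot(n, (c + q.p) * 0.5);
      if (clip_poly(P, n, d, q.cell, q.p, Lmin)) {
        Rmax2 = 0;
        for (const Vec3& v : P.verts) {
          Vec3 r = v - c;
          double d2v = dot(r, r);
          if (d2v > Rmax2) Rmax2 = d2v;
        }
      }
    }
    bool open = false;
    for (int fc : P.face_cell)
      if (fc < 0) open = true;
    // the closure bound requires all candidates out to 2*Rmax to be present
    if (!open && 4.0 * Rmax2 <= rc2) return P;
    rc *= 1.7;
  }
  stop("periodic Voronoi cell construction failed to close (pathological input)");
}

// volume and surface area by fan triangulation of each face
static void measure_poly(const Poly& P, double& V, double& S) {
  V = 0;
  S = 0;
  for (const auto& f : P.faces) {
    const Vec3& o = P.verts[f[0]];
    for (size_t k = 1; k + 1 < f.size(); ++k) {
      const Vec3& a = P.verts[f[k]];
      const Vec3& b = P.verts[f[k + 1]];
      V += dot(o, cross(a, b));
      S += 0.5 * norm(cross(a - o, b - o));
    }
  }
  V /= 6.0;
}

static std::vector<Vec3> as_vecs(const NumericMatrix& m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return v;
}

// [[Rcpp::export]]
List cpp_voronoi(NumericMatrix centers, NumericVector box) {
  std::vector<Vec3> cen = as_vecs(centers);
  Vec3 L(box[0], box[1], box[2]);
  const int N = (int)cen.size();
  List cells(N);
  for (int i = 0; i < N; ++i) {
    Poly P = build_cell(i, cen, L);
    double V, S;
    measure_poly(P, V, S);
    NumericMatrix vm(P.verts.size(), 3);
    for (size_t k = 0; k < P.verts.size(); ++k) {
      vm(k, 0) = P.verts[k].x;
      vm(k, 1) = P.verts[k].y;
      vm(k, 2) = P.verts[k].z;
    }
    List fl(P.faces.size());
    IntegerVector nb(P.faces.size());
    NumericVector fa(P.faces.size());
    NumericMatrix gp(P.faces.size(), 3);
    for (size_t f = 0; f < P.faces.size(); ++f) {
      IntegerVector idx(P.faces[f].size());
      for (size_t k = 0; k < P.faces[f].size(); ++k) idx[k] = P.faces[f][k] + 1;
      fl[f] = idx;
      nb[f] = P.face_cell[f] + 1;
      gp(f, 0) = P.face_gen[f].x;
      gp(f, 1) = P.face_gen[f].y;
      gp(f, 2) = P.face_gen[f].z;
      // face area
      double A = 0;
      const Vec3& o = P.verts[P.faces[f][0]];
      for (size_t k = 1; k + 1 < P.faces[f].size(); ++k)
        A += 0.5 * norm(cross(P.verts[P.faces[f][k]] - o,
                              P.verts[P.faces[f][k + 1]] - o));
      fa[f] = A;
    }
    cells[i] = List::create(
        _["cell_id"] = i + 1, _["vertices"] = vm, _["faces"] = fl,
        _["neighbor_ids"] = nb, _["face_areas"] = fa, _["face_generators"] = gp,
        _["V"] = V, _["S"] = S);
  }
  return cells;
}

static double energy_of(const std::vector<Vec3>& cen, const Vec3& L,
                        const NumericVector& S0, const NumericVector& V0,
                        double kS, double kV) {
  double E = 0;
  for (int i = 0; i < (int)cen.size(); ++i) {
    Poly P = build_cell(i, cen, L);
    double V, S;
    measure_poly(P, V, S);
    E += kS * (S - S0[i]) * (S - S0[i]) + kV * (V - V0[i]) * (V - V0[i]);
  }
  return E;
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix centers, NumericVector box, NumericVector S0,
                  NumericVector V0, double kS, double kV) {
  return energy_of(as_vecs(centers), Vec3(box[0], box[1], box[2]), S0, V0, kS, kV);
}

// [[Rcpp::export]]
NumericVector cpp_cell_VS(NumericMatrix centers, NumericVector box) {
  std::vector<Vec3> cen = as_vecs(centers);
  Vec3 L(box[0], box[1], box[2]);
  const int N = (int)cen.size();
  NumericVector out(2 * N);
  for (int i = 0; i < N; ++i) {
    Poly P = build_cell(i, cen, L);
    double V, S;
    measure_poly(P, V, S);
    out[i] = V;
    out[N + i] = S;
  }
  return out;
}

static bool solve3(const double A[3][3], const double b[3], double x[3]) {
  double m[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) m[i][j] = A[i][j];
    m[i][3] = b[i];
  }
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(m[r][col]) > std::fabs(m[piv][col])) piv = r;
    if (std::fabs(m[piv][col]) < 1e-14) return false;
    if (piv != col)
      for (int j = 0; j < 4; ++j) std::swap(m[col][j], m[piv][j]);
    for (int r = 0; r < 3; ++r) {
      if (r == col) continue;
      double f = m[r][col] / m[col][col];
      for (int j = col; j < 4; ++j) m[r][j] -= f * m[col][j];
    }
  }
  for (int i = 0; i < 3; ++i) x[i] = m[i][3] / m[i][i];
  return true;
}

// Analytic gradient dE/d(center positions).
//
// Every Voronoi vertex is the circumcenter of its cell's generator g0 and the
// three neighbor generators g1..g3 of the faces meeting at the vertex:
//   (g_k - g0) . v = (|g_k|^2 - |g0|^2)/2,  k = 1..3    (A v = b)
// The implicit function theorem gives rank-one Jacobians
//   dv/dg0 = (A^{-1} 1) (v - g0)^T,   dv/dg_m = (A^{-1} e_m) (g_m - v)^T,
// which are chained with the per-vertex gradients of each cell's V and S.
static NumericMatrix gradient_core(const std::vector<Vec3>& cen, const Vec3& L,
                                   const NumericVector& S0, const NumericVector& V0,
                                   double kS, double kV, std::vector<double>& Vout,
                                   std::vector<double>& Sout) {
  const int N = (int)cen.size();
  NumericMatrix grad(N, 3);
  Vout.assign(N, 0.0);
  Sout.assign(N, 0.0);

  for (int j = 0; j < N; ++j) {
    Poly P = build_cell(j, cen, L);
    double V, S;
    measure_poly(P, V, S);
    Vout[j] = V;
    Sout[j] = S;
    const int nv = (int)P.verts.size();

    // per-vertex gradients of V and S
    std::vector<Vec3> gV(nv), gS(nv);
    for (const auto& f : P.faces) {
      const int m = (int)f.size();
      const Vec3& o = P.verts[f[0]];
      for (int k = 1; k + 1 < m; ++k) {
        const Vec3& a = P.verts[f[k]];
        const Vec3& b = P.verts[f[k + 1]];
        // V contribution o.(a x b)/6
        gV[f[0]] = gV[f[0]] + cross(a, b) * (1.0 / 6.0);
        gV[f[k]] = gV[f[k]] + cross(b, o) * (1.0 / 6.0);
        gV[f[k + 1]] = gV[f[k + 1]] + cross(o, a) * (1.0 / 6.0);
        // S contribution |(a-o) x (b-o)|/2
        Vec3 u = a - o, w = b - o;
        Vec3 cr = cross(u, w);
        double nc = norm(cr);
        if (nc > 1e-14) {
          Vec3 nh = cr * (1.0 / nc);
          Vec3 da = cross(w, nh) * 0.5;
          Vec3 db = cross(nh, u) * 0.5;
          gS[f[k]] = gS[f[k]] + da;
          gS[f[k + 1]] = gS[f[k + 1]] + db;
          gS[f[0]] = gS[f[0]] - da - db;
        }
      }
    }

    // faces incident to each vertex
    std::vector<std::array<int, 3>> vfaces(nv, {-1, -1, -1});
    std::vector<int> vcount(nv, 0);
    for (int f = 0; f < (int)P.faces.size(); ++f)
      for (int v : P.faces[f]) {
        if (vcount[v] < 3) vfaces[v][vcount[v]] = f;
        vcount[v]++;
      }

    const double cS = 2.0 * kS * (S - S0[j]);
    const double cV = 2.0 * kV * (V - V0[j]);
    const Vec3 g0 = cen[j];

    for (int v = 0; v < nv; ++v) {
      if (vcount[v] < 3) continue;  // should not happen
      Vec3 w = gS[v] * cS + gV[v] * cV;
      if (dot(w, w) < 1e-30) continue;
      Vec3 g[3];
      int cellid[3];
      for (int k = 0; k < 3; ++k) {
        int f = vfaces[v][k];
        g[k] = P.face_gen[f];
        cellid[k] = P.face_cell[f];
      }
      double A[3][3] = {{g[0].x - g0.x, g[0].y - g0.y, g[0].z - g0.z},
                        {g[1].x - g0.x, g[1].y - g0.y, g[1].z - g0.z},
                        {g[2].x - g0.x, g[2].y - g0.y, g[2].z - g0.z}};
      // columns of A^{-1}: solve A u = e_m; and u0 = A^{-1} 1
      double u0[3], um[3][3];
      double ones[3] = {1, 1, 1};
      if (!solve3(A, ones, u0)) continue;  // degenerate vertex
      for (int m3 = 0; m3 < 3; ++m3) {
        double e[3] = {0, 0, 0};
        e[m3] = 1;
        solve3(A, e, um[m3]);
      }
      const Vec3 vv = P.verts[v];
      // dE/dg0 += (w . u0) (v - g0)
      double wu0 = w.x * u0[0] + w.y * u0[1] + w.z * u0[2];
      grad(j, 0) += wu0 * (vv.x - g0.x);
      grad(j, 1) += wu0 * (vv.y - g0.y);
      grad(j, 2) += wu0 * (vv.z - g0.z);
      for (int m3 = 0; m3 < 3; ++m3) {
        double wum = w.x * um[m3][0] + w.y * um[m3][1] + w.z * um[m3][2];
        int ci = cellid[m3];
        if (ci < 0) continue;
        grad(ci, 0) += wum * (g[m3].x - vv.x);
        grad(ci, 1) += wum * (g[m3].y - vv.y);
        grad(ci, 2) += wum * (g[m3].z - vv.z);
      }
    }
  }
  return grad;
}

// [[Rcpp::export]]
NumericMatrix cpp_energy_gradient(NumericMatrix centers, NumericVector box,
                                  NumericVector S0, NumericVector V0, double kS,
                                  double kV) {
  std::vector<double> V, S;
  return gradient_core(as_vecs(centers), Vec3(box[0], box[1], box[2]), S0, V0,
                       kS, kV, V, S);
}

// One-pass model evaluation: energy, per-cell V and S, and (optionally) the
// analytic gradient.  Used by the FIRE driver so each step tessellates once.
// [[Rcpp::export]]
List cpp_model_eval(NumericMatrix centers, NumericVector box, NumericVector S0,
                    NumericVector V0, double kS, double kV, bool want_grad) {
  const int N = centers.nrow();
  std::vector<Vec3> cen = as_vecs(centers);
  Vec3 L(box[0], box[1], box[2]);
  std::vector<double> Vv, Sv;
  NumericMatrix grad;
  if (want_grad) {
    grad = gradient_core(cen, L, S0, V0, kS, kV, Vv, Sv);
  } else {
    Vv.resize(N);
    Sv.resize(N);
    for (int i = 0; i < N; ++i) {
      Poly P = build_cell(i, cen, L);
      measure_poly(P, Vv[i], Sv[i]);
    }
  }
  double E = 0;
  NumericVector V(N), S(N);
  for (int i = 0; i < N; ++i) {
    V[i] = Vv[i];
    S[i] = Sv[i];
    E += kS * (S[i] - S0[i]) * (S[i] - S0[i]) +
         kV * (V[i] - V0[i]) * (V[i] - V0[i]);
  }
  List out = List::create(_["E"] = E, _["V"] = V, _["S"] = S);
  if (want_grad) out["gradient"] = grad;
  return out;
}

// central finite-difference gradient (full re-tessellation; reference path)
// [[Rcpp::export]]
NumericMatrix cpp_energy_gradient_fd(NumericMatrix centers, NumericVector box,
                                     NumericVector S0, NumericVector V0,
                                     double kS, double kV, double h) {
  std::vector<Vec3> cen = as_vecs(centers);
  Vec3 L(box[0], box[1], box[2]);
  const int N = (int)cen.size();
  NumericMatrix grad(N, 3);
  for (int i = 0; i < N; ++i) {
    for (int d = 0; d < 3; ++d) {
      double* comp = (d == 0) ? &cen[i].x : (d == 1) ? &cen[i].y : &cen[i].z;
      double orig = *comp;
      *comp = orig + h;
      double Ep = energy_of(cen, L, S0, V0, kS, kV);
      *comp = orig - h;
      double Em = energy_of(cen, L, S0, V0, kS, kV);
      *comp = orig;
      double g = (Ep - Em) / (2.0 * h);
      if (!std::isfinite(g)) stop("non-finite finite-difference gradient (step too small?)");
      grad(i, d) = g;
    }
  }
  return grad;
}

// ---------- 2D polygon statistics ----------

// perimeter, area, centroid, anisotropy index from the central second-area-
// moment tensor (exact Green's-theorem polygon integration)
static void polygon_stats(const std::vector<double>& x, const std::vector<double>& y,
                          double& Lp, double& A, double& cx, double& cy, double& m) {
  const int n = (int)x.size();
  Lp = 0;
  double a2 = 0, sx = 0, sy = 0, ixx = 0, iyy = 0, ixy = 0;
  for (int k = 0; k < n; ++k) {
    int k1 = (k + 1) % n;
    double cr = x[k] * y[k1] - x[k1] * y[k];
    a2 += cr;
    sx += (x[k] + x[k1]) * cr;
    sy += (y[k] + y[k1]) * cr;
    ixx += (x[k] * x[k] + x[k] * x[k1] + x[k1] * x[k1]) * cr;
    iyy += (y[k] * y[k] + y[k] * y[k1] + y[k1] * y[k1]) * cr;
    ixy += (x[k] * y[k1] + 2 * x[k] * y[k] + 2 * x[k1] * y[k1] + x[k1] * y[k]) * cr;
    double dx = x[k1] - x[k], dy = y[k1] - y[k];
    Lp += std::sqrt(dx * dx + dy * dy);
  }
  A = 0.5 * a2;
  double sgn = (A >= 0) ? 1.0 : -1.0;
  cx = sx / (6.0 * A);
  cy = sy / (6.0 * A);
  ixx = sgn * ixx / 12.0;
  iyy = sgn * iyy / 12.0;
  ixy = sgn * ixy / 24.0;
  A = std::fabs(A);
  // central moments
  ixx -= A * cx * cx;
  iyy -= A * cy * cy;
  ixy -= A * cx * cy;
  double tr = ixx + iyy;
  double dlt = std::sqrt(0.25 * (ixx - iyy) * (ixx - iyy) + ixy * ixy);
  m = (tr > 0) ? (2.0 * dlt / tr) : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_polygon_stats(NumericMatrix poly) {
  std::vector<double> x(poly.nrow()), y(poly.nrow());
  for (int i = 0; i < poly.nrow(); ++i) {
    x[i] = poly(i, 0);
    y[i] = poly(i, 1);
  }
  double L, A, cx, cy, m;
  polygon_stats(x, y, L, A, cx, cy, m);
  return NumericVector::create(_["L"] = L, _["a"] = A, _["cx"] = cx,
                               _["cy"] = cy, _["m"] = m);
}

// cross-section of a convex polyhedron with plane n.x = c -> ordered polygon
// (3D points); empty if no intersection
static std::vector<Vec3> poly_plane_section(const Poly& P, const Vec3& shift,
                                            const Vec3& n, double c,
                                            double eps_scale) {
  const double eps = 1e-9 * eps_scale;
  const int nv = (int)P.verts.size();
  std::vector<double> s(nv);
  bool anyp = false, anym = false;
  for (int i = 0; i < nv; ++i) {
    Vec3 v = P.verts[i] + shift;
    s[i] = dot(n, v) - c;
    if (s[i] > eps) anyp = true;
    if (s[i] < -eps) anym = true;
  }
  if (!anyp || !anym) return {};
  std::vector<Vec3> pts;
  auto add_pt = [&](const Vec3& p) {
    for (const Vec3& q : pts) {
      Vec3 d = p - q;
      if (dot(d, d) < eps * eps) return;
    }
    pts.push_back(p);
  };
  for (const auto& f : P.faces) {
    const int mfc = (int)f.size();
    for (int k = 0; k < mfc; ++k) {
      int u = f[k], w = f[(k + 1) % mfc];
      if (std::fabs(s[u]) <= eps) add_pt(P.verts[u] + shift);
      if ((s[u] > eps && s[w] < -eps) || (s[u] < -eps && s[w] > eps)) {
        double t = s[u] / (s[u] - s[w]);
        Vec3 p = (P.verts[u] + shift) + ((P.verts[w] + shift) - (P.verts[u] + shift)) * t;
        add_pt(p);
      }
    }
  }
  if (pts.size() < 3) return {};
  // order by angle in the plane
  Vec3 cent(0, 0, 0);
  for (const Vec3& p : pts) cent = cent + p;
  cent = cent * (1.0 / pts.size());
  Vec3 a = std::fabs(n.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  Vec3 e1 = cross(n, a);
  e1 = e1 * (1.0 / norm(e1));
  Vec3 e2 = cross(n, e1);
  std::vector<std::pair<double, int>> ang;
  for (int i = 0; i < (int)pts.size(); ++i) {
    Vec3 r = pts[i] - cent;
    ang.push_back(std::make_pair(std::atan2(dot(r, e2), dot(r, e1)), i));
  }
  std::sort(ang.begin(), ang.end());
  std::vector<Vec3> out;
  for (auto& p : ang) out.push_back(pts[p.second]);
  return out;
}

// 2D Sutherland-Hodgman clip of convex polygon against half-plane a.x <= b
static void clip2d(std::vector<double>& x, std::vector<double>& y, double ax,
                   double ay, double b) {
  const int n = (int)x.size();
  if (n == 0) return;
  std::vector<double> nx_, ny_;
  for (int k = 0; k < n; ++k) {
    int k1 = (k + 1) % n;
    double su = ax * x[k] + ay * y[k] - b;
    double sw = ax * x[k1] + ay * y[k1] - b;
    if (su <= 0) {
      nx_.push_back(x[k]);
      ny_.push_back(y[k]);
    }
    if ((su < 0 && sw > 0) || (su > 0 && sw < 0)) {
      double t = su / (su - sw);
      nx_.push_back(x[k] + t * (x[k1] - x[k]));
      ny_.push_back(y[k] + t * (y[k1] - y[k]));
    }
  }
  x = nx_;
  y = ny_;
}

// Slice a periodic packing with the plane n.x = offset.
//
// mode 0 ("centroid"): for every periodic image of every cell that the plane
// cuts, the full cross-section polygon is kept iff its area centroid falls
// inside the box cross-section (associated-point rule; unbiased, no clipped
// fragments).  mode 1 ("clip"): polygons are clipped to the box cross-section
// so that they tile it exactly.
// [[Rcpp::export]]
List cpp_slice_packing(NumericMatrix centers, NumericVector box,
                       NumericVector normal, double offset, int mode,
                       double min_area, bool keep_polygons) {
  std::vector<Vec3> cen = as_vecs(centers);
  Vec3 L(box[0], box[1], box[2]);
  Vec3 n(normal[0], normal[1], normal[2]);
  double nn = norm(n);
  n = n * (1.0 / nn);
  const double coff = offset / nn;  // plane in unit-normal form
  const int N = (int)cen.size();
  double Lmin = std::min(L.x, std::min(L.y, L.z));

  // in-plane basis
  Vec3 a0 = std::fabs(n.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  Vec3 e1 = cross(n, a0);
  e1 = e1 * (1.0 / norm(e1));
  Vec3 e2 = cross(n, e1);
  Vec3 origin = n * coff;  // a point on the plane

  std::vector<double> col_id, col_L, col_a, col_p2, col_m, col_clip;
  List polys;
  std::vector<SEXP> poly_list;
  int dropped = 0;

  for (int i = 0; i < N; ++i) {
    // quick reject: min distance from any image of c_i to plane vs cell size
    Poly P = build_cell(i, cen, L);
    double Rmax = 0;
    for (const Vec3& v : P.verts) {
      Vec3 r = v - cen[i];
      Rmax = std::max(Rmax, norm(r));
    }
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          Vec3 shift(ox * L.x, oy * L.y, oz * L.z);
          double dist = dot(n, cen[i] + shift) - coff;
          if (std::fabs(dist) > Rmax) continue;
          std::vector<Vec3> sec = poly_plane_section(P, shift, n, coff, Lmin);
          if (sec.size() < 3) continue;
          // to 2D in-plane coordinates
          std::vector<double> x(sec.size()), y(sec.size());
          for (size_t k = 0; k < sec.size(); ++k) {
            Vec3 r = sec[k] - origin;
            x[k] = dot(r, e1);
            y[k] = dot(r, e2);
          }
          double Lp, A, cx, cy, mm;
          polygon_stats(x, y, Lp, A, cx, cy, mm);
          bool clipped = false;
          if (mode == 0) {
            // associated-point rule on the 3D centroid
            Vec3 q = origin + e1 * cx + e2 * cy;
            if (!(q.x >= 0 && q.x < L.x && q.y >= 0 && q.y < L.y && q.z >= 0 &&
                  q.z < L.z))
              continue;
          } else {
            // clip against the 6 box half-spaces restricted to the plane:
            // x-dir: 0 <= origin + x e1 + y e2 (component) <= L
            double A0 = A;
            double comp_o[3] = {origin.x, origin.y, origin.z};
            double comp_1[3] = {e1.x, e1.y, e1.z};
            double comp_2[3] = {e2.x, e2.y, e2.z};
            double Lv[3] = {L.x, L.y, L.z};
            for (int dcomp = 0; dcomp < 3 && x.size() >= 3; ++dcomp) {
              // comp >= 0  ->  -c1 x - c2 y <= o
              clip2d(x, y, -comp_1[dcomp], -comp_2[dcomp], comp_o[dcomp]);
              if (x.size() < 3) break;
              // comp <= L  ->  c1 x + c2 y <= L - o
              clip2d(x, y, comp_1[dcomp], comp_2[dcomp], Lv[dcomp] - comp_o[dcomp]);
            }
            if (x.size() < 3) continue;
            polygon_stats(x, y, Lp, A, cx, cy, mm);
            clipped = (A < A0 * (1 - 1e-9));
          }
          if (A <= min_area) {
            dropped++;
            continue;
          }
          col_id.push_back(i + 1);
          col_L.push_back(Lp);
          col_a.push_back(A);
          col_p2.push_back(Lp / std::sqrt(A));
          col_m.push_back(mm);
          col_clip.push_back(clipped ? 1.0 : 0.0);
          if (keep_polygons) {
            NumericMatrix pm(x.size(), 2);
            for (size_t k = 0; k < x.size(); ++k) {
              pm(k, 0) = x[k];
              pm(k, 1) = y[k];
            }
            poly_list.push_back(pm);
          }
        }
  }
  List out = List::create(
      _["cell_id"] = wrap(col_id), _["L"] = wrap(col_L), _["a"] = wrap(col_a),
      _["p2D"] = wrap(col_p2), _["m"] = wrap(col_m),
      _["clipped"] = wrap(col_clip), _["n_dropped"] = dropped);
  if (keep_polygons) {
    List pl(poly_list.size());
    for (size_t k = 0; k < poly_list.size(); ++k) pl[k] = poly_list[k];
    out["polygons"] = pl;
  }
  return out;
}

static bool solve4(double A[4][5]) {
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
    if (std::fabs(A[piv][col]) < 1e-12) return false;
    if (piv != col)
      for (int j = 0; j < 5; ++j) std::swap(A[col][j], A[piv][j]);
    for (int r = 0; r < 4; ++r) {
      if (r == col) continue;
      double f = A[r][col] / A[col][col];
      for (int j = col; j < 5; ++j) A[r][j] -= f * A[col][j];
    }
  }
  return true;
}

// maximize r s.t. n_f . x + r <= d_f over the faces in `idx`, by enumerating
// quadruples of active constraints (the optimum of a nondegenerate LP in 4
// variables lies at a vertex with 4 active rows); returns r (or -1)
static double cheb_enum(const NumericMatrix& normals, const NumericVector& dvals,
                        const std::vector<int>& idxset, double out_x[3]) {
  const int nf = (int)idxset.size();
  double best_r = -1;
  for (int a = 0; a < nf; ++a)
    for (int b = a + 1; b < nf; ++b)
      for (int c = b + 1; c < nf; ++c)
        for (int d = c + 1; d < nf; ++d) {
          int idx[4] = {idxset[a], idxset[b], idxset[c], idxset[d]};
          double M[4][5];
          for (int r = 0; r < 4; ++r) {
            M[r][0] = normals(idx[r], 0);
            M[r][1] = normals(idx[r], 1);
            M[r][2] = normals(idx[r], 2);
            M[r][3] = 1.0;
            M[r][4] = dvals[idx[r]];
          }
          if (!solve4(M)) continue;
          double x = M[0][4] / M[0][0], y = M[1][4] / M[1][1],
                 z = M[2][4] / M[2][2], r = M[3][4] / M[3][3];
          if (r <= best_r) continue;
          bool feas = true;
          for (int f = 0; f < nf; ++f) {
            int ff = idxset[f];
            double s = normals(ff, 0) * x + normals(ff, 1) * y +
                       normals(ff, 2) * z + r - dvals[ff];
            if (s > 1e-8 * (1 + std::fabs(dvals[ff]))) {
              feas = false;
              break;
            }
          }
          if (feas) {
            best_r = r;
            out_x[0] = x;
            out_x[1] = y;
            out_x[2] = z;
          }
        }
  return best_r;
}

// Chebyshev center: largest inscribed sphere of the convex region
// {x : n_f . x <= d_f}.  For small face counts the vertex enumeration above
// is exact; for many faces an active-set loop solves on a working subset and
// adds the most violated constraint until none remains.
// [[Rcpp::export]]
NumericVector cpp_chebyshev(NumericMatrix normals, NumericVector dvals) {
  const int nf = normals.nrow();
  if (nf < 4) stop("need at least 4 faces");
  double x[3] = {0, 0, 0};
  double r = -1;
  if (nf <= 24) {
    std::vector<int> all(nf);
    for (int i = 0; i < nf; ++i) all[i] = i;
    r = cheb_enum(normals, dvals, all, x);
  } else {
    // seed the working set with the faces most aligned with +-x, +-y, +-z
    // (their normals positively span space, so the subset LP is bounded)
    std::vector<int> W;
    for (int dir = 0; dir < 6; ++dir) {
      int axis = dir / 2;
      double sgn = (dir % 2) ? -1.0 : 1.0;
      int best = 0;
      double bv = -2;
      for (int f = 0; f < nf; ++f) {
        double v = sgn * normals(f, axis);
        if (v > bv) { bv = v; best = f; }
      }
      if (std::find(W.begin(), W.end(), best) == W.end()) W.push_back(best);
    }
    for (int iter = 0; iter < 64; ++iter) {
      r = cheb_enum(normals, dvals, W, x);
      if (r < 0) break;
      int worst = -1;
      double wv = 1e-8;
      for (int f = 0; f < nf; ++f) {
        double s = (normals(f, 0) * x[0] + normals(f, 1) * x[1] +
                    normals(f, 2) * x[2] + r - dvals[f]) /
                   (1 + std::fabs(dvals[f]));
        if (s > wv) {
          wv = s;
          worst = f;
        }
      }
      if (worst < 0) break;
      W.push_back(worst);
    }
  }
  if (r <= 0) stop("inscribed-sphere program infeasible (non-convex or degenerate input?)");
  return NumericVector::create(_["r"] = r, _["x"] = x[0], _["y"] = x[1],
                               _["z"] = x[2]);
}
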