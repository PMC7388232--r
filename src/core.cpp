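// Numerical core: signed distances on a regular grid (exact near-band +
// fast marching), trilinear resampling, the hyperelastic matching
// objective/gradient, displacement-field inversion and marching tetrahedra.
//
// Grid convention (shared with the R side): n nodes per axis on [0,1]^3,
// spacing h = 1/(n-1), node (i,j,k) (0-based) at (i*h, j*h, k*h), linear
// index i + n*(j + n*k) -- identical to an R array [i+1,j+1,k+1] in
// column-major order.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int lindex(int i, int j, int k, int n) {
  return i + n * (j + n * k);
}

// ---------------------------------------------------------------------------
// point-triangle distance (Eberly-style region decomposition)
// ---------------------------------------------------------------------------
static double point_triangle_dist2(const double *p, const double *a,
                                   const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int t = 0; t < 3; ++t) {
    ab[t] = b[t] - a[t];
    ac[t] = c[t] - a[t];
    ap[t] = p[t] - a[t];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0]*ap[0] + ap[1]*ap[1] + ap[2]*ap[2];
  }
  double bp[3];
  for (int t = 0; t < 3; ++t) bp[t] = p[t] - b[t];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0]*bp[0] + bp[1]*bp[1] + bp[2]*bp[2];
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double dd = 0.0;
    for (int t = 0; t < 3; ++t) {
      double e = ap[t] - v * ab[t];
      dd += e * e;
    }
    return dd;
  }
  double cp[3];
  for (int t = 0; t < 3; ++t) cp[t] = p[t] - c[t];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0]*cp[0] + cp[1]*cp[1] + cp[2]*cp[2];
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double dd = 0.0;
    for (int t = 0; t < 3; ++t) {
      double e = ap[t] - w * ac[t];
      dd += e * e;
    }
    return dd;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double dd = 0.0;
    for (int t = 0; t < 3; ++t) {
      double e = bp[t] + w * (c[t] - b[t]);
      dd += e * e;
    }
    return dd;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double dd = 0.0;
  for (int t = 0; t < 3; ++t) {
    double e = ap[t] - (v * ab[t] + w * ac[t]);
    dd += e * e;
  }
  return dd;
}

// [[Rcpp::export]]
NumericVector cpp_point_triangle_dist(NumericMatrix pts, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      double a[3] = {V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
      double b[3] = {V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
      double c[3] = {V(F(f,2),0), V(F(f,2),1), V(F(f,2),2)};
      double d2 = point_triangle_dist2(pp, a, b, c);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// fast marching (Eikonal |grad d| = 1) from a set of accepted seed nodes
// ---------------------------------------------------------------------------
struct HeapNode {
  double val;
  int idx;
  bool operator<(const HeapNode &o) const { return val > o.val; }
};

static double eikonal_update(const std::vector<double> &d,
                             const std::vector<char> &state, int i, int j,
                             int k, int n, double h) {
  // gather smallest accepted neighbor per axis
  double a[3];
  int na = 0;
  const int di[3] = {1, n, n * n};
  const int ci[3] = {i, j, k};
  int idx = lindex(i, j, k, n);
  for (int ax = 0; ax < 3; ++ax) {
    double best = std::numeric_limits<double>::infinity();
    if (ci[ax] > 0 && state[idx - di[ax]] == 2) best = d[idx - di[ax]];
    if (ci[ax] < n - 1 && state[idx + di[ax]] == 2)
      best = std::min(best, d[idx + di[ax]]);
    if (std::isfinite(best)) a[na++] = best;
  }
  if (na == 0) return std::numeric_limits<double>::infinity();
  std::sort(a, a + na);
  // solve sum_{used} ((t - a_m)/h)^2 = 1 with the standard causality check
  for (int m = na; m >= 1; --m) {
    double s = 0.0, s2 = 0.0;
    for (int q = 0; q < m; ++q) {
      s += a[q];
      s2 += a[q] * a[q];
    }
    double A = m, B = -2.0 * s, C = s2 - h * h;
    double disc = B * B - 4.0 * A * C;
    if (disc >= 0.0) {
      double t = (-B + std::sqrt(disc)) / (2.0 * A);
      if (m == 1 || t >= a[m - 1]) return t;
    }
  }
  return a[0] + h;
}

static void fast_march(std::vector<double> &d, std::vector<char> &state,
                       int n, double h) {
  std::priority_queue<HeapNode> heap;
  // initialize trial values for neighbors of accepted nodes
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        int idx = lindex(i, j, k, n);
        if (state[idx] != 2) continue;
        const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int q = 0; q < 6; ++q) {
          int ii = i + off[q][0], jj = j + off[q][1], kk = k + off[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n || jj >= n || kk >= n)
            continue;
          int nidx = lindex(ii, jj, kk, n);
          if (state[nidx] == 2) continue;
          double t = eikonal_update(d, state, ii, jj, kk, n, h);
          if (t < d[nidx]) {
            d[nidx] = t;
            state[nidx] = 1;
            heap.push({t, nidx});
          }
        }
      }
  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    if (state[top.idx] == 2 || top.val > d[top.idx]) continue;
    state[top.idx] = 2;
    int k = top.idx / (n * n), j = (top.idx / n) % n, i = top.idx % n;
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int q = 0; q < 6; ++q) {
      int ii = i + off[q][0], jj = j + off[q][1], kk = k + off[q][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n || jj >= n || kk >= n) continue;
      int nidx = lindex(ii, jj, kk, n);
      if (state[nidx] == 2) continue;
      double t = eikonal_update(d, state, ii, jj, kk, n, h);
      if (t < d[nidx]) {
        d[nidx] = t;
        state[nidx] = 1;
        heap.push({t, nidx});
      }
    }
  }
}

// ---------------------------------------------------------------------------
// inside/outside by ray parity, one x-directed ray per (j,k) grid line
// ---------------------------------------------------------------------------
static void ray_parity(const NumericMatrix &V, const IntegerMatrix &F, int n,
                       double h, std::vector<char> &inside) {
  const int nf = F.nrow();
  // bin triangles by their (j,k) cell ranges
  std::vector<std::vector<int>> bins((size_t)n * n);
  for (int f = 0; f < nf; ++f) {
    double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30;
    for (int v = 0; v < 3; ++v) {
      ymin = std::min(ymin, V(F(f, v), 1));
      ymax = std::max(ymax, V(F(f, v), 1));
      zmin = std::min(zmin, V(F(f, v), 2));
      zmax = std::max(zmax, V(F(f, v), 2));
    }
    int j0 = std::max(0, (int)std::floor(ymin / h));
    int j1 = std::min(n - 1, (int)std::ceil(ymax / h));
    int k0 = std::max(0, (int)std::floor(zmin / h));
    int k1 = std::min(n - 1, (int)std::ceil(zmax / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) bins[j + (size_t)n * k].push_back(f);
  }
  const double jy = 0.5e-6 * h, jz = 0.7e-6 * h;  // deterministic tie jitter
  std::vector<double> xs;
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) {
      xs.clear();
      double y = j * h + jy, z = k * h + jz;
      for (int f : bins[j + (size_t)n * k]) {
        double ay = V(F(f,0),1) - y, az = V(F(f,0),2) - z;
        double by = V(F(f,1),1) - y, bz = V(F(f,1),2) - z;
        double cy = V(F(f,2),1) - y, cz = V(F(f,2),2) - z;
        // signed areas of the yz-projected sub-triangles
        double s1 = ay * bz - az * by;
        double s2 = by * cz - bz * cy;
        double s3 = cy * az - cz * ay;
        double stot = s1 + s2 + s3;
        if (stot == 0.0) continue;  // projection degenerate
        double w2 = s3 / stot, w3 = s1 / stot, w1 = s2 / stot;
        if (w1 < 0.0 || w2 < 0.0 || w3 < 0.0) continue;
        double x =
            w1 * V(F(f,0),0) + w2 * V(F(f,1),0) + w3 * V(F(f,2),0);
        xs.push_back(x);
      }
      std::sort(xs.begin(), xs.end());
      // walk the row: parity flips at every crossing
      size_t c = 0;
      for (int i = 0; i < n; ++i) {
        double x = i * h;
        while (c < xs.size() && xs[c] < x) ++c;
        inside[lindex(i, j, k, n)] = (char)(c % 2 == 1);
      }
    }
}

// [[Rcpp::export]]
List cpp_signed_distance_mesh(NumericMatrix V, IntegerMatrix F, int n,
                              double band_layers) {
  const double h = 1.0 / (n - 1);
  const size_t N = (size_t)n * n * n;
  const double band = band_layers * h;
  std::vector<double> d(N, std::numeric_limits<double>::infinity());
  std::vector<char> state(N, 0);

  // exact distances on the near band
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    double a[3] = {V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
    double b[3] = {V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
    double c[3] = {V(F(f,2),0), V(F(f,2),1), V(F(f,2),2)};
    double lo[3], hi[3];
    for (int t = 0; t < 3; ++t) {
      lo[t] = std::min(a[t], std::min(b[t], c[t])) - band;
      hi[t] = std::max(a[t], std::max(b[t], c[t])) + band;
    }
    int i0 = std::max(0, (int)std::ceil(lo[0] / h));
    int i1 = std::min(n - 1, (int)std::floor(hi[0] / h));
    int j0 = std::max(0, (int)std::ceil(lo[1] / h));
    int j1 = std::min(n - 1, (int)std::floor(hi[1] / h));
    int k0 = std::max(0, (int)std::ceil(lo[2] / h));
    int k1 = std::min(n - 1, (int)std::floor(hi[2] / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double p[3] = {i * h, j * h, k * h};
          double dd = std::sqrt(point_triangle_dist2(p, a, b, c));
          int idx = lindex(i, j, k, n);
          if (dd < d[idx]) d[idx] = dd;
        }
  }
  for (size_t q = 0; q < N; ++q)
    if (d[q] <= band) state[q] = 2;  // accepted seeds (exact)
    else d[q] = std::numeric_limits<double>::infinity();

  fast_march(d, state, n, h);

  std::vector<char> inside(N, 0);
  ray_parity(V, F, n, h, inside);

  NumericVector out(N);
  for (size_t q = 0; q < N; ++q) out[q] = inside[q] ? d[q] : -d[q];
  return List::create(_["d"] = out);
}

// Signed distance to the {values == level} isosurface of a nodal field.
// Positive where values > level.
// [[Rcpp::export]]
NumericVector cpp_sdf_from_field(NumericVector values, int n, double level) {
  const double h = 1.0 / (n - 1);
  const size_t N = (size_t)n * n * n;
  std::vector<double> d(N, std::numeric_limits<double>::infinity());
  std::vector<char> state(N, 0);
  const int di[3] = {1, n, n * n};
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        int idx = lindex(i, j, k, n);
        double f0 = values[idx] - level;
        bool iface = false;
        const int ci[3] = {i, j, k};
        double g2 = 0.0;
        for (int ax = 0; ax < 3; ++ax) {
          double fm = (ci[ax] > 0) ? values[idx - di[ax]] - level : f0;
          double fp = (ci[ax] < n - 1) ? values[idx + di[ax]] - level : f0;
          if (f0 == 0.0 || f0 * fm < 0.0 || f0 * fp < 0.0) iface = true;
          double g = (fp - fm) / (2.0 * h);
          g2 += g * g;
        }
        if (iface) {
          double gn = std::sqrt(g2);
          double dd = (gn > 1e-12) ? std::abs(f0) / gn : 0.0;
          d[idx] = std::min(dd, h);  // seed values stay sub-voxel
          state[idx] = 2;
        }
      }
  fast_march(d, state, n, h);
  NumericVector out(N);
  for (size_t q = 0; q < N; ++q) {
    bool in = values[q] > level;
    double dd = std::isfinite(d[q]) ? d[q] : 2.0;  // no interface reached
    out[q] = in ? dd : -dd;
  }
  return out;
}

// ---------------------------------------------------------------------------
// trilinear resampling (value and value+gradient)
// ---------------------------------------------------------------------------
static inline bool locate(double x, double y, double z, int n, double h,
                          int &ci, int &cj, int &ck, double &tx, double &ty,
                          double &tz) {
  // negated form so NaN coordinates are rejected too
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 && x <= 1.0 && y <= 1.0 &&
        z <= 1.0))
    return false;
  ci = std::min((int)(x / h), n - 2);
  cj = std::min((int)(y / h), n - 2);
  ck = std::min((int)(z / h), n - 2);
  tx = x / h - ci;
  ty = y / h - cj;
  tz = z / h - ck;
  return true;
}

static inline double interp_cell(const double *v, int n, int ci, int cj,
                                 int ck, double tx, double ty, double tz,
                                 double *grad, double h) {
  double c[8];
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx)
        c[dx + 2 * dy + 4 * dz] = v[lindex(ci + dx, cj + dy, ck + dz, n)];
  double wx[2] = {1 - tx, tx}, wy[2] = {1 - ty, ty}, wz[2] = {1 - tz, tz};
  double val = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx)
        val += c[dx + 2 * dy + 4 * dz] * wx[dx] * wy[dy] * wz[dz];
  if (grad) {
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double cc = c[dx + 2 * dy + 4 * dz];
          gx += cc * (dx ? 1.0 : -1.0) * wy[dy] * wz[dz];
          gy += cc * wx[dx] * (dy ? 1.0 : -1.0) * wz[dz];
          gz += cc * wx[dx] * wy[dy] * (dz ? 1.0 : -1.0);
        }
    grad[0] = gx / h;
    grad[1] = gy / h;
    grad[2] = gz / h;
  }
  return val;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, int n, NumericMatrix pts,
                           double outside) {
  const double h = 1.0 / (n - 1);
  const int np = pts.nrow();
  NumericVector out(np);
  const double *v = values.begin();
  for (int p = 0; p < np; ++p) {
    int ci, cj, ck;
    double tx, ty, tz;
    if (!locate(pts(p,0), pts(p,1), pts(p,2), n, h, ci, cj, ck, tx, ty, tz)) {
      out[p] = outside;
      continue;
    }
    out[p] = interp_cell(v, n, ci, cj, ck, tx, ty, tz, nullptr, h);
  }
  return out;
}

// ---------------------------------------------------------------------------
// hyperelastic matching objective and gradient
// ---------------------------------------------------------------------------
static inline void cofactor3(const double F[9], double C[9]) {
  C[0] = F[4]*F[8] - F[5]*F[7];
  C[1] = F[5]*F[6] - F[3]*F[8];
  C[2] = F[3]*F[7] - F[4]*F[6];
  C[3] = F[2]*F[7] - F[1]*F[8];
  C[4] = F[0]*F[8] - F[2]*F[6];
  C[5] = F[1]*F[6] - F[0]*F[7];
  C[6] = F[1]*F[5] - F[2]*F[4];
  C[7] = F[2]*F[3] - F[0]*F[5];
  C[8] = F[0]*F[4] - F[1]*F[3];
}

// disp: N x 3 nodal displacements; wcell: (n-1)^3 elastic cell weights
// (cell-averaged reference occupancy); chiref: n^3 (smoothed) reference
// occupancy at nodes; chifix: n^3 (smoothed) target occupancy at nodes.
// Elastic term: cell-center quadrature weighted by wcell. Mismatch term:
// mass-lumped nodal quadrature gamma * sum_nodes h^3 (chiref - chifix o
// phi)^2 with trilinear interpolation of chifix (0 outside the domain).
// Returns the total objective, its parts and the gradient; obj = +Inf with
// barrier = TRUE when det(Dphi) <= 0 on an occupied cell.
// [[Rcpp::export]]
List cpp_match_objgrad(NumericMatrix disp, int n, NumericVector wcell,
                       NumericVector chiref, NumericVector chifix, double mu,
                       double lam, double gamma, bool want_grad) {
  const double h = 1.0 / (n - 1);
  const int nc = n - 1;
  const int N = n * n * n;
  const double vol = h * h * h;
  const double gcoef = 1.0 / (4.0 * h);
  const double *chif = chifix.begin();
  const double *dx0 = disp.begin();           // column-major N x 3
  const double *dy0 = dx0 + N;
  const double *dz0 = dx0 + 2 * N;
  double elastic = 0.0, mismatch = 0.0;
  bool barrier = false;
  NumericMatrix grad;
  double *gx0 = nullptr, *gy0 = nullptr, *gz0 = nullptr;
  if (want_grad) {
    grad = NumericMatrix(disp.nrow(), 3);
    gx0 = grad.begin();
    gy0 = gx0 + N;
    gz0 = gx0 + 2 * N;
  }

  // ---- elastic term over cells ----
  int nodes[8];
  for (int ck = 0; ck < nc && !barrier; ++ck)
    for (int cj = 0; cj < nc && !barrier; ++cj)
      for (int ci = 0; ci < nc; ++ci) {
        int cidx = ci + nc * (cj + nc * ck);
        double w = wcell[cidx];
        if (w <= 0.0) continue;
        double dvert[8][3];
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int a = dx + 2 * dy + 4 * dz;
              nodes[a] = lindex(ci + dx, cj + dy, ck + dz, n);
              dvert[a][0] = dx0[nodes[a]];
              dvert[a][1] = dy0[nodes[a]];
              dvert[a][2] = dz0[nodes[a]];
            }
        double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};  // row-major F[p*3+q]
        for (int a = 0; a < 8; ++a) {
          double sx = (a & 1) ? gcoef : -gcoef;
          double sy = (a & 2) ? gcoef : -gcoef;
          double sz = (a & 4) ? gcoef : -gcoef;
          for (int p = 0; p < 3; ++p) {
            F[p * 3 + 0] += dvert[a][p] * sx;
            F[p * 3 + 1] += dvert[a][p] * sy;
            F[p * 3 + 2] += dvert[a][p] * sz;
          }
        }
        double C[9];
        cofactor3(F, C);
        double det = F[0]*C[0] + F[1]*C[1] + F[2]*C[2];
        if (det <= 1e-10) {
          barrier = true;
          break;
        }
        double nrm2 = 0.0;
        for (int t = 0; t < 9; ++t) nrm2 += F[t] * F[t];
        double W = 0.5 * mu * nrm2 + 0.25 * lam * det * det -
                   (mu + 0.5 * lam) * std::log(det) - 1.5 * mu - 0.25 * lam;
        elastic += w * vol * W;
        if (want_grad) {
          double coefC = 0.5 * lam * det - (mu + 0.5 * lam) / det;
          double P[9];
          for (int t = 0; t < 9; ++t) P[t] = mu * F[t] + coefC * C[t];
          double wv = w * vol;
          for (int a = 0; a < 8; ++a) {
            double sx = (a & 1) ? gcoef : -gcoef;
            double sy = (a & 2) ? gcoef : -gcoef;
            double sz = (a & 4) ? gcoef : -gcoef;
            gx0[nodes[a]] += wv * (P[0] * sx + P[1] * sy + P[2] * sz);
            gy0[nodes[a]] += wv * (P[3] * sx + P[4] * sy + P[5] * sz);
            gz0[nodes[a]] += wv * (P[6] * sx + P[7] * sy + P[8] * sz);
          }
        }
      }

  // ---- mismatch term over nodes ----
  if (!barrier) {
    const double *cr = chiref.begin();
    int idx = 0;
    for (int k = 0; k < n; ++k)
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i, ++idx) {
          double xq = i * h + dx0[idx];
          double yq = j * h + dy0[idx];
          double zq = k * h + dz0[idx];
          int qi, qj, qk;
          double tx, ty, tz;
          double val = 0.0, g[3] = {0, 0, 0};
          if (locate(xq, yq, zq, n, h, qi, qj, qk, tx, ty, tz))
            val = interp_cell(chif, n, qi, qj, qk, tx, ty, tz,
                              want_grad ? g : nullptr, h);
          double r = cr[idx] - val;
          mismatch += gamma * vol * r * r;
          if (want_grad) {
            double cc = gamma * vol * 2.0 * r;
            gx0[idx] -= cc * g[0];
            gy0[idx] -= cc * g[1];
            gz0[idx] -= cc * g[2];
          }
        }
  }

  double obj = barrier ? R_PosInf : elastic + mismatch;
  return List::create(_["obj"] = obj, _["elastic"] = elastic,
                      _["mismatch"] = mismatch, _["grad"] = grad,
                      _["barrier"] = barrier);
}

// objective + gradient evaluation into raw buffers; returns false on barrier
static bool objgrad_raw(const double *x, int n, const double *wcell,
                        const double *chiref, const double *chifix, double mu,
                        double lam, double gamma, double *obj, double *elast,
                        double *mism, double *g) {
  const double h = 1.0 / (n - 1);
  const int nc = n - 1;
  const int N = n * n * n;
  const double vol = h * h * h;
  const double gcoef = 1.0 / (4.0 * h);
  const double *dx0 = x, *dy0 = x + N, *dz0 = x + 2 * N;
  double *gx0 = nullptr, *gy0 = nullptr, *gz0 = nullptr;
  if (g) {
    std::fill(g, g + 3 * N, 0.0);
    gx0 = g;
    gy0 = g + N;
    gz0 = g + 2 * N;
  }
  double elastic = 0.0, mismatch = 0.0;
  int nodes[8];
  for (int ck = 0; ck < nc; ++ck)
    for (int cj = 0; cj < nc; ++cj)
      for (int ci = 0; ci < nc; ++ci) {
        int cidx = ci + nc * (cj + nc * ck);
        double w = wcell[cidx];
        if (w <= 0.0) continue;
        double dvert[8][3];
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dxs = 0; dxs < 2; ++dxs) {
              int a = dxs + 2 * dy + 4 * dz;
              nodes[a] = lindex(ci + dxs, cj + dy, ck + dz, n);
              dvert[a][0] = dx0[nodes[a]];
              dvert[a][1] = dy0[nodes[a]];
              dvert[a][2] = dz0[nodes[a]];
            }
        double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
        for (int a = 0; a < 8; ++a) {
          double sx = (a & 1) ? gcoef : -gcoef;
          double sy = (a & 2) ? gcoef : -gcoef;
          double sz = (a & 4) ? gcoef : -gcoef;
          for (int p = 0; p < 3; ++p) {
            F[p * 3 + 0] += dvert[a][p] * sx;
            F[p * 3 + 1] += dvert[a][p] * sy;
            F[p * 3 + 2] += dvert[a][p] * sz;
          }
        }
        double C[9];
        cofactor3(F, C);
        double det = F[0]*C[0] + F[1]*C[1] + F[2]*C[2];
        if (det <= 1e-10) return false;
        double nrm2 = 0.0;
        for (int t = 0; t < 9; ++t) nrm2 += F[t] * F[t];
        elastic += w * vol *
                   (0.5 * mu * nrm2 + 0.25 * lam * det * det -
                    (mu + 0.5 * lam) * std::log(det) - 1.5 * mu - 0.25 * lam);
        if (g) {
          double coefC = 0.5 * lam * det - (mu + 0.5 * lam) / det;
          double P[9];
          for (int t = 0; t < 9; ++t) P[t] = mu * F[t] + coefC * C[t];
          double wv = w * vol;
          for (int a = 0; a < 8; ++a) {
            double sx = (a & 1) ? gcoef : -gcoef;
            double sy = (a & 2) ? gcoef : -gcoef;
            double sz = (a & 4) ? gcoef : -gcoef;
            gx0[nodes[a]] += wv * (P[0] * sx + P[1] * sy + P[2] * sz);
            gy0[nodes[a]] += wv * (P[3] * sx + P[4] * sy + P[5] * sz);
            gz0[nodes[a]] += wv * (P[6] * sx + P[7] * sy + P[8] * sz);
          }
        }
      }
  int idx = 0;
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i, ++idx) {
        double xq = i * h + dx0[idx];
        double yq = j * h + dy0[idx];
        double zq = k * h + dz0[idx];
        int qi, qj, qk;
        double tx, ty, tz;
        double val = 0.0, gg[3] = {0, 0, 0};
        if (locate(xq, yq, zq, n, h, qi, qj, qk, tx, ty, tz))
          val = interp_cell(chifix, n, qi, qj, qk, tx, ty, tz,
                            g ? gg : nullptr, h);
        double r = chiref[idx] - val;
        mismatch += gamma * vol * r * r;
        if (g) {
          double cc = gamma * vol * 2.0 * r;
          gx0[idx] -= cc * gg[0];
          gy0[idx] -= cc * gg[1];
          gz0[idx] -= cc * gg[2];
        }
      }
  *obj = elastic + mismatch;
  *elast = elastic;
  *mism = mismatch;
  return true;
}

// Full L-BFGS (Armijo backtracking) minimization of the matching objective,
// entirely in compiled code; the barrier (det <= 0) is handled by
// backtracking. Mirrors the R-level contract of match_shapes at one level.
// [[Rcpp::export]]
List cpp_match_lbfgs(NumericMatrix disp0, int n, NumericVector wcell,
                     NumericVector chiref, NumericVector chifix, double mu,
                     double lam, double gamma, int max_iter, double rel_tol,
                     int mem) {
  const int N3 = 3 * n * n * n;
  std::vector<double> x(disp0.begin(), disp0.begin() + N3);
  std::vector<double> gcur(N3), gnew(N3), xn(N3), dir(N3), q(N3);
  std::vector<std::vector<double>> S, Y;
  std::vector<double> rho;
  double f, fe, fm;
  if (!objgrad_raw(x.data(), n, wcell.begin(), chiref.begin(), chifix.begin(),
                   mu, lam, gamma, &f, &fe, &fm, gcur.data()))
    stop("cpp_match_lbfgs: objective not finite at the initial point");
  std::vector<double> trace;
  trace.push_back(f);
  bool converged = false;
  int iters = 0;
  auto dot = [N3](const std::vector<double> &a, const std::vector<double> &b) {
    double s = 0.0;
    for (int i = 0; i < N3; ++i) s += a[i] * b[i];
    return s;
  };
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    // two-loop recursion
    std::copy(gcur.begin(), gcur.end(), q.begin());
    int m = (int)S.size();
    std::vector<double> alpha(m);
    for (int i = m - 1; i >= 0; --i) {
      alpha[i] = rho[i] * dot(S[i], q);
      for (int t = 0; t < N3; ++t) q[t] -= alpha[i] * Y[i][t];
    }
    double t0 = 1.0;
    if (m > 0) {
      double gam = dot(S[m - 1], Y[m - 1]) / dot(Y[m - 1], Y[m - 1]);
      for (int t = 0; t < N3; ++t) q[t] *= gam;
      for (int i = 0; i < m; ++i) {
        double beta = rho[i] * dot(Y[i], q);
        for (int t = 0; t < N3; ++t) q[t] += (alpha[i] - beta) * S[i][t];
      }
      for (int t = 0; t < N3; ++t) dir[t] = -q[t];
    } else {
      double gn = std::sqrt(dot(gcur, gcur));
      t0 = 1.0 / std::max(gn, 1e-12);
      for (int t = 0; t < N3; ++t) dir[t] = -gcur[t];
    }
    double gd = dot(gcur, dir);
    if (gd >= 0.0) {  // restart from steepest descent
      double gn = std::sqrt(dot(gcur, gcur));
      t0 = 1.0 / std::max(gn, 1e-12);
      for (int t = 0; t < N3; ++t) dir[t] = -gcur[t];
      gd = -gn * gn;
      S.clear();
      Y.clear();
      rho.clear();
    }
    double step = t0, fn = f, fen, fmn;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int t = 0; t < N3; ++t) xn[t] = x[t] + step * dir[t];
      if (objgrad_raw(xn.data(), n, wcell.begin(), chiref.begin(),
                      chifix.begin(), mu, lam, gamma, &fn, &fen, &fmn,
                      gnew.data()) &&
          fn <= f + 1e-4 * step * gd) {
        ok = true;
        break;
      }
      step *= 0.5;
    }
    if (!ok) {
      converged = true;
      break;
    }
    // curvature update
    std::vector<double> s(N3), y(N3);
    for (int t = 0; t < N3; ++t) {
      s[t] = xn[t] - x[t];
      y[t] = gnew[t] - gcur[t];
    }
    double sy = dot(s, y);
    if (sy > 1e-12 * std::sqrt(dot(s, s) * dot(y, y))) {
      S.push_back(std::move(s));
      Y.push_back(std::move(y));
      rho.push_back(1.0 / sy);
      if ((int)S.size() > mem) {
        S.erase(S.begin());
        Y.erase(Y.begin());
        rho.erase(rho.begin());
      }
    }
    double dec = f - fn;
    x.swap(xn);
    gcur.swap(gnew);
    f = fn;
    fe = fen;
    fm = fmn;
    trace.push_back(f);
    double gmax = 0.0;
    for (int t = 0; t < N3; ++t) gmax = std::max(gmax, std::abs(gcur[t]));
    if (dec <= rel_tol * std::max(std::abs(f), 1e-4) || gmax <= 1e-9) {
      converged = true;
      break;
    }
  }
  NumericMatrix out(n * n * n, 3);
  std::copy(x.begin(), x.end(), out.begin());
  return List::create(_["disp"] = out, _["obj"] = f, _["elastic"] = fe,
                      _["mismatch"] = fm, _["iterations"] = iters,
                      _["converged"] = converged,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Deformation gradient Dphi = I + Du of the trilinear displacement field at
// arbitrary points; returns np x 9 (row-major F).
// [[Rcpp::export]]
NumericMatrix cpp_def_grad_at(NumericMatrix disp, int n, NumericMatrix pts) {
  const double h = 1.0 / (n - 1);
  const int np = pts.nrow();
  NumericMatrix out(np, 9);
  std::vector<double> comp((size_t)n * n * n);
  // process per component to reuse interp_cell's gradient
  for (int t = 0; t < 3; ++t) {
    for (size_t q = 0; q < comp.size(); ++q) comp[q] = disp(q, t);
    for (int p = 0; p < np; ++p) {
      int ci, cj, ck;
      double tx, ty, tz, g[3];
      double x = std::min(std::max(pts(p,0), 0.0), 1.0);
      double y = std::min(std::max(pts(p,1), 0.0), 1.0);
      double z = std::min(std::max(pts(p,2), 0.0), 1.0);
      locate(x, y, z, n, h, ci, cj, ck, tx, ty, tz);
      interp_cell(comp.data(), n, ci, cj, ck, tx, ty, tz, g, h);
      for (int q = 0; q < 3; ++q)
        out(p, t * 3 + q) = g[q] + (t == q ? 1.0 : 0.0);
    }
  }
  return out;
}

// Approximate preimages x with x + u(x) = y by damped fixed-point iteration.
// [[Rcpp::export]]
NumericMatrix cpp_invert_disp(NumericMatrix disp, int n, NumericMatrix pts,
                              int iters) {
  const double h = 1.0 / (n - 1);
  const int np = pts.nrow();
  NumericMatrix out(np, 3);
  std::vector<double> ux((size_t)n*n*n), uy((size_t)n*n*n), uz((size_t)n*n*n);
  for (size_t q = 0; q < ux.size(); ++q) {
    ux[q] = disp(q, 0);
    uy[q] = disp(q, 1);
    uz[q] = disp(q, 2);
  }
  for (int p = 0; p < np; ++p) {
    double y0 = pts(p, 0), y1 = pts(p, 1), y2 = pts(p, 2);
    double x0 = y0, x1 = y1, x2 = y2;
    for (int it = 0; it < iters; ++it) {
      int ci, cj, ck;
      double tx, ty, tz;
      double cx = std::min(std::max(x0, 0.0), 1.0);
      double cy = std::min(std::max(x1, 0.0), 1.0);
      double cz = std::min(std::max(x2, 0.0), 1.0);
      locate(cx, cy, cz, n, h, ci, cj, ck, tx, ty, tz);
      double vx = interp_cell(ux.data(), n, ci, cj, ck, tx, ty, tz, nullptr, h);
      double vy = interp_cell(uy.data(), n, ci, cj, ck, tx, ty, tz, nullptr, h);
      double vz = interp_cell(uz.data(), n, ci, cj, ck, tx, ty, tz, nullptr, h);
      x0 = y0 - vx;
      x1 = y1 - vy;
      x2 = y2 - vz;
    }
    out(p, 0) = x0;
    out(p, 1) = x1;
    out(p, 2) = x2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// marching tetrahedra on the nodal field {values == level}
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, int n, double level) {
  const double h = 1.0 / (n - 1);
  const double *v = values.begin();
  // each cube split into 6 tets around the main diagonal (0,7)
  static const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                                 {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  std::map<std::pair<int, int>, int> edge_vertex;
  std::vector<double> verts;
  std::vector<int> tris;
  auto edge_point = [&](int ga, int gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    auto key = std::make_pair(ga, gb);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = v[ga] - level, fb = v[gb] - level;
    double t = fa / (fa - fb);
    t = std::min(std::max(t, 0.0), 1.0);
    int ia = ga % n, ja = (ga / n) % n, ka = ga / (n * n);
    int ib = gb % n, jb = (gb / n) % n, kb = gb / (n * n);
    double p[3] = {(ia + t * (ib - ia)) * h, (ja + t * (jb - ja)) * h,
                   (ka + t * (kb - ka)) * h};
    int id = (int)(verts.size() / 3);
    verts.insert(verts.end(), p, p + 3);
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const int *g, const double *f) {
    // orient so the normal points away from the inside (values > level)
    // use the tet vertex signs: normal should point toward the negative side
    tris.push_back(a);
    tris.push_back(b);
    tris.push_back(c);
  };
  (void)emit;
  for (int ck = 0; ck < n - 1; ++ck)
    for (int cj = 0; cj < n - 1; ++cj)
      for (int ci = 0; ci < n - 1; ++ci) {
        int corner[8];
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              corner[dx + 2 * dy + 4 * dz] =
                  lindex(ci + dx, cj + dy, ck + dz, n);
        for (int t = 0; t < 6; ++t) {
          int g[4];
          double f[4];
          int npos = 0;
          for (int q = 0; q < 4; ++q) {
            g[q] = corner[tets[t][q]];
            f[q] = v[g[q]] - level;
            if (f[q] > 0.0) ++npos;
          }
          if (npos == 0 || npos == 4) continue;
          // collect indices of positive (inside) vertices
          int pos[4], neg[4], np_ = 0, nn = 0;
          for (int q = 0; q < 4; ++q)
            (f[q] > 0.0 ? pos[np_++] : neg[nn++]) = q;
          if (npos == 1) {
            int a = edge_point(g[pos[0]], g[neg[0]]);
            int b = edge_point(g[pos[0]], g[neg[1]]);
            int c = edge_point(g[pos[0]], g[neg[2]]);
            tris.push_back(a); tris.push_back(b); tris.push_back(c);
          } else if (npos == 3) {
            int a = edge_point(g[neg[0]], g[pos[0]]);
            int b = edge_point(g[neg[0]], g[pos[1]]);
            int c = edge_point(g[neg[0]], g[pos[2]]);
            tris.push_back(a); tris.push_back(b); tris.push_back(c);
          } else {  // 2-2: quad split into two triangles
            int a = edge_point(g[pos[0]], g[neg[0]]);
            int b = edge_point(g[pos[0]], g[neg[1]]);
            int c = edge_point(g[pos[1]], g[neg[1]]);
            int d = edge_point(g[pos[1]], g[neg[0]]);
            tris.push_back(a); tris.push_back(b); tris.push_back(c);
            tris.push_back(a); tris.push_back(c); tris.push_back(d);
          }
        }
      }
  int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int t = 0; t < 3; ++t) V(i, t) = verts[3 * i + t];
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int t = 0; t < 3; ++t) T(i, t) = tris[3 * i + t];
  // fix orientation: outward normal must oppose the field gradient
  std::vector<double> comp(values.begin(), values.end());
  for (int i = 0; i < nt; ++i) {
    double cx = (V(T(i,0),0) + V(T(i,1),0) + V(T(i,2),0)) / 3.0;
    double cy = (V(T(i,0),1) + V(T(i,1),1) + V(T(i,2),1)) / 3.0;
    double cz = (V(T(i,0),2) + V(T(i,1),2) + V(T(i,2),2)) / 3.0;
    int ci, cj, ck;
    double tx, ty, tz, g[3];
    locate(std::min(std::max(cx, 0.0), 1.0), std::min(std::max(cy, 0.0), 1.0),
           std::min(std::max(cz, 0.0), 1.0), n, h, ci, cj, ck, tx, ty, tz);
    interp_cell(comp.data(), n, ci, cj, ck, tx, ty, tz, g, h);
    double e1[3] = {V(T(i,1),0) - V(T(i,0),0), V(T(i,1),1) - V(T(i,0),1),
                    V(T(i,1),2) - V(T(i,0),2)};
    double e2[3] = {V(T(i,2),0) - V(T(i,0),0), V(T(i,2),1) - V(T(i,0),1),
                    V(T(i,2),2) - V(T(i,0),2)};
    double nx = e1[1]*e2[2] - e1[2]*e2[1];
    double ny = e1[2]*e2[0] - e1[0]*e2[2];
    double nz = e1[0]*e2[1] - e1[1]*e2[0];
    if (nx * g[0] + ny * g[1] + nz * g[2] > 0.0) {
      int tmp = T(i, 1);
      T(i, 1) = T(i, 2);
      T(i, 2) = tmp;
    }
  }
  return List::create(_["vertices"] = V, _["faces"] = T);
}
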