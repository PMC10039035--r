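#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Point-to-triangle squared distance: closest point on triangle by
// Voronoi-region tests (Ericson, Real-Time Collision Detection, 5.1.5).
static double tri_dist2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3], q[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else {
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] + w * ac[i];
            }
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(name = ".cpp_point_mesh_distance")]]
NumericVector cpp_point_mesh_distance(NumericMatrix points,
                                      NumericMatrix verts,
                                      IntegerMatrix faces) {
  int n = points.nrow(), m = faces.nrow();
  NumericVector out(n);
  std::vector<double> P(3 * n), V(3 * verts.nrow());
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) P[3 * i + j] = points(i, j);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = verts(i, j);
  // skip degenerate triangles (zero area)
  std::vector<int> keep;
  keep.reserve(m);
  for (int t = 0; t < m; ++t) {
    const double *a = &V[3 * (faces(t, 0) - 1)];
    const double *b = &V[3 * (faces(t, 1) - 1)];
    const double *c = &V[3 * (faces(t, 2) - 1)];
    double e1[3], e2[3], cr[3];
    for (int j = 0; j < 3; ++j) { e1[j] = b[j] - a[j]; e2[j] = c[j] - a[j]; }
    cr[0] = e1[1] * e2[2] - e1[2] * e2[1];
    cr[1] = e1[2] * e2[0] - e1[0] * e2[2];
    cr[2] = e1[0] * e2[1] - e1[1] * e2[0];
    if (cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2] > 1e-30) keep.push_back(t);
  }
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double *p = &P[3 * i];
    for (size_t kk = 0; kk < keep.size(); ++kk) {
      int t = keep[kk];
      const double *a = &V[3 * (faces(t, 0) - 1)];
      const double *b = &V[3 * (faces(t, 1) - 1)];
      const double *c = &V[3 * (faces(t, 2) - 1)];
      double d2 = tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  out.attr("skipped_triangles") = m - (int)keep.size();
  return out;
}

// Voxelize a closed triangle mesh on a regular grid by vertical-ray
// parity counting: for every (x, y) cell-center column, z-crossings with
// the surface are collected and voxels between crossing pairs are filled.
// [[Rcpp::export(name = ".cpp_voxelize")]]
LogicalVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           NumericVector origin, double h,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = faces.nrow();
  std::vector<std::vector<double> > cross((size_t)nx * ny);
  for (int t = 0; t < m; ++t) {
    double ax = verts(faces(t, 0) - 1, 0), ay = verts(faces(t, 0) - 1, 1),
           az = verts(faces(t, 0) - 1, 2);
    double bx = verts(faces(t, 1) - 1, 0), by = verts(faces(t, 1) - 1, 1),
           bz = verts(faces(t, 1) - 1, 2);
    double cx = verts(faces(t, 2) - 1, 0), cy = verts(faces(t, 2) - 1, 1),
           cz = verts(faces(t, 2) - 1, 2);
    double xmin = std::min(ax, std::min(bx, cx)),
           xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)),
           ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0] - 0.5 * h) / h));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - origin[0] - 0.5 * h) / h));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1] - 0.5 * h) / h));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - origin[1] - 0.5 * h) / h));
    double d = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(d) < 1e-300) continue; // triangle vertical in z
    for (int i = i0; i <= i1; ++i) {
      double px = origin[0] + (i + 0.5) * h;
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + (j + 0.5) * h;
        // barycentric coordinates w.r.t. triangle projected to xy
        double w0 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        double w1 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double z = w0 * az + w1 * bz + w2 * cz;
        cross[(size_t)j * nx + i].push_back(z);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &zs = cross[(size_t)j * nx + i];
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      // merge near-duplicate crossings (edge/vertex grazes)
      std::vector<double> uz;
      for (size_t k = 0; k < zs.size(); ++k) {
        if (uz.empty() || zs[k] - uz.back() > 1e-9) uz.push_back(zs[k]);
      }
      size_t npair = uz.size() / 2;
      for (size_t pr = 0; pr < npair; ++pr) {
        double z0 = uz[2 * pr], z1 = uz[2 * pr + 1];
        int k0 = std::max(0, (int)std::ceil((z0 - origin[2] - 0.5 * h) / h));
        int k1 = std::min(nz - 1,
                          (int)std::floor((z1 - origin[2] - 0.5 * h) / h));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = TRUE;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Boundary-face surface extraction from a filled voxel grid: one quad
// (two triangles) per face between a filled and an empty cell.
// [[Rcpp::export(name = ".cpp_voxel_surface")]]
List cpp_voxel_surface(LogicalVector vox, NumericVector origin, double h,
                       IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return vox[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] != 0;
  };
  // vertex ids on the (nx+1) x (ny+1) x (nz+1) corner lattice
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  std::vector<long long> corner_id((size_t)(nx + 1) * (ny + 1) * (nz + 1), -1);
  auto corner = [&](int i, int j, int k) -> int {
    size_t idx = (size_t)k * (nx + 1) * (ny + 1) + (size_t)j * (nx + 1) + i;
    if (corner_id[idx] < 0) {
      corner_id[idx] = (long long)vx.size();
      vx.push_back(origin[0] + i * h);
      vy.push_back(origin[1] + j * h);
      vz.push_back(origin[2] + k * h);
    }
    return (int)corner_id[idx] + 1; // 1-based
  };
  auto quad = [&](int a, int b, int c, int d) {
    f1.push_back(a); f2.push_back(b); f3.push_back(c);
    f1.push_back(a); f2.push_back(c); f3.push_back(d);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        if (!at(i - 1, j, k)) // -x face, outward normal -x
          quad(corner(i, j, k), corner(i, j, k + 1), corner(i, j + 1, k + 1),
               corner(i, j + 1, k));
        if (!at(i + 1, j, k)) // +x
          quad(corner(i + 1, j, k), corner(i + 1, j + 1, k),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j, k + 1));
        if (!at(i, j - 1, k)) // -y
          quad(corner(i, j, k), corner(i + 1, j, k), corner(i + 1, j, k + 1),
               corner(i, j, k + 1));
        if (!at(i, j + 1, k)) // +y
          quad(corner(i, j + 1, k), corner(i, j + 1, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j + 1, k));
        if (!at(i, j, k - 1)) // -z
          quad(corner(i, j, k), corner(i, j + 1, k), corner(i + 1, j + 1, k),
               corner(i + 1, j, k));
        if (!at(i, j, k + 1)) // +z
          quad(corner(i, j, k + 1), corner(i + 1, j, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i, j + 1, k + 1));
      }
  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  int nf = (int)f1.size();
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f1[i]; F(i, 1) = f2[i]; F(i, 2) = f3[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
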