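// Low-level numerical kernels: trilinear resampling, displacement-field
// inversion, beam-aligned water-equivalent path-length tracing, analytic
// pencil-beam dose evaluation, surface distances and gamma analysis.
//
// Grid convention throughout: column-major R arrays, voxel (i,j,k) has world
// center origin + (i + 0.5) * spacing; `origin` is the corner of the grid.

#include <Rcpp.h>
#include <map>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sample of a scalar volume at continuous voxel-index coordinates
// (gx, gy, gz measured in voxel units relative to voxel centers).
static double sample_trilinear(const double* vol, int nx, int ny, int nz,
                               double gx, double gy, double gz, double fill) {
  if (gx < -0.5 || gy < -0.5 || gz < -0.5 ||
      gx > nx - 0.5 || gy > ny - 0.5 || gz > nz - 0.5) return fill;
  // clamp to the cell range so edge voxels extend half a voxel outwards
  gx = clampd(gx, 0.0, nx - 1.0);
  gy = clampd(gy, 0.0, ny - 1.0);
  gz = clampd(gz, 0.0, nz - 1.0);
  int i0 = (int)std::floor(gx); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
  int j0 = (int)std::floor(gy); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
  int k0 = (int)std::floor(gz); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  int i1 = nx == 1 ? i0 : i0 + 1, j1 = ny == 1 ? j0 : j0 + 1, k1 = nz == 1 ? k0 : k0 + 1;
  size_t sxy = (size_t)nx * ny;
  const double* p = vol;
  double c000 = p[i0 + j0 * (size_t)nx + k0 * sxy];
  double c100 = p[i1 + j0 * (size_t)nx + k0 * sxy];
  double c010 = p[i0 + j1 * (size_t)nx + k0 * sxy];
  double c110 = p[i1 + j1 * (size_t)nx + k0 * sxy];
  double c001 = p[i0 + j0 * (size_t)nx + k1 * sxy];
  double c101 = p[i1 + j0 * (size_t)nx + k1 * sxy];
  double c011 = p[i0 + j1 * (size_t)nx + k1 * sxy];
  double c111 = p[i1 + j1 * (size_t)nx + k1 * sxy];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static double sample_nearest(const double* vol, int nx, int ny, int nz,
                             double gx, double gy, double gz, double fill) {
  int i = (int)std::floor(gx + 0.5), j = (int)std::floor(gy + 0.5), k = (int)std::floor(gz + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return vol[i + j * (size_t)nx + k * (size_t)nx * ny];
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, double fill, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int r = 0; r < n; ++r) {
    double gx = (pts(r, 0) - origin[0]) / spacing[0] - 0.5;
    double gy = (pts(r, 1) - origin[1]) / spacing[1] - 0.5;
    double gz = (pts(r, 2) - origin[2]) / spacing[2] - 0.5;
    out[r] = nearest ? sample_nearest(v, nx, ny, nz, gx, gy, gz, fill)
                     : sample_trilinear(v, nx, ny, nz, gx, gy, gz, fill);
  }
  return out;
}

// Warp a scalar volume by a displacement field given on the same grid:
// out(x) = vol(x + d(x)).  `dvf` is a 4D array (nx, ny, nz, 3) in mm.
// [[Rcpp::export]]
NumericVector cpp_warp_by_dvf(NumericVector vol, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericVector dvf, double fill, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double* v = vol.begin();
  const double* d = dvf.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double wx = origin[0] + (i + 0.5) * spacing[0] + d[idx];
        double wy = origin[1] + (j + 0.5) * spacing[1] + d[idx + nvox];
        double wz = origin[2] + (k + 0.5) * spacing[2] + d[idx + 2 * nvox];
        double gx = (wx - origin[0]) / spacing[0] - 0.5;
        double gy = (wy - origin[1]) / spacing[1] - 0.5;
        double gz = (wz - origin[2]) / spacing[2] - 0.5;
        out[idx] = nearest ? sample_nearest(v, nx, ny, nz, gx, gy, gz, fill)
                           : sample_trilinear(v, nx, ny, nz, gx, gy, gz, fill);
      }
  return out;
}

// Numerically invert a displacement field by fixed-point iteration.
// Input field maps x -> x + d(x); output field u satisfies u(x) = -d(x + u(x)),
// so that x -> x + u(x) is the inverse map.
// [[Rcpp::export]]
NumericVector cpp_invert_dvf(NumericVector dvf, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(3 * nvox);
  const double* d = dvf.begin();
  double* u = out.begin();
  for (int it = 0; it < iters; ++it) {
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          double wx = origin[0] + (i + 0.5) * spacing[0] + u[idx];
          double wy = origin[1] + (j + 0.5) * spacing[1] + u[idx + nvox];
          double wz = origin[2] + (k + 0.5) * spacing[2] + u[idx + 2 * nvox];
          double gx = (wx - origin[0]) / spacing[0] - 0.5;
          double gy = (wy - origin[1]) / spacing[1] - 0.5;
          double gz = (wz - origin[2]) / spacing[2] - 0.5;
          u[idx]            = -sample_trilinear(d,            nx, ny, nz, gx, gy, gz, 0.0);
          u[idx + nvox]     = -sample_trilinear(d + nvox,     nx, ny, nz, gx, gy, gz, 0.0);
          u[idx + 2 * nvox] = -sample_trilinear(d + 2 * nvox, nx, ny, nz, gx, gy, gz, 0.0);
        }
  }
  return out;
}

// Separable Gaussian smoothing of a 3D volume, sigma in voxel units,
// reflecting boundaries.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) { ker[t + rad] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + rad]; }
    for (auto& kv : ker) kv /= sum;
    int n = dims[ax];
    size_t str = strides[ax];
    // iterate over all lines along axis ax
    int n1 = dims[(ax + 1) % 3], n2 = dims[(ax + 2) % 3];
    size_t s1 = strides[(ax + 1) % 3], s2 = strides[(ax + 2) % 3];
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        size_t base = i1 * s1 + i2 * s2;
        for (int p = 0; p < n; ++p) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;          // reflect
            if (q >= n) q = 2 * n - 1 - q;
            if (q < 0) q = 0; if (q >= n) q = n - 1;
            acc += ker[t + rad] * a[base + (size_t)q * str];
          }
          b[base + (size_t)p * str] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Beam-aligned WEPL volume.
//
// Rays are cast parallel to `dir` through a lateral lattice spanned by unit
// vectors e1, e2 centered on `iso`.  The returned array has dimensions
// (n1, n2, nt): lateral coordinates l1 = lat0 + a*lat_spacing (a = 0..n1-1),
// same for l2, and depth samples t = t0 + m*t_spacing along dir (t measured
// from iso, so upstream positions are negative).  Marching step = t_spacing.
// [[Rcpp::export]]
NumericVector cpp_beam_wepl(NumericVector rsp, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector dir, NumericVector e1, NumericVector e2,
                            NumericVector iso,
                            double lat0, double lat_spacing, int n1, int n2,
                            double t0, double t_spacing, int nt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = rsp.begin();
  NumericVector out((size_t)n1 * n2 * nt);
  double* o = out.begin();
  for (int b = 0; b < n2; ++b) {
    double l2 = lat0 + b * lat_spacing;
    for (int a = 0; a < n1; ++a) {
      double l1 = lat0 + a * lat_spacing;
      double px = iso[0] + l1 * e1[0] + l2 * e2[0];
      double py = iso[1] + l1 * e1[1] + l2 * e2[1];
      double pz = iso[2] + l1 * e1[2] + l2 * e2[2];
      double acc = 0;
      size_t base = (size_t)a + (size_t)b * n1;
      for (int m = 0; m < nt; ++m) {
        // midpoint of the marching interval [t_{m-1}, t_m]
        double tm = t0 + (m - 0.5) * t_spacing;
        if (m == 0) {
          o[base] = 0.0;
          continue;
        }
        double qx = px + tm * dir[0], qy = py + tm * dir[1], qz = pz + tm * dir[2];
        double gx = (qx - origin[0]) / spacing[0] - 0.5;
        double gy = (qy - origin[1]) / spacing[1] - 0.5;
        double gz = (qz - origin[2]) / spacing[2] - 0.5;
        double r = sample_trilinear(v, nx, ny, nz, gx, gy, gz, 0.0);
        acc += r * t_spacing;
        o[base + (size_t)m * n1 * n2] = acc;
      }
    }
  }
  return out;
}

// Analytic normalized depth-dose: plateau (logistic shoulder) plus Gaussian
// Bragg peak centered at rp.  Shared by R and C++ through this one definition.
static inline double depth_dose(double z, double rp, double plateau,
                                double plateau_width, double peak_sigma) {
  double g = std::exp(-0.5 * (z - rp) * (z - rp) / (peak_sigma * peak_sigma));
  double s = plateau / (1.0 + std::exp((z - rp) / plateau_width));
  return s + g;
}

// [[Rcpp::export]]
NumericVector cpp_depth_dose(NumericVector z, double rp, double plateau,
                             double plateau_width, double peak_sigma) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = depth_dose(z[i], rp, plateau, plateau_width, peak_sigma);
  return out;
}

// ---------------------------------------------------------------------------
// Dose at arbitrary world points from a multi-beam spot plan.
//
// Scenario handling: `shift` (mm) is added to every evaluation point before
// dose lookup (patient shifted by -shift relative to the beams), and the WEPL
// depth is divided by `range_scale` before entering the depth-dose curve.
//
// beam_* are per-beam geometry rows; `wepls` is a list of beam-aligned WEPL
// arrays from cpp_beam_wepl with shared lattice metadata (lat0, lat_spacing,
// n1, n2, t0, t_spacing, nt).
//
// mode = 0: return total dose vector (length N) given spot `weights`.
// mode = 1: return influence triplets (point index, spot index, dose) for
//           entries exceeding `thresh`.
// [[Rcpp::export]]
List cpp_dose_points(NumericMatrix pts, NumericVector shift,
                     NumericMatrix beam_dir, NumericMatrix beam_e1,
                     NumericMatrix beam_e2, NumericVector iso,
                     List wepls, NumericVector wepl_meta,
                     IntegerVector spot_beam, NumericVector spot_u,
                     NumericVector spot_v, NumericVector spot_r80,
                     NumericVector weights,
                     double range_scale, double sigma0, double ksig,
                     double plateau, double plateau_width, double peak_sigma,
                     double r80_offset, double nsig, int mode, double thresh) {
  int npts = pts.nrow();
  int nbeam = beam_dir.nrow();
  int nspot = spot_beam.size();
  double lat0 = wepl_meta[0], lat_spacing = wepl_meta[1];
  int n1 = (int)wepl_meta[2], n2 = (int)wepl_meta[3];
  double t0 = wepl_meta[4], t_spacing = wepl_meta[5];
  int nt = (int)wepl_meta[6];

  // group spots by beam and bin them laterally so each point only visits
  // spots within the Gaussian cutoff radius
  double r80max = 0;
  for (int s = 0; s < nspot; ++s) if (spot_r80[s] > r80max) r80max = spot_r80[s];
  double sigmax = sigma0 + ksig * (r80max / range_scale) + 1.0;
  double rad = nsig * sigmax;
  const double cell = 25.0;
  int reach = (int)(rad / cell) + 1;
  auto cell_key = [](int cu, int cv) {
    return (long long)(cu + 100000) * 200001LL + (cv + 100000);
  };
  std::vector<std::map<long long, std::vector<int>>> bins(nbeam);
  for (int s = 0; s < nspot; ++s) {
    int cu = (int)std::floor(spot_u[s] / cell);
    int cv = (int)std::floor(spot_v[s] / cell);
    bins[spot_beam[s]][cell_key(cu, cv)].push_back(s);
  }
  std::vector<std::vector<int>> by_beam(nbeam);
  for (int s = 0; s < nspot; ++s) by_beam[spot_beam[s]].push_back(s);

  std::vector<const double*> wp(nbeam);
  for (int b = 0; b < nbeam; ++b) {
    NumericVector w = wepls[b];
    wp[b] = w.begin();
  }

  NumericVector dose(mode == 0 ? npts : 0);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  double distal_cut = 3.5 * peak_sigma;

  for (int r = 0; r < npts; ++r) {
    double qx = pts(r, 0) + shift[0];
    double qy = pts(r, 1) + shift[1];
    double qz = pts(r, 2) + shift[2];
    double acc = 0;
    for (int b = 0; b < nbeam; ++b) {
      if (by_beam[b].empty()) continue;
      double dx = qx - iso[0], dy = qy - iso[1], dz = qz - iso[2];
      double l1 = dx * beam_e1(b, 0) + dy * beam_e1(b, 1) + dz * beam_e1(b, 2);
      double l2 = dx * beam_e2(b, 0) + dy * beam_e2(b, 1) + dz * beam_e2(b, 2);
      double t  = dx * beam_dir(b, 0) + dy * beam_dir(b, 1) + dz * beam_dir(b, 2);
      // lattice coordinates in the WEPL volume
      double ga = (l1 - lat0) / lat_spacing;
      double gb = (l2 - lat0) / lat_spacing;
      double gt = (t - t0) / t_spacing;
      if (ga < 0 || gb < 0 || gt < 0 || ga > n1 - 1 || gb > n2 - 1 || gt > nt - 1)
        continue;
      double W = sample_trilinear(wp[b], n1, n2, nt, ga, gb, gt, 0.0);
      double z = W / range_scale;
      double sig = sigma0 + ksig * (z > 0 ? z : 0);
      double lat_cut2 = nsig * nsig * sig * sig;
      double inv2s2 = 0.5 / (sig * sig);
      int pcu = (int)std::floor(l1 / cell), pcv = (int)std::floor(l2 / cell);
      for (int du = -reach; du <= reach; ++du)
      for (int dv = -reach; dv <= reach; ++dv) {
      auto it = bins[b].find(cell_key(pcu + du, pcv + dv));
      if (it == bins[b].end()) continue;
      for (int sidx : it->second) {
        double du = l1 - spot_u[sidx];
        double dv = l2 - spot_v[sidx];
        double dl2 = du * du + dv * dv;
        if (dl2 > lat_cut2) continue;
        double rp = spot_r80[sidx] - r80_offset;
        if (z > rp + distal_cut) continue;
        double val = depth_dose(z, rp, plateau, plateau_width, peak_sigma) *
                     std::exp(-dl2 * inv2s2);
        if (mode == 0) {
          acc += weights[sidx] * val;
        } else if (val > thresh) {
          ti.push_back(r); tj.push_back(sidx); tx.push_back(val);
        }
      }
      }
    }
    if (mode == 0) dose[r] = acc;
  }
  if (mode == 0) return List::create(_["dose"] = dose);
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// Symmetric mean surface distance between two point sets (rows = points, mm).
// [[Rcpp::export]]
double cpp_msd(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  if (na == 0 || nb == 0) return NA_REAL;
  double sa = 0, sb = 0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    sa += std::sqrt(best);
  }
  for (int j = 0; j < nb; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    sb += std::sqrt(best);
  }
  return 0.5 * (sa / na + sb / nb);
}

// Global-normalization gamma analysis.  For every reference voxel at or above
// `threshold`, search evaluated dose positions within `radius` mm (sampled at
// `step` mm with trilinear interpolation) for min gamma^2; a voxel passes if
// gamma <= 1.  Returns c(n_pass, n_included).
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector eval, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double dta, double dd_abs, double threshold,
                        double radius, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* rv = ref.begin();
  const double* ev = eval.begin();
  // precompute search offsets sorted by distance
  std::vector<double> offs;
  int nr = (int)std::floor(radius / step);
  std::vector<std::array<double, 4>> cand;
  for (int a = -nr; a <= nr; ++a)
    for (int b = -nr; b <= nr; ++b)
      for (int c = -nr; c <= nr; ++c) {
        double ox = a * step, oy = b * step, oz = c * step;
        double d2 = ox * ox + oy * oy + oz * oz;
        if (d2 <= radius * radius)
          cand.push_back({ox, oy, oz, d2});
      }
  std::sort(cand.begin(), cand.end(),
            [](const std::array<double, 4>& p, const std::array<double, 4>& q) {
              return p[3] < q[3];
            });
  long npass = 0, ninc = 0;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double dr = rv[idx];
        if (dr < threshold) continue;
        ++ninc;
        double wx = origin[0] + (i + 0.5) * spacing[0];
        double wy = origin[1] + (j + 0.5) * spacing[1];
        double wz = origin[2] + (k + 0.5) * spacing[2];
        double best = R_PosInf;
        for (const auto& o : cand) {
          double dist_term = o[3] / (dta * dta);
          if (dist_term >= best) break;  // candidates sorted by distance
          double gx = (wx + o[0] - origin[0]) / spacing[0] - 0.5;
          double gy = (wy + o[1] - origin[1]) / spacing[1] - 0.5;
          double gz = (wz + o[2] - origin[2]) / spacing[2] - 0.5;
          double de = sample_trilinear(ev, nx, ny, nz, gx, gy, gz, 0.0);
          double dd = (de - dr) / dd_abs;
          double g2 = dist_term + dd * dd;
          if (g2 < best) best = g2;
          if (best <= 1.0) break;
        }
        if (best <= 1.0) ++npass;
      }
  return NumericVector::create((double)npass, (double)ninc);
}

// Voxels whose 6-neighbourhood mixes inside/outside for a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_mixed_boundary(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny;
  LogicalVector out((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int v = mask[idx];
        bool mixed = false;
        if (i > 0      && mask[idx - 1] != v) mixed = true;
        else if (i < nx - 1 && mask[idx + 1] != v) mixed = true;
        else if (j > 0      && mask[idx - nx] != v) mixed = true;
        else if (j < ny - 1 && mask[idx + nx] != v) mixed = true;
        else if (k > 0      && mask[idx - sxy] != v) mixed = true;
        else if (k < nz - 1 && mask[idx + sxy] != v) mixed = true;
        out[idx] = mixed;
      }
  return out;
}

// y = A x and g = A^T r for a sparse matrix given as raw 1-based triplets;
// avoids building a compressed matrix for the optimizer's stacked influence.
// [[Rcpp::export]]
NumericVector cpp_trip_matvec(IntegerVector ti, IntegerVector tj,
                              NumericVector tx, NumericVector w, int nrow) {
  NumericVector y(nrow);
  R_xlen_t nnz = ti.size();
  for (R_xlen_t k = 0; k < nnz; ++k)
    y[ti[k] - 1] += tx[k] * w[tj[k] - 1];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_trip_tmatvec(IntegerVector ti, IntegerVector tj,
                               NumericVector tx, NumericVector r, int ncol) {
  NumericVector g(ncol);
  R_xlen_t nnz = ti.size();
  for (R_xlen_t k = 0; k < nnz; ++k)
    g[tj[k] - 1] += tx[k] * r[ti[k] - 1];
  return g;
}
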