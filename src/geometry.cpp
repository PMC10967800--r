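#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Deterministic golden-spiral lattice on the unit sphere.
static void spiral_points(int n, std::vector<double> &px,
                          std::vector<double> &py, std::vector<double> &pz) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double ph = ga * k;
    px[k] = r * std::cos(ph);
    py[k] = r * std::sin(ph);
    pz[k] = z;
  }
}

// Shrake-Rupley SASA: fraction of lattice points on each solvent-expanded
// sphere not occluded by any neighbouring expanded sphere.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley_cpp(NumericMatrix xyz, NumericVector radii,
                                     double probe, int npoints) {
  int n = xyz.nrow();
  std::vector<double> px, py, pz;
  spiral_points(npoints, px, py, pz);
  NumericVector area(n);
  // neighbour lists by pairwise prefilter (n is at most a few thousand)
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = xyz(i,0)-xyz(j,0), dy = xyz(i,1)-xyz(j,1), dz = xyz(i,2)-xyz(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      double cut = ri + rj;
      if (d2 < cut * cut) nb.push_back(j);
    }
    int free_pts = 0;
    for (int k = 0; k < npoints; ++k) {
      double qx = xyz(i,0) + ri * px[k];
      double qy = xyz(i,1) + ri * py[k];
      double qz = xyz(i,2) + ri * pz[k];
      bool occl = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = qx - xyz(j,0), dy = qy - xyz(j,1), dz = qz - xyz(j,2);
        if (dx*dx + dy*dy + dz*dz < rj * rj) { occl = true; break; }
      }
      if (!occl) ++free_pts;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double)free_pts / npoints);
  }
  return area;
}

// ---------------------------------------------------------------------------
// Voxel machinery for the solvent-excluded surface (morphological closing).
// ---------------------------------------------------------------------------

struct Grid {
  int nx, ny, nz;
  double h, ox, oy, oz;
  std::vector<double> d; // signed distance to the union of vdW spheres
};

static const double DINF = 1e30;

// Exact signed distance d(x) = min_j(|x - c_j| - r_j), relaxed atom-by-atom
// out to a cutoff beyond which the value is irrelevant (far free space).
static Grid build_distance_grid(NumericMatrix xyz, NumericVector radii,
                                double voxel, double pad, double reach) {
  Grid g;
  int n = xyz.nrow();
  double lox = DINF, loy = DINF, loz = DINF, hix = -DINF, hiy = -DINF, hiz = -DINF;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    lox = std::min(lox, xyz(i,0)); hix = std::max(hix, xyz(i,0));
    loy = std::min(loy, xyz(i,1)); hiy = std::max(hiy, xyz(i,1));
    loz = std::min(loz, xyz(i,2)); hiz = std::max(hiz, xyz(i,2));
    rmax = std::max(rmax, (double)radii[i]);
  }
  double ext = rmax + pad;
  g.h = voxel;
  g.ox = lox - ext; g.oy = loy - ext; g.oz = loz - ext;
  g.nx = (int)std::ceil((hix + ext - g.ox) / voxel) + 1;
  g.ny = (int)std::ceil((hiy + ext - g.oy) / voxel) + 1;
  g.nz = (int)std::ceil((hiz + ext - g.oz) / voxel) + 1;
  g.d.assign((size_t)g.nx * g.ny * g.nz, DINF);
  for (int i = 0; i < n; ++i) {
    double r = radii[i];
    double R = r + reach; // beyond this the voxel keeps DINF (free space)
    int i0 = std::max(0, (int)std::floor((xyz(i,0) - R - g.ox) / voxel));
    int i1 = std::min(g.nx - 1, (int)std::ceil((xyz(i,0) + R - g.ox) / voxel));
    int j0 = std::max(0, (int)std::floor((xyz(i,1) - R - g.oy) / voxel));
    int j1 = std::min(g.ny - 1, (int)std::ceil((xyz(i,1) + R - g.oy) / voxel));
    int k0 = std::max(0, (int)std::floor((xyz(i,2) - R - g.oz) / voxel));
    int k1 = std::min(g.nz - 1, (int)std::ceil((xyz(i,2) + R - g.oz) / voxel));
    for (int a = i0; a <= i1; ++a) {
      double dx = g.ox + a * voxel - xyz(i,0);
      for (int b = j0; b <= j1; ++b) {
        double dy = g.oy + b * voxel - xyz(i,1);
        for (int c = k0; c <= k1; ++c) {
          double dz = g.oz + c * voxel - xyz(i,2);
          double dist = std::sqrt(dx*dx + dy*dy + dz*dz) - r;
          size_t idx = ((size_t)a * g.ny + b) * g.nz + c;
          if (dist < g.d[idx]) g.d[idx] = dist;
        }
      }
    }
  }
  return g;
}

// Solvent-excluded surface = iso-surface {F = probe}, with F(x) the distance
// from x to the allowed probe-centre region {d >= probe}.  Every free voxel y
// near the region boundary carries a margin m(y) = d(y) - probe that is the
// EXACT distance from y to the iso-surface {d = probe} (d is 1-Lipschitz with
// unit gradient towards the nearest atom), so the ball B(y, m(y)) lies wholly
// in the free region and F(x) = min_y (|x - y| - m(y)) to O(voxel^2).
// The area is then read off with a smoothed-delta (co-area) estimator whose
// kernel has a vanishing second moment, cancelling the leading curvature bias.
static double ses_area_from_grid(const Grid &g, double probe) {
  size_t nvox = g.d.size();
  const double CINF = 1e14;
  double h = g.h;
  double band = 1.5 * h;             // boundary layer of free voxels
  double eps = std::min(2.0 * h, 0.75 * probe); // delta-kernel half width
  double reach = probe + eps + h;    // how far F is needed around the boundary
  std::vector<double> F(nvox, CINF);
  int rr = (int)std::ceil(reach / h);
  for (int a = 0; a < g.nx; ++a)
    for (int b = 0; b < g.ny; ++b)
      for (int c = 0; c < g.nz; ++c) {
        size_t idx = ((size_t)a * g.ny + b) * g.nz + c;
        double d = g.d[idx];
        if (d < probe || d >= probe + band) continue; // not a boundary voxel
        double m = d - probe;
        int i0 = std::max(0, a - rr), i1 = std::min(g.nx - 1, a + rr);
        int j0 = std::max(0, b - rr), j1 = std::min(g.ny - 1, b + rr);
        int k0 = std::max(0, c - rr), k1 = std::min(g.nz - 1, c + rr);
        double up = probe + eps + m; // updates above the kernel band are moot
        double up2 = up * up;
        for (int i = i0; i <= i1; ++i) {
          double dx = (i - a) * h;
          for (int j = j0; j <= j1; ++j) {
            double dy = (j - b) * h;
            double dxy2 = dx * dx + dy * dy;
            if (dxy2 > up2) continue;
            for (int k = k0; k <= k1; ++k) {
              double dz = (k - c) * h;
              double dist2 = dxy2 + dz * dz;
              if (dist2 > up2) continue;
              size_t q = ((size_t)i * g.ny + j) * g.nz + k;
              double dq = g.d[q];
              // only voxels that can end up in the kernel band matter:
              // free space sits below it, deep interior above it
              if (dq >= probe || dq < -(eps + h)) continue;
              double val = std::sqrt(dist2) - m;
              if (val < F[q]) F[q] = val;
            }
          }
        }
      }
  double a0 = 9.0 / (8.0 * eps), a2 = 5.0 / 3.0;
  double area = 0.0, h3 = h * h * h;
  for (size_t i = 0; i < nvox; ++i) {
    if (g.d[i] >= probe) continue;   // free space: well below the iso-level
    if (F[i] >= CINF) continue;      // deep interior: well above it
    double phi = F[i] - probe;
    if (phi < -eps || phi > eps) continue;
    double t = phi / eps;
    area += h3 * a0 * (1.0 - a2 * t * t);
  }
  return area;
}

// [[Rcpp::export]]
NumericVector ses_area_cpp(NumericMatrix xyz, NumericVector radii,
                           NumericVector probes, double voxel) {
  double pmax = 0.0;
  for (int i = 0; i < probes.size(); ++i) pmax = std::max(pmax, (double)probes[i]);
  double pad = pmax + 8.0 * voxel;
  Grid g = build_distance_grid(xyz, radii, voxel, pad, pmax + 6.0 * voxel);
  NumericVector out(probes.size());
  for (int i = 0; i < probes.size(); ++i)
    out[i] = ses_area_from_grid(g, probes[i]);
  return out;
}

// van der Waals envelope volume: smoothed Heaviside of the signed distance.
// [[Rcpp::export]]
double volume_cpp(NumericMatrix xyz, NumericVector radii, double voxel) {
  Grid g = build_distance_grid(xyz, radii, voxel, 4.0 * voxel, 3.0 * voxel);
  double eps = voxel, vol = 0.0, h3 = voxel * voxel * voxel;
  for (size_t i = 0; i < g.d.size(); ++i) {
    double t = -g.d[i]; // positive inside
    double w;
    if (t <= -eps) w = 0.0;
    else if (t >= eps) w = 1.0;
    else w = 0.5 * (1.0 + t / eps + std::sin(M_PI * t / eps) / M_PI);
    vol += h3 * w;
  }
  return vol;
}
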