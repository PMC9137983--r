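// Grid site-point detection and ray-cast burial.
//
// A grid point is a candidate site point iff it lies outside every atom's
// vdW radius + probe offset, within `near_cut` of some atom, and its burial
// (fraction of quasi-uniform rays that enter a protein atom within
// `ray_len`) reaches `burial_min`.  Atoms are binned into a uniform cell
// grid so each query touches only nearby atoms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct CellGrid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;

  CellGrid(const NumericMatrix& atoms, double cell_size, double pad)
      : cell(cell_size) {
    double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
    double maxx = R_NegInf, maxy = R_NegInf, maxz = R_NegInf;
    for (int i = 0; i < atoms.nrow(); ++i) {
      minx = std::min(minx, atoms(i, 0)); maxx = std::max(maxx, atoms(i, 0));
      miny = std::min(miny, atoms(i, 1)); maxy = std::max(maxy, atoms(i, 1));
      minz = std::min(minz, atoms(i, 2)); maxz = std::max(maxz, atoms(i, 2));
    }
    ox = minx - pad; oy = miny - pad; oz = minz - pad;
    nx = std::max(1, (int)std::floor((maxx + pad - ox) / cell) + 1);
    ny = std::max(1, (int)std::floor((maxy + pad - oy) / cell) + 1);
    nz = std::max(1, (int)std::floor((maxz + pad - oz) / cell) + 1);
    bins.resize((size_t)nx * ny * nz);
    for (int i = 0; i < atoms.nrow(); ++i) {
      int cx = (int)std::floor((atoms(i, 0) - ox) / cell);
      int cy = (int)std::floor((atoms(i, 1) - oy) / cell);
      int cz = (int)std::floor((atoms(i, 2) - oz) / cell);
      if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz)
        continue;
      bins[(size_t)cx + (size_t)nx * (cy + (size_t)ny * cz)].push_back(i);
    }
  }

  // indices of atoms within `radius` (by cell overlap, superset) of (x,y,z)
  void gather(double x, double y, double z, double radius,
              std::vector<int>& out) const {
    out.clear();
    int lo_x = (int)std::floor((x - radius - ox) / cell);
    int hi_x = (int)std::floor((x + radius - ox) / cell);
    int lo_y = (int)std::floor((y - radius - oy) / cell);
    int hi_y = (int)std::floor((y + radius - oy) / cell);
    int lo_z = (int)std::floor((z - radius - oz) / cell);
    int hi_z = (int)std::floor((z + radius - oz) / cell);
    lo_x = std::max(lo_x, 0); hi_x = std::min(hi_x, nx - 1);
    lo_y = std::max(lo_y, 0); hi_y = std::min(hi_y, ny - 1);
    lo_z = std::max(lo_z, 0); hi_z = std::min(hi_z, nz - 1);
    for (int cz = lo_z; cz <= hi_z; ++cz)
      for (int cy = lo_y; cy <= hi_y; ++cy)
        for (int cx = lo_x; cx <= hi_x; ++cx) {
          const std::vector<int>& b =
              bins[(size_t)cx + (size_t)nx * (cy + (size_t)ny * cz)];
          out.insert(out.end(), b.begin(), b.end());
        }
  }
};

// rays: m x 3 unit vectors; returns number of rays hitting an atom within
// ray_len, and fills `open_mask` (length m, 1 = unobstructed).  The atom
// list is pre-sorted by distance so buried points exit each ray early.
int ray_hits(double px, double py, double pz, const NumericMatrix& atoms,
             const NumericVector& radii, std::vector<int>& near,
             const NumericMatrix& rays, double ray_len,
             std::vector<unsigned char>& open_mask) {
  std::sort(near.begin(), near.end(), [&](int a, int b) {
    double da = (atoms(a, 0) - px) * (atoms(a, 0) - px) +
                (atoms(a, 1) - py) * (atoms(a, 1) - py) +
                (atoms(a, 2) - pz) * (atoms(a, 2) - pz);
    double db = (atoms(b, 0) - px) * (atoms(b, 0) - px) +
                (atoms(b, 1) - py) * (atoms(b, 1) - py) +
                (atoms(b, 2) - pz) * (atoms(b, 2) - pz);
    return da < db;
  });
  int m = rays.nrow();
  int hits = 0;
  for (int r = 0; r < m; ++r) {
    double dx = rays(r, 0), dy = rays(r, 1), dz = rays(r, 2);
    bool hit = false;
    for (size_t k = 0; k < near.size() && !hit; ++k) {
      int a = near[k];
      double ax = atoms(a, 0) - px, ay = atoms(a, 1) - py,
             az = atoms(a, 2) - pz;
      double t = ax * dx + ay * dy + az * dz;
      if (t <= 0) continue;
      double d2 = ax * ax + ay * ay + az * az;
      double perp2 = d2 - t * t;
      double r2 = radii[a] * radii[a];
      if (perp2 > r2) continue;
      double entry = t - std::sqrt(r2 - perp2);
      if (entry <= ray_len) hit = true;
    }
    open_mask[r] = hit ? 0 : 1;
    if (hit) ++hits;
  }
  return hits;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_find_site_points")]]
List cpp_find_site_points(NumericMatrix atoms, NumericVector radii,
                          NumericVector origin, double spacing,
                          IntegerVector dims, double probe_offset,
                          double near_cut, double burial_min,
                          NumericMatrix rays, double ray_len) {
  double max_r = 0;
  for (int i = 0; i < radii.size(); ++i) max_r = std::max(max_r, radii[i]);
  CellGrid grid(atoms, 4.0, ray_len + max_r + 1.0);
  double excl_reach = max_r + probe_offset;
  double prox_reach = std::max(near_cut, excl_reach);
  int m = rays.nrow();

  std::vector<double> keep_x, keep_y, keep_z, keep_burial;
  std::vector<int> keep_ix, keep_iy, keep_iz;
  std::vector<unsigned char> masks;
  std::vector<int> near, near_far;
  std::vector<unsigned char> open_mask(m);

  for (int iz = 0; iz < dims[2]; ++iz) {
    double pz = origin[2] + iz * spacing;
    for (int iy = 0; iy < dims[1]; ++iy) {
      double py = origin[1] + iy * spacing;
      for (int ix = 0; ix < dims[0]; ++ix) {
        double px = origin[0] + ix * spacing;
        grid.gather(px, py, pz, prox_reach, near);
        bool near_atom = false, clash = false;
        for (size_t k = 0; k < near.size(); ++k) {
          int a = near[k];
          double dx = atoms(a, 0) - px, dy = atoms(a, 1) - py,
                 dz = atoms(a, 2) - pz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d <= radii[a] + probe_offset) { clash = true; break; }
          if (d <= near_cut) near_atom = true;
        }
        if (clash || !near_atom) continue;
        grid.gather(px, py, pz, ray_len + max_r, near_far);
        int hits = ray_hits(px, py, pz, atoms, radii, near_far, rays,
                            ray_len, open_mask);
        double burial = (double)hits / m;
        if (burial < burial_min) continue;
        keep_x.push_back(px); keep_y.push_back(py); keep_z.push_back(pz);
        keep_ix.push_back(ix); keep_iy.push_back(iy); keep_iz.push_back(iz);
        keep_burial.push_back(burial);
        masks.insert(masks.end(), open_mask.begin(), open_mask.end());
      }
    }
  }

  int n = (int)keep_x.size();
  NumericMatrix coords(n, 3);
  IntegerMatrix index(n, 3);
  NumericVector burial(n);
  LogicalMatrix open(n, m);
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = keep_x[i]; coords(i, 1) = keep_y[i]; coords(i, 2) = keep_z[i];
    index(i, 0) = keep_ix[i]; index(i, 1) = keep_iy[i]; index(i, 2) = keep_iz[i];
    burial[i] = keep_burial[i];
    for (int r = 0; r < m; ++r) open(i, r) = masks[(size_t)i * m + r];
  }
  return List::create(_["coords"] = coords, _["index"] = index,
                      _["burial"] = burial, _["open"] = open);
}

// [[Rcpp::export(name = ".cpp_burial")]]
List cpp_burial(NumericMatrix points, NumericMatrix atoms,
                NumericVector radii, NumericMatrix rays, double ray_len) {
  double max_r = 0;
  for (int i = 0; i < radii.size(); ++i) max_r = std::max(max_r, radii[i]);
  CellGrid grid(atoms, 4.0, ray_len + max_r + 1.0);
  int n = points.nrow(), m = rays.nrow();
  NumericVector burial(n);
  LogicalMatrix open(n, m);
  std::vector<int> near;
  std::vector<unsigned char> open_mask(m);
  for (int i = 0; i < n; ++i) {
    grid.gather(points(i, 0), points(i, 1), points(i, 2), ray_len + max_r,
                near);
    int hits = ray_hits(points(i, 0), points(i, 1), points(i, 2), atoms,
                        radii, near, rays, ray_len, open_mask);
    burial[i] = (double)hits / m;
    for (int r = 0; r < m; ++r) open(i, r) = open_mask[r];
  }
  return List::create(_["burial"] = burial, _["open"] = open);
}
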