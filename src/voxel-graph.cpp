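// Voxel-grid primitives used by the 3D morphometry code:
//  - 26-connected component labelling of a binary mask
//  - CSR adjacency graph over foreground voxels with physical edge weights
//  - multi-source Dijkstra on that graph
//  - surface-area estimation from exposed voxel faces with normal correction
//
// All arrays are column-major (R order); linear index = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long long)ny * z);
}

// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            int w = lin(xx, yy, zz, nx, ny);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Foreground adjacency as CSR. Returns:
//   fg   : 1-based linear grid indices of foreground voxels (length m)
//   ptr  : 1-based CSR row pointers (length m + 1)
//   nbr  : 1-based foreground-position indices of neighbours
//   wt   : physical edge lengths (um)
//   boundary: 1-based fg positions of voxels with a 6-neighbour outside the mask
// [[Rcpp::export]]
List mask_csr(LogicalVector mask, IntegerVector dims, NumericVector voxel_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  const R_xlen_t n = mask.size();

  std::vector<int> fgpos(n, -1);
  std::vector<int> fg;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { fgpos[i] = (int)fg.size(); fg.push_back((int)i); }
  const int m = (int)fg.size();

  // precompute the 26 offsets and their physical lengths
  int offs[26][3]; double olen[26]; int no = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs[no][0] = dx; offs[no][1] = dy; offs[no][2] = dz;
        olen[no] = std::sqrt(dx*dx*vx*vx + dy*dy*vy*vy + dz*dz*vz*vz);
        ++no;
      }

  IntegerVector ptr(m + 1);
  std::vector<int> nbr; nbr.reserve((size_t)m * 13);
  std::vector<double> wt; wt.reserve((size_t)m * 13);
  std::vector<int> boundary;

  for (int p = 0; p < m; ++p) {
    int v = fg[p];
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    bool is_boundary =
      x == 0 || x == nx - 1 || y == 0 || y == ny - 1 || z == 0 || z == nz - 1;
    if (!is_boundary) {
      if (!mask[lin(x-1,y,z,nx,ny)] || !mask[lin(x+1,y,z,nx,ny)] ||
          !mask[lin(x,y-1,z,nx,ny)] || !mask[lin(x,y+1,z,nx,ny)] ||
          !mask[lin(x,y,z-1,nx,ny)] || !mask[lin(x,y,z+1,nx,ny)])
        is_boundary = true;
    }
    if (is_boundary) boundary.push_back(p + 1);
    for (int o = 0; o < no; ++o) {
      int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      int q = fgpos[lin(xx, yy, zz, nx, ny)];
      if (q >= 0) { nbr.push_back(q + 1); wt.push_back(olen[o]); }
    }
    ptr[p + 1] = (int)nbr.size();
  }
  // ptr[p] currently holds the number of entries in rows 0..p-1; shift to
  // 1-based start pointers (row p occupies entries [ptr[p], ptr[p+1]) - 1).
  for (int p = 0; p <= m; ++p) ptr[p] = ptr[p] + 1;

  IntegerVector fg_r(m);
  for (int p = 0; p < m; ++p) fg_r[p] = fg[p] + 1;
  return List::create(_["fg"] = fg_r,
                      _["ptr"] = ptr,
                      _["nbr"] = IntegerVector(nbr.begin(), nbr.end()),
                      _["wt"] = NumericVector(wt.begin(), wt.end()),
                      _["boundary"] = IntegerVector(boundary.begin(), boundary.end()),
                      _["dims"] = dims,
                      _["voxel_size"] = voxel_size);
}

// Multi-source Dijkstra over the CSR graph; sources are 1-based fg positions.
// Returns dist (um) and 1-based parent fg positions (0 for roots/unreached).
// [[Rcpp::export]]
List csr_dijkstra(List g, IntegerVector sources) {
  IntegerVector ptr = g["ptr"], nbr = g["nbr"];
  NumericVector wt = g["wt"];
  const int m = ptr.size() - 1;
  NumericVector dist(m, R_PosInf);
  IntegerVector parent(m, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i] - 1;
    if (dist[s] > 0.0) { dist[s] = 0.0; pq.push(QE(0.0, s)); }
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    for (int k = ptr[v] - 1; k < ptr[v + 1] - 1; ++k) {
      int w = nbr[k] - 1;
      double nd = d + wt[k];
      if (nd < dist[w]) {
        dist[w] = nd;
        parent[w] = v + 1;
        pq.push(QE(nd, w));
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

static void gaussian_smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                                 int axis, double sigma_vox) {
  if (sigma_vox <= 0) return;
  int r = (int)std::ceil(2.5 * sigma_vox);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  std::vector<double> out(a.size());
  int strides[3] = {1, nx, nx * ny};
  int dims[3] = {nx, ny, nz};
  int st = strides[axis], nd = dims[axis];
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        long long base = lin(x, y, z, nx, ny);
        for (int i = 0; i < nd; ++i) {
          double acc = 0;
          for (int j = -r; j <= r; ++j) {
            int ij = i + j;
            if (ij < 0) ij = 0; else if (ij >= nd) ij = nd - 1;
            acc += k[j + r] * a[base + (long long)ij * st];
          }
          out[base + (long long)i * st] = acc;
        }
      }
  a.swap(out);
}

// Surface area of the 0.5 isosurface of a binary mask, estimated by summing
// exposed voxel faces weighted by 1/(|nx|+|ny|+|nz|) where n is the unit
// surface normal from the gradient of a Gaussian-smoothed copy of the mask.
// Exact for axis-aligned boxes; converges to the true area for smooth shapes.
// [[Rcpp::export]]
double surface_area_mask(LogicalVector mask, IntegerVector dims,
                         NumericVector voxel_size, double sigma_um) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  std::vector<double> f(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) f[i] = mask[i] ? 1.0 : 0.0;
  gaussian_smooth_axis(f, nx, ny, nz, 0, sigma_um / vx);
  gaussian_smooth_axis(f, nx, ny, nz, 1, sigma_um / vy);
  gaussian_smooth_axis(f, nx, ny, nz, 2, sigma_um / vz);

  const double face_area[3] = {vy * vz, vx * vz, vx * vy};
  double area = 0;

  // gradient (physical units) at voxel (x,y,z), clamped at borders
  auto grad = [&](int x, int y, int z, double g[3]) {
    int xm = x > 0 ? x - 1 : x, xp = x < nx - 1 ? x + 1 : x;
    int ym = y > 0 ? y - 1 : y, yp = y < ny - 1 ? y + 1 : y;
    int zm = z > 0 ? z - 1 : z, zp = z < nz - 1 ? z + 1 : z;
    g[0] = (f[lin(xp,y,z,nx,ny)] - f[lin(xm,y,z,nx,ny)]) / ((xp - xm) * vx);
    g[1] = (f[lin(x,yp,z,nx,ny)] - f[lin(x,ym,z,nx,ny)]) / ((yp - ym) * vy);
    g[2] = (f[lin(x,y,zp,nx,ny)] - f[lin(x,y,zm,nx,ny)]) / ((zp - zm) * vz);
  };

  const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[lin(x, y, z, nx, ny)]) continue;
        for (int o = 0; o < 6; ++o) {
          int xx = x + d6[o][0], yy = y + d6[o][1], zz = z + d6[o][2];
          bool outside = xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                         zz < 0 || zz >= nz;
          if (!outside && mask[lin(xx, yy, zz, nx, ny)]) continue;
          double g1[3], g2[3];
          grad(x, y, z, g1);
          if (!outside) grad(xx, yy, zz, g2);
          else { g2[0] = g1[0]; g2[1] = g1[1]; g2[2] = g1[2]; }
          double gx = 0.5 * (g1[0] + g2[0]);
          double gy = 0.5 * (g1[1] + g2[1]);
          double gz = 0.5 * (g1[2] + g2[2]);
          double norm = std::sqrt(gx * gx + gy * gy + gz * gz);
          double w;
          if (norm < 1e-12) {
            w = 1.0;  // isolated voxel or flat field: face-aligned normal
          } else {
            double l1 = (std::fabs(gx) + std::fabs(gy) + std::fabs(gz)) / norm;
            w = 1.0 / l1;
          }
          area += w * face_area[o / 2];
        }
      }
  return area;
}
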