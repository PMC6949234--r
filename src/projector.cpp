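#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Distance-driven cone-beam projector core.
//
// Conventions (shared with the R layer):
//   - right-handed frame, detector plane at Z = 0, X along detector columns,
//     Y along the source motion, Z up toward the source;
//   - cells are half-open boxes [corner, corner + pitch): zero-length overlaps
//     contribute nothing;
//   - the footprint of a detector pixel on slice k is the central projection
//     of the pixel's X/Y boundaries from the source onto the slice mid-plane;
//   - a voxel's weight is the fractional footprint overlap times dz / cos(phi),
//     phi being the angle between the central pixel ray and the Z axis, so
//     weights are effective intersection path lengths in mm and A x is a
//     Beer-Lambert line integral;
//   - all arithmetic double precision, fixed loop order, single thread:
//     repeated calls are bitwise reproducible.
//
// Geometry is passed packed as a 13-vector:
//   [0..2]  source position (sx, sy, sz)
//   [3..4]  detector origin (corner of pixel (0,0)): x, y
//   [5..6]  detector pitch: x (columns), y (rows)
//   [7..9]  volume grid origin (gx, gy, gz)
//   [10..12] voxel pitch (dx, dy, dz)
// dims is (Nx, Ny, Nz); detector shape (nrow = n_y, ncol = n_x).

struct Geo {
  double sx, sy, sz;
  double dox, doy, px, py;
  double gx, gy, gz, dx, dy, dz;
  int Nx, Ny, Nz;
};

static Geo unpack(const NumericVector& g, const IntegerVector& dims) {
  Geo geo;
  geo.sx = g[0]; geo.sy = g[1]; geo.sz = g[2];
  geo.dox = g[3]; geo.doy = g[4]; geo.px = g[5]; geo.py = g[6];
  geo.gx = g[7]; geo.gy = g[8]; geo.gz = g[9];
  geo.dx = g[10]; geo.dy = g[11]; geo.dz = g[12];
  geo.Nx = dims[0]; geo.Ny = dims[1]; geo.Nz = dims[2];
  return geo;
}

// Visit every voxel the (row, col) pixel's beam touches in slices [k0, k1),
// calling fn(flat_index, weight). Weight semantics as described above.
template <typename F>
static inline void dd_pixel(const Geo& g, int row, int col, int k0, int k1,
                            F fn) {
  const double xlo = g.dox + col * g.px, xhi = xlo + g.px;
  const double ylo = g.doy + row * g.py, yhi = ylo + g.py;
  const double pcx = 0.5 * (xlo + xhi), pcy = 0.5 * (ylo + yhi);
  const double rx = pcx - g.sx, ry = pcy - g.sy;
  const double cosphi = g.sz / std::sqrt(rx * rx + ry * ry + g.sz * g.sz);

  for (int k = k0; k < k1; ++k) {
    const double z = g.gz + (k + 0.5) * g.dz;
    if (z >= g.sz)
      stop("degenerate geometry: slice mid-plane at or above the source");
    const double t = (g.sz - z) / g.sz;  // detector -> slice scaling factor
    const double X0 = g.sx + t * (xlo - g.sx), X1 = g.sx + t * (xhi - g.sx);
    const double Y0 = g.sy + t * (ylo - g.sy), Y1 = g.sy + t * (yhi - g.sy);
    const double fw = X1 - X0, fh = Y1 - Y0;
    if (fw <= 0.0 || fh <= 0.0) continue;
    const double wslab = (g.dz / cosphi) / (fw * fh);

    int i0 = (int)std::floor((X0 - g.gx) / g.dx);
    int i1 = (int)std::floor((X1 - g.gx) / g.dx);
    int j0 = (int)std::floor((Y0 - g.gy) / g.dy);
    int j1 = (int)std::floor((Y1 - g.gy) / g.dy);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 > g.Nx - 1) i1 = g.Nx - 1;
    if (j1 > g.Ny - 1) j1 = g.Ny - 1;
    if (i0 > i1 || j0 > j1) continue;

    for (int j = j0; j <= j1; ++j) {
      const double vy0 = g.gy + j * g.dy, vy1 = vy0 + g.dy;
      const double oy = std::min(Y1, vy1) - std::max(Y0, vy0);
      if (oy <= 0.0) continue;
      for (int i = i0; i <= i1; ++i) {
        const double vx0 = g.gx + i * g.dx, vx1 = vx0 + g.dx;
        const double ox = std::min(X1, vx1) - std::max(X0, vx0);
        if (ox <= 0.0) continue;
        const double w = ox * oy * wslab;
        if (w > 0.0)
          fn((size_t)i + (size_t)g.Nx * ((size_t)j + (size_t)g.Ny * (size_t)k),
             w);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_dd_row(NumericVector geo, IntegerVector dims, int row, int col,
                int k0, int k1) {
  Geo g = unpack(geo, dims);
  std::vector<double> idx, w;
  dd_pixel(g, row, col, k0, k1, [&](size_t j, double wj) {
    idx.push_back((double)j);
    w.push_back(wj);
  });
  return List::create(_["indices"] = wrap(idx), _["weights"] = wrap(w));
}

// Forward projection of one angle over slices [k0, k1): returns n_y x n_x.
// [[Rcpp::export]]
NumericMatrix cpp_forward_angle(NumericVector vol, NumericVector geo,
                                IntegerVector dims, int nrow, int ncol,
                                int k0, int k1) {
  Geo g = unpack(geo, dims);
  if ((size_t)vol.size() != (size_t)g.Nx * g.Ny * g.Nz)
    stop("volume size does not match grid dims");
  NumericMatrix out(nrow, ncol);
  const double* v = vol.begin();
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r) {
      double acc = 0.0;
      dd_pixel(g, r, c, k0, k1,
               [&](size_t j, double wj) { acc += wj * v[j]; });
      out(r, c) = acc;
    }
  return out;
}

// Backward projection (adjoint) of one angle over slices [k0, k1):
// accumulates A^T r into a full-size volume vector (zeros outside [k0, k1)).
// [[Rcpp::export]]
NumericVector cpp_back_angle(NumericMatrix proj, NumericVector geo,
                             IntegerVector dims, int k0, int k1) {
  Geo g = unpack(geo, dims);
  NumericVector out((size_t)g.Nx * g.Ny * g.Nz);
  double* v = out.begin();
  const int nrow = proj.nrow(), ncol = proj.ncol();
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r) {
      const double val = proj(r, c);
      if (val == 0.0) continue;
      dd_pixel(g, r, c, k0, k1,
               [&](size_t j, double wj) { v[j] += wj * val; });
    }
  return out;
}

// Count of nonzero system-matrix entries for one angle (for density checks).
// [[Rcpp::export]]
double cpp_nnz_angle(NumericVector geo, IntegerVector dims, int nrow,
                     int ncol) {
  Geo g = unpack(geo, dims);
  double nnz = 0.0;
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r)
      dd_pixel(g, r, c, 0, g.Nz, [&](size_t, double) { nnz += 1.0; });
  return nnz;
}
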