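#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Catmull-Rom cubic kernel weights for fractional offset u in [0,1).
// Interpolating (exact at nodes): u = 0 gives weights (0, 1, 0, 0).
static inline void cubic_weights(double u, double w[4]) {
  w[0] = ((-0.5 * u + 1.0) * u - 0.5) * u;
  w[1] = ((1.5 * u - 2.5) * u) * u + 1.0;
  w[2] = ((-1.5 * u + 2.0) * u + 0.5) * u;
  w[3] = ((0.5 * u - 0.5) * u) * u;
}

static inline double get0(const double* v, int nx, int ny, int nz,
                          int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Sample vol at continuous voxel index (x,y,z); zero outside the grid.
static double sample(const double* v, int nx, int ny, int nz,
                     double x, double y, double z, int order) {
  if (order == 0) {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    return get0(v, nx, ny, nz, i, j, k);
  }
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double ux = x - ix, uy = y - iy, uz = z - iz;
  if (order == 1) {
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      double wz = dk ? uz : 1.0 - uz;
      for (int dj = 0; dj <= 1; ++dj) {
        double wy = dj ? uy : 1.0 - uy;
        for (int di = 0; di <= 1; ++di) {
          double wx = di ? ux : 1.0 - ux;
          double w = wx * wy * wz;
          if (w != 0.0) acc += w * get0(v, nx, ny, nz, ix + di, iy + dj, iz + dk);
        }
      }
    }
    return acc;
  }
  // cubic (Catmull-Rom), zero-padded support
  double wx[4], wy[4], wz[4];
  cubic_weights(ux, wx);
  cubic_weights(uy, wy);
  cubic_weights(uz, wz);
  double acc = 0.0;
  if (ix >= 1 && iy >= 1 && iz >= 1 &&
      ix + 2 < nx && iy + 2 < ny && iz + 2 < nz) {
    // fast path: 4x4x4 neighborhood fully interior, no bounds checks
    const double* base = v + (ix - 1) +
      (size_t)nx * ((iy - 1) + (size_t)ny * (iz - 1));
    for (int dk = 0; dk < 4; ++dk) {
      double accj = 0.0;
      const double* pk = base + (size_t)nx * ny * dk;
      for (int dj = 0; dj < 4; ++dj) {
        const double* pj = pk + (size_t)nx * dj;
        accj += wy[dj] * (wx[0] * pj[0] + wx[1] * pj[1] +
                          wx[2] * pj[2] + wx[3] * pj[3]);
      }
      acc += wz[dk] * accj;
    }
    return acc;
  }
  if (ix < -4 || iy < -4 || iz < -4 || ix > nx + 2 || iy > ny + 2 ||
      iz > nz + 2)
    return 0.0;
  for (int dk = 0; dk < 4; ++dk) {
    if (wz[dk] == 0.0) continue;
    double accj = 0.0;
    for (int dj = 0; dj < 4; ++dj) {
      if (wy[dj] == 0.0) continue;
      double acci = 0.0;
      for (int di = 0; di < 4; ++di) {
        if (wx[di] == 0.0) continue;
        acci += wx[di] * get0(v, nx, ny, nz, ix - 1 + di, iy - 1 + dj, iz - 1 + dk);
      }
      accj += wy[dj] * acci;
    }
    acc += wz[dk] * accj;
  }
  return acc;
}

// Rigid-body warp of a 3-D volume.
//
// params = (Rx, Ry, Rz [deg], Tx, Ty, Tz [mm]) describe the MOVEMENT of the
// volume: a point at physical position p (mm, relative to the grid centre)
// moves to R p + t with R = Rx %*% Ry %*% Rz. The output image therefore
// samples the input at R^{-1}(p - t). With invert = true the inverse rigid
// transform is applied instead (used to resample a moved volume back onto
// the reference grid). Out-of-field voxels are 0.
// [[Rcpp::export]]
NumericVector cpp_rigid_warp(NumericVector vol, IntegerVector dims,
                             NumericVector voxel_size, NumericVector params,
                             bool invert, int interp_order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double d2r = M_PI / 180.0;
  double ax = params[0] * d2r, ay = params[1] * d2r, az = params[2] * d2r;
  double tx = params[3], ty = params[4], tz = params[5];
  double cx = std::cos(ax), sx = std::sin(ax);
  double cy = std::cos(ay), sy = std::sin(ay);
  double cz = std::cos(az), sz = std::sin(az);
  // R = Rx * Ry * Rz (row-major entries)
  double R[3][3] = {
    { cy * cz,                 -cy * sz,                 sy      },
    { cx * sz + sx * sy * cz,   cx * cz - sx * sy * sz, -sx * cy },
    { sx * sz - cx * sy * cz,   sx * cz + cx * sy * sz,  cx * cy }
  };
  // mapping from output position p to source position q:
  //   forward movement: q = R^T (p - t)   (R^{-1} = R^T)
  //   invert:           q = R p + t
  double M[3][3], off[3];
  if (!invert) {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) M[r][c] = R[c][r];
    off[0] = -(M[0][0] * tx + M[0][1] * ty + M[0][2] * tz);
    off[1] = -(M[1][0] * tx + M[1][1] * ty + M[1][2] * tz);
    off[2] = -(M[2][0] * tx + M[2][1] * ty + M[2][2] * tz);
  } else {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) M[r][c] = R[r][c];
    off[0] = tx; off[1] = ty; off[2] = tz;
  }
  double ccx = 0.5 * (nx - 1), ccy = 0.5 * (ny - 1), ccz = 0.5 * (nz - 1);
  double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  NumericVector out(vol.size());
  const double* src = vol.begin();
  double* dst = out.begin();
  for (int k = 0; k < nz; ++k) {
    double pz = (k - ccz) * vz;
    for (int j = 0; j < ny; ++j) {
      double py = (j - ccy) * vy;
      for (int i = 0; i < nx; ++i) {
        double px = (i - ccx) * vx;
        double qx = M[0][0] * px + M[0][1] * py + M[0][2] * pz + off[0];
        double qy = M[1][0] * px + M[1][1] * py + M[1][2] * pz + off[1];
        double qz = M[2][0] * px + M[2][1] * py + M[2][2] * pz + off[2];
        dst[i + (size_t)nx * (j + (size_t)ny * k)] =
          sample(src, nx, ny, nz, qx / vx + ccx, qy / vy + ccy, qz / vz + ccz,
                 interp_order);
      }
    }
  }
  return out;
}

// 6-connected component labelling of a 3-D logical mask.
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  const int dx[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, 1, -1 };
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t t = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
      }
    }
  }
  return lab;
}
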