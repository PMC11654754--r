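#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Trilinear sample of vol at grid coordinates (gx, gy, gz); outside -> 0.
static inline double trilinear(const double *vol, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
  if (gx <= -1.0 || gy <= -1.0 || gz <= -1.0 ||
      gx >= nx || gy >= ny || gz >= nz) return 0.0;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
      iz = (int)std::floor(gz);
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int z = iz + dz;
    if (z < 0 || z >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int y = iy + dy;
      if (y < 0 || y >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int x = ix + dx;
        if (x < 0 || x >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * vol[x + nx * (y + (R_xlen_t)ny * z)];
      }
    }
  }
  return acc;
}

// Line integral of vol from point s to point d (world mm), sampled at
// midpoints with step <= `step` inside the volume bounding box.
static double ray_integral(const double *vol, int nx, int ny, int nz,
                           const double *vox, const double *orig,
                           const double *s, const double *d, double step) {
  double dir[3], lo, hi, t0 = 0.0, t1 = 1.0;
  for (int k = 0; k < 3; ++k) dir[k] = d[k] - s[k];
  // clip to the full support of the trilinear interpolant (one voxel
  // beyond the outermost voxel centers)
  int n_ax[3] = {nx, ny, nz};
  for (int k = 0; k < 3; ++k) {
    lo = orig[k] - vox[k];
    hi = orig[k] + n_ax[k] * vox[k];
    if (std::fabs(dir[k]) < 1e-12) {
      if (s[k] < lo || s[k] > hi) return 0.0;
    } else {
      double ta = (lo - s[k]) / dir[k], tb = (hi - s[k]) / dir[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;
  double len = (t1 - t0) * std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                     dir[2] * dir[2]);
  if (len <= 0.0) return 0.0;
  int n = (int)std::ceil(len / step);
  if (n < 1) n = 1;
  double h = (t1 - t0) / n, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = t0 + (i + 0.5) * h;
    double gx = (s[0] + t * dir[0] - orig[0]) / vox[0];
    double gy = (s[1] + t * dir[1] - orig[1]) / vox[1];
    double gz = (s[2] + t * dir[2] - orig[2]) / vox[2];
    acc += trilinear(vol, nx, ny, nz, gx, gy, gz);
  }
  return acc * (len / n);
}

// Core projector. Returns nu x nv x S array:
//   mode 0: aperture-averaged transmission mean_sub exp(-P)
//   mode 1: raw line integral P at the pixel center (n_sub ignored)
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dims,
                          NumericVector vox, NumericVector orig,
                          NumericMatrix src, NumericVector detx,
                          NumericVector dety, double pitch_x, int n_sub,
                          double step, int mode) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nu = detx.size(), nv = dety.size(), S = src.nrow();
  if ((R_xlen_t)nx * ny * nz != vol.size()) stop("volume size mismatch");
  if (step <= 0) stop("step must be > 0");
  NumericVector out(Dimension(nu, nv, S));
  std::vector<double> sub(n_sub < 1 ? 1 : n_sub);
  int ns = (int)sub.size();
  for (int i = 0; i < ns; ++i)
    sub[i] = ((i + 0.5) / ns - 0.5) * pitch_x;
  const double *v = REAL(vol);
  for (int isrc = 0; isrc < S; ++isrc) {
    double s[3] = {src(isrc, 0), src(isrc, 1), src(isrc, 2)};
    for (int j = 0; j < nv; ++j) {
      for (int i = 0; i < nu; ++i) {
        double val = 0.0;
        if (mode == 1) {
          double d[3] = {detx[i], dety[j], 0.0};
          val = ray_integral(v, nx, ny, nz, REAL(vox), REAL(orig), s, d, step);
        } else {
          for (int k = 0; k < ns; ++k) {
            double d[3] = {detx[i] + sub[k], dety[j], 0.0};
            double p = ray_integral(v, nx, ny, nz, REAL(vox), REAL(orig),
                                    s, d, step);
            val += std::exp(-p);
          }
          val /= ns;
        }
        out[i + (R_xlen_t)nu * (j + (R_xlen_t)nv * isrc)] = val;
      }
    }
  }
  return out;
}

// Grayscale erosion (type 0) / dilation (type 1) with an arbitrary offset
// structuring element; border handled by replication.
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, IntegerMatrix offsets,
                             int type) {
  int nr = img.nrow(), nc = img.ncol(), K = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = type ? -INFINITY : INFINITY;
      for (int k = 0; k < K; ++k) {
        int ii = i + offsets(k, 0), jj = j + offsets(k, 1);
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        double x = img(ii, jj);
        if (type) { if (x > best) best = x; }
        else      { if (x < best) best = x; }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// 8-connected component labeling of a logical matrix; labels from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
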