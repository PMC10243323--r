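#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conventions (documented in R/transforms.R):
//  * 2D image: matrix [row, col]; physical x = (col-1)*sc mm, y = (row-1)*sr mm.
//  * forward rigid map T(p) = R(theta) (p - c) + c + t, theta CCW positive.
//  * 3D volume: array [i, j, k] = (lateral, AP, SI); physical mm likewise.
//  * 3D rotation: R = Ry(roll) * Rx(pitch) * Rz(yaw)  (extrinsic yaw->pitch->roll
//    about SI (z), lateral (x), AP (y) axes).

static inline double bilin(const NumericMatrix& img, double fr, double fc,
                           bool& ok) {
  const int R = img.nrow(), C = img.ncol();
  if (fr < 0.0 || fc < 0.0 || fr > R - 1.0 || fc > C - 1.0) { ok = false; return NA_REAL; }
  ok = true;
  int r0 = (int)std::floor(fr), c0 = (int)std::floor(fc);
  if (r0 == R - 1) r0--;
  if (c0 == C - 1) c0--;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  double ar = fr - r0, ac = fc - c0;
  return img(r0, c0) * (1 - ar) * (1 - ac) + img(r0 + 1, c0) * ar * (1 - ac) +
         img(r0, c0 + 1) * (1 - ar) * ac + img(r0 + 1, c0 + 1) * ar * ac;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector x_mm,
                           NumericVector y_mm, double sr, double sc) {
  const int n = x_mm.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    bool ok;
    out[i] = bilin(img, y_mm[i] / sr, x_mm[i] / sc, ok);
  }
  return out;
}

// Resample an image under the *inverse* of the forward rigid map, i.e. produce
// the image of anatomy moved by (dx, dy, theta): out(q) = in(T^{-1}(q)).
// [[Rcpp::export]]
NumericMatrix cpp_resample2d(NumericMatrix img, double dx, double dy,
                             double theta, double cx, double cy, double sr,
                             double sc, double fill) {
  const int R = img.nrow(), C = img.ncol();
  NumericMatrix out(R, C);
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int c = 0; c < C; c++) {
    const double qx = c * sc;
    for (int r = 0; r < R; r++) {
      const double qy = r * sr;
      const double ux = qx - cx - dx, uy = qy - cy - dy;
      // R^{-1} = R(-theta)
      const double px = ct * ux + st * uy + cx;
      const double py = -st * ux + ct * uy + cy;
      bool ok;
      double v = bilin(img, py / sr, px / sc, ok);
      out(r, c) = ok ? v : fill;
    }
  }
  return out;
}

// Pearson correlation between reference ROI values and the moving image
// sampled at forward-transformed ROI locations, for a batch of candidate
// transforms (columns: dx_mm, dy_mm, theta_rad). Pairs whose transformed
// location falls outside the moving image, or within half a pixel of a
// flagged moving-frame line (crossline artifact), are dropped; NA is
// returned when fewer than `min_valid` pairs remain or a sample set is
// constant.
// [[Rcpp::export]]
NumericVector cpp_score2d(NumericMatrix moving, NumericVector ref_vals,
                          NumericVector px, NumericVector py,
                          NumericMatrix cand, double cx, double cy, double sr,
                          double sc, int min_valid, LogicalVector bad_row,
                          LogicalVector bad_col) {
  const int n = ref_vals.size(), m = cand.nrow();
  const int R = moving.nrow(), C = moving.ncol();
  const bool any_bad = bad_row.size() == R && bad_col.size() == C;
  NumericVector scores(m);
  for (int k = 0; k < m; k++) {
    const double dx = cand(k, 0), dy = cand(k, 1), th = cand(k, 2);
    const double ct = std::cos(th), st = std::sin(th);
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    int nv = 0;
    for (int i = 0; i < n; i++) {
      const double ux = px[i] - cx, uy = py[i] - cy;
      const double tx = ct * ux - st * uy + cx + dx;
      const double ty = st * ux + ct * uy + cy + dy;
      bool ok;
      const double b = bilin(moving, ty / sr, tx / sc, ok);
      if (!ok) continue;
      if (any_bad) {
        const int ri = (int)std::lround(ty / sr), ci = (int)std::lround(tx / sc);
        if ((ri >= 0 && ri < R && bad_row[ri]) ||
            (ci >= 0 && ci < C && bad_col[ci])) continue;
      }
      const double a = ref_vals[i];
      sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      nv++;
    }
    if (nv < min_valid) { scores[k] = NA_REAL; continue; }
    const double va = saa - sa * sa / nv, vb = sbb - sb * sb / nv;
    if (va <= 0 || vb <= 0) { scores[k] = NA_REAL; continue; }
    scores[k] = (sab - sa * sb / nv) / std::sqrt(va * vb);
  }
  return scores;
}

static inline void rot3(double roll, double pitch, double yaw, double Rm[9]) {
  const double cr = std::cos(roll), sr_ = std::sin(roll);
  const double cp = std::cos(pitch), sp = std::sin(pitch);
  const double cy = std::cos(yaw), sy = std::sin(yaw);
  // R = Ry(roll) * Rx(pitch) * Rz(yaw)
  Rm[0] = cr * cy + sr_ * sp * sy;  Rm[1] = -cr * sy + sr_ * sp * cy; Rm[2] = sr_ * cp;
  Rm[3] = cp * sy;                  Rm[4] = cp * cy;                  Rm[5] = -sp;
  Rm[6] = -sr_ * cy + cr * sp * sy; Rm[7] = sr_ * sy + cr * sp * cy;  Rm[8] = cr * cp;
}

static inline double trilin(const double* v, int nx, int ny, int nz, double fx,
                            double fy, double fz, bool& ok) {
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1.0 || fy > ny - 1.0 ||
      fz > nz - 1.0) { ok = false; return NA_REAL; }
  ok = true;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  const double ax = fx - x0, ay = fy - y0, az = fz - z0;
  const long sxy = (long)nx * ny;
  const double* p = v + x0 + (long)y0 * nx + (long)z0 * sxy;
  const double c00 = p[0] * (1 - ax) + p[1] * ax;
  const double c10 = p[nx] * (1 - ax) + p[nx + 1] * ax;
  const double c01 = p[sxy] * (1 - ax) + p[sxy + 1] * ax;
  const double c11 = p[sxy + nx] * (1 - ax) + p[sxy + nx + 1] * ax;
  return (c00 * (1 - ay) + c10 * ay) * (1 - az) + (c01 * (1 - ay) + c11 * ay) * az;
}

// out(q) = in(T^{-1}(q)) for a 6-DOF rigid transform in mm about `center`.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, NumericVector params,
                             NumericVector center, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double Rm[9];
  rot3(params[3], params[4], params[5], Rm);
  const double tx = params[0], ty = params[1], tz = params[2];
  const double cx = center[0], cy = center[1], cz = center[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = vol.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++) {
    const double qz = k * sz;
    for (int j = 0; j < ny; j++) {
      const double qy = j * sy;
      for (int i = 0; i < nx; i++, idx++) {
        const double qx = i * sx;
        const double ux = qx - cx - tx, uy = qy - cy - ty, uz = qz - cz - tz;
        // R^{-1} = R^T
        const double px = Rm[0] * ux + Rm[3] * uy + Rm[6] * uz + cx;
        const double py = Rm[1] * ux + Rm[4] * uy + Rm[7] * uz + cy;
        const double pz = Rm[2] * ux + Rm[5] * uy + Rm[8] * uz + cz;
        bool ok;
        const double val = trilin(v, nx, ny, nz, px / sx, py / sy, pz / sz, ok);
        out[idx] = ok ? val : fill;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Mutual information between pre-binned fixed-image samples and the moving
// volume sampled at forward-transformed point locations, for a batch of
// candidate 6-DOF transforms (columns: lat, ap, si mm, roll, pitch, yaw rad).
// [[Rcpp::export]]
NumericVector cpp_mi3d(IntegerVector fixed_bin, NumericMatrix pts,
                       NumericVector vol, IntegerVector dims,
                       NumericVector spacing, NumericMatrix cand,
                       NumericVector center, int bins, double mmin,
                       double mmax, int min_valid) {
  const int n = fixed_bin.size(), m = cand.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx = center[0], cy = center[1], cz = center[2];
  const double rng = (mmax > mmin) ? (mmax - mmin) : 1.0;
  NumericVector scores(m);
  std::vector<double> joint(bins * bins), pf(bins), pm(bins);
  const double* v = vol.begin();
  for (int k = 0; k < m; k++) {
    double Rm[9];
    rot3(cand(k, 3), cand(k, 4), cand(k, 5), Rm);
    const double tx = cand(k, 0), ty = cand(k, 1), tz = cand(k, 2);
    std::fill(joint.begin(), joint.end(), 0.0);
    int nv = 0;
    for (int i = 0; i < n; i++) {
      const double ux = pts(i, 0) - cx, uy = pts(i, 1) - cy, uz = pts(i, 2) - cz;
      const double qx = Rm[0] * ux + Rm[1] * uy + Rm[2] * uz + cx + tx;
      const double qy = Rm[3] * ux + Rm[4] * uy + Rm[5] * uz + cy + ty;
      const double qz = Rm[6] * ux + Rm[7] * uy + Rm[8] * uz + cz + tz;
      bool ok;
      const double val = trilin(v, nx, ny, nz, qx / sx, qy / sy, qz / sz, ok);
      if (!ok) continue;
      int mb = (int)((val - mmin) / rng * bins);
      if (mb < 0) mb = 0;
      if (mb >= bins) mb = bins - 1;
      joint[fixed_bin[i] * bins + mb] += 1.0;
      nv++;
    }
    if (nv < min_valid) { scores[k] = NA_REAL; continue; }
    std::fill(pf.begin(), pf.end(), 0.0);
    std::fill(pm.begin(), pm.end(), 0.0);
    for (int a = 0; a < bins; a++)
      for (int b = 0; b < bins; b++) {
        pf[a] += joint[a * bins + b];
        pm[b] += joint[a * bins + b];
      }
    double mi = 0.0;
    for (int a = 0; a < bins; a++) {
      if (pf[a] == 0) continue;
      for (int b = 0; b < bins; b++) {
        const double pj = joint[a * bins + b];
        if (pj == 0 || pm[b] == 0) continue;
        mi += (pj / nv) * std::log(pj * nv / (pf[a] * pm[b]));
      }
    }
    scores[k] = mi;
  }
  return scores;
}
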