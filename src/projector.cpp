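#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Multi-slice parallel-beam Siddon traversal. Rays live in the axial (x,y)
// plane; slice k of the sinogram depends only on slice k of the image.
// Angle convention: theta = 0 rays run parallel to the y axis; the signed
// radial coordinate is measured along (cos theta, sin theta) from the world
// in-plane origin. Segment lengths are in mm, so forward projection returns
// line integrals in value * mm.
//
// forward = true : sino[r,a,k] = sum_j len_j * img[voxel_j, k]
// forward = false: img[voxel_j, k] += sum over rays len_j * sino[r,a,k]
// The two directions share one traversal, so back projection is the exact
// adjoint of forward projection.

static inline void trace_ray(double s, double cth, double sth,
                             double xmin, double ymin,
                             double vx, double vy,
                             int nx, int ny,
                             const double* slice_img, double* slice_img_out,
                             double sino_val, double* sino_accum,
                             bool forward) {
  // Ray point P = s*(cth, sth), direction u = (-sth, cth), |u| = 1.
  const double px = s * cth, py = s * sth;
  const double ux = -sth, uy = cth;
  const double xmax = xmin + nx * vx, ymax = ymin + ny * vy;
  const double INF = std::numeric_limits<double>::infinity();

  // Clip parameter range to the in-plane bounding box.
  double t0 = -INF, t1 = INF;
  if (std::fabs(ux) > 1e-12) {
    double ta = (xmin - px) / ux, tb = (xmax - px) / ux;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  } else if (px < xmin || px > xmax) return;
  if (std::fabs(uy) > 1e-12) {
    double ta = (ymin - py) / uy, tb = (ymax - py) / uy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  } else if (py < ymin || py > ymax) return;
  if (t1 - t0 < 1e-12) return;

  // Entry voxel from a point nudged just inside the box.
  const double eps = 1e-9 * (t1 - t0);
  double x = px + (t0 + eps) * ux, y = py + (t0 + eps) * uy;
  int ix = (int)std::floor((x - xmin) / vx);
  int iy = (int)std::floor((y - ymin) / vy);
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;

  // Parametric distances to the next x/y voxel boundary crossings.
  double tx, ty, dtx, dty;
  int stepx, stepy;
  if (ux > 1e-12)       { stepx = 1;  dtx = vx / ux;  tx = (xmin + (ix + 1) * vx - px) / ux; }
  else if (ux < -1e-12) { stepx = -1; dtx = -vx / ux; tx = (xmin + ix * vx - px) / ux; }
  else                  { stepx = 0;  dtx = INF;      tx = INF; }
  if (uy > 1e-12)       { stepy = 1;  dty = vy / uy;  ty = (ymin + (iy + 1) * vy - py) / uy; }
  else if (uy < -1e-12) { stepy = -1; dty = -vy / uy; ty = (ymin + iy * vy - py) / uy; }
  else                  { stepy = 0;  dty = INF;      ty = INF; }

  double t = t0;
  double acc = 0.0;
  while (t < t1 - 1e-12) {
    const double tnext = std::min(std::min(tx, ty), t1);
    const double seg = tnext - t;
    if (seg > 0 && ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
      const R_xlen_t idx = (R_xlen_t)iy * nx + ix;
      if (forward) acc += seg * slice_img[idx];
      else         slice_img_out[idx] += seg * sino_val;
    }
    // advance whichever boundary was crossed; a corner advances both
    const bool advx = (stepx != 0 && tx <= tnext + 1e-12);
    const bool advy = (stepy != 0 && ty <= tnext + 1e-12);
    if (advx) { ix += stepx; tx += dtx; }
    if (advy) { iy += stepy; ty += dty; }
    t = tnext;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
  if (forward) *sino_accum = acc;
}

// [[Rcpp::export(name = ".cpp_project")]]
NumericVector cpp_project(NumericVector img, IntegerVector dims,
                          NumericVector voxel_mm, NumericVector origin_mm,
                          NumericVector angles, IntegerVector angle_index,
                          NumericVector radial_mm, int n_radial,
                          NumericVector sino, bool forward) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel_mm[0], vy = voxel_mm[1];
  // origin_mm is the world center of voxel (1,1,1); box edge is half a voxel out
  const double xmin = origin_mm[0] - 0.5 * vx;
  const double ymin = origin_mm[1] - 0.5 * vy;
  const int na_sub = angle_index.size();
  const R_xlen_t slice_img_n = (R_xlen_t)nx * ny;
  const R_xlen_t slice_sino_n = (R_xlen_t)n_radial * na_sub;

  NumericVector out = forward
    ? NumericVector(slice_sino_n * nz)
    : NumericVector((R_xlen_t)nx * ny * nz);

  for (int k = 0; k < nz; ++k) {
    const double* img_in = forward ? &img[slice_img_n * k] : nullptr;
    double* img_out = forward ? nullptr : &out[slice_img_n * k];
    for (int aa = 0; aa < na_sub; ++aa) {
      const int a = angle_index[aa];          // 0-based index into angles
      const double th = angles[a];
      const double cth = std::cos(th), sth = std::sin(th);
      for (int r = 0; r < n_radial; ++r) {
        const R_xlen_t sidx = slice_sino_n * k + (R_xlen_t)aa * n_radial + r;
        if (forward) {
          double acc = 0.0;
          trace_ray(radial_mm[r], cth, sth, xmin, ymin, vx, vy, nx, ny,
                    img_in, nullptr, 0.0, &acc, true);
          out[sidx] = acc;
        } else {
          const double v = sino[sidx];
          if (v != 0.0)
            trace_ray(radial_mm[r], cth, sth, xmin, ymin, vx, vy, nx, ny,
                      nullptr, img_out, v, nullptr, false);
        }
      }
    }
  }
  return out;
}
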