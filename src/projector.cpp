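// Equiangular fan-beam projector pair.
//
// Forward: exact Siddon ray tracing of per-material coefficient maps,
// returning path lengths in the units of `pixelSize`. Backprojection:
// distance-weighted accumulation with linear interpolation across detector
// cells (the filtering step lives in R).
//
// Conventions (shared with the R side): isocenter origin; pixel (ix, iy)
// (0-based, x index first) has center ((ix + 0.5) - N/2, (iy + 0.5) - N/2)
// * pixelSize; source at angle beta sits at R_si * (cos b, sin b); the ray
// of fan angle gamma is the source-to-iso direction rotated by gamma
// (positive gamma = counterclockwise).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector coeffs, int n, double pixelSize,
                                  NumericVector betas, NumericVector gammas,
                                  double sourceToIso) {
  IntegerVector dims = coeffs.attr("dim");
  const int N = dims[0], P = dims[2];
  const int nViews = betas.size(), nCells = gammas.size();
  if (N != n) stop("grid size mismatch");
  NumericVector out(Dimension(nViews, nCells, P));
  const double h = pixelSize;
  const double x0 = -N * h / 2.0;
  const double x1 = N * h / 2.0;
  if (sourceToIso <= x1 * std::sqrt(2.0))
    stop("degenerate geometry: source inside the field of view");
  const double *cf = REAL(coeffs);
  double *o = REAL(out);

  for (int v = 0; v < nViews; ++v) {
    const double b = betas[v];
    const double sx = sourceToIso * std::cos(b);
    const double sy = sourceToIso * std::sin(b);
    const double d0x = -std::cos(b), d0y = -std::sin(b);
    for (int c = 0; c < nCells; ++c) {
      const double g = gammas[c];
      const double dx = d0x * std::cos(g) - d0y * std::sin(g);
      const double dy = d0x * std::sin(g) + d0y * std::cos(g);

      // slab clipping against the grid bounding box
      double tmin = 0.0, tmax = 1e30;
      bool miss = false;
      const double sp[2] = {sx, sy}, dd[2] = {dx, dy};
      for (int ax = 0; ax < 2; ++ax) {
        if (std::fabs(dd[ax]) < 1e-12) {
          if (sp[ax] <= x0 || sp[ax] >= x1) { miss = true; break; }
        } else {
          double t1 = (x0 - sp[ax]) / dd[ax];
          double t2 = (x1 - sp[ax]) / dd[ax];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (miss || tmax <= tmin) continue;

      // Siddon walk from tmin to tmax
      double t = tmin;
      double px = sx + t * dx, py = sy + t * dy;
      int ix = (int)std::floor((px - x0) / h);
      int iy = (int)std::floor((py - x0) / h);
      if (ix < 0) ix = 0; if (ix > N - 1) ix = N - 1;
      if (iy < 0) iy = 0; if (iy > N - 1) iy = N - 1;
      const int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1;
      double txNext = (std::fabs(dx) < 1e-12) ? 1e30
        : ((x0 + (ix + (stepx > 0 ? 1 : 0)) * h) - sx) / dx;
      double tyNext = (std::fabs(dy) < 1e-12) ? 1e30
        : ((x0 + (iy + (stepy > 0 ? 1 : 0)) * h) - sy) / dy;
      const double tdx = (std::fabs(dx) < 1e-12) ? 1e30 : h / std::fabs(dx);
      const double tdy = (std::fabs(dy) < 1e-12) ? 1e30 : h / std::fabs(dy);

      while (t < tmax - 1e-12) {
        double tNext = std::min(std::min(txNext, tyNext), tmax);
        const double len = tNext - t;
        if (len > 0 && ix >= 0 && ix < N && iy >= 0 && iy < N) {
          const size_t base = (size_t)ix + (size_t)N * iy;
          for (int p = 0; p < P; ++p) {
            const double cval = cf[base + (size_t)N * N * p];
            if (cval != 0.0)
              o[(size_t)v + (size_t)nViews * c +
                (size_t)nViews * nCells * p] += len * cval;
          }
        }
        t = tNext;
        if (txNext <= tyNext && txNext <= tmax) { ix += stepx; txNext += tdx; }
        else if (tyNext < txNext && tyNext <= tmax) { iy += stepy; tyNext += tdy; }
        if (ix < 0 || ix >= N || iy < 0 || iy >= N) break;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix filtered, int n,
                                  double pixelSize, NumericVector betas,
                                  double dgamma, int nCells,
                                  double sourceToIso) {
  const int N = n, nViews = betas.size();
  if (filtered.nrow() != nViews || filtered.ncol() != nCells)
    stop("filtered sinogram / geometry mismatch");
  NumericMatrix img(N, N);
  const double h = pixelSize;
  const double cellCenter = (nCells - 1) / 2.0;
  const double dbeta = 2.0 * M_PI / nViews;

  std::vector<double> coord(N);
  for (int i = 0; i < N; ++i) coord[i] = ((i + 0.5) - N / 2.0) * h;

  for (int v = 0; v < nViews; ++v) {
    const double b = betas[v];
    const double sx = sourceToIso * std::cos(b);
    const double sy = sourceToIso * std::sin(b);
    const double d0x = -std::cos(b), d0y = -std::sin(b);
    const NumericMatrix::Row q = filtered(v, _);
    for (int iy = 0; iy < N; ++iy) {
      const double vy0 = coord[iy] - sy;
      for (int ix = 0; ix < N; ++ix) {
        const double vx = coord[ix] - sx;
        const double L2 = vx * vx + vy0 * vy0;
        const double gp = std::atan2(d0x * vy0 - d0y * vx,
                                     d0x * vx + d0y * vy0);
        const double pos = gp / dgamma + cellCenter;
        const int c0 = (int)std::floor(pos);
        if (c0 < 0 || c0 >= nCells - 1) continue;
        const double w = pos - c0;
        img(ix, iy) += dbeta / L2 * ((1.0 - w) * q[c0] + w * q[c0 + 1]);
      }
    }
  }
  return img;
}
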