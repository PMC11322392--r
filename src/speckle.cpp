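#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Splat point scatterers onto the pixel raster with bilinear weights, then
// apply a separable Gaussian blur (the point-spread function). Coordinates
// are 0-based pixel units (row = axial, col = lateral).
// [[Rcpp::export]]
NumericMatrix cppRenderFrame(int nrow, int ncol,
                             NumericVector srow, NumericVector scol,
                             NumericVector amp,
                             double sigmaRow, double sigmaCol) {
  NumericMatrix img(nrow, ncol);
  const int n = srow.size();
  for (int i = 0; i < n; ++i) {
    double r = srow[i], c = scol[i];
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double fr = r - r0, fc = c - c0;
    for (int dr = 0; dr <= 1; ++dr) {
      int rr = r0 + dr;
      if (rr < 0 || rr >= nrow) continue;
      double wr = dr ? fr : 1.0 - fr;
      for (int dc = 0; dc <= 1; ++dc) {
        int cc = c0 + dc;
        if (cc < 0 || cc >= ncol) continue;
        double wc = dc ? fc : 1.0 - fc;
        img(rr, cc) += amp[i] * wr * wc;
      }
    }
  }
  // separable Gaussian blur, truncated at 3 sigma
  auto blur1d = [](NumericMatrix &m, double sigma, bool alongRows) {
    if (sigma <= 0) return;
    int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * rad + 1);
    double s = 0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
      s += k[i + rad];
    }
    for (auto &v : k) v /= s;
    int nr = m.nrow(), nc = m.ncol();
    NumericMatrix out(nr, nc);
    if (alongRows) {               // blur down columns (axial direction)
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            int rr = r + i;
            if (rr < 0) rr = 0;
            if (rr >= nr) rr = nr - 1;
            acc += k[i + rad] * m(rr, c);
          }
          out(r, c) = acc;
        }
    } else {
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            int cc = c + i;
            if (cc < 0) cc = 0;
            if (cc >= nc) cc = nc - 1;
            acc += k[i + rad] * m(r, cc);
          }
          out(r, c) = acc;
        }
    }
    m = out;
  };
  blur1d(img, sigmaRow, true);
  blur1d(img, sigmaCol, false);
  return img;
}

static inline double bilinear(const NumericMatrix &im, double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  return im(r0, c0) * (1 - fr) * (1 - fc) + im(r0 + 1, c0) * fr * (1 - fc) +
         im(r0, c0 + 1) * (1 - fr) * fc + im(r0 + 1, c0 + 1) * fr * fc;
}

static NumericMatrix downsample2(const NumericMatrix &im) {
  int nr = im.nrow() / 2, nc = im.ncol() / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = 0.25 * (im(2 * r, 2 * c) + im(2 * r + 1, 2 * c) +
                          im(2 * r, 2 * c + 1) + im(2 * r + 1, 2 * c + 1));
  return out;
}

// Pyramidal Lucas-Kanade tracking of points from `ref` to `cur`.
// pts: n x 2 matrix of 0-based (row, col) positions in `ref`.
// Returns n x 6: drow, dcol, residual (mean squared window difference),
// converged, minEig (per-pixel), valid.
// [[Rcpp::export]]
NumericMatrix cppLKTrack(NumericMatrix ref, NumericMatrix cur,
                         NumericMatrix pts, int halfwin, int levels,
                         int maxIter, double tol, double minEig,
                         double maxResidual) {
  const int n = pts.nrow();
  NumericMatrix out(n, 6);

  std::vector<NumericMatrix> pyrRef, pyrCur;
  pyrRef.push_back(ref);
  pyrCur.push_back(cur);
  for (int l = 1; l < levels; ++l) {
    if (pyrRef.back().nrow() < 4 * halfwin || pyrRef.back().ncol() < 4 * halfwin)
      break;
    pyrRef.push_back(downsample2(pyrRef.back()));
    pyrCur.push_back(downsample2(pyrCur.back()));
  }
  const int L = (int)pyrRef.size();
  const int wn = 2 * halfwin + 1;
  const int npix = wn * wn;
  std::vector<double> Ix(npix), Iy(npix), T(npix);

  for (int p = 0; p < n; ++p) {
    double dr = 0, dc = 0;
    bool ok = true, converged = false;
    double eigMin = 0, resid = NA_REAL;
    for (int l = L - 1; l >= 0; --l) {
      const NumericMatrix &R = pyrRef[l], &C = pyrCur[l];
      const double scale = std::pow(2.0, l);
      const double pr = pts(p, 0) / scale, pc = pts(p, 1) / scale;
      dr /= scale; dc /= scale;
      // window and gradients from the reference image at this level
      if (pr - halfwin - 1 < 0 || pr + halfwin + 2 >= R.nrow() ||
          pc - halfwin - 1 < 0 || pc + halfwin + 2 >= R.ncol()) {
        if (l == 0) ok = false;
        dr *= 2; dc *= 2;  // undo for next finer level
        continue;
      }
      double gxx = 0, gxy = 0, gyy = 0;
      int k = 0;
      for (int wr = -halfwin; wr <= halfwin; ++wr)
        for (int wc = -halfwin; wc <= halfwin; ++wc, ++k) {
          double r = pr + wr, c = pc + wc;
          T[k] = bilinear(R, r, c);
          Iy[k] = 0.5 * (bilinear(R, r + 1, c) - bilinear(R, r - 1, c));
          Ix[k] = 0.5 * (bilinear(R, r, c + 1) - bilinear(R, r, c - 1));
          gxx += Ix[k] * Ix[k];
          gxy += Ix[k] * Iy[k];
          gyy += Iy[k] * Iy[k];
        }
      double tr = gxx + gyy, det = gxx * gyy - gxy * gxy;
      double disc = std::sqrt(std::max(0.0, tr * tr / 4 - det));
      double lmin = tr / 2 - disc;
      if (l == 0) eigMin = lmin / npix;
      if (det <= 1e-12 || lmin <= 0) {
        if (l == 0) ok = false;
        dr *= 2; dc *= 2;
        continue;
      }
      converged = false;
      for (int it = 0; it < maxIter; ++it) {
        double nr2 = pr + dr, nc2 = pc + dc;
        if (nr2 - halfwin < 0 || nr2 + halfwin + 1 >= C.nrow() ||
            nc2 - halfwin < 0 || nc2 + halfwin + 1 >= C.ncol()) {
          if (l == 0) ok = false;
          break;
        }
        double bx = 0, by = 0, ss = 0;
        k = 0;
        for (int wr = -halfwin; wr <= halfwin; ++wr)
          for (int wc = -halfwin; wc <= halfwin; ++wc, ++k) {
            double diff = bilinear(C, nr2 + wr, nc2 + wc) - T[k];
            bx += Ix[k] * diff;
            by += Iy[k] * diff;
            ss += diff * diff;
          }
        if (l == 0) resid = ss / npix;
        double stepc = -(gyy * bx - gxy * by) / det;
        double stepr = -(-gxy * bx + gxx * by) / det;
        dr += stepr; dc += stepc;
        if (std::sqrt(stepr * stepr + stepc * stepc) < tol) {
          converged = true;
          break;
        }
      }
      if (l > 0) { dr *= 2; dc *= 2; }
    }
    bool valid = ok && converged && eigMin >= minEig &&
                 R_finite(resid) && resid <= maxResidual;
    out(p, 0) = dr;
    out(p, 1) = dc;
    out(p, 2) = resid;
    out(p, 3) = converged ? 1.0 : 0.0;
    out(p, 4) = eigMin;
    out(p, 5) = valid ? 1.0 : 0.0;
  }
  return out;
}
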