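// Fourier-space kernels for pseudo-subtomogram construction, likelihood
// evaluation and reconstruction.
//
// Conventions (shared with the R side):
//  * All Fourier arrays are unshifted DFTs of centre-origin real arrays
//    (DC at linear index 0); frequency of 0-based index i is
//    h = i < n/2 ? i : i - n, in grid units (cycles per box).
//  * Boxes are even; frequencies with any |component| >= n/2 (Nyquist)
//    are excluded from sampling and insertion.
//  * Arrays are column-major with x fastest: linear = ix + n*(iy + n*iz).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int wrap_idx(int h, int n) { return h < 0 ? h + n : h; }

static inline int lin3(int ix, int iy, int iz, int n) {
  return ix + n * (iy + n * iz);
}

// trilinear sample of a complex volume at grid frequency (qx,qy,qz);
// returns false (value 0) beyond the Nyquist box
static bool sample_complex(const Rcomplex* V, int n,
                           double qx, double qy, double qz,
                           double& re, double& im) {
  const double half = n / 2.0;
  re = 0.0; im = 0.0;
  if (std::fabs(qx) >= half || std::fabs(qy) >= half || std::fabs(qz) >= half)
    return false;
  const int fx = (int)std::floor(qx), fy = (int)std::floor(qy),
            fz = (int)std::floor(qz);
  const double wx = qx - fx, wy = qy - fy, wz = qz - fz;
  for (int dz = 0; dz < 2; ++dz) {
    const double wwz = dz ? wz : 1.0 - wz;
    if (wwz == 0.0) continue;
    const int iz = wrap_idx(fz + dz, n);
    for (int dy = 0; dy < 2; ++dy) {
      const double wwy = dy ? wy : 1.0 - wy;
      if (wwy == 0.0) continue;
      const int iy = wrap_idx(fy + dy, n);
      for (int dx = 0; dx < 2; ++dx) {
        const double w = (dx ? wx : 1.0 - wx) * wwy * wwz;
        if (w == 0.0) continue;
        const int ix = wrap_idx(fx + dx, n);
        const Rcomplex v = V[lin3(ix, iy, iz, n)];
        re += w * v.r; im += w * v.i;
      }
    }
  }
  return true;
}

static bool sample_real(const double* V, int n,
                        double qx, double qy, double qz, double& out) {
  const double half = n / 2.0;
  out = 0.0;
  if (std::fabs(qx) >= half || std::fabs(qy) >= half || std::fabs(qz) >= half)
    return false;
  const int fx = (int)std::floor(qx), fy = (int)std::floor(qy),
            fz = (int)std::floor(qz);
  const double wx = qx - fx, wy = qy - fy, wz = qz - fz;
  for (int dz = 0; dz < 2; ++dz) {
    const double wwz = dz ? wz : 1.0 - wz;
    if (wwz == 0.0) continue;
    const int iz = wrap_idx(fz + dz, n);
    for (int dy = 0; dy < 2; ++dy) {
      const double wwy = dy ? wy : 1.0 - wy;
      if (wwy == 0.0) continue;
      const int iy = wrap_idx(fy + dy, n);
      for (int dx = 0; dx < 2; ++dx) {
        const double w = (dx ? wx : 1.0 - wx) * wwy * wwz;
        if (w == 0.0) continue;
        const int ix = wrap_idx(fx + dx, n);
        out += w * V[lin3(ix, iy, iz, n)];
      }
    }
  }
  return true;
}

// Extract a 2D central slice from a 3D Fourier volume.
// Q (3 x 2): grid-unit mapping from 2D crop frequency h to 3D frequency q = Q h.
// shift: 2D shift in crop pixels applied as a phase ramp exp(-2*pi*i*h.s/n2).
// [[Rcpp::export]]
ComplexMatrix cpp_slice_sample(ComplexVector V, int n3, NumericMatrix Q,
                               int n2, double sx, double sy) {
  ComplexMatrix out(n2, n2);
  const Rcomplex* v = V.begin();
  const double twopi = 2.0 * M_PI;
  for (int iy = 0; iy < n2; ++iy) {
    const int hy = iy < n2 / 2 ? iy : iy - n2;
    for (int ix = 0; ix < n2; ++ix) {
      const int hx = ix < n2 / 2 ? ix : ix - n2;
      Rcomplex z; z.r = 0.0; z.i = 0.0;
      if (std::abs(hx) < n2 / 2 && std::abs(hy) < n2 / 2) {
        const double qx = Q(0, 0) * hx + Q(0, 1) * hy;
        const double qy = Q(1, 0) * hx + Q(1, 1) * hy;
        const double qz = Q(2, 0) * hx + Q(2, 1) * hy;
        double re, im;
        if (sample_complex(v, n3, qx, qy, qz, re, im)) {
          const double ph = -twopi * (sx * hx + sy * hy) / n2;
          const double c = std::cos(ph), s = std::sin(ph);
          z.r = re * c - im * s;
          z.i = re * s + im * c;
        }
      }
      out(ix, iy) = z;
    }
  }
  return out;
}

// Forward insertion of one CTF-premultiplied 2D crop into the (D, W, M)
// triplet: each in-radius 2D pixel updates the 8 nearest 3D voxels with
// trilinear weights summing to one. Returns c(inserted, skipped).
// [[Rcpp::export]]
IntegerVector cpp_forward_insert(ComplexMatrix X, NumericMatrix ctf,
                                 NumericMatrix Q, int n3,
                                 ComplexVector D, NumericVector W,
                                 NumericVector M) {
  const int n2 = X.nrow();
  Rcomplex* d = D.begin();
  double* w = W.begin();
  double* m = M.begin();
  const double half3 = n3 / 2.0;
  int inserted = 0, skipped = 0;
  for (int iy = 0; iy < n2; ++iy) {
    const int hy = iy < n2 / 2 ? iy : iy - n2;
    if (std::abs(hy) >= n2 / 2) continue;
    for (int ix = 0; ix < n2; ++ix) {
      const int hx = ix < n2 / 2 ? ix : ix - n2;
      if (std::abs(hx) >= n2 / 2) continue;
      const double qx = Q(0, 0) * hx + Q(0, 1) * hy;
      const double qy = Q(1, 0) * hx + Q(1, 1) * hy;
      const double qz = Q(2, 0) * hx + Q(2, 1) * hy;
      if (std::fabs(qx) >= half3 || std::fabs(qy) >= half3 ||
          std::fabs(qz) >= half3) { ++skipped; continue; }
      const int fx = (int)std::floor(qx), fy = (int)std::floor(qy),
                fz = (int)std::floor(qz);
      const double wx = qx - fx, wy = qy - fy, wz = qz - fz;
      const Rcomplex xv = X(ix, iy);
      const double c = ctf(ix, iy);
      const double dr = c * xv.r, di = c * xv.i, c2 = c * c;
      for (int dz = 0; dz < 2; ++dz) {
        const double wwz = dz ? wz : 1.0 - wz;
        const int iz3 = wrap_idx(fz + dz, n3);
        for (int dy = 0; dy < 2; ++dy) {
          const double wwy = (dy ? wy : 1.0 - wy) * wwz;
          const int iy3 = wrap_idx(fy + dy, n3);
          for (int dxk = 0; dxk < 2; ++dxk) {
            const double wt = (dxk ? wx : 1.0 - wx) * wwy;
            const int ix3 = wrap_idx(fx + dxk, n3);
            const int li = lin3(ix3, iy3, iz3, n3);
            d[li].r += wt * dr;
            d[li].i += wt * di;
            w[li] += wt * c2;
            m[li] += wt;
          }
        }
      }
      ++inserted;
    }
  }
  return IntegerVector::create(inserted, skipped);
}

// Negative log-likelihood of a pseudo-subtomogram against reference V:
// sum over voxels k (M >= mthresh) of |D_k - W_k V(R k) e^{-2pi i k.s/n}|^2
// / (M_k sigma2[shell(k)]).  R maps pseudo-frame frequencies into the
// reference frame; s is a 3D shift in pixels.
// [[Rcpp::export]]
double cpp_nll_pseudo(ComplexVector D, NumericVector W, NumericVector M,
                      int n, ComplexVector V, int nv, NumericMatrix R,
                      NumericVector shift, NumericVector sigma2,
                      double mthresh) {
  const Rcomplex* d = D.begin();
  const double* w = W.begin();
  const double* m = M.begin();
  const Rcomplex* v = V.begin();
  const int nsig = sigma2.size();
  const double twopi = 2.0 * M_PI;
  double acc = 0.0;
  for (int iz = 0; iz < n; ++iz) {
    const int hz = iz < n / 2 ? iz : iz - n;
    if (std::abs(hz) >= n / 2) continue;
    for (int iy = 0; iy < n; ++iy) {
      const int hy = iy < n / 2 ? iy : iy - n;
      if (std::abs(hy) >= n / 2) continue;
      for (int ix = 0; ix < n; ++ix) {
        const int hx = ix < n / 2 ? ix : ix - n;
        if (std::abs(hx) >= n / 2) continue;
        const int li = lin3(ix, iy, iz, n);
        const double mk = m[li];
        if (mk < mthresh) continue;
        const double qx = R(0, 0) * hx + R(0, 1) * hy + R(0, 2) * hz;
        const double qy = R(1, 0) * hx + R(1, 1) * hy + R(1, 2) * hz;
        const double qz = R(2, 0) * hx + R(2, 1) * hy + R(2, 2) * hz;
        double vr, vi;
        sample_complex(v, nv, qx, qy, qz, vr, vi);
        const double ph = -twopi *
          (shift[0] * hx + shift[1] * hy + shift[2] * hz) / n;
        const double cc = std::cos(ph), ss = std::sin(ph);
        const double pr = w[li] * (vr * cc - vi * ss);
        const double pi_ = w[li] * (vr * ss + vi * cc);
        const double er = d[li].r - pr, ei = d[li].i - pi_;
        int shell = (int)std::lround(std::sqrt((double)(hx * hx + hy * hy +
                                                        hz * hz)));
        if (shell >= nsig) shell = nsig - 1;
        acc += (er * er + ei * ei) / (mk * sigma2[shell]);
      }
    }
  }
  return acc;
}

// Per-shell residual statistics of a pseudo-subtomogram against V(R k):
// columns: sum |D - W V|^2, sum M, sum W, voxel count. Used by the
// sigma^2 (Eq.-style residual) and tau^2 updates.
// [[Rcpp::export]]
NumericMatrix cpp_residual_shells(ComplexVector D, NumericVector W,
                                  NumericVector M, int n, ComplexVector V,
                                  int nv, NumericMatrix R,
                                  NumericVector shift, int nshell,
                                  double mthresh) {
  const Rcomplex* d = D.begin();
  const double* w = W.begin();
  const double* m = M.begin();
  const Rcomplex* v = V.begin();
  NumericMatrix out(nshell, 4);
  const double twopi = 2.0 * M_PI;
  for (int iz = 0; iz < n; ++iz) {
    const int hz = iz < n / 2 ? iz : iz - n;
    if (std::abs(hz) >= n / 2) continue;
    for (int iy = 0; iy < n; ++iy) {
      const int hy = iy < n / 2 ? iy : iy - n;
      if (std::abs(hy) >= n / 2) continue;
      for (int ix = 0; ix < n; ++ix) {
        const int hx = ix < n / 2 ? ix : ix - n;
        if (std::abs(hx) >= n / 2) continue;
        const int li = lin3(ix, iy, iz, n);
        const double mk = m[li];
        if (mk < mthresh) continue;
        int shell = (int)std::lround(std::sqrt((double)(hx * hx + hy * hy +
                                                        hz * hz)));
        if (shell >= nshell) shell = nshell - 1;
        const double qx = R(0, 0) * hx + R(0, 1) * hy + R(0, 2) * hz;
        const double qy = R(1, 0) * hx + R(1, 1) * hy + R(1, 2) * hz;
        const double qz = R(2, 0) * hx + R(2, 1) * hy + R(2, 2) * hz;
        double vr, vi;
        sample_complex(v, nv, qx, qy, qz, vr, vi);
        const double ph = -twopi *
          (shift[0] * hx + shift[1] * hy + shift[2] * hz) / n;
        const double cc = std::cos(ph), ss = std::sin(ph);
        const double pr = w[li] * (vr * cc - vi * ss);
        const double pi_ = w[li] * (vr * ss + vi * cc);
        const double er = d[li].r - pr, ei = d[li].i - pi_;
        out(shell, 0) += er * er + ei * ei;
        out(shell, 1) += mk;
        out(shell, 2) += w[li];
        out(shell, 3) += 1.0;
      }
    }
  }
  return out;
}

// Accumulate one particle into the reconstruction: for every reference-frame
// voxel k, gather D, W, M at the pseudo-frame position R^T k (trilinear) and
// add into the numerator/denominator/multiplicity accumulators, weighted by
// 1/sigma2[shell(k)]. A 3D shift (pixels, pseudo frame) de-modulates D.
// [[Rcpp::export]]
void cpp_backproject(ComplexVector D, NumericVector W, NumericVector M,
                     int n, NumericMatrix R, NumericVector shift,
                     NumericVector sigma2, ComplexVector accN,
                     NumericVector accD, NumericVector accM) {
  const Rcomplex* d = D.begin();
  const double* w = W.begin();
  const double* m = M.begin();
  Rcomplex* an = accN.begin();
  double* ad = accD.begin();
  double* am = accM.begin();
  const int nsig = sigma2.size();
  const double twopi = 2.0 * M_PI;
  for (int iz = 0; iz < n; ++iz) {
    const int hz = iz < n / 2 ? iz : iz - n;
    if (std::abs(hz) >= n / 2) continue;
    for (int iy = 0; iy < n; ++iy) {
      const int hy = iy < n / 2 ? iy : iy - n;
      if (std::abs(hy) >= n / 2) continue;
      for (int ix = 0; ix < n; ++ix) {
        const int hx = ix < n / 2 ? ix : ix - n;
        if (std::abs(hx) >= n / 2) continue;
        // pseudo-frame position of reference voxel k: q = R^T k
        const double qx = R(0, 0) * hx + R(1, 0) * hy + R(2, 0) * hz;
        const double qy = R(0, 1) * hx + R(1, 1) * hy + R(2, 1) * hz;
        const double qz = R(0, 2) * hx + R(1, 2) * hy + R(2, 2) * hz;
        double dr, di, wv, mv;
        if (!sample_complex(d, n, qx, qy, qz, dr, di)) continue;
        sample_real(w, n, qx, qy, qz, wv);
        sample_real(m, n, qx, qy, qz, mv);
        if (mv <= 0.0 && wv <= 0.0) continue;
        // undo the particle's translation: D was built from shifted images
        const double ph = twopi *
          (shift[0] * qx + shift[1] * qy + shift[2] * qz) / n;
        const double cc = std::cos(ph), ss = std::sin(ph);
        const double drr = dr * cc - di * ss;
        const double dii = dr * ss + di * cc;
        int shell = (int)std::lround(std::sqrt((double)(hx * hx + hy * hy +
                                                        hz * hz)));
        if (shell >= nsig) shell = nsig - 1;
        const double wgt = 1.0 / sigma2[shell];
        const int li = lin3(ix, iy, iz, n);
        an[li].r += wgt * drr;
        an[li].i += wgt * dii;
        ad[li] += wgt * wv;
        am[li] += mv;
      }
    }
  }
}

// Catmull-Rom weights for fractional offset t in [0, 1)
static inline void cr_weights(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t + t2 - 0.5 * t3;
  w[1] = 1.0 - 2.5 * t2 + 1.5 * t3;
  w[2] = 0.5 * t + 2.0 * t2 - 1.5 * t3;
  w[3] = -0.5 * t2 + 0.5 * t3;
}

// Real-space orthographic projection of a cubic volume along the camera
// z-axis, with tricubic (Catmull-Rom) sampling. G (3 x 3) maps centred
// camera coordinates (x, y, z) to centred volume coordinates;
// out-of-volume taps are zero. Used by the simulator as an independent
// projection path (no Fourier-slice code involved); the cubic kernel
// keeps the high-frequency content of the projection faithful.
// [[Rcpp::export]]
NumericMatrix cpp_project_real(NumericVector vol, int n, NumericMatrix G,
                               int n2, double ox, double oy) {
  const double* v = vol.begin();
  NumericMatrix out(n2, n2);
  const double c3 = n / 2.0;
  const double c2 = n2 / 2.0;
  double wx[4], wy[4], wz[4];
  for (int iy = 0; iy < n2; ++iy) {
    const double y = iy - c2 - oy;
    for (int ix = 0; ix < n2; ++ix) {
      const double x = ix - c2 - ox;
      double acc = 0.0;
      for (int izs = 0; izs < n; ++izs) {
        const double z = izs - c3;
        const double px = G(0, 0) * x + G(0, 1) * y + G(0, 2) * z + c3;
        const double py = G(1, 0) * x + G(1, 1) * y + G(1, 2) * z + c3;
        const double pz = G(2, 0) * x + G(2, 1) * y + G(2, 2) * z + c3;
        if (px < 1 || py < 1 || pz < 1 ||
            px > n - 3 || py > n - 3 || pz > n - 3) continue;
        const int fx = (int)px, fy = (int)py, fz = (int)pz;
        cr_weights(px - fx, wx);
        cr_weights(py - fy, wy);
        cr_weights(pz - fz, wz);
        for (int dz = 0; dz < 4; ++dz) {
          const int kz = fz - 1 + dz;
          double accy = 0.0;
          for (int dy = 0; dy < 4; ++dy) {
            const int ky = fy - 1 + dy;
            const double* row = v + lin3(0, ky, kz, n);
            const double vx = wx[0] * row[fx - 1] + wx[1] * row[fx] +
                              wx[2] * row[fx + 1] + wx[3] * row[fx + 2];
            accy += wy[dy] * vx;
          }
          acc += wz[dz] * accy;
        }
      }
      out(ix, iy) = acc;
    }
  }
  return out;
}
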