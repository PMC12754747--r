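// Core numerical kernels: Joseph-style line integration through voxel grids
// (value + analytic gradient w.r.t. the segment endpoints), TOF bin-mass
// kernels, the batched coincidence forward model used by the calibration
// objective, ray-traced back-to-back photon transport for the simulator, and
// trilinear backprojection for list-mode OSEM.
//
// Conventions:
//  - all lengths in mm; voxel centers at origin + (i + 0.5) * spacing
//  - the signed TOF coordinate s is measured along the LOR from its midpoint,
//    positive toward the first endpoint (detector 1)
//  - grids are zero outside their bounding box; fields are expected to carry
//    a zero margin of >= 2 voxels at the grid faces (voxelize_phantom pads),
//    which makes the boundary terms dropped from the analytic gradient
//    negligible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;
static const double INV_SQRT_2 = 0.7071067811865476;

struct Grid {
  const double* v;
  double o[3], sp[3];
  int n[3];
  const int* brick;   // coarse occupancy, may be nullptr
  int bn[3];
  int bsz;
  const double* boxes;  // support AABBs (nb x 6, col-major lo xyz, hi xyz)
  int nboxes;
};

static Grid make_grid(const NumericVector& values, const NumericVector& origin,
                      const NumericVector& spacing, const IntegerVector& dims,
                      const IntegerVector& brick, const IntegerVector& bdims,
                      int bsz, const NumericMatrix& boxes) {
  Grid g;
  g.v = values.begin();
  for (int a = 0; a < 3; ++a) {
    g.o[a] = origin[a];
    g.sp[a] = spacing[a];
    g.n[a] = dims[a];
  }
  if (brick.size() > 0) {
    g.brick = brick.begin();
    for (int a = 0; a < 3; ++a) g.bn[a] = bdims[a];
    g.bsz = bsz;
  } else {
    g.brick = nullptr;
    g.bn[0] = g.bn[1] = g.bn[2] = 0;
    g.bsz = 1;
  }
  g.nboxes = boxes.nrow();
  g.boxes = g.nboxes > 0 ? boxes.begin() : nullptr;
  return g;
}

// trilinear interpolation (zero-padded outside) with optional gradient
static inline double trilin(const Grid& g, const double x[3], double* grad) {
  double gc[3];
  int i0[3];
  double fr[3];
  for (int a = 0; a < 3; ++a) {
    gc[a] = (x[a] - g.o[a]) / g.sp[a] - 0.5;
    double fl = std::floor(gc[a]);
    i0[a] = (int)fl;
    fr[a] = gc[a] - fl;
    if (i0[a] < -1 || i0[a] > g.n[a] - 1) {  // fully outside support
      if (grad) grad[0] = grad[1] = grad[2] = 0.0;
      return 0.0;
    }
  }
  double c[8];
  for (int k = 0; k < 8; ++k) {
    int ia = i0[0] + (k & 1), ib = i0[1] + ((k >> 1) & 1), ic = i0[2] + ((k >> 2) & 1);
    if (ia < 0 || ia >= g.n[0] || ib < 0 || ib >= g.n[1] || ic < 0 || ic >= g.n[2])
      c[k] = 0.0;
    else
      c[k] = g.v[(size_t)ia + (size_t)g.n[0] * ((size_t)ib + (size_t)g.n[1] * ic)];
  }
  double fx = fr[0], fy = fr[1], fz = fr[2];
  double c00 = c[0] * (1 - fx) + c[1] * fx, c10 = c[2] * (1 - fx) + c[3] * fx;
  double c01 = c[4] * (1 - fx) + c[5] * fx, c11 = c[6] * (1 - fx) + c[7] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  double val = c0 * (1 - fz) + c1 * fz;
  if (grad) {
    double dx0 = (c[1] - c[0]) * (1 - fy) + (c[3] - c[2]) * fy;
    double dx1 = (c[5] - c[4]) * (1 - fy) + (c[7] - c[6]) * fy;
    grad[0] = (dx0 * (1 - fz) + dx1 * fz) / g.sp[0];
    grad[1] = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / g.sp[1];
    grad[2] = (c1 - c0) / g.sp[2];
  }
  return val;
}

// scatter w into the 8 trilinear corners around x (adjoint of trilin)
static inline void splat(double* img, const Grid& g, const double x[3], double w) {
  int i0[3];
  double fr[3];
  for (int a = 0; a < 3; ++a) {
    double gc = (x[a] - g.o[a]) / g.sp[a] - 0.5;
    double fl = std::floor(gc);
    i0[a] = (int)fl;
    fr[a] = gc - fl;
    if (i0[a] < -1 || i0[a] > g.n[a] - 1) return;
  }
  for (int k = 0; k < 8; ++k) {
    int ia = i0[0] + (k & 1), ib = i0[1] + ((k >> 1) & 1), ic = i0[2] + ((k >> 2) & 1);
    if (ia < 0 || ia >= g.n[0] || ib < 0 || ib >= g.n[1] || ic < 0 || ic >= g.n[2])
      continue;
    double wk = ((k & 1) ? fr[0] : 1 - fr[0]) * (((k >> 1) & 1) ? fr[1] : 1 - fr[1]) *
                (((k >> 2) & 1) ? fr[2] : 1 - fr[2]);
    img[(size_t)ia + (size_t)g.n[0] * ((size_t)ib + (size_t)g.n[1] * ic)] += w * wk;
  }
}

static inline bool brick_occupied(const Grid& g, const double x[3]) {
  if (!g.brick) return true;
  int b[3];
  for (int a = 0; a < 3; ++a) {
    int i = (int)std::floor((x[a] - g.o[a]) / g.sp[a]);
    b[a] = i / g.bsz;
    if (b[a] < 0) b[a] = 0;
    if (b[a] >= g.bn[a]) b[a] = g.bn[a] - 1;
  }
  return g.brick[b[0] + g.bn[0] * (b[1] + g.bn[1] * b[2])] != 0;
}

// ---- TOF bin-mass kernels -------------------------------------------------
// mode: 0 = none (K = 1), 1 = single bin, 2 = marginal over all bins
struct TofLut {            // tabulated bin mass and derivative (fast path)
  std::vector<double> K1, dK1;   // single-bin mass vs u = s - center
  std::vector<double> K2, dK2;   // marginal mass vs s
  double u0, s0, step;
  int n1, n2;
  bool ready = false;
};

struct Tof {
  int mode;
  double sigma;     // Gaussian sigma (mm) of the localization kernel
  double binw;      // bin width (mm)
  int nbins;
  int tbin;         // 0-based bin index (mode 1)
  bool exact;       // erf-integrated bin mass vs midpoint rule
  const TofLut* lut = nullptr;
  double center(int t) const { return (t - 0.5 * (nbins - 1)) * binw; }
};

static inline double norm_cdf(double z) { return 0.5 * std::erfc(-z * INV_SQRT_2); }
static inline double norm_pdf(double z) { return INV_SQRT_2PI * std::exp(-0.5 * z * z); }

// exact bin mass (no table) used to build the lookup tables
static double tof_mass_exact(const Tof& tf, double s, double* dK);

// build lookup tables for the bin mass and its derivative; resolution
// sigma/64 with linear interpolation keeps the error below ~1e-5 relative
static void tof_build_lut(TofLut& lut, const Tof& tf) {
  if (tf.mode == 0) return;
  double half = 0.5 * tf.binw + 4.5 * tf.sigma;
  // symmetric node layout: +u and -u interpolate identically, preserving
  // the mirror symmetry of the bin mass exactly
  int nh = (int)std::ceil(half / (tf.sigma / 64.0));
  double step = half / nh;
  lut.step = step;
  lut.u0 = -half;
  lut.n1 = 2 * nh + 1;
  lut.K1.resize(lut.n1);
  lut.dK1.resize(lut.n1);
  Tof t1 = tf;
  t1.mode = 1;
  t1.lut = nullptr;
  t1.tbin = (tf.nbins - 1) / 2;   // center bin: mass is a function of s - c
  double c = t1.center(t1.tbin);
  for (int i = 0; i < lut.n1; ++i) {
    double u = lut.u0 + i * step;
    lut.K1[i] = tof_mass_exact(t1, c + u, &lut.dK1[i]);
  }
  double lo = tf.center(0) - 0.5 * tf.binw - 4.5 * tf.sigma;
  double hi = tf.center(tf.nbins - 1) + 0.5 * tf.binw + 4.5 * tf.sigma;
  lut.s0 = lo;
  lut.n2 = (int)std::ceil((hi - lo) / step) + 2;
  lut.K2.resize(lut.n2);
  lut.dK2.resize(lut.n2);
  Tof t2 = tf;
  t2.mode = 2;
  t2.lut = nullptr;
  for (int i = 0; i < lut.n2; ++i)
    lut.K2[i] = tof_mass_exact(t2, lo + i * step, &lut.dK2[i]);
  lut.ready = true;
}

// bin mass K(s) and derivative dK/ds (table-accelerated when available)
static inline double tof_mass(const Tof& tf, double s, double* dK) {
  if (tf.mode == 0) {
    if (dK) *dK = 0.0;
    return 1.0;
  }
  if (tf.lut && tf.lut->ready) {
    const TofLut& L = *tf.lut;
    // the derivative returned is the slope of the interpolant itself, so
    // analytic gradients are exactly consistent with the evaluated value
    if (tf.mode == 1) {
      double u = s - tf.center(tf.tbin);
      double x = (u - L.u0) / L.step;
      if (x <= 0 || x >= L.n1 - 1) {
        if (dK) *dK = 0.0;
        return 0.0;
      }
      int i = (int)x;
      double f = x - i;
      if (dK) *dK = (L.K1[i + 1] - L.K1[i]) / L.step;
      return L.K1[i] * (1 - f) + L.K1[i + 1] * f;
    }
    double x = (s - L.s0) / L.step;
    if (x <= 0 || x >= L.n2 - 1) {
      if (dK) *dK = 0.0;
      return 0.0;
    }
    int i = (int)x;
    double f = x - i;
    if (dK) *dK = (L.K2[i + 1] - L.K2[i]) / L.step;
    return L.K2[i] * (1 - f) + L.K2[i + 1] * f;
  }
  return tof_mass_exact(tf, s, dK);
}

static double tof_mass_exact(const Tof& tf, double s, double* dK) {
  if (tf.mode == 1) {
    double c = tf.center(tf.tbin);
    if (tf.exact) {
      double zh = (c + 0.5 * tf.binw - s) / tf.sigma;
      double zl = (c - 0.5 * tf.binw - s) / tf.sigma;
      if (dK) *dK = -(norm_pdf(zh) - norm_pdf(zl)) / tf.sigma;
      return norm_cdf(zh) - norm_cdf(zl);
    }
    double z = (s - c) / tf.sigma;
    double g = norm_pdf(z) / tf.sigma;  // unit-area Gaussian in s
    if (dK) *dK = -tf.binw * g * z / tf.sigma;
    return tf.binw * g;
  }
  // marginal: bins tile contiguously, so the erf masses telescope
  if (tf.exact) {
    double lo = tf.center(0) - 0.5 * tf.binw;
    double hi = tf.center(tf.nbins - 1) + 0.5 * tf.binw;
    double zh = (hi - s) / tf.sigma, zl = (lo - s) / tf.sigma;
    if (dK) *dK = -(norm_pdf(zh) - norm_pdf(zl)) / tf.sigma;
    return norm_cdf(zh) - norm_cdf(zl);
  }
  double acc = 0.0, dacc = 0.0;
  for (int t = 0; t < tf.nbins; ++t) {
    double z = (s - tf.center(t)) / tf.sigma;
    double g = norm_pdf(z) / tf.sigma;
    acc += tf.binw * g;
    dacc += -tf.binw * g * z / tf.sigma;
  }
  if (dK) *dK = dacc;
  return acc;
}

// ---- Joseph traversal ------------------------------------------------------
// Integrates the trilinear field along segment p0 -> p1, weighted by the TOF
// bin mass. Samples lie at principal-axis plane crossings (where trilinear
// reduces to bilinear) plus the clipped segment ends; trapezoid weights.
// If grad != nullptr, accumulates d(value)/d(p0) into grad[0..2] and
// d(value)/d(p1) into grad[3..5] (interior-sample terms; boundary-limit terms
// are negligible for zero-margin fields).
static double joseph(const Grid& g, const double p0[3], const double p1[3],
                     const Tof& tf, double* grad) {
  double d[3];
  double len2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    len2 += d[a] * d[a];
  }
  double len = std::sqrt(len2);
  if (grad) for (int i = 0; i < 6; ++i) grad[i] = 0.0;
  if (len < 1e-12) return 0.0;

  // clip to the grid's outer box
  double ta = 0.0, tb = 1.0;
  for (int a = 0; a < 3; ++a) {
    double lo = g.o[a], hi = g.o[a] + g.n[a] * g.sp[a];
    if (std::fabs(d[a]) < 1e-300) {
      if (p0[a] < lo || p0[a] > hi) return 0.0;
    } else {
      double t1 = (lo - p0[a]) / d[a], t2 = (hi - p0[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > ta) ta = t1;
      if (t2 < tb) tb = t2;
    }
  }
  if (tb <= ta) return 0.0;

  // clip to the kernel support: s(t) = len * (1/2 - t)
  if (tf.mode == 1) {
    double c = tf.center(tf.tbin);
    double smin = c - 0.5 * tf.binw - 4.0 * tf.sigma;
    double smax = c + 0.5 * tf.binw + 4.0 * tf.sigma;
    // s decreasing in t: t = 1/2 - s/len
    double t1 = 0.5 - smax / len, t2 = 0.5 - smin / len;
    if (t1 > ta) ta = t1;
    if (t2 < tb) tb = t2;
    if (tb <= ta) return 0.0;
  } else if (tf.mode == 2) {
    double lo = tf.center(0) - 0.5 * tf.binw - 4.0 * tf.sigma;
    double hi = tf.center(tf.nbins - 1) + 0.5 * tf.binw + 4.0 * tf.sigma;
    double t1 = 0.5 - hi / len, t2 = 0.5 - lo / len;
    if (t1 > ta) ta = t1;
    if (t2 < tb) tb = t2;
    if (tb <= ta) return 0.0;
  }

  // principal axis: most planes crossed per unit t
  int ax = 0;
  double best = 0.0;
  for (int a = 0; a < 3; ++a) {
    double r = std::fabs(d[a]) / g.sp[a];
    if (r > best) {
      best = r;
      ax = a;
    }
  }
  double dga = d[ax] / g.sp[ax];  // plane-index change per unit t
  double g0a = (p0[ax] - g.o[ax]) / g.sp[ax] - 0.5;

  double val = 0.0;
  double dl = len / std::fabs(dga);  // interior trapezoid weight
  // gradient of dl w.r.t. endpoints
  double ddl_p0[3] = {0, 0, 0}, ddl_p1[3] = {0, 0, 0};
  if (grad) {
    double sgn = (d[ax] >= 0) ? 1.0 : -1.0;
    for (int a = 0; a < 3; ++a) {
      double ud = d[a] / len;
      ddl_p1[a] = g.sp[ax] * ud / std::fabs(d[ax]);
      ddl_p0[a] = -ddl_p1[a];
    }
    ddl_p1[ax] += -g.sp[ax] * len * sgn / (d[ax] * d[ax]);
    ddl_p0[ax] += g.sp[ax] * len * sgn / (d[ax] * d[ax]);
  }

  // integrate one clipped sub-interval [ia, ib] by principal-axis stepping;
  // eval_ends = FALSE when both ends sit on support-box faces, where the
  // field is zero by construction (1-voxel padding) and the endpoint
  // trapezoid samples can be skipped
  auto run = [&](double ia, double ib, bool eval_ends) {
    double ga_ta = g0a + ia * dga, ga_tb = g0a + ib * dga;
    double kmin = std::ceil(std::min(ga_ta, ga_tb) - 1e-12);
    double kmax = std::floor(std::max(ga_ta, ga_tb) + 1e-12);

    // endpoint samples (no gradient contribution: zero margin / kernel tail)
    if (eval_ends) {
      double x[3];
      for (int a = 0; a < 3; ++a) x[a] = p0[a] + ia * d[a];
      double f = brick_occupied(g, x) ? trilin(g, x, nullptr) : 0.0;
      if (f != 0.0) {
        double tnext = (kmin <= kmax) ? (kmin - g0a) / dga : ib;
        if (dga < 0 && kmin <= kmax) tnext = (kmax - g0a) / dga;
        double w = 0.5 * (std::min(tnext, ib) - ia) * len;
        val += f * tof_mass(tf, len * (0.5 - ia), nullptr) * w;
      }
      for (int a = 0; a < 3; ++a) x[a] = p0[a] + ib * d[a];
      f = brick_occupied(g, x) ? trilin(g, x, nullptr) : 0.0;
      if (f != 0.0) {
        double tprev = (kmin <= kmax) ? (kmax - g0a) / dga : ia;
        if (dga < 0 && kmin <= kmax) tprev = (kmin - g0a) / dga;
        double w = 0.5 * (ib - std::max(tprev, ia)) * len;
        val += f * tof_mass(tf, len * (0.5 - ib), nullptr) * w;
      }
    }

    if (kmin > kmax) return;
    int nk = (int)(kmax - kmin) + 1;
    int kstart = (dga >= 0) ? (int)kmin : (int)kmax;
    int kstep = (dga >= 0) ? 1 : -1;

    double x[3], gf[3];
    for (int ik = 0; ik < nk; ++ik) {
      double k = (double)(kstart + kstep * ik);
      double t = (k - g0a) / dga;
      for (int a = 0; a < 3; ++a) x[a] = p0[a] + t * d[a];
      if (!brick_occupied(g, x)) continue;
      // trapezoid weight: half-intervals to the neighboring samples
      double tlo = (ik == 0) ? 0.5 * (ia + t) : t - 0.5 / std::fabs(dga);
      double thi = (ik == nk - 1) ? 0.5 * (t + ib) : t + 0.5 / std::fabs(dga);
      double w = (thi - tlo) * len;
      double s = len * (0.5 - t);
      double dK;
      double K = tof_mass(tf, s, grad ? &dK : nullptr);
      double f = trilin(g, x, grad ? gf : nullptr);
      if (f == 0.0 && (!grad)) continue;
      val += f * K * w;
      if (grad) {
        if (f == 0.0 && gf[0] == 0.0 && gf[1] == 0.0 && gf[2] == 0.0) continue;
        // field term: dF/dp via dx/dp (a-component of x fixed at the plane)
        double gd = gf[0] * d[0] + gf[1] * d[1] + gf[2] * d[2];
        double gperp = (gd - gf[ax] * d[ax]) / d[ax];
        double Kw = K * w;
        for (int a = 0; a < 3; ++a) {
          if (a == ax) continue;
          grad[a] += Kw * gf[a] * (1.0 - t);
          grad[3 + a] += Kw * gf[a] * t;
        }
        grad[ax] += Kw * gperp * (t - 1.0);
        grad[3 + ax] += Kw * gperp * (-t);
        // kernel term: ds/dp
        if (tf.mode != 0) {
          double fw = f * w * dK;
          double c0 = 0.5 - t;
          for (int a = 0; a < 3; ++a) {
            double ud = d[a] / len;
            grad[a] += fw * (-c0 * ud);
            grad[3 + a] += fw * (c0 * ud);
          }
          grad[ax] += fw * (-len * (t - 1.0) / d[ax]);
          grad[3 + ax] += fw * (len * t / d[ax]);
        }
        // weight term (interior weight ~ dl)
        double fK = f * K * (w / dl);
        for (int a = 0; a < 3; ++a) {
          grad[a] += fK * ddl_p0[a];
          grad[3 + a] += fK * ddl_p1[a];
        }
      }
    }
  };

  if (!g.boxes) {
    run(ta, tb, true);
    return val;
  }
  // support boxes: integrate only where the segment crosses a support AABB.
  // Touching or overlapping clipped intervals are merged first, so interval
  // ends always fall in (near-)zero field and the boundary terms absent
  // from the analytic gradient stay negligible.
  int nb = g.nboxes;
  const int CAP = 64;
  double iv_a[CAP], iv_b[CAP];
  int niv = 0;
  for (int b = 0; b < nb; ++b) {
    double ba = ta, bb = tb;
    bool out = false;
    for (int a = 0; a < 3; ++a) {
      double lo = g.boxes[b + nb * a], hi = g.boxes[b + nb * (3 + a)];
      if (std::fabs(d[a]) < 1e-300) {
        if (p0[a] < lo || p0[a] > hi) { out = true; break; }
      } else {
        double t1 = (lo - p0[a]) / d[a], t2 = (hi - p0[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > ba) ba = t1;
        if (t2 < bb) bb = t2;
        if (bb <= ba) { out = true; break; }
      }
    }
    if (!out && bb > ba && niv < CAP) {
      iv_a[niv] = ba;
      iv_b[niv] = bb;
      ++niv;
    }
  }
  if (niv == 0) return val;
  // insertion sort by start (lists are tiny)
  for (int i = 1; i < niv; ++i) {
    double ka = iv_a[i], kb = iv_b[i];
    int j = i - 1;
    while (j >= 0 && iv_a[j] > ka) {
      iv_a[j + 1] = iv_a[j];
      iv_b[j + 1] = iv_b[j];
      --j;
    }
    iv_a[j + 1] = ka;
    iv_b[j + 1] = kb;
  }
  double cur_a = iv_a[0], cur_b = iv_b[0];
  double eps = 1e-7;
  // an interval end matching the global clip (grid boundary or kernel
  // window) still needs its endpoint sample; box-face ends do not
  auto emit = [&](double a, double b) {
    bool clip_end = (a <= ta + eps) || (b >= tb - eps);
    run(a, b, clip_end);
  };
  for (int i = 1; i < niv; ++i) {
    if (iv_a[i] <= cur_b + eps) {
      if (iv_b[i] > cur_b) cur_b = iv_b[i];
    } else {
      emit(cur_a, cur_b);
      cur_a = iv_a[i];
      cur_b = iv_b[i];
    }
  }
  emit(cur_a, cur_b);
  return val;
}

// ---- exported: plain / TOF line integrals ---------------------------------

// [[Rcpp::export]]
NumericVector cpp_line_integrals(NumericVector values, NumericVector origin,
                                 NumericVector spacing, IntegerVector dims,
                                 IntegerVector brick, IntegerVector bdims, int bsz,
                                 NumericMatrix boxes,
                                 NumericMatrix P0, NumericMatrix P1,
                                 List tofspec, bool want_grad,
                                 Nullable<NumericMatrix> grad_out) {
  Grid g = make_grid(values, origin, spacing, dims, brick, bdims, bsz, boxes);
  Tof tf;
  tf.mode = as<int>(tofspec["mode"]);
  tf.sigma = as<double>(tofspec["sigma"]);
  tf.binw = as<double>(tofspec["binw"]);
  tf.nbins = as<int>(tofspec["nbins"]);
  tf.exact = as<bool>(tofspec["exact"]);
  TofLut lut;
  if (tf.mode != 0) {
    tof_build_lut(lut, tf);
    tf.lut = &lut;
  }
  IntegerVector tbins = tofspec["tbin"];  // per-row bin (0-based), recycled
  int n = P0.nrow();
  NumericVector out(n);
  NumericMatrix G;
  if (want_grad) G = NumericMatrix(grad_out.get());
  double p0[3], p1[3], gr[6];
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) {
      p0[a] = P0(i, a);
      p1[a] = P1(i, a);
    }
    tf.tbin = tbins[tbins.size() == 1 ? 0 : i];
    out[i] = joseph(g, p0, p1, tf, want_grad ? gr : nullptr);
    if (want_grad)
      for (int j = 0; j < 6; ++j) G(i, j) = gr[j];
  }
  return out;
}

// ---- exported: batched forward model for calibration ----------------------
// For each coincidence bin, draws n_samples point pairs inside the two
// crystal voxels, evaluates attenuation x TOF-weighted activity integral per
// sampled line, and averages. Optionally returns d(mu)/d(12 block params):
// [T_d1 (3), R_d1 (3), T_d2 (3), R_d2 (3)], rotations in degrees.

// [[Rcpp::export]]
List cpp_batch_forward(NumericMatrix pos_eff,      // Ndet x 3: P + T
                       NumericMatrix axes,         // Ndet x 9: blueprint X,Y,Z rows
                       NumericMatrix rot,          // Ndet x 9: M (row-major rows)
                       NumericMatrix drot,         // Ndet x 27: dM/dRx,dRy,dRz (deg)
                       NumericMatrix lut_centers,  // Ncr x 3 (block-local mm)
                       NumericMatrix lut_half,     // Ncr x 3
                       IntegerVector d1, IntegerVector cr1,
                       IntegerVector d2, IntegerVector cr2,
                       IntegerVector tbin,         // 0-based; -1 => TOF-marginal
                       NumericVector Fv, NumericVector Fo, NumericVector Fsp,
                       IntegerVector Fd, IntegerVector Fbrick, IntegerVector Fbd,
                       int Fbsz, NumericMatrix Fboxes,
                       Nullable<NumericVector> Av_, NumericVector Ao,
                       NumericVector Asp, IntegerVector Ad,
                       List tofspec, int n_samples, int seed, bool want_grad) {
  Grid gF = make_grid(Fv, Fo, Fsp, Fd, Fbrick, Fbd, Fbsz, Fboxes);
  bool useA = Av_.isNotNull();
  NumericVector Av;
  Grid gA;
  IntegerVector noBrick(0);
  NumericMatrix noBoxes(0, 6);
  if (useA) {
    Av = NumericVector(Av_.get());
    gA = make_grid(Av, Ao, Asp, Ad, noBrick, noBrick, 1, noBoxes);
  }
  Tof tf;
  tf.mode = as<int>(tofspec["mode"]);
  tf.sigma = as<double>(tofspec["sigma"]);
  tf.binw = as<double>(tofspec["binw"]);
  tf.nbins = as<int>(tofspec["nbins"]);
  tf.exact = as<bool>(tofspec["exact"]);
  TofLut lut;
  if (tf.mode != 0) {
    tof_build_lut(lut, tf);
    tf.lut = &lut;
  }
  Tof tfA;
  tfA.mode = 0;  // attenuation along the full LOR
  tfA.sigma = 1;
  tfA.binw = 1;
  tfA.nbins = 1;
  tfA.exact = false;
  tfA.tbin = 0;

  int n = d1.size();
  NumericVector mu(n);
  NumericMatrix G = want_grad ? NumericMatrix(n, 12) : NumericMatrix(0, 0);
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1442695040888963407ULL);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);

  double p0[3], p1[3], gr[6], grA[6];
  double w1[3], w2[3];
  for (int i = 0; i < n; ++i) {
    int b1 = d1[i], b2 = d2[i], c1 = cr1[i], c2 = cr2[i];
    if (tf.mode != 0) tf.tbin = tbin[i];
    int mode_i = (tf.mode == 0) ? 0 : (tbin[i] < 0 ? 2 : 1);
    Tof tfi = tf;
    tfi.mode = mode_i;
    double acc = 0.0;
    double gacc[12] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    double prev1[3] = {0, 0, 0}, prev2[3] = {0, 0, 0};
    for (int s = 0; s < n_samples; ++s) {
      // local offsets within the crystal voxels (antithetic pairs for
      // variance reduction), then to global via blueprint axes and the
      // per-block alignment rotation
      double l1[3], l2[3];
      if (s % 2 == 0) {
        for (int a = 0; a < 3; ++a) prev1[a] = unif(rng) * lut_half(c1, a);
        for (int a = 0; a < 3; ++a) prev2[a] = unif(rng) * lut_half(c2, a);
      } else {
        for (int a = 0; a < 3; ++a) prev1[a] = -prev1[a];
        for (int a = 0; a < 3; ++a) prev2[a] = -prev2[a];
      }
      for (int a = 0; a < 3; ++a) l1[a] = lut_centers(c1, a) + prev1[a];
      for (int a = 0; a < 3; ++a) l2[a] = lut_centers(c2, a) + prev2[a];
      for (int a = 0; a < 3; ++a) {
        w1[a] = axes(b1, a) * l1[0] + axes(b1, 3 + a) * l1[1] + axes(b1, 6 + a) * l1[2];
        w2[a] = axes(b2, a) * l2[0] + axes(b2, 3 + a) * l2[1] + axes(b2, 6 + a) * l2[2];
      }
      for (int a = 0; a < 3; ++a) {
        p0[a] = pos_eff(b1, a) + rot(b1, 3 * a) * w1[0] + rot(b1, 3 * a + 1) * w1[1] +
                rot(b1, 3 * a + 2) * w1[2];
        p1[a] = pos_eff(b2, a) + rot(b2, 3 * a) * w2[0] + rot(b2, 3 * a + 1) * w2[1] +
                rot(b2, 3 * a + 2) * w2[2];
      }
      double tv = joseph(gF, p0, p1, tfi, want_grad ? gr : nullptr);
      double att = 1.0, av = 0.0;
      if (useA) {
        av = joseph(gA, p0, p1, tfA, want_grad ? grA : nullptr);
        att = std::exp(-av);
      }
      acc += att * tv;
      if (want_grad) {
        double dv[6];
        for (int j = 0; j < 6; ++j)
          dv[j] = useA ? att * (gr[j] - tv * grA[j]) : gr[j];
        // chain to block parameters
        for (int a = 0; a < 3; ++a) {
          gacc[a] += dv[a];          // dT_d1
          gacc[6 + a] += dv[3 + a];  // dT_d2
        }
        for (int r = 0; r < 3; ++r) {  // rotation angles (degrees)
          double acc1 = 0.0, acc2 = 0.0;
          for (int a = 0; a < 3; ++a) {
            double dMw1 = drot(b1, 9 * r + 3 * a) * w1[0] +
                          drot(b1, 9 * r + 3 * a + 1) * w1[1] +
                          drot(b1, 9 * r + 3 * a + 2) * w1[2];
            double dMw2 = drot(b2, 9 * r + 3 * a) * w2[0] +
                          drot(b2, 9 * r + 3 * a + 1) * w2[1] +
                          drot(b2, 9 * r + 3 * a + 2) * w2[2];
            acc1 += dv[a] * dMw1;
            acc2 += dv[3 + a] * dMw2;
          }
          gacc[3 + r] += acc1;
          gacc[9 + r] += acc2;
        }
      }
    }
    mu[i] = acc / n_samples;
    if (want_grad)
      for (int j = 0; j < 12; ++j) G(i, j) = gacc[j] / n_samples;
  }
  if (want_grad) return List::create(_["mu"] = mu, _["grad"] = G);
  return List::create(_["mu"] = mu);
}

// ---- exported: back-to-back photon transport ------------------------------
// For each emission point / direction, casts the two opposed rays and finds
// the first block each enters. The interaction point sits at distance
// u * free_path_max along the chord from the entry point (uniform free path,
// thin-absorber limit); if that exceeds the chord the photon escapes and the
// coincidence is rejected. Detection probability is therefore proportional
// to the path length inside the block, matching the line-integral response
// model. Returns block-local interaction coordinates so events can be
// rebinned under any crystal-voxel layout.

// [[Rcpp::export]]
List cpp_trace_rays(NumericMatrix pos,    // Ndet x 3 block centers (ground truth)
                    NumericMatrix axes,   // Ndet x 9 unit axes X,Y,Z (rows of 3)
                    NumericVector half,   // block half-dims (local x,y,z), mm
                    NumericMatrix em,     // n x 3 emission points
                    NumericMatrix dir,    // n x 3 unit directions
                    NumericVector u1, NumericVector u2,
                    double free_path_max, bool prune = true) {
  int nd = pos.nrow(), n = em.nrow();
  IntegerVector D1(n), D2(n);
  NumericMatrix L1(n, 3), L2(n, 3);
  NumericVector S(n);
  LogicalVector ok(n);
  double hx = half[0], hy = half[1], hz = half[2];
  // pruning precomputation: block azimuths / z on the mid-radius cylinder
  std::vector<double> bphi(nd), bz(nd);
  double Rc = 0.0;
  for (int d = 0; d < nd; ++d) {
    bphi[d] = std::atan2(pos(d, 1), pos(d, 0));
    bz[d] = pos(d, 2);
    Rc += std::sqrt(pos(d, 0) * pos(d, 0) + pos(d, 1) * pos(d, 1));
  }
  Rc /= nd;
  // generous angular / axial halfwidths (block extent + misalignment slack)
  double dphi_max = std::atan2(hx + hy + 10.0, Rc - hy - 5.0);
  for (int i = 0; i < n; ++i) {
    double e[3] = {em(i, 0), em(i, 1), em(i, 2)};
    double v[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double tint[2] = {-1, -1};
    int blk[2] = {-1, -1};
    double loc[2][3];
    for (int side = 0; side < 2; ++side) {
      double sgn = side == 0 ? 1.0 : -1.0;
      double bestt = 1e300;
      // crossing of the mid-radius cylinder (for candidate pruning)
      double cphi = 0.0, cz = 0.0, dz_max = 1e300;
      bool have_cross = false;
      if (prune) {
        double ex = e[0], ey = e[1];
        double wx = sgn * v[0], wy = sgn * v[1], wz = sgn * v[2];
        double a2 = wx * wx + wy * wy;
        if (a2 > 1e-12) {
          double b2 = ex * wx + ey * wy;
          double c2 = ex * ex + ey * ey - Rc * Rc;
          double disc = b2 * b2 - a2 * c2;
          if (disc >= 0) {
            double tc = (-b2 + std::sqrt(disc)) / a2;
            if (tc > 0) {
              have_cross = true;
              cphi = std::atan2(ey + tc * wy, ex + tc * wx);
              cz = e[2] + tc * wz;
              dz_max = hz + 10.0 +
                       std::fabs(wz) / std::sqrt(a2) * (2.0 * hy + 10.0);
            }
          }
        }
        if (!have_cross) continue;  // exits axially: cannot hit the ring
      }
      for (int d = 0; d < nd; ++d) {
        if (prune) {
          double dphi = std::fabs(bphi[d] - cphi);
          if (dphi > M_PI) dphi = 2 * M_PI - dphi;
          if (dphi > dphi_max || std::fabs(bz[d] - cz) > dz_max) continue;
        }
        // ray in block-local frame
        double q[3], w[3];
        for (int a = 0; a < 3; ++a) {
          double ea = e[0] - pos(d, 0), eb = e[1] - pos(d, 1), ec = e[2] - pos(d, 2);
          q[a] = axes(d, 3 * a) * ea + axes(d, 3 * a + 1) * eb + axes(d, 3 * a + 2) * ec;
          w[a] = sgn * (axes(d, 3 * a) * v[0] + axes(d, 3 * a + 1) * v[1] +
                        axes(d, 3 * a + 2) * v[2]);
        }
        double h3[3] = {hx, hy, hz};
        double t0 = 0.0, t1 = 1e300;
        bool hit = true;
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(w[a]) < 1e-12) {
            if (q[a] < -h3[a] || q[a] > h3[a]) { hit = false; break; }
          } else {
            double ta = (-h3[a] - q[a]) / w[a], tb = (h3[a] - q[a]) / w[a];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
            if (t0 >= t1) { hit = false; break; }
          }
        }
        if (!hit || t1 <= 1e-9) continue;
        if (t0 < bestt) {
          bestt = t0;
          double u = side == 0 ? u1[i] : u2[i];
          double tin = t0 + u * free_path_max;
          if (tin <= t1) {   // interacted before exiting; else escapes
            blk[side] = d;
            tint[side] = tin;
            for (int a = 0; a < 3; ++a) loc[side][a] = q[a] + tin * w[a];
          } else {
            blk[side] = -1;
          }
        }
      }
    }
    if (blk[0] >= 0 && blk[1] >= 0) {
      ok[i] = true;
      D1[i] = blk[0];
      D2[i] = blk[1];
      for (int a = 0; a < 3; ++a) {
        L1(i, a) = loc[0][a];
        L2(i, a) = loc[1][a];
      }
      // signed midpoint offset toward detector 1 along the LOR
      S[i] = 0.5 * (tint[1] - tint[0]);
    } else {
      ok[i] = false;
    }
  }
  return List::create(_["ok"] = ok, _["d1"] = D1, _["d2"] = D2, _["l1"] = L1,
                      _["l2"] = L2, _["s"] = S);
}

// ---- exported: trilinear TOF backprojection -------------------------------
// Adds w_i * K(s) * dl at every Joseph sample of each segment into img.

// [[Rcpp::export]]
void cpp_backproject(NumericVector img,  // modified in place (dims as grid)
                     NumericVector origin, NumericVector spacing, IntegerVector dims,
                     NumericMatrix P0, NumericMatrix P1, NumericVector wts,
                     IntegerVector tbin,  // 0-based; -1 marginal; -2 plain
                     List tofspec) {
  IntegerVector noBrick(0);
  NumericMatrix noBoxes(0, 6);
  Grid g = make_grid(img, origin, spacing, dims, noBrick, noBrick, 1, noBoxes);
  double* im = img.begin();
  Tof tf;
  tf.sigma = as<double>(tofspec["sigma"]);
  tf.binw = as<double>(tofspec["binw"]);
  tf.nbins = as<int>(tofspec["nbins"]);
  tf.exact = as<bool>(tofspec["exact"]);
  int n = P0.nrow();
  double p0[3], p1[3];
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) {
      p0[a] = P0(i, a);
      p1[a] = P1(i, a);
    }
    int tb = tbin[i];
    tf.mode = tb == -2 ? 0 : (tb == -1 ? 2 : 1);
    tf.tbin = tb >= 0 ? tb : 0;
    double d[3];
    double len2 = 0;
    for (int a = 0; a < 3; ++a) {
      d[a] = p1[a] - p0[a];
      len2 += d[a] * d[a];
    }
    double len = std::sqrt(len2);
    if (len < 1e-12) continue;
    double ta = 0.0, tb2 = 1.0;
    bool out = false;
    for (int a = 0; a < 3; ++a) {
      double lo = g.o[a], hi = g.o[a] + g.n[a] * g.sp[a];
      if (std::fabs(d[a]) < 1e-300) {
        if (p0[a] < lo || p0[a] > hi) { out = true; break; }
      } else {
        double t1 = (lo - p0[a]) / d[a], t2 = (hi - p0[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > ta) ta = t1;
        if (t2 < tb2) tb2 = t2;
      }
    }
    if (out || tb2 <= ta) continue;
    if (tf.mode == 1) {
      double c = tf.center(tf.tbin);
      double t1 = 0.5 - (c + 0.5 * tf.binw + 4 * tf.sigma) / len;
      double t2 = 0.5 - (c - 0.5 * tf.binw - 4 * tf.sigma) / len;
      if (t1 > ta) ta = t1;
      if (t2 < tb2) tb2 = t2;
      if (tb2 <= ta) continue;
    }
    int ax = 0;
    double best = 0;
    for (int a = 0; a < 3; ++a) {
      double r = std::fabs(d[a]) / g.sp[a];
      if (r > best) { best = r; ax = a; }
    }
    double dga = d[ax] / g.sp[ax];
    double g0a = (p0[ax] - g.o[ax]) / g.sp[ax] - 0.5;
    double ga1 = g0a + ta * dga, ga2 = g0a + tb2 * dga;
    double kmin = std::ceil(std::min(ga1, ga2) - 1e-12);
    double kmax = std::floor(std::max(ga1, ga2) + 1e-12);
    if (kmin > kmax) continue;
    double dl = len / std::fabs(dga);
    int nk = (int)(kmax - kmin) + 1;
    double x[3];
    for (int ik = 0; ik < nk; ++ik) {
      double k = kmin + ik;
      double t = (k - g0a) / dga;
      for (int a = 0; a < 3; ++a) x[a] = p0[a] + t * d[a];
      double K = tof_mass(tf, len * (0.5 - t), nullptr);
      double w = wts[i] * K * dl;
      if (w != 0.0) splat(im, g, x, w);
    }
  }
}
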