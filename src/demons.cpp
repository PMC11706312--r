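#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Intensity-driven (Thirion) demons for 2D frames with Gaussian
// regularization of the displacement field and a coarse-to-fine pyramid.
// Displacements are stored in voxel units, (row, col) components.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sampling with clamped (replicated) borders.
static inline double sampleBilinear(const NumericMatrix &img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

static NumericMatrix warpImage(const NumericMatrix &img,
                               const NumericMatrix &ur,
                               const NumericMatrix &uc) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = sampleBilinear(img, r + ur(r, c), c + uc(r, c));
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, replicated edges.
static void gaussSmooth(NumericMatrix &f, double sigma) {
  if (sigma <= 0) return;
  const int nr = f.nrow(), nc = f.ncol();
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = (int)clampd(r + i, 0, nr - 1);
        acc += k[i + rad] * f(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = (int)clampd(c + i, 0, nc - 1);
        acc += k[i + rad] * tmp(r, cc);
      }
      f(r, c) = acc;
    }
}

// Block-mean downsampling by a factor of 2 (trailing odd row/col averaged in).
static NumericMatrix downsample2(const NumericMatrix &img) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = (nr + 1) / 2, mc = (nc + 1) / 2;
  NumericMatrix out(mr, mc);
  for (int c = 0; c < mc; ++c)
    for (int r = 0; r < mr; ++r) {
      double acc = 0;
      int n = 0;
      for (int dr = 0; dr < 2; ++dr)
        for (int dc = 0; dc < 2; ++dc) {
          int rr = 2 * r + dr, cc = 2 * c + dc;
          if (rr < nr && cc < nc) { acc += img(rr, cc); ++n; }
        }
      out(r, c) = acc / n;
    }
  return out;
}

// Bilinear upsampling of a displacement component to (nr, nc), values x2.
static NumericMatrix upsampleField(const NumericMatrix &u, int nr, int nc) {
  NumericMatrix out(nr, nc);
  const double sr = (double)u.nrow() / nr, sc = (double)u.ncol() / nc;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = 2.0 * sampleBilinear(u, (r + 0.5) * sr - 0.5, (c + 0.5) * sc - 0.5);
  return out;
}

// One pyramid level of demons iterations; updates ur, uc in place.
static void demonsLevel(const NumericMatrix &fixed, const NumericMatrix &moving,
                        NumericMatrix &ur, NumericMatrix &uc,
                        int maxIter, double sigmaField, double stepTol,
                        double sigmaUpdate) {
  const int nr = fixed.nrow(), nc = fixed.ncol();
  NumericMatrix dur(nr, nc), duc(nr, nc);
  double prevStep = R_PosInf;
  for (int it = 0; it < maxIter; ++it) {
    NumericMatrix mw = warpImage(moving, ur, uc);
    double meanStep = 0;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        // symmetric force: average of fixed and warped-moving gradients
        int rm = r > 0 ? r - 1 : r, rp = r < nr - 1 ? r + 1 : r;
        int cm = c > 0 ? c - 1 : c, cp = c < nc - 1 ? c + 1 : c;
        double gr = 0.5 * ((fixed(rp, c) - fixed(rm, c)) / (rp - rm > 0 ? rp - rm : 1) +
                           (mw(rp, c) - mw(rm, c)) / (rp - rm > 0 ? rp - rm : 1));
        double gc = 0.5 * ((fixed(r, cp) - fixed(r, cm)) / (cp - cm > 0 ? cp - cm : 1) +
                           (mw(r, cp) - mw(r, cm)) / (cp - cm > 0 ? cp - cm : 1));
        double diff = fixed(r, c) - mw(r, c);
        double denom = gr * gr + gc * gc + diff * diff;
        double sr_ = 0, sc_ = 0;
        if (denom > 1e-12) {
          sr_ = diff * gr / denom;
          sc_ = diff * gc / denom;
          // cap single-iteration displacement for stability
          double mag = std::sqrt(sr_ * sr_ + sc_ * sc_);
          if (mag > 1.25) { sr_ *= 1.25 / mag; sc_ *= 1.25 / mag; }
        }
        dur(r, c) = sr_;
        duc(r, c) = sc_;
        meanStep += std::sqrt(sr_ * sr_ + sc_ * sc_);
      }
    }
    meanStep /= (double)(nr * nc);
    // fluid-like smoothing of the update suppresses noise-driven forces
    gaussSmooth(dur, sigmaUpdate);
    gaussSmooth(duc, sigmaUpdate);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        ur(r, c) += dur(r, c);
        uc(r, c) += duc(r, c);
      }
    gaussSmooth(ur, sigmaField);
    gaussSmooth(uc, sigmaField);
    // stop on convergence or when progress plateaus (noise floor reached)
    if (meanStep < stepTol || (it > 3 && meanStep > 0.95 * prevStep)) break;
    prevStep = meanStep;
  }
}

//' @noRd
// [[Rcpp::export(name = ".demons_register_cpp")]]
List demons_register_cpp(NumericMatrix fixed, NumericMatrix moving,
                         int levels = 3, int max_iter = 50,
                         double sigma_field = 1.5, double sigma_pre = 0.5,
                         double step_tol = 0.01,
                         Nullable<NumericMatrix> ur_init = R_NilValue,
                         Nullable<NumericMatrix> uc_init = R_NilValue,
                         double sigma_update = 1.0) {
  NumericMatrix mv = clone(moving);
  NumericMatrix fx = clone(fixed);
  gaussSmooth(mv, sigma_pre);
  gaussSmooth(fx, sigma_pre);
  NumericMatrix ur, uc;
  if (ur_init.isNotNull() && uc_init.isNotNull()) {
    // warm start: refine at full resolution only
    ur = clone(NumericMatrix(ur_init.get()));
    uc = clone(NumericMatrix(uc_init.get()));
    demonsLevel(fx, mv, ur, uc, max_iter, sigma_field, step_tol, sigma_update);
  } else {
    std::vector<NumericMatrix> pyrF, pyrM;
    pyrF.push_back(fx);
    pyrM.push_back(mv);
    for (int l = 1; l < levels; ++l) {
      pyrF.push_back(downsample2(pyrF[l - 1]));
      pyrM.push_back(downsample2(pyrM[l - 1]));
    }
    ur = NumericMatrix(pyrF[levels - 1].nrow(), pyrF[levels - 1].ncol());
    uc = NumericMatrix(pyrF[levels - 1].nrow(), pyrF[levels - 1].ncol());
    for (int l = levels - 1; l >= 0; --l) {
      if (l < levels - 1) {
        ur = upsampleField(ur, pyrF[l].nrow(), pyrF[l].ncol());
        uc = upsampleField(uc, pyrF[l].nrow(), pyrF[l].ncol());
      }
      demonsLevel(pyrF[l], pyrM[l], ur, uc, max_iter, sigma_field, step_tol,
                  sigma_update);
    }
  }
  NumericMatrix warped = warpImage(moving, ur, uc);
  double meanDisp = 0;
  for (int c = 0; c < uc.ncol(); ++c)
    for (int r = 0; r < ur.nrow(); ++r)
      meanDisp += std::sqrt(ur(r, c) * ur(r, c) + uc(r, c) * uc(r, c));
  meanDisp /= (double)(ur.nrow() * ur.ncol());
  return List::create(_["warped"] = warped, _["ur"] = ur, _["uc"] = uc,
                      _["mean_displacement_vox"] = meanDisp);
}

//' @noRd
// [[Rcpp::export(name = ".warp_bilinear_cpp")]]
NumericMatrix warp_bilinear_cpp(NumericMatrix img, NumericMatrix ur, NumericMatrix uc) {
  return warpImage(img, ur, uc);
}
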