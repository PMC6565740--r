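#include <Rcpp.h>
using namespace Rcpp;

// Bilinear rotation of an image about (cr, cc) (1-based, fractional allowed)
// by `angle_deg` counter-clockwise in the usual (x right, y up) sense, which
// on a row-major image with rows increasing downwards corresponds to the
// inverse mapping used below. Pixels sampling outside the source are set to
// `fill` and reported via the companion weight map when requested.

// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(const NumericMatrix& img, double angle_deg,
                                  double cr, double cc, double fill = 0.0) {
  const int n = img.nrow(), m = img.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double co = std::cos(th), si = std::sin(th);
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double dc = (j + 1) - cc;
    for (int i = 0; i < n; ++i) {
      const double dr = (i + 1) - cr;
      // inverse rotation: where does output pixel come from in the source?
      const double sr = co * dr + si * dc + cr;
      const double sc = -si * dr + co * dc + cc;
      if (sr >= 1 && sr <= n && sc >= 1 && sc <= m) {
        const int r0 = std::min((int)std::floor(sr), n - 1);
        const int c0 = std::min((int)std::floor(sc), m - 1);
        const double fr = sr - r0, fc = sc - c0;
        const double* col0 = &img(0, c0 - 1);
        const double* col1 = &img(0, c0);
        const double v =
          (1 - fr) * (1 - fc) * col0[r0 - 1] + fr * (1 - fc) * col0[r0] +
          (1 - fr) * fc * col1[r0 - 1] + fr * fc * col1[r0];
        out(i, j) = v;
      } else {
        out(i, j) = fill;
      }
    }
  }
  return out;
}

// Rotate an image and a validity weight map together: the weight of an output
// pixel is the bilinear interpolation of the source validity (1 = good,
// 0 = masked/outside). Used by the merge step so that pixels fed by masked
// source regions are down-weighted rather than silently averaged in.

// [[Rcpp::export]]
List cpp_rotate_weighted(const NumericMatrix& img, const NumericMatrix& wt,
                         double angle_deg, double cr, double cc) {
  const int n = img.nrow(), m = img.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double co = std::cos(th), si = std::sin(th);
  NumericMatrix out(n, m), wout(n, m);
  for (int j = 0; j < m; ++j) {
    const double dc = (j + 1) - cc;
    for (int i = 0; i < n; ++i) {
      const double dr = (i + 1) - cr;
      const double sr = co * dr + si * dc + cr;
      const double sc = -si * dr + co * dc + cc;
      if (sr >= 1 && sr <= n && sc >= 1 && sc <= m) {
        const int r0 = std::min((int)std::floor(sr), n - 1);
        const int c0 = std::min((int)std::floor(sc), m - 1);
        const double fr = sr - r0, fc = sc - c0;
        const double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
        const double w01 = (1 - fr) * fc, w11 = fr * fc;
        out(i, j) = w00 * img(r0 - 1, c0 - 1) + w10 * img(r0, c0 - 1) +
                    w01 * img(r0 - 1, c0) + w11 * img(r0, c0);
        wout(i, j) = w00 * wt(r0 - 1, c0 - 1) + w10 * wt(r0, c0 - 1) +
                     w01 * wt(r0 - 1, c0) + w11 * wt(r0, c0);
      }
    }
  }
  return List::create(_["image"] = out, _["weight"] = wout);
}

// Accumulate `weight` x rotate(img, angle) into `acc` in place. `acc` must be
// a plain double matrix owned by the caller; used by the shot simulator to sum
// per-filament intensities without allocating one matrix per filament.

// [[Rcpp::export]]
void cpp_accumulate_rotated(NumericMatrix acc, const NumericMatrix& img,
                            double angle_deg, double cr, double cc,
                            double weight) {
  const int n = img.nrow(), m = img.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double co = std::cos(th), si = std::sin(th);
  for (int j = 0; j < m; ++j) {
    const double dc = (j + 1) - cc;
    for (int i = 0; i < n; ++i) {
      const double dr = (i + 1) - cr;
      const double sr = co * dr + si * dc + cr;
      const double sc = -si * dr + co * dc + cc;
      if (sr >= 1 && sr <= n && sc >= 1 && sc <= m) {
        const int r0 = std::min((int)std::floor(sr), n - 1);
        const int c0 = std::min((int)std::floor(sc), m - 1);
        const double fr = sr - r0, fc = sc - c0;
        const double* col0 = &img(0, c0 - 1);
        const double* col1 = &img(0, c0);
        acc(i, j) += weight *
          ((1 - fr) * (1 - fc) * col0[r0 - 1] + fr * (1 - fc) * col0[r0] +
           (1 - fr) * fc * col1[r0 - 1] + fr * fc * col1[r0]);
      }
    }
  }
}
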