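// Separable Gaussian (derivative) convolution for 3-D volumes stored as
// R arrays with dim = c(nz, ny, nx), z fastest in memory.  Boundaries are
// handled by reflection (half-sample symmetric), matching the usual
// image-processing convention.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sampled Gaussian-derivative kernel.  The order-0 kernel is normalized to
// sum 1; derivative kernels are the analytic derivatives of that normalized
// kernel, so a constant input maps to 0 for order >= 1.
static std::vector<double> gauss_kernel(double sigma, int order, int radius) {
  std::vector<double> k(2 * radius + 1);
  const double s2 = sigma * sigma;
  double sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / s2);
    sum += k[i + radius];
  }
  for (auto &v : k) v /= sum;
  if (order == 1) {
    for (int i = -radius; i <= radius; ++i) k[i + radius] *= -i / s2;
  } else if (order == 2) {
    for (int i = -radius; i <= radius; ++i) k[i + radius] *= (i * i - s2) / (s2 * s2);
    // truncation leaves a nonzero sum that would leak constants into the
    // second derivative; project it out so constants map exactly to zero
    double s = 0.0;
    for (auto v : k) s += v;
    s /= k.size();
    for (auto &v : k) v -= s;
  }
  return k;
}

static inline int reflect(int i, int n) {
  // half-sample symmetric: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Convolve along axis 0 (contiguous lines).
static void conv_axis0(const double *in, double *out, int d0, long nlines,
                       const std::vector<double> &k, int r) {
  const int taps = 2 * r + 1;
  for (long l = 0; l < nlines; ++l) {
    const double *src = in + l * d0;
    double *dst = out + l * d0;
    const int lo = std::min(r, d0), hi = std::max(d0 - r, lo);
    for (int i = 0; i < lo; ++i) {
      double acc = 0;
      for (int t = 0; t < taps; ++t) acc += k[t] * src[reflect(i + t - r, d0)];
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {  // interior fast path
      double acc = 0;
      const double *s = src + i - r;
      for (int t = 0; t < taps; ++t) acc += k[t] * s[t];
      dst[i] = acc;
    }
    for (int i = hi; i < d0; ++i) {
      double acc = 0;
      for (int t = 0; t < taps; ++t) acc += k[t] * src[reflect(i + t - r, d0)];
      dst[i] = acc;
    }
  }
}

// Convolve along a strided axis: for each output hyper-row, accumulate
// weighted contiguous runs (cache friendly for axes 1 and 2).
static void conv_axis_strided(const double *in, double *out, int run, int n,
                              long nouter, long outer_stride,
                              const std::vector<double> &k, int r) {
  const int taps = 2 * r + 1;
  for (long o = 0; o < nouter; ++o) {
    const double *src = in + o * outer_stride;
    double *dst = out + o * outer_stride;
    for (int j = 0; j < n; ++j) {
      double *d = dst + (long)j * run;
      for (int x = 0; x < run; ++x) d[x] = 0.0;
      for (int t = 0; t < taps; ++t) {
        const double w = k[t];
        if (w == 0.0) continue;
        const double *s = src + (long)reflect(j + t - r, n) * run;
        for (int x = 0; x < run; ++x) d[x] += w * s[x];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_deriv(NumericVector v, IntegerVector dims,
                                 double sigma, IntegerVector orders,
                                 double truncate = 4.0) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  if ((long)d0 * d1 * d2 != (long)v.size()) stop("dims do not match data length");
  if (sigma <= 0) stop("sigma must be > 0");
  const int r = std::max(1, (int)std::lround(truncate * sigma));
  NumericVector out(v.size());
  std::vector<double> buf(v.size());
  const double *src = v.begin();
  double *a = out.begin(), *b = buf.data();
  // axis 0 (z)
  conv_axis0(src, a, d0, (long)d1 * d2, gauss_kernel(sigma, orders[0], r), r);
  // axis 1 (y): runs of length d0, n = d1, outer = d2
  conv_axis_strided(a, b, d0, d1, d2, (long)d0 * d1, gauss_kernel(sigma, orders[1], r), r);
  // axis 2 (x): runs of length d0*d1, n = d2, outer = 1
  conv_axis_strided(b, a, d0 * d1, d2, 1, (long)d0 * d1 * d2, gauss_kernel(sigma, orders[2], r), r);
  return out;
}
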