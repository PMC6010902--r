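// Voxel-wise eigenvalues of the symmetric 3x3 Hessian and the multi-scale
// objectness (Frangi-type) response built from them.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric method),
// returned in ascending order of signed value.
static inline void eig3_sym(double a00, double a01, double a02,
                            double a11, double a12, double a22,
                            double w[3]) {
  const double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  if (p1 == 0.0) {
    w[0] = a00; w[1] = a11; w[2] = a22;
  } else {
    const double q = (a00 + a11 + a22) / 3.0;
    const double b00 = a00 - q, b11 = a11 - q, b22 = a22 - q;
    const double p2 = b00 * b00 + b11 * b11 + b22 * b22 + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    const double det = b00 * (b11 * b22 - a12 * a12)
                     - a01 * (a01 * b22 - a12 * a02)
                     + a02 * (a01 * a12 - b11 * a02);
    double r = det / (2.0 * p * p * p);
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    w[2] = q + 2.0 * p * std::cos(phi);
    w[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    w[1] = 3.0 * q - w[2] - w[0];
  }
  if (w[0] > w[1]) std::swap(w[0], w[1]);
  if (w[1] > w[2]) std::swap(w[1], w[2]);
  if (w[0] > w[1]) std::swap(w[0], w[1]);
}

static inline void sort_by_abs(double w[3]) {
  if (std::abs(w[0]) > std::abs(w[1])) std::swap(w[0], w[1]);
  if (std::abs(w[1]) > std::abs(w[2])) std::swap(w[1], w[2]);
  if (std::abs(w[0]) > std::abs(w[1])) std::swap(w[0], w[1]);
}

// Eigenvalue volumes sorted by |lambda1| <= |lambda2| <= |lambda3|.
// [[Rcpp::export]]
List cpp_eig3_volumes(NumericVector hzz, NumericVector hyy, NumericVector hxx,
                      NumericVector hzy, NumericVector hzx, NumericVector hyx) {
  const R_xlen_t n = hzz.size();
  NumericVector l1(n), l2(n), l3(n);
  double w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig3_sym(hzz[i], hzy[i], hzx[i], hyy[i], hyx[i], hxx[i], w);
    sort_by_abs(w);
    l1[i] = w[0]; l2[i] = w[1]; l3[i] = w[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// Single-scale objectness response.  blob_enhance = true flips the R_B term
// to (1 - exp(-R_B^2/2beta^2)) so that blob-like somata are enhanced rather
// than suppressed (ITK objectness convention for 0-dimensional structures);
// blob_enhance = false is the textbook vesselness (tubes only).
// bright = true requires lambda2, lambda3 < 0 (bright on dark).
// [[Rcpp::export]]
NumericVector cpp_objectness(NumericVector hzz, NumericVector hyy, NumericVector hxx,
                             NumericVector hzy, NumericVector hzx, NumericVector hyx,
                             double alpha, double beta, double gamma,
                             bool blob_enhance, bool bright) {
  const R_xlen_t n = hzz.size();
  NumericVector out(n);
  const double ia = 1.0 / (2.0 * alpha * alpha);
  const double ib = 1.0 / (2.0 * beta * beta);
  const double ig = 1.0 / (2.0 * gamma * gamma);
  const double eps = 1e-12;
  double w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig3_sym(hzz[i], hzy[i], hzx[i], hyy[i], hyx[i], hxx[i], w);
    sort_by_abs(w);
    const double l1 = w[0], l2 = w[1], l3 = w[2];
    const bool pol = bright ? (l2 < 0 && l3 < 0) : (l2 > 0 && l3 > 0);
    if (!pol) { out[i] = 0.0; continue; }
    const double Ra = std::abs(l2) / (std::abs(l3) + eps);
    const double Rb = std::abs(l1) / (std::sqrt(std::abs(l2 * l3)) + eps);
    const double S2 = l1 * l1 + l2 * l2 + l3 * l3;
    const double tA = 1.0 - std::exp(-Ra * Ra * ia);
    const double eB = std::exp(-Rb * Rb * ib);
    const double tB = blob_enhance ? (1.0 - eB) : eB;
    const double tS = 1.0 - std::exp(-S2 * ig);
    out[i] = tA * tB * tS;
  }
  return out;
}
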