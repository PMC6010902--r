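// Sparse-field level-set evolution (Whitaker-style five-layer band) with a
// two-phase region data term (Chan-Vese means) and mean-curvature smoothing.
//
// The level-set function phi is negative inside the contour.  Only voxels in
// the active band (layers -2..2 around the zero crossing) are ever touched;
// the interior is clamped at -3 and the exterior at +3.  The data force on
// the zero layer is F = (I - c_in)^2 - (I - c_out)^2, normalized by its
// maximum magnitude, and the update is
//   phi += dt * (F/max|F| + zeta * kappa),  dt = 0.45 / max|dphi|
// so zeta is the relative weight of curve smoothness against the data term.
//
// Works for 2-D (any dim equal to 1) and 3-D grids; dim = c(nz, ny, nx),
// z fastest in memory.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int d0, d1, d2;
  long n;
  long s0 = 1, s1, s2;
  Grid(int a, int b, int c) : d0(a), d1(b), d2(c) {
    n = (long)d0 * d1 * d2;
    s1 = d0;
    s2 = (long)d0 * d1;
  }
  inline void coords(long p, int &z, int &y, int &x) const {
    z = (int)(p % d0);
    y = (int)((p / d0) % d1);
    x = (int)(p / s2);
  }
};

class Sfm {
public:
  const Grid g;
  const double *I;
  std::vector<double> phi;
  std::vector<signed char> lbl; // layer id in {-3..3}
  std::vector<long> Lz, Ln1, Lp1, Ln2, Lp2;
  double sum_in = 0.0, sum_all = 0.0;
  long n_in = 0;

  Sfm(const double *img, int d0, int d1, int d2)
      : g(d0, d1, d2), I(img), phi(g.n), lbl(g.n) {}

  inline void set_phi(long p, double v) {
    const bool was = phi[p] <= 0, is = v <= 0;  // phi == 0 counts as inside
    if (was != is) {
      if (is) { sum_in += I[p]; ++n_in; }
      else    { sum_in -= I[p]; --n_in; }
    }
    phi[p] = v;
  }

  template <typename Fn>
  inline void for_nb6(long p, Fn fn) const {
    int z, y, x;
    g.coords(p, z, y, x);
    if (z > 0)        fn(p - g.s0);
    if (z < g.d0 - 1) fn(p + g.s0);
    if (y > 0)        fn(p - g.s1);
    if (y < g.d1 - 1) fn(p + g.s1);
    if (x > 0)        fn(p - g.s2);
    if (x < g.d2 - 1) fn(p + g.s2);
  }

  void init(const int *mask) {
    for (long p = 0; p < g.n; ++p) {
      const bool in = mask[p] != 0;
      phi[p] = in ? -3.0 : 3.0;
      lbl[p] = in ? -3 : 3;
      sum_all += I[p];
      if (in) { sum_in += I[p]; ++n_in; }
    }
    // L0: inside voxels with an outside 6-neighbour
    for (long p = 0; p < g.n; ++p) {
      if (!mask[p]) continue;
      bool edge = false;
      for_nb6(p, [&](long q) { if (!mask[q]) edge = true; });
      if (edge) { set_phi(p, 0.0); lbl[p] = 0; Lz.push_back(p); }
    }
    for (long p : Lz)
      for_nb6(p, [&](long q) {
        if (lbl[q] == -3) { set_phi(q, -1.0); lbl[q] = -1; Ln1.push_back(q); }
        else if (lbl[q] == 3) { set_phi(q, 1.0); lbl[q] = 1; Lp1.push_back(q); }
      });
    for (long p : Ln1)
      for_nb6(p, [&](long q) {
        if (lbl[q] == -3) { set_phi(q, -2.0); lbl[q] = -2; Ln2.push_back(q); }
      });
    for (long p : Lp1)
      for_nb6(p, [&](long q) {
        if (lbl[q] == 3) { set_phi(q, 2.0); lbl[q] = 2; Lp2.push_back(q); }
      });
  }

  inline double phi_at(int z, int y, int x) const {
    return phi[(long)z + (long)y * g.s1 + (long)x * g.s2];
  }

  // mean curvature from central differences of phi (band values are valid;
  // beyond the band phi is clamped at +-3, an acceptable approximation)
  double curvature(long p) const {
    int z, y, x;
    g.coords(p, z, y, x);
    const int zm = std::max(z - 1, 0), zp = std::min(z + 1, g.d0 - 1);
    const int ym = std::max(y - 1, 0), yp = std::min(y + 1, g.d1 - 1);
    const int xm = std::max(x - 1, 0), xp = std::min(x + 1, g.d2 - 1);
    const double c = phi[p];
    const double pz = 0.5 * (phi_at(zp, y, x) - phi_at(zm, y, x));
    const double py = 0.5 * (phi_at(z, yp, x) - phi_at(z, ym, x));
    const double px = 0.5 * (phi_at(z, y, xp) - phi_at(z, y, xm));
    const double pzz = phi_at(zp, y, x) - 2 * c + phi_at(zm, y, x);
    const double pyy = phi_at(z, yp, x) - 2 * c + phi_at(z, ym, x);
    const double pxx = phi_at(z, y, xp) - 2 * c + phi_at(z, y, xm);
    const double pzy = 0.25 * (phi_at(zp, yp, x) - phi_at(zp, ym, x)
                             - phi_at(zm, yp, x) + phi_at(zm, ym, x));
    const double pzx = 0.25 * (phi_at(zp, y, xp) - phi_at(zp, y, xm)
                             - phi_at(zm, y, xp) + phi_at(zm, y, xm));
    const double pyx = 0.25 * (phi_at(z, yp, xp) - phi_at(z, ym, xp)
                             - phi_at(z, yp, xm) + phi_at(z, ym, xm));
    const double g2 = pz * pz + py * py + px * px;
    if (g2 < 1e-12) return 0.0;
    const double num = pzz * (py * py + px * px) + pyy * (pz * pz + px * px)
                     + pxx * (pz * pz + py * py)
                     - 2.0 * (pz * py * pzy + pz * px * pzx + py * px * pyx);
    return num / (g2 * std::sqrt(g2) + 1e-12);
  }

  // fixed region means (semi-automated propagation); NaN = adaptive
  double fix_in = NA_REAL, fix_out = NA_REAL;

  // One evolution step; returns false when the contour vanished.
  bool step(double zeta) {
    if (Lz.empty() || n_in == 0 || n_in == (long)g.n) return false;
    const bool fixed = R_FINITE(fix_in) && R_FINITE(fix_out);
    const double c_in = fixed ? fix_in : sum_in / n_in;
    const double c_out = fixed ? fix_out : (sum_all - sum_in) / (g.n - n_in);
    std::vector<double> dphi(Lz.size());
    double fmax = 1e-12;
    for (size_t i = 0; i < Lz.size(); ++i) {
      const double d = I[Lz[i]];
      dphi[i] = (d - c_in) * (d - c_in) - (d - c_out) * (d - c_out);
      fmax = std::max(fmax, std::abs(dphi[i]));
    }
    double dmax = 1e-12;
    for (size_t i = 0; i < Lz.size(); ++i) {
      dphi[i] = dphi[i] / fmax + (zeta != 0.0 ? zeta * curvature(Lz[i]) : 0.0);
      dmax = std::max(dmax, std::abs(dphi[i]));
    }
    const double dt = 0.45 / dmax;
    for (size_t i = 0; i < Lz.size(); ++i)
      set_phi(Lz[i], phi[Lz[i]] + dt * dphi[i]);
    update_layers();
    return !Lz.empty() && n_in > 0;
  }

  void update_layers() {
    std::vector<long> keep_z, keep_n1, keep_p1, keep_n2, keep_p2;
    std::vector<long> to_z, to_n1, to_p1, to_n2, to_p2;

    for (long p : Lz) {
      if (phi[p] > 0.5) to_p1.push_back(p);
      else if (phi[p] < -0.5) to_n1.push_back(p);
      else keep_z.push_back(p);
    }
    for (long p : Ln1) {
      double M = -1e30;
      for_nb6(p, [&](long q) { if (lbl[q] == 0 && phi[q] > M) M = phi[q]; });
      if (M < -1e29) { to_n2.push_back(p); continue; } // lost zero-layer contact
      set_phi(p, M - 1.0);
      if (phi[p] >= -0.5) to_z.push_back(p);
      else if (phi[p] < -1.5) to_n2.push_back(p);
      else keep_n1.push_back(p);
    }
    for (long p : Lp1) {
      double m = 1e30;
      for_nb6(p, [&](long q) { if (lbl[q] == 0 && phi[q] < m) m = phi[q]; });
      if (m > 1e29) { to_p2.push_back(p); continue; }
      set_phi(p, m + 1.0);
      if (phi[p] <= 0.5) to_z.push_back(p);
      else if (phi[p] > 1.5) to_p2.push_back(p);
      else keep_p1.push_back(p);
    }
    for (long p : Ln2) {
      double M = -1e30;
      for_nb6(p, [&](long q) { if (lbl[q] == -1 && phi[q] > M) M = phi[q]; });
      if (M < -1e29) { set_phi(p, -3.0); lbl[p] = -3; continue; }
      set_phi(p, M - 1.0);
      if (phi[p] >= -1.5) to_n1.push_back(p);
      else if (phi[p] < -2.5) { set_phi(p, -3.0); lbl[p] = -3; }
      else keep_n2.push_back(p);
    }
    for (long p : Lp2) {
      double m = 1e30;
      for_nb6(p, [&](long q) { if (lbl[q] == 1 && phi[q] < m) m = phi[q]; });
      if (m > 1e29) { set_phi(p, 3.0); lbl[p] = 3; continue; }
      set_phi(p, m + 1.0);
      if (phi[p] <= 1.5) to_p1.push_back(p);
      else if (phi[p] > 2.5) { set_phi(p, 3.0); lbl[p] = 3; }
      else keep_p2.push_back(p);
    }

    for (long p : to_z) { lbl[p] = 0; keep_z.push_back(p); }
    for (long p : to_n1) {
      lbl[p] = -1; keep_n1.push_back(p);
      // pull fresh interior voxels into layer -2
      for_nb6(p, [&](long q) {
        if (lbl[q] == -3) {
          set_phi(q, phi[p] - 1.0);
          lbl[q] = -2;
          keep_n2.push_back(q);
        }
      });
    }
    for (long p : to_p1) {
      lbl[p] = 1; keep_p1.push_back(p);
      for_nb6(p, [&](long q) {
        if (lbl[q] == 3) {
          set_phi(q, phi[p] + 1.0);
          lbl[q] = 2;
          keep_p2.push_back(q);
        }
      });
    }
    for (long p : to_n2) { lbl[p] = -2; keep_n2.push_back(p); }
    for (long p : to_p2) { lbl[p] = 2; keep_p2.push_back(p); }

    Lz.swap(keep_z); Ln1.swap(keep_n1); Lp1.swap(keep_p1);
    Ln2.swap(keep_n2); Lp2.swap(keep_p2);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_sfm(NumericVector img, IntegerVector dims, IntegerVector init_mask,
             int n_iter, double zeta,
             double fixed_c_in = NA_REAL, double fixed_c_out = NA_REAL) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  if ((long)d0 * d1 * d2 != (long)img.size()) stop("dims do not match data length");
  if ((long)img.size() != (long)init_mask.size()) stop("mask does not match image");
  Sfm s(img.begin(), d0, d1, d2);
  s.fix_in = fixed_c_in;
  s.fix_out = fixed_c_out;
  s.init(init_mask.begin());
  bool vanished = false;
  int done = 0;
  for (; done < n_iter; ++done) {
    if (!s.step(zeta)) { vanished = (s.n_in == 0 || s.Lz.empty()); break; }
  }
  IntegerVector mask(img.size());
  for (long p = 0; p < s.g.n; ++p) mask[p] = s.phi[p] <= 0 ? 1 : 0;
  NumericVector phi(img.size());
  std::copy(s.phi.begin(), s.phi.end(), phi.begin());
  return List::create(_["mask"] = mask, _["phi"] = phi,
                      _["iterations"] = done, _["vanished"] = vanished,
                      _["band_size"] = (double)(s.Lz.size() + s.Ln1.size() +
                                                s.Lp1.size() + s.Ln2.size() +
                                                s.Lp2.size()));
}
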