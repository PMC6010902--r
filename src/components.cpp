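// Connected-component labelling (6 or 26 connectivity) and seeded region
// growing for 3-D volumes stored with dim = c(nz, ny, nx), z fastest.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Nbh {
  std::vector<long> off;       // linear offsets
  std::vector<int> dz, dy, dx; // coordinate deltas, for boundary checks
};

static Nbh make_nbh(int d0, int d1, int connectivity) {
  Nbh nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        const int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.dz.push_back(dz); nb.dy.push_back(dy); nb.dx.push_back(dx);
        nb.off.push_back((long)dz + (long)dy * d0 + (long)dx * d0 * d1);
      }
  return nb;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long n = (long)d0 * d1 * d2;
  if (n != (long)mask.size()) stop("dims do not match data length");
  Nbh nb = make_nbh(d0, d1, connectivity);
  const int nn = (int)nb.off.size();
  IntegerVector lab(mask.size(), 0);
  std::vector<long> stack;
  int cur = 0;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const long p = stack.back(); stack.pop_back();
      const int z = (int)(p % d0), y = (int)((p / d0) % d1), x = (int)(p / ((long)d0 * d1));
      for (int k = 0; k < nn; ++k) {
        const int zz = z + nb.dz[k], yy = y + nb.dy[k], xx = x + nb.dx[k];
        if (zz < 0 || zz >= d0 || yy < 0 || yy >= d1 || xx < 0 || xx >= d2) continue;
        const long q = p + nb.off[k];
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Seeded region growing with a running region mean: a voxel joins the region
// of the seed it is reached from if |I - current region mean| <= tol.
// Seeds are 0-based (z, y, x) rows; regions are grown one seed at a time and
// voxels already claimed by an earlier seed are not revisited.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(NumericVector img, IntegerVector dims,
                              IntegerMatrix seeds, double tol,
                              int connectivity = 6) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long n = (long)d0 * d1 * d2;
  if (n != (long)img.size()) stop("dims do not match data length");
  Nbh nb = make_nbh(d0, d1, connectivity);
  const int nn = (int)nb.off.size();
  IntegerVector lab(img.size(), 0);
  std::vector<long> queue;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int sz = seeds(s, 0), sy = seeds(s, 1), sx = seeds(s, 2);
    if (sz < 0 || sz >= d0 || sy < 0 || sy >= d1 || sx < 0 || sx >= d2)
      stop("seed outside volume");
    const long sp = (long)sz + (long)sy * d0 + (long)sx * d0 * d1;
    if (ISNAN(img[sp])) stop("seed lies on a NaN voxel");
    if (lab[sp] != 0) continue; // already claimed by an earlier region
    const int id = s + 1;
    double sum = img[sp];
    long cnt = 1;
    lab[sp] = id;
    queue.clear();
    queue.push_back(sp);
    size_t head = 0;
    while (head < queue.size()) {
      const long p = queue[head++];
      const int z = (int)(p % d0), y = (int)((p / d0) % d1), x = (int)(p / ((long)d0 * d1));
      const double mean = sum / cnt;
      for (int k = 0; k < nn; ++k) {
        const int zz = z + nb.dz[k], yy = y + nb.dy[k], xx = x + nb.dx[k];
        if (zz < 0 || zz >= d0 || yy < 0 || yy >= d1 || xx < 0 || xx >= d2) continue;
        const long q = p + nb.off[k];
        if (lab[q] != 0 || ISNAN(img[q])) continue;
        // small relative slack so tolerance 0 admits exactly-equal values
        // despite running-mean rounding
        if (std::abs(img[q] - mean) <=
            tol + 1e-12 * (std::abs(img[q]) + 1.0)) {
          lab[q] = id;
          sum += img[q];
          ++cnt;
          queue.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Per-pixel running median over a window of n slices along axis 0 (z).
// The window is truncated symmetrically at the volume ends.
// [[Rcpp::export]]
NumericVector cpp_median_axis0(NumericVector v, IntegerVector dims, int n) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  if ((long)d0 * d1 * d2 != (long)v.size()) stop("dims do not match data length");
  if (n < 1 || n > d0) stop("window must be between 1 and the slice count");
  NumericVector out(v.size());
  const int half = n / 2;
  std::vector<double> buf(n);
  for (long c = 0; c < (long)d1 * d2; ++c) {
    const double *col = v.begin() + c * d0;
    double *dst = out.begin() + c * d0;
    for (int z = 0; z < d0; ++z) {
      int lo = std::max(0, z - half), hi = std::min(d0 - 1, z + (n - 1) / 2);
      const int m = hi - lo + 1;
      for (int i = 0; i < m; ++i) buf[i] = col[lo + i];
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      dst[z] = med;
    }
  }
  return out;
}
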