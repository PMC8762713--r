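#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running 3-D median filter with window truncation at the grid borders.
// w holds odd window extents per axis; a window of 1 leaves that axis alone.
// [[Rcpp::export]]
NumericVector median_filter3_cpp(NumericVector x, IntegerVector dim, IntegerVector w) {
  const int nb = dim[0], na = dim[1], nz = dim[2];
  const int rb = (w[0] - 1) / 2, ra = (w[1] - 1) / 2, rz = (w[2] - 1) / 2;
  NumericVector out(x.size());
  std::vector<double> buf;
  buf.reserve((size_t)w[0] * w[1] * w[2]);
  for (int z = 0; z < nz; ++z) {
    const int z0 = std::max(0, z - rz), z1 = std::min(nz - 1, z + rz);
    for (int a = 0; a < na; ++a) {
      const int a0 = std::max(0, a - ra), a1 = std::min(na - 1, a + ra);
      for (int b = 0; b < nb; ++b) {
        const int b0 = std::max(0, b - rb), b1 = std::min(nb - 1, b + rb);
        buf.clear();
        for (int zz = z0; zz <= z1; ++zz)
          for (int aa = a0; aa <= a1; ++aa) {
            const R_xlen_t base = (R_xlen_t)zz * nb * na + (R_xlen_t)aa * nb;
            for (int bb = b0; bb <= b1; ++bb) buf.push_back(x[base + bb]);
          }
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[(R_xlen_t)z * nb * na + (R_xlen_t)a * nb + b] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a 3-D binary mask (flood fill).
// Returns integer labels, 0 for background; labels start at 1.
// [[Rcpp::export]]
IntegerVector label_components26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nb = dim[0], na = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nb * na * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int z = p / ((R_xlen_t)nb * na);
      const int rem = p - (R_xlen_t)z * nb * na;
      const int a = rem / nb, b = rem % nb;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int da = -1; da <= 1; ++da) {
          const int aa = a + da;
          if (aa < 0 || aa >= na) continue;
          for (int db = -1; db <= 1; ++db) {
            if (db == 0 && da == 0 && dz == 0) continue;
            const int bb = b + db;
            if (bb < 0 || bb >= nb) continue;
            const R_xlen_t q = (R_xlen_t)zz * nb * na + (R_xlen_t)aa * nb + bb;
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Non-local means on a single 2-D slice: patch comparison within a square
// search window; h is the similarity bandwidth on patch mean squared
// differences. Borders handled by patch truncation.
// [[Rcpp::export]]
NumericMatrix nlm2_cpp(NumericMatrix img, int search_radius, int patch_radius, double h) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double h2 = h * h;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double wsum = 0.0, acc = 0.0;
      for (int sc = std::max(0, c - search_radius); sc <= std::min(nc - 1, c + search_radius); ++sc) {
        for (int sr = std::max(0, r - search_radius); sr <= std::min(nr - 1, r + search_radius); ++sr) {
          double d2 = 0.0;
          int cnt = 0;
          for (int pc = -patch_radius; pc <= patch_radius; ++pc) {
            for (int pr = -patch_radius; pr <= patch_radius; ++pr) {
              const int r1 = r + pr, c1 = c + pc, r2 = sr + pr, c2 = sc + pc;
              if (r1 < 0 || r1 >= nr || c1 < 0 || c1 >= nc) continue;
              if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
              const double d = img(r1, c1) - img(r2, c2);
              d2 += d * d;
              ++cnt;
            }
          }
          if (cnt == 0) continue;
          const double wgt = std::exp(-(d2 / cnt) / h2);
          wsum += wgt;
          acc += wgt * img(sr, sc);
        }
      }
      out(r, c) = wsum > 0 ? acc / wsum : img(r, c);
    }
  }
  return out;
}
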