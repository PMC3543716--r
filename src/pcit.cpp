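#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT trio scan over a symmetric correlation matrix.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed, a trio tolerance eps is taken as the mean of
// the partial/direct ratios (skipping ratios whose direct correlation is
// zero within 1e-12), and an edge (a, b) is flagged non-significant in the
// trio when |r_ab| < |eps * r_ac| AND |r_ab| < |eps * r_bc| (strict by
// default). An edge survives iff its correlation is nonzero and no trio
// flags it. Trios containing a near-unit off-diagonal correlation
// (|r| >= 1 - 1e-12, e.g. duplicated genes) are skipped and counted, so
// duplicates are never used as conditioning variables.
//
// Complexity is O(n^3) over trios; the loop body is branch-light so n of a
// few thousand genes remains practical on one core.

static inline double clamp1(double v) {
  if (v > 1.0) return 1.0;
  if (v < -1.0) return -1.0;
  return v;
}

// [[Rcpp::export(name = ".pcit_mask_cpp")]]
List pcit_mask_cpp(NumericMatrix r, bool absolute_ratio, bool strict) {
  const int n = r.nrow();
  if (r.ncol() != n) stop("correlation matrix must be square");
  const double unit_tol = 1.0 - 1e-12;
  const double zero_tol = 1e-12;

  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool k = r(i, j) != 0.0;
      keep(i, j) = k;
      keep(j, i) = k;
    }
    keep(i, i) = false;
  }

  double n_degenerate = 0.0;  // trios skipped for a near-unit correlation
  double n_no_ratio = 0.0;    // trios with all three directs ~ 0

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);

        if (std::fabs(rxy) >= unit_tol || std::fabs(rxz) >= unit_tol ||
            std::fabs(ryz) >= unit_tol) {
          n_degenerate += 1.0;
          continue;
        }

        const double pxy = clamp1((rxy - rxz * ryz) /
                                  std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz)));
        const double pxz = clamp1((rxz - rxy * ryz) /
                                  std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz)));
        const double pyz = clamp1((ryz - rxy * rxz) /
                                  std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz)));

        double sum = 0.0;
        int cnt = 0;
        if (std::fabs(rxy) > zero_tol) {
          double t = pxy / rxy;
          sum += absolute_ratio ? std::fabs(t) : t;
          ++cnt;
        }
        if (std::fabs(rxz) > zero_tol) {
          double t = pxz / rxz;
          sum += absolute_ratio ? std::fabs(t) : t;
          ++cnt;
        }
        if (std::fabs(ryz) > zero_tol) {
          double t = pyz / ryz;
          sum += absolute_ratio ? std::fabs(t) : t;
          ++cnt;
        }
        if (cnt == 0) {
          n_no_ratio += 1.0;
          continue;
        }
        const double eps = sum / cnt;

        const double axy = std::fabs(rxy);
        const double axz = std::fabs(rxz);
        const double ayz = std::fabs(ryz);
        const double exy = std::fabs(eps * rxy);
        const double exz = std::fabs(eps * rxz);
        const double eyz = std::fabs(eps * ryz);

        bool fxy, fxz, fyz;
        if (strict) {
          fxy = axy < exz && axy < eyz;
          fxz = axz < exy && axz < eyz;
          fyz = ayz < exy && ayz < exz;
        } else {
          fxy = axy <= exz && axy <= eyz;
          fxz = axz <= exy && axz <= eyz;
          fyz = ayz <= exy && ayz <= exz;
        }
        if (fxy) { keep(x, y) = false; keep(y, x) = false; }
        if (fxz) { keep(x, z) = false; keep(z, x) = false; }
        if (fyz) { keep(y, z) = false; keep(z, y) = false; }
      }
    }
  }

  return List::create(_["keep"] = keep,
                      _["n_degenerate_trios"] = n_degenerate,
                      _["n_no_ratio_trios"] = n_no_ratio);
}
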