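// Global 2D gamma index with fine-grid distance-to-agreement search.
// The evaluated distribution is sampled by bilinear interpolation on a
// sub-grid of stepFrac*dta within a disc of radius searchMult*dta around each
// reference point; candidate offsets are visited in order of increasing
// spatial distance so the search can stop as soon as the distance term alone
// exceeds the current best gamma^2.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Offset { double du, dv, dist2; };

// [[Rcpp::export(name = ".gammaMapCpp")]]
NumericMatrix gamma_map_cpp(NumericMatrix ref, NumericMatrix ev,
                            double sy, double sx,
                            double doseTolPct, double dta,
                            double thresholdPct,
                            double searchMult, double stepFrac) {
  const int nr = ref.nrow(), nc = ref.ncol();
  if (ev.nrow() != nr || ev.ncol() != nc)
    stop("reference and evaluated grids must share shape and spacing");
  double dmax = -1.0;
  for (int k = 0; k < nr * nc; ++k) dmax = std::max(dmax, ref[k]);
  if (!(dmax > 0)) stop("reference distribution has no positive dose");
  const double tol = doseTolPct / 100.0 * dmax;
  const double thr = thresholdPct / 100.0 * dmax;

  // candidate offsets (mm), sorted by spatial distance; (0,0) comes first
  const double step = stepFrac * dta;
  const double radius = searchMult * dta;
  const int nstep = (int)std::floor(radius / step + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((2 * nstep + 1) * (2 * nstep + 1));
  for (int a = -nstep; a <= nstep; ++a)
    for (int b = -nstep; b <= nstep; ++b) {
      const double du = a * step, dv = b * step;
      const double r2 = du * du + dv * dv;
      if (r2 <= radius * radius + 1e-9)
        offs.push_back({du, dv, r2 / (dta * dta)});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& p, const Offset& q) { return p.dist2 < q.dist2; });

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double dref = ref(r, c);
      if (dref < thr) { out(r, c) = NA_REAL; continue; }
      const double y0 = r * sy, x0 = c * sx;
      double gmin2 = std::numeric_limits<double>::infinity();
      for (const Offset& o : offs) {
        if (o.dist2 >= gmin2) break;
        const double gy = (y0 + o.dv) / sy;
        const double gx = (x0 + o.du) / sx;
        if (gy < 0 || gy > nr - 1 || gx < 0 || gx > nc - 1) continue;
        const int iy = std::min((int)std::floor(gy), nr - 2 >= 0 ? nr - 2 : 0);
        const int ix = std::min((int)std::floor(gx), nc - 2 >= 0 ? nc - 2 : 0);
        double fy = gy - iy, fx = gx - ix;
        double dev;
        if (nr == 1 && nc == 1) dev = ev(0, 0);
        else if (nr == 1) dev = ev(0, ix) * (1 - fx) + ev(0, ix + 1) * fx;
        else if (nc == 1) dev = ev(iy, 0) * (1 - fy) + ev(iy + 1, 0) * fy;
        else dev = ev(iy, ix) * (1 - fy) * (1 - fx) +
                   ev(iy + 1, ix) * fy * (1 - fx) +
                   ev(iy, ix + 1) * (1 - fy) * fx +
                   ev(iy + 1, ix + 1) * fy * fx;
        const double dd = (dev - dref) / tol;
        const double g2 = o.dist2 + dd * dd;
        if (g2 < gmin2) gmin2 = g2;
      }
      out(r, c) = std::sqrt(gmin2);
    }
  }
  return out;
}
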