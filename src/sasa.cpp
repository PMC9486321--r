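#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
//
// Each atom's van der Waals sphere is expanded by the probe radius and
// sampled with a deterministic golden-spiral point set; the accessible area
// is the expanded-sphere area times the fraction of sample points not
// contained in any neighbour's expanded sphere. No RNG is involved, so the
// result is reproducible across platforms for a fixed point count.
//
// `subset` (1-based indices) restricts which atoms' areas are computed;
// all atoms still act as occluders. Uncomputed entries return -1.
//
// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix coords,
                                 NumericVector radii,
                                 double probe = 1.4,
                                 int n_points = 960,
                                 IntegerVector subset = IntegerVector()) {
  const int n = coords.nrow();
  NumericVector area(n, -1.0);
  if (n == 0) return area;

  std::vector<int> todo;
  if (subset.size() == 0) {
    todo.resize(n);
    for (int i = 0; i < n; ++i) todo[i] = i;
  } else {
    todo.reserve(subset.size());
    for (int k = 0; k < subset.size(); ++k) todo.push_back(subset[k] - 1);
  }

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  std::vector<double> ex(n);  // expanded radii
  double max_er = 0.0;
  for (int i = 0; i < n; ++i) {
    ex[i] = radii[i] + probe;
    if (ex[i] > max_er) max_er = ex[i];
  }
  const double reach = 2.0 * max_er;

  std::vector<std::pair<double, int> > nb;
  nb.reserve(256);
  std::vector<char> covered(n_points);

  for (size_t t = 0; t < todo.size(); ++t) {
    const int i = todo[t];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = ex[i];

    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi;
      if (std::fabs(dx) > reach) continue;
      double dy = coords(j, 1) - yi;
      if (std::fabs(dy) > reach) continue;
      double dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double cut = ri + ex[j];
      if (d2 < cut * cut) nb.push_back(std::make_pair(d2, j));
    }
    // closest occluders first: buried points get marked early
    std::sort(nb.begin(), nb.end());

    std::fill(covered.begin(), covered.end(), 0);
    int n_covered = 0;
    for (size_t m = 0; m < nb.size() && n_covered < n_points; ++m) {
      const int j = nb[m].second;
      const double jx = coords(j, 0), jy = coords(j, 1), jz = coords(j, 2);
      const double r2 = ex[j] * ex[j];
      for (int k = 0; k < n_points; ++k) {
        if (covered[k]) continue;
        const double dx = xi + ri * px[k] - jx;
        const double dy = yi + ri * py[k] - jy;
        const double dz = zi + ri * pz[k] - jz;
        if (dx * dx + dy * dy + dz * dz < r2) {
          covered[k] = 1;
          ++n_covered;
        }
      }
    }
    area[i] = 4.0 * M_PI * ri * ri * (n_points - n_covered) / n_points;
  }
  return area;
}
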