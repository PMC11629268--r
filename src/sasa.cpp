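#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// For each atom, test points on the sphere of radius (r_i + probe) against
// all neighbouring expanded spheres; the accessible fraction times the
// expanded-sphere area is the atom's SASA.  Points come from a
// deterministic golden-spiral lattice so results are reproducible for a
// given point count.
//
// coords: n x 3 (nm), radii: n (nm).  Returns per-atom SASA in nm^2.
// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix coords, NumericVector radii,
                                 double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (1.0 + std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double t = (i + 0.5) / n_points;
    double phi = std::acos(1.0 - 2.0 * t);
    double theta = golden * (i + 0.5);
    px[i] = std::sin(phi) * std::cos(theta);
    py[i] = std::sin(phi) * std::sin(theta);
    pz[i] = std::cos(phi);
  }

  std::vector<double> er(n);
  double er_max = 0.0;
  for (int i = 0; i < n; ++i) {
    er[i] = radii[i] + probe;
    if (er[i] > er_max) er_max = er[i];
  }

  std::vector<int> nbr;
  nbr.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = er[i];
    nbr.clear();
    const double cut = ri + er_max;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + er[j];
      if (d2 < lim * lim && d2 < cut * cut) nbr.push_back(j);
    }
    int accessible = 0;
    for (int p = 0; p < n_points; ++p) {
      const double qx = xi + ri * px[p];
      const double qy = yi + ri * py[p];
      const double qz = zi + ri * pz[p];
      bool buried = false;
      for (size_t k = 0; k < nbr.size(); ++k) {
        const int j = nbr[k];
        double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
               dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++accessible;
    }
    out[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return out;
}
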