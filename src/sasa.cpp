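#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// Fibonacci-lattice point set. For each atom i a sphere of radius
// r_i + probe is sampled at n_points quasi-uniform points; a point is
// accessible when it lies outside every neighbour's solvent-expanded
// sphere. Neighbour search uses the pairwise cutoff r_i + r_j + 2*probe.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  if (radius.size() != n) stop("radius length mismatch");
  if (n_points < 16) stop("n_points must be >= 16");
  if (probe < 0) stop("probe radius must be >= 0");

  // Fibonacci lattice on the unit sphere (golden-angle spiral)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = std::cos(phi) * rho;
    py[k] = std::sin(phi) * rho;
    pz[k] = z;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radius[i] + probe;

  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = R[i] + R[j];           // = r_i + r_j + 2*probe
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    const double Ri = R[i];
    for (int k = 0; k < n_points; ++k) {
      const double sx = xi + Ri * px[k];
      const double sy = yi + Ri * py[k];
      const double sz = zi + Ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double dx = sx - xyz(j, 0);
        const double dy = sy - xyz(j, 1);
        const double dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return area;
}

// Minimum distance between two coordinate sets, returning
// (min_distance, index_A, index_B) with 1-based indices.
// [[Rcpp::export(name = ".min_dist_cpp")]]
NumericVector min_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) stop("empty coordinate set");
  double best = R_PosInf;
  int bi = 0, bj = 0;
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = i; bj = j; }
    }
  }
  return NumericVector::create(std::sqrt(best), bi + 1.0, bj + 1.0);
}

// All cross-set atom pairs within a distance cutoff; returns a 3-column
// matrix (index_A, index_B, distance), 1-based.
// [[Rcpp::export(name = ".pairs_within_cpp")]]
NumericMatrix pairs_within_cpp(NumericMatrix a, NumericMatrix b,
                               double cutoff) {
  const int na = a.nrow(), nb = b.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> ia, ib, dd;
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        ia.push_back(i + 1.0);
        ib.push_back(j + 1.0);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  NumericMatrix out(ia.size(), 3);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k]; out(k, 1) = ib[k]; out(k, 2) = dd[k];
  }
  return out;
}
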