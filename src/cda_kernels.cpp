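#include <Rcpp.h>
using namespace Rcpp;

// Screened (Yukawa) superposition of point-source fields at every cluster
// center. Positions are rows of `pos` (n x 3, um); `shifts` are the
// periodic image translations to add to each source (precomputed in R;
// a single zero row for open boundaries). Sources beyond `cutoff` are
// skipped. The gradient omits all images of the target cluster itself.
// With `self_conc` the cluster's own secretion, evaluated at its surface
// radius, is added to the concentration (the "total felt" concentration
// used for secretion-dependent proliferation); without it the
// concentration is the external field only (the motility denominator).
// [[Rcpp::export]]
List cpp_field_at_clusters(NumericMatrix pos, NumericVector m,
                           NumericVector radius, NumericMatrix shifts,
                           double lambda, double Dh, double beta_h,
                           double cutoff, bool screened, bool self_conc) {
  const int n = pos.nrow(), ns = shifts.nrow();
  NumericVector conc(n);
  NumericMatrix grad(n, 3);
  const double pref = beta_h / (4.0 * M_PI * Dh);
  for (int i = 0; i < n; ++i) {
    double ci = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    for (int j = 0; j < n; ++j) {
      const double qj = m[j];
      for (int s = 0; s < ns; ++s) {
        const double dx = pos(i, 0) - (pos(j, 0) + shifts(s, 0));
        const double dy = pos(i, 1) - (pos(j, 1) + shifts(s, 1));
        const double dz = pos(i, 2) - (pos(j, 2) + shifts(s, 2));
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > cutoff * cutoff) continue;
        if (r2 == 0.0) continue;  // self minimum image, surface value added below
        const double r = std::sqrt(r2);
        double cc, dmag;  // dmag = (dc/dr)/r, so grad = dmag * d_vec
        if (screened) {
          const double e = std::exp(-r / lambda);
          cc = qj * e / r;
          dmag = -qj * e * (1.0 / r + 1.0 / lambda) / r2;
        } else {
          cc = qj / r;
          dmag = -qj / (r2 * r);
        }
        ci += cc;
        if (j != i) {
          gx += dmag * dx;
          gy += dmag * dy;
          gz += dmag * dz;
        }
      }
    }
    // own secretion, sensed at the cluster surface (total-felt mode only)
    if (self_conc) {
      const double R = radius[i];
      ci += screened ? m[i] * std::exp(-R / lambda) / R : m[i] / R;
    }
    conc[i] = pref * ci;
    grad(i, 0) = pref * gx;
    grad(i, 1) = pref * gy;
    grad(i, 2) = pref * gz;
  }
  return List::create(_["c"] = conc, _["grad"] = grad);
}

// Monte-Carlo velocity-field oracle. For each sample, a Poisson number of
// unit sources (mean density * (4/3) pi Rmax^3) is scattered uniformly in
// the sphere of radius Rmax around the test point at the origin, and the
// inverse-square (optionally Yukawa-screened) contributions are summed
// directly. Returns the raw vector sum `g` (units 1/um^2), the summed
// 1/(um) concentration factor `csum`, and the nearest-source term `gnn`
// so the caller can split nearest-neighbour vs far-field contributions.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_oracle_samples(int n_samples, double density, double Rmax,
                        double lambda, bool screened) {
  NumericMatrix g(n_samples, 3), gnn(n_samples, 3);
  NumericVector csum(n_samples);
  const double mean_pts = density * 4.0 / 3.0 * M_PI * Rmax * Rmax * Rmax;
  RNGScope scope;
  for (int i = 0; i < n_samples; ++i) {
    const int npts = (int) R::rpois(mean_pts);
    double gx = 0, gy = 0, gz = 0, cs = 0;
    double best_r2 = R_PosInf, nx = 0, ny = 0, nz = 0;
    for (int j = 0; j < npts; ++j) {
      // uniform point in the sphere: r ~ Rmax * U^(1/3), isotropic direction
      const double r = Rmax * std::cbrt(unif_rand());
      const double u = 2.0 * unif_rand() - 1.0;   // cos(theta)
      const double phi = 2.0 * M_PI * unif_rand();
      const double st = std::sqrt(1.0 - u * u);
      const double sx = r * st * std::cos(phi);
      const double sy = r * st * std::sin(phi);
      const double sz = r * u;
      if (r <= 0) continue;
      double gmag, cc;  // contribution magnitude along +r_hat (toward source)
      if (screened) {
        const double e = std::exp(-r / lambda);
        gmag = e * (1.0 / (r * r) + 1.0 / (lambda * r));
        cc = e / r;
      } else {
        gmag = 1.0 / (r * r);
        cc = 1.0 / r;
      }
      const double cx = gmag * sx / r, cy = gmag * sy / r, cz = gmag * sz / r;
      gx += cx; gy += cy; gz += cz; cs += cc;
      if (r * r < best_r2) {
        best_r2 = r * r; nx = cx; ny = cy; nz = cz;
      }
    }
    g(i, 0) = gx; g(i, 1) = gy; g(i, 2) = gz;
    gnn(i, 0) = nx; gnn(i, 1) = ny; gnn(i, 2) = nz;
    csum[i] = cs;
  }
  return List::create(_["g"] = g, _["csum"] = csum, _["gnn"] = gnn);
}
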