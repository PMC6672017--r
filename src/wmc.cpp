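#include <Rcpp.h>
using namespace Rcpp;

// White Monte Carlo random walk in a semi-infinite medium, z > 0.
// Unit scattering coefficient, zero absorption: all lengths are in units of
// one scattering mean free path (1/mu_s). Each photon is launched at the
// origin along +z; step lengths are -log(xi); deflection angles follow the
// Henyey-Greenstein inversion. A photon that crosses z = 0 escapes (matched
// boundary) or escapes with the Fresnel transmission probability for its
// incidence angle (mismatched boundary, relative index n_rel > 1). Exit
// radius rho and total dimensionless path Lambda are recorded per escapee;
// walks exceeding max_path are truncated and counted.

static inline double hg_cos(double g, double xi) {
  if (g < 1e-8) return 2.0 * xi - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// unpolarized Fresnel reflectance for incidence cosine ci, going from index
// n1 (medium) to n2 (outside); n_rel = n1/n2 >= 1
static inline double fresnel_R(double ci, double n_rel) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_rel * si;                    // Snell: n1 sin(i) = n2 sin(t)
  if (st >= 1.0) return 1.0;                 // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".wmc_walk")]]
List wmc_walk(int n_photons, double g, double max_path,
              bool fresnel, double n_rel) {
  std::vector<double> rho, lambda;
  rho.reserve(n_photons);
  lambda.reserve(n_photons);
  int n_trunc = 0;
  RNGScope scope;  // use R's RNG so set.seed() governs reproducibility

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double path = 0.0;
    bool alive = true;
    while (alive) {
      double s = -std::log(unif_rand());
      double znew = z + uz * s;
      if (znew <= 0.0 && uz < 0.0) {
        // partial step to the boundary
        double sb = -z / uz;
        double ci = -uz;  // incidence cosine on the z = 0 plane
        bool escape = true;
        if (fresnel) {
          double R = fresnel_R(ci, n_rel);
          if (unif_rand() < R) escape = false;
        }
        if (escape) {
          double xb = x + ux * sb, yb = y + uy * sb;
          rho.push_back(std::sqrt(xb * xb + yb * yb));
          lambda.push_back(path + sb);
          break;
        }
        // specular internal reflection at the boundary, finish the step
        x += ux * sb; y += uy * sb; z = 0.0;
        uz = -uz;
        double srem = s - sb;
        x += ux * srem; y += uy * srem; z += uz * srem;
        path += s;
      } else {
        x += ux * s; y += uy * s; z = znew;
        path += s;
      }
      if (path > max_path) { ++n_trunc; break; }
      // Henyey-Greenstein scattering
      double ct = hg_cos(g, unif_rand());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      double nx, ny, nz;
      if (std::fabs(uz) > 0.99999) {
        nx = st * cp; ny = st * sp; nz = ct * (uz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nz = -st * cp * den + uz * ct;
      }
      double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
      ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
    }
  }
  return List::create(_["rho"] = wrap(rho),
                      _["path"] = wrap(lambda),
                      _["n_truncated"] = n_trunc);
}

// [[Rcpp::export(name = ".hg_sample_cos")]]
NumericVector hg_sample_cos(int n, double g) {
  NumericVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, unif_rand());
  return out;
}
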