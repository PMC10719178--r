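// Simplified analog photon Monte Carlo for 90Y bremsstrahlung SPECT.
//
// Per history: a decay voxel is sampled proportional to activity, a photon
// energy is drawn from the tabulated emission spectrum and an isotropic
// direction chosen. The photon is tracked through the density map with
// Woodcock (delta) tracking; interactions are Compton scattering
// (Klein-Nishina energy/angle sampling, cross section from the KN formula
// times the electron density of water scaled by mass density) and
// photoelectric absorption (water table scaled by density). A photon
// escaping the volume within the collimator acceptance half-angle of a view
// normal is scored into the geometrically mapped bin if its
// Gaussian-blurred energy lies in the acquisition window; >= 1 interaction
// scores to scatter, 0 interactions to primary. Analog (binary) scoring.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double R_E = 2.8179403e-13;   // classical electron radius, cm
static const double NE_WATER = 3.343e23;   // electrons per gram of water

// Klein-Nishina total cross section per electron (cm^2), k = E/511 keV
static double kn_sigma(double e_keV) {
  double k = e_keV / 511.0;
  double t = 1.0 + 2.0 * k;
  return 2.0 * M_PI * R_E * R_E *
         ((1.0 + k) / (k * k) * (2.0 * (1.0 + k) / t - std::log(t) / k) +
          std::log(t) / (2.0 * k) - (1.0 + 3.0 * k) / (t * t));
}

// photoelectric mass attenuation of water, log-log interpolation
static double pe_mass_mu(double e_keV, const std::vector<double>& loge,
                         const std::vector<double>& logmu) {
  double le = std::log(e_keV);
  size_t n = loge.size();
  if (le <= loge[0]) return std::exp(logmu[0]);
  if (le >= loge[n - 1]) return std::exp(logmu[n - 1]);
  size_t i = 1;
  while (i < n - 1 && loge[i] < le) ++i;
  double w = (le - loge[i - 1]) / (loge[i] - loge[i - 1]);
  return std::exp(logmu[i - 1] + w * (logmu[i] - logmu[i - 1]));
}

// total mass attenuation used for transport (Compton + photoelectric), cm^2/g
static inline double mass_mu(double e_keV, const std::vector<double>& loge,
                             const std::vector<double>& logmu) {
  return NE_WATER * kn_sigma(e_keV) + pe_mass_mu(e_keV, loge, logmu);
}

// sample cos(theta) from the Klein-Nishina angular distribution by
// rejection against the forward-peak envelope
static double kn_sample_cos(double e_keV) {
  double k = e_keV / 511.0;
  for (int it = 0; it < 10000; ++it) {
    double c = 2.0 * R::runif(0.0, 1.0) - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - c)); // E'/E
    double sin2 = 1.0 - c * c;
    double w = r * r * (r + 1.0 / r - sin2); // dsigma/dcos up to constants
    if (R::runif(0.0, 1.0) * 2.0 <= w) return c;
  }
  return 1.0;
}

// [[Rcpp::export]]
NumericVector kn_sample_cos_cpp(int n, double e_keV) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kn_sample_cos(e_keV);
  return out;
}

// rotate direction d by polar angle theta (cos ct) with uniform azimuth
static void rotate_direction(double* d, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * R::runif(0.0, 1.0);
  double sp = std::sin(phi), cp = std::cos(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  double norm = std::sqrt(dx * dx + dy * dy);
  double nx, ny, nz;
  if (norm > 1e-12) {
    // orthonormal frame around d: u perp d, v = d x u
    double ux = -dy / norm, uy = dx / norm, uz = 0.0;
    double vx = -dz * uy, vy = dz * ux, vz = dx * uy - dy * ux;
    nx = ct * dx + st * (cp * ux + sp * vx);
    ny = ct * dy + st * (cp * uy + sp * vy);
    nz = ct * dz + st * (cp * uz + sp * vz);
  } else { // travelling along +-z
    nx = st * cp;
    ny = st * sp;
    nz = ct * (dz >= 0 ? 1.0 : -1.0);
  }
  double n = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / n; d[1] = ny / n; d[2] = nz / n;
}

// [[Rcpp::export]]
List photon_mc_cpp(NumericVector activity, NumericVector density,
                   IntegerVector dims, NumericVector vox_mm,
                   NumericVector origin_mm,
                   NumericVector angles_deg, int nu, int nv,
                   NumericVector pitch_mm, double radius_mm,
                   double win_lo, double win_hi,
                   double n_hist, double eres_frac_140,
                   double half_angle_deg, double cutoff_keV,
                   NumericVector spec_e_keV, NumericVector spec_cdf,
                   NumericVector pe_loge, NumericVector pe_logmu) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  const int n_views = angles_deg.size();
  std::vector<double> loge(pe_loge.begin(), pe_loge.end());
  std::vector<double> logmu(pe_logmu.begin(), pe_logmu.end());

  // activity CDF for decay-site sampling
  std::vector<double> cdf(nvox);
  double tot = 0.0;
  for (long i = 0; i < nvox; ++i) { tot += activity[i]; cdf[i] = tot; }
  if (tot <= 0.0) stop("photon_mc: activity map is empty");
  for (long i = 0; i < nvox; ++i) cdf[i] /= tot;

  double rho_max = 0.0;
  for (long i = 0; i < nvox; ++i) rho_max = std::max(rho_max, density[i]);
  if (rho_max <= 0.0) rho_max = 1e-6;

  std::vector<double> cosv(n_views), sinv(n_views);
  for (int v = 0; v < n_views; ++v) {
    double a = angles_deg[v] * M_PI / 180.0;
    cosv[v] = std::cos(a); sinv[v] = std::sin(a);
  }
  const double cos_acc = std::cos(half_angle_deg * M_PI / 180.0);

  NumericVector scat(nu * nv * n_views), prim(nu * nv * n_views);
  const double x0 = origin_mm[0], y0 = origin_mm[1], z0 = origin_mm[2];
  const double dx = vox_mm[0], dy = vox_mm[1], dz = vox_mm[2];
  const double xmax = x0 + nx * dx, ymax = y0 + ny * dy, zmax = z0 + nz * dz;
  const double ou = -nu * pitch_mm[0] / 2.0, ov = -nv * pitch_mm[1] / 2.0;

  long NH = (long)n_hist;
  for (long h = 0; h < NH; ++h) {
    // decay site
    double u = R::runif(0.0, 1.0);
    long lo = 0, hi = nvox - 1;
    while (lo < hi) { long mid = (lo + hi) / 2; if (cdf[mid] < u) lo = mid + 1; else hi = mid; }
    long vi = lo;
    int iz = vi / (nx * ny); int rem = vi - (long)iz * nx * ny;
    int iy = rem / nx; int ix = rem - iy * nx;
    double px = x0 + (ix + R::runif(0.0, 1.0)) * dx;
    double py = y0 + (iy + R::runif(0.0, 1.0)) * dy;
    double pz = z0 + (iz + R::runif(0.0, 1.0)) * dz;
    // energy
    double ue = R::runif(0.0, 1.0);
    int elo = 0, ehi = spec_cdf.size() - 1;
    while (elo < ehi) { int m = (elo + ehi) / 2; if (spec_cdf[m] < ue) elo = m + 1; else ehi = m; }
    double E = spec_e_keV[elo];
    // direction
    double cz = 2.0 * R::runif(0.0, 1.0) - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double ph = 2.0 * M_PI * R::runif(0.0, 1.0);
    double dir[3] = { sz * std::cos(ph), sz * std::sin(ph), cz };
    int n_int = 0;
    bool alive = true, escaped = false;

    while (alive) {
      double mu_mass = mass_mu(E, loge, logmu);        // cm^2/g
      double sig_maj = rho_max * mu_mass * 0.1;        // per mm
      double s = -std::log(R::runif(0.0, 1.0)) / sig_maj;
      px += s * dir[0]; py += s * dir[1]; pz += s * dir[2];
      if (px < x0 || px >= xmax || py < y0 || py >= ymax ||
          pz < z0 || pz >= zmax) { escaped = true; break; }
      int jx = (int)((px - x0) / dx), jy = (int)((py - y0) / dy),
          jz = (int)((pz - z0) / dz);
      double rho = density[(long)jz * nx * ny + (long)jy * nx + jx];
      if (R::runif(0.0, 1.0) * rho_max > rho) continue;  // virtual
      // real interaction
      double pe = pe_mass_mu(E, loge, logmu);
      if (R::runif(0.0, 1.0) < pe / mu_mass) { alive = false; break; } // photo
      double c = kn_sample_cos(E);
      E = E / (1.0 + (E / 511.0) * (1.0 - c));
      ++n_int;
      if (E < cutoff_keV) { alive = false; break; }
      rotate_direction(dir, c);
    }
    if (!escaped) continue;

    // score against every view whose normal is within the acceptance cone
    NumericVector& tgt = (n_int > 0) ? scat : prim;
    for (int v = 0; v < n_views; ++v) {
      double nxv = -sinv[v], nyv = cosv[v]; // view normal (-sin a, cos a, 0)
      double dot = dir[0] * nxv + dir[1] * nyv;
      if (dot < cos_acc) continue;
      // propagate to the detector plane r.n = radius (invariant to how far
      // the Woodcock flight overshot the volume; models the geometric
      // distance-dependent blur of the acceptance cone)
      double s = (radius_mm - (px * nxv + py * nyv)) / dot;
      double ux = px + s * dir[0], uy = py + s * dir[1],
             uz = pz + s * dir[2];
      double uc = ux * cosv[v] + uy * sinv[v]; // transverse coordinate
      int iu = (int)std::floor((uc - ou) / pitch_mm[0]);
      int ivb = (int)std::floor((uz - ov) / pitch_mm[1]);
      if (iu < 0 || iu >= nu || ivb < 0 || ivb >= nv) continue;
      double fwhm = eres_frac_140 * std::sqrt(140.0 * E);
      double eb = E + R::norm_rand() * fwhm / 2.3548200450309493;
      if (eb < win_lo || eb > win_hi) continue;
      tgt[(long)v * nu * nv + (long)ivb * nu + iu] += 1.0;
    }
  }
  scat.attr("dim") = IntegerVector::create(nu, nv, n_views);
  prim.attr("dim") = IntegerVector::create(nu, nv, n_views);
  return List::create(_["scatter"] = scat, _["primary"] = prim);
}
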