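#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hop-drop-spin photon transport in a single homogeneous slab, MCML-style.
// Units: lengths in cm, coefficients in 1/cm. Uses R's RNG so results are
// reproducible under set.seed() from the R side.

static inline double rnd01() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Henyey-Greenstein deflection cosine; isotropic when g == 0.
static inline double hg_cos(double g) {
  if (g == 0.0) return 2.0 * rnd01() - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rnd01());
  return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

// Internal Fresnel reflectance for a photon hitting a boundary with
// |cos(theta_i)| = ca1, going from index n_in to n_out (unpolarised).
static double fresnel(double n_in, double n_out, double ca1) {
  if (n_in == n_out) return 0.0;
  if (ca1 > 1.0 - 1e-12) {           // normal incidence
    double r = (n_out - n_in) / (n_out + n_in);
    return r * r;
  }
  double sa1 = std::sqrt(1.0 - ca1 * ca1);
  double sa2 = n_in * sa1 / n_out;
  if (sa2 >= 1.0) return 1.0;        // total internal reflection
  double ca2 = std::sqrt(1.0 - sa2 * sa2);
  double cap = ca1 * ca2 - sa1 * sa2;   // cos(a1 + a2) etc. via identities
  double cam = ca1 * ca2 + sa1 * sa2;
  double sap = sa1 * ca2 + ca1 * sa2;
  double sam = sa1 * ca2 - ca1 * sa2;
  double r = 0.5 * sam * sam * (cam * cam + cap * cap) /
             (sap * sap * cam * cam);
  return r;
}

// [[Rcpp::export]]
List mc_slab_cpp(double mu_a, double mu_s, double g, double n_rel,
                 double thickness, int n_photons, double r_max, int n_bins,
                 double w_threshold = 1e-4, double survival_chance = 0.1) {
  const double mu_t = mu_a + mu_s;
  const double albedo_drop = (mu_t > 0.0) ? mu_a / mu_t : 0.0;
  NumericVector rd_hist(n_bins);
  const double dr = r_max / n_bins;
  double tot_rd = 0.0, tot_td = 0.0, tot_abs = 0.0, tot_spec = 0.0;
  double rd_overflow = 0.0;
  const double inv_m = survival_chance;

  for (int ph = 0; ph < n_photons; ++ph) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    if (n_rel != 1.0) {               // specular reflection at launch
      double rsp = (n_rel - 1.0) / (n_rel + 1.0);
      rsp *= rsp;
      tot_spec += rsp;
      w -= rsp;
    }
    bool alive = true;
    double s_left = 0.0;              // dimensionless leftover step
    while (alive) {
      if (s_left <= 0.0) s_left = -std::log(rnd01());
      double s = s_left / mu_t;
      // distance to the face the photon is heading for
      double db = 1e30;
      int face = 0;                   // -1 top (z=0), +1 bottom (z=d)
      if (uz < 0.0)      { db = -z / uz;               face = -1; }
      else if (uz > 0.0) { db = (thickness - z) / uz;  face = +1; }
      if (db < s) {                   // hop to boundary
        x += db * ux; y += db * uy; z += db * uz;
        s_left -= db * mu_t;
        double r_int = fresnel(n_rel, 1.0, std::fabs(uz));
        if (unif_rand() > r_int) {    // transmit out of the slab
          double r_exit = std::sqrt(x * x + y * y);
          if (face < 0) {
            tot_rd += w;
            int bin = (int)(r_exit / dr);
            if (bin < n_bins) rd_hist[bin] += w; else rd_overflow += w;
          } else {
            tot_td += w;
          }
          alive = false;
        } else {                      // internally reflect, keep leftover
          uz = -uz;
          z = (face < 0) ? 0.0 : thickness;
        }
        continue;
      }
      // interior hop
      x += s * ux; y += s * uy; z += s * uz;
      s_left = 0.0;
      // drop
      double dw = w * albedo_drop;
      tot_abs += dw;
      w -= dw;
      if (w <= 0.0) { alive = false; continue; }
      // spin
      double ct = hg_cos(g);
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double psi = 2.0 * M_PI * rnd01();
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double ux2 = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double uy2 = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double uz2 = -st * cp * den + uz * ct;
        ux = ux2; uy = uy2; uz = uz2;
      }
      // roulette with exact weight bookkeeping: the weight injected on
      // survival is debited from (and killed weight credited to) the
      // absorbed tally, so R + T + A + specular sums to 1 exactly
      if (w < w_threshold) {
        if (rnd01() < inv_m) {
          tot_abs -= w * (1.0 / inv_m - 1.0);
          w /= inv_m;
        } else {
          tot_abs += w;
          alive = false;
        }
      }
    }
  }
  double np = (double)n_photons;
  NumericVector rd_per_area(n_bins);
  for (int b = 0; b < n_bins; ++b) {
    double area = M_PI * dr * dr * (2.0 * b + 1.0);  // annulus area
    rd_per_area[b] = rd_hist[b] / (np * area);
  }
  return List::create(
    _["rd_hist"] = rd_hist / np,
    _["rd_per_cm2"] = rd_per_area,
    _["rd_overflow"] = rd_overflow / np,
    _["total_rd"] = tot_rd / np,
    _["total_td"] = tot_td / np,
    _["total_absorbed"] = tot_abs / np,
    _["total_specular"] = tot_spec / np);
}

// [[Rcpp::export]]
NumericVector hg_sample_cpp(double g, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g);
  return out;
}
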