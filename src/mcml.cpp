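// Weighted-photon Monte Carlo transport in a plane-parallel layered medium
// (MCML scheme): pencil beam at normal incidence, Fresnel specular deduction,
// exponential free-path sampling on mu_t, fractional weight deposition,
// Henyey-Greenstein scattering, Fresnel internal reflection at interfaces,
// Russian-roulette termination. Units: cm and cm^-1 throughout.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64 (seed expansion) + xoshiro256++ (stream)
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: never returns 0 so -log(u) is finite
  double runif_oc() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  // uniform in [0, 1)
  double runif_co() {
    return static_cast<double>(next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance for incidence cosine ci going n1 -> n2;
// also returns the transmitted cosine via ct.
double fresnel(double n1, double n2, double ci, double &ct) {
  if (ci > 1.0) ci = 1.0;
  if (n1 == n2) { ct = ci; return 0.0; }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { ct = 0.0; return 1.0; }  // total internal reflection
  ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  if (ci > 0.999999) {  // normal incidence limit
    double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

struct Photon {
  double x, y, z;      // cm; z grows downward, z=0 at top surface
  double ux, uy, uz;   // direction cosines
  double w;            // weight
  int layer;           // current layer index
  bool alive;
};

struct Geometry {
  int nlay;
  std::vector<double> z0, z1;      // layer boundaries (top, bottom)
  std::vector<double> mua, mus, g, n;
  double n_top, n_bot;
};

void spin(Photon &p, double g, Rng &rng) {
  double ct;
  if (std::fabs(g) < 1e-12) {
    ct = 2.0 * rng.runif_co() - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif_co());
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct < -1.0) ct = -1.0; else if (ct > 1.0) ct = 1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.runif_co();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  if (std::fabs(uz) > 0.99999) {
    p.ux = st * cp;
    p.uy = st * sp;
    p.uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    p.ux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    p.uy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    p.uz = -den * st * cp + uz * ct;
  }
  // renormalize against drift
  double norm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= norm; p.uy /= norm; p.uz /= norm;
}

enum Exit { NONE, TOP, BOTTOM };

// Propagate one photon until it exits or its weight is disposed of.
// In white mode (mua all zero, record != nullptr) per-layer geometric path
// lengths are accumulated into record. Tallies are added to refl/trans/absorb.
// In white mode geo.mua holds the per-layer lower envelope of the
// absorption combos, treated as an analog absorber: photons die at the
// envelope rate and each combo is reweighted by the excess absorption only
// (absorption-rescaling identity), so estimates stay unbiased for every
// combo while walk lengths match the least absorbing physical medium.
template <bool WHITE>
Exit trace(Photon &p, const Geometry &geo, Rng &rng,
           double w_threshold, double p_survival,
           double &absorb, double *record, double &exit_weight) {
  const int GUARD = 50000000;  // nontermination guard on events
  int events = 0;
  double sleft = 0.0;  // dimensionless remaining step
  while (p.alive) {
    if (++events > GUARD) stop("photon did not terminate (non-interacting trap?)");
    const int L = p.layer;
    double mut = geo.mua[L] + geo.mus[L];
    double step;          // physical path available this substep
    bool interacts;
    if (mut <= 0.0) {
      step = R_PosInf;    // ballistic: go straight to a boundary
      interacts = false;
    } else {
      if (sleft <= 0.0) sleft = -std::log(rng.runif_oc());
      step = sleft / mut;
      interacts = true;
    }
    // distance to the boundary along uz
    double dbound = R_PosInf;
    bool up = p.uz < 0.0, down = p.uz > 0.0;
    if (up)   dbound = (geo.z0[L] - p.z) / p.uz;
    if (down) dbound = (geo.z1[L] - p.z) / p.uz;
    if (dbound <= step) {
      // move to boundary
      p.x += p.ux * dbound; p.y += p.uy * dbound; p.z += p.uz * dbound;
      if (WHITE) record[L] += dbound;
      if (interacts) sleft -= dbound * mut;
      // interface crossing
      double ci = std::fabs(p.uz);
      double n1 = geo.n[L];
      double n2;
      bool to_top = up && L == 0;
      bool to_bot = down && L == geo.nlay - 1;
      if (to_top) n2 = geo.n_top;
      else if (to_bot) n2 = geo.n_bot;
      else n2 = geo.n[up ? L - 1 : L + 1];
      double ct;
      double R = fresnel(n1, n2, ci, ct);
      if (rng.runif_co() > R) {
        // transmit / refract
        if (to_top || to_bot) {
          exit_weight = p.w;
          p.alive = false;
          return to_top ? TOP : BOTTOM;
        }
        double scale = n1 / n2;
        p.ux *= scale; p.uy *= scale;
        p.uz = (down ? ct : -ct);
        double norm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
        p.ux /= norm; p.uy /= norm; p.uz /= norm;
        p.layer = up ? L - 1 : L + 1;
      } else {
        p.uz = -p.uz;  // internal reflection
      }
      continue;
    }
    if (!interacts) stop("photon trapped in non-interacting layer");
    // full interaction step inside the layer
    p.x += p.ux * step; p.y += p.uy * step; p.z += p.uz * step;
    if (WHITE) record[L] += step;
    sleft = 0.0;
    if (!WHITE) {
      double dw = p.w * geo.mua[L] / mut;
      absorb += dw;
      p.w -= dw;
      if (p.w <= 0.0) {  // zero albedo: nothing left to propagate
        p.alive = false;
        return NONE;
      }
      if (p.w < w_threshold) {
        if (rng.runif_co() < p_survival) {
          // boosted weight is debited from the absorbed tally so the
          // per-run energy ledger stays exact while tallies stay unbiased
          double boost = p.w * (1.0 / p_survival - 1.0);
          absorb -= boost;
          p.w += boost;
        } else {
          absorb += p.w;
          p.w = 0.0;
          p.alive = false;
          return NONE;
        }
      }
    } else if (geo.mua[L] > 0.0 &&
               rng.runif_co() < geo.mua[L] / mut) {
      p.alive = false;  // analog absorption at the envelope rate
      return NONE;
    }
    spin(p, geo.g[L], rng);
  }
  return NONE;
}

Geometry make_geometry(NumericVector d, NumericVector mua, NumericVector mus,
                       NumericVector g, NumericVector n,
                       double n_top, double n_bot) {
  int nl = d.size();
  Geometry geo;
  geo.nlay = nl;
  geo.z0.resize(nl); geo.z1.resize(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) { geo.z0[i] = z; z += d[i]; geo.z1[i] = z; }
  geo.mua.assign(mua.begin(), mua.end());
  geo.mus.assign(mus.begin(), mus.end());
  geo.g.assign(g.begin(), g.end());
  geo.n.assign(n.begin(), n.end());
  geo.n_top = n_top; geo.n_bot = n_bot;
  return geo;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_mc_simulate(NumericVector d, NumericVector mua, NumericVector mus,
                     NumericVector g, NumericVector n,
                     double n_top, double n_bot,
                     int n_photons, double seed,
                     double w_threshold, double p_survival) {
  Geometry geo = make_geometry(d, mua, mus, g, n, n_top, n_bot);
  Rng rng(static_cast<uint64_t>(seed));
  double ct;
  double rsp = fresnel(n_top, geo.n[0], 1.0, ct);  // specular at launch
  double w0 = 1.0 - rsp;
  double refl = 0.0, trans = 0.0, absorb = 0.0;
  double refl_sq = 0.0;
  for (int i = 0; i < n_photons; ++i) {
    Photon p{0.0, 0.0, 0.0, 0.0, 0.0, 1.0, w0, 0, true};
    double exit_w = 0.0;
    Exit e = trace<false>(p, geo, rng, w_threshold, p_survival,
                          absorb, nullptr, exit_w);
    if (e == TOP) { refl += exit_w; refl_sq += exit_w * exit_w; }
    else if (e == BOTTOM) trans += exit_w;
  }
  double N = static_cast<double>(n_photons);
  double Rd = refl / N, Td = trans / N, Ad = absorb / N;
  double var = refl_sq / N - Rd * Rd;
  double se = std::sqrt(std::max(0.0, var) / N);
  return List::create(_["specular"] = rsp, _["diffuse_reflectance"] = Rd,
                      _["total_transmittance"] = Td, _["absorbed"] = Ad,
                      _["se_reflectance"] = se, _["n_photons"] = n_photons);
}

//' @noRd
// [[Rcpp::export]]
List cpp_mc_white(NumericVector d, NumericVector mus,
                  NumericVector g, NumericVector n,
                  double n_top, double n_bot,
                  int n_photons, double seed,
                  NumericMatrix mua_combos) {
  // scattering-only transport; absorption applied post hoc per combo by
  // Beer-Lambert reweighting of the recorded per-layer path lengths
  int nl = d.size();
  int ncombo_pre = mua_combos.nrow();
  NumericVector floor_mua(nl);
  for (int l = 0; l < nl; ++l) {
    double m = mua_combos(0, l);
    for (int j = 1; j < ncombo_pre; ++j) m = std::min(m, mua_combos(j, l));
    floor_mua[l] = m;
  }
  Geometry geo = make_geometry(d, floor_mua, mus, g, n, n_top, n_bot);
  Rng rng(static_cast<uint64_t>(seed));
  double ct;
  double rsp = fresnel(n_top, geo.n[0], 1.0, ct);
  double w0 = 1.0 - rsp;
  int ncombo = mua_combos.nrow();
  if (mua_combos.ncol() != nl) stop("mua_combos must have one column per layer");
  std::vector<double> refl(ncombo, 0.0), refl_sq(ncombo, 0.0);
  std::vector<double> trans(ncombo, 0.0);
  std::vector<double> record(nl);
  double dummy = 0.0;
  for (int i = 0; i < n_photons; ++i) {
    Photon p{0.0, 0.0, 0.0, 0.0, 0.0, 1.0, w0, 0, true};
    std::fill(record.begin(), record.end(), 0.0);
    double exit_w = 0.0;
    Exit e = trace<true>(p, geo, rng, 0.0, 1.0,
                         dummy, record.data(), exit_w);
    if (e == NONE) continue;
    for (int j = 0; j < ncombo; ++j) {
      double att = 0.0;
      // excess absorption over the analog envelope already paid in-flight
      for (int L = 0; L < nl; ++L) {
        att += (mua_combos(j, L) - floor_mua[L]) * record[L];
      }
      double wout = exit_w * std::exp(-att);
      if (e == TOP) { refl[j] += wout; refl_sq[j] += wout * wout; }
      else trans[j] += wout;
    }
  }
  double N = static_cast<double>(n_photons);
  NumericVector Rd(ncombo), Td(ncombo), SE(ncombo);
  for (int j = 0; j < ncombo; ++j) {
    Rd[j] = refl[j] / N;
    Td[j] = trans[j] / N;
    double var = refl_sq[j] / N - Rd[j] * Rd[j];
    SE[j] = std::sqrt(std::max(0.0, var) / N);
  }
  return List::create(_["specular"] = rsp, _["diffuse_reflectance"] = Rd,
                      _["total_transmittance"] = Td, _["se_reflectance"] = SE,
                      _["n_photons"] = n_photons);
}
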