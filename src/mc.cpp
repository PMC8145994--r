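#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Unpolarized Fresnel reflectance for a ray in medium ni hitting an interface
// with medium nt at incidence cosine cosi (relative to the normal).
static double fresnel_R(double cosi, double ni, double nt) {
  cosi = std::fabs(cosi);
  if (cosi > 1.0) cosi = 1.0;
  const double sini2 = 1.0 - cosi * cosi;
  const double sint2 = (ni / nt) * (ni / nt) * sini2;
  if (sint2 >= 1.0) return 1.0;  // total internal reflection
  const double cost = std::sqrt(1.0 - sint2);
  if (cosi > 0.999999) {  // normal incidence limit
    const double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  const double rs = (ni * cosi - nt * cost) / (ni * cosi + nt * cost);
  const double rp = (ni * cost - nt * cosi) / (ni * cost + nt * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine.
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Uniform azimuth as (cos, sin) by Marsaglia rejection (no trig calls).
static inline void rand_azimuth(Xoshiro256 &rng, double &cp, double &sp) {
  double u, v, s;
  do {
    u = 2.0 * rng.unif() - 1.0;
    v = 2.0 * rng.unif() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  const double inv = 1.0 / s;
  cp = (u * u - v * v) * inv;
  sp = 2.0 * u * v * inv;
}

static inline void spin(double ct, double cp, double sp, double &ux,
                        double &uy, double &uz) {
  const double st = std::sqrt(1.0 - ct * ct);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double inv = 1.0 / den;
    const double nux = st * (ux * uz * cp - uy * sp) * inv + ux * ct;
    const double nuy = st * (uy * uz * cp + ux * sp) * inv + uy * ct;
    const double nuz = -den * st * cp + uz * ct;
    ux = nux;
    uy = nuy;
    uz = nuz;
  }
}

// occasional renormalization guards against drift of the direction cosines
static inline void renorm(double &ux, double &uy, double &uz) {
  const double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n;
  uy /= n;
  uz /= n;
}

// Layered white Monte Carlo: pencil beam at the origin, mu_a = 0 everywhere,
// Henyey-Greenstein scattering with mu_s = mu_s' / (1 - g), probabilistic
// Fresnel at the top surface (internal interfaces are index-matched), photons
// crossing the bottom of the deepest layer are lost. Per-layer pathlengths and
// the exit radius are recorded for every photon escaping the top surface.
// Photons whose total pathlength exceeds max_pathlength (cm) are terminated:
// their Beer factor at any absorption of interest is negligible.
// [[Rcpp::export]]
List cpp_white_mc(NumericVector thickness, NumericVector musp, NumericVector g,
                  double n_medium, double n_ambient, int n_photons,
                  double seed, double max_pathlength) {
  const int nlay = thickness.size();
  std::vector<double> mus(nlay), inv_mus(nlay), zb(nlay + 1);
  zb[0] = 0.0;
  for (int k = 0; k < nlay; ++k) {
    mus[k] = musp[k] / (1.0 - g[k]);
    inv_mus[k] = 1.0 / mus[k];
    zb[k + 1] = zb[k] + thickness[k];
  }
  const double w0 = 1.0 - fresnel_R(1.0, n_ambient, n_medium);
  const double ROULETTE_WMIN = 1e-4, ROULETTE_P = 0.1;

  Xoshiro256 rng(static_cast<uint64_t>(seed));

  std::vector<double> out_w, out_r;
  std::vector<std::vector<double> > out_L(nlay);
  out_w.reserve(n_photons);
  out_r.reserve(n_photons);
  long n_lost = 0, n_capped = 0;

  std::vector<double> L(nlay);
  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w0;
    int layer = 0;
    std::fill(L.begin(), L.end(), 0.0);
    double Ltot = 0.0;
    bool exited = false, dead = false;
    long events = 0;

    while (!exited && !dead) {
      double sopt = -std::log(rng.unif());  // optical depth in mu_s units
      for (;;) {
        const double s_full = sopt * inv_mus[layer];
        double db;
        if (uz > 0.0)
          db = (zb[layer + 1] - z) / uz;
        else if (uz < 0.0)
          db = (zb[layer] - z) / uz;
        else
          db = 1e300;
        if (s_full < db) {
          x += s_full * ux;
          y += s_full * uy;
          z += s_full * uz;
          L[layer] += s_full;
          Ltot += s_full;
          break;  // scatter here
        }
        x += db * ux;
        y += db * uy;
        z += db * uz;
        L[layer] += db;
        Ltot += db;
        sopt -= db * mus[layer];
        if (uz < 0.0 && layer == 0) {
          const double R = fresnel_R(uz, n_medium, n_ambient);
          if (rng.unif() < R) {
            uz = -uz;  // internal reflection at the top surface
            z = 0.0;
          } else {
            exited = true;
            break;
          }
        } else if (uz > 0.0 && layer == nlay - 1) {
          dead = true;  // lost through the bottom of the deepest layer
          break;
        } else {
          layer += (uz > 0.0) ? 1 : -1;
          z = (uz > 0.0) ? zb[layer] : zb[layer + 1];
        }
      }
      if (exited || dead) break;
      double cp, sp;
      const double ct = hg_cos(g[layer], rng.unif());
      rand_azimuth(rng, cp, sp);
      spin(ct, cp, sp, ux, uy, uz);
      if ((++events & 127) == 0) renorm(ux, uy, uz);
      if (Ltot + z > max_pathlength) {
        dead = true;  // cannot exit below the pathlength cap
        ++n_capped;
      }
      if (w < ROULETTE_WMIN) {
        if (rng.unif() < ROULETTE_P)
          w /= ROULETTE_P;
        else
          dead = true;
      }
    }

    if (exited) {
      out_w.push_back(w);
      out_r.push_back(std::sqrt(x * x + y * y));
      for (int k = 0; k < nlay; ++k) out_L[k].push_back(L[k]);
    } else {
      ++n_lost;
    }
  }

  const int nex = static_cast<int>(out_w.size());
  NumericMatrix Lm(nex, nlay);
  for (int k = 0; k < nlay; ++k)
    for (int i = 0; i < nex; ++i) Lm(i, k) = out_L[k][i];
  return List::create(_["weight"] = NumericVector(out_w.begin(), out_w.end()),
                      _["radius"] = NumericVector(out_r.begin(), out_r.end()),
                      _["pathlengths"] = Lm, _["n_photons"] = n_photons,
                      _["n_lost"] = n_lost, _["n_capped"] = n_capped,
                      _["specular"] = 1.0 - w0);
}

// Direct absorbing Monte Carlo (independent oracle path): steps sampled from
// mu_t = mu_a + mu_s, survival weighting by the single-scattering albedo,
// Russian roulette below 1e-4. Scores Rd(fx) = mean of w * J0(2 pi fx rho)
// over launched photons, with the standard error of that mean.
// [[Rcpp::export]]
List cpp_direct_mc(NumericVector thickness, NumericVector musp,
                   NumericVector g, NumericVector mua, double n_medium,
                   double n_ambient, int n_photons, NumericVector fx,
                   double seed) {
  const int nlay = thickness.size();
  const int nfx = fx.size();
  std::vector<double> mus(nlay), mut(nlay), albedo(nlay), zb(nlay + 1);
  zb[0] = 0.0;
  for (int k = 0; k < nlay; ++k) {
    mus[k] = musp[k] / (1.0 - g[k]);
    mut[k] = mus[k] + mua[k];
    albedo[k] = mus[k] / mut[k];
    zb[k + 1] = zb[k] + thickness[k];
  }
  const double w0 = 1.0 - fresnel_R(1.0, n_ambient, n_medium);
  const double ROULETTE_WMIN = 1e-4, ROULETTE_P = 0.1;

  Xoshiro256 rng(static_cast<uint64_t>(seed));
  std::vector<double> sum(nfx, 0.0), sumsq(nfx, 0.0);

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w0;
    int layer = 0;
    bool exited = false, dead = false;
    long events = 0;

    while (!exited && !dead) {
      double sopt = -std::log(rng.unif());  // optical depth in mu_t units
      for (;;) {
        const double s_full = sopt / mut[layer];
        double db;
        if (uz > 0.0)
          db = (zb[layer + 1] - z) / uz;
        else if (uz < 0.0)
          db = (zb[layer] - z) / uz;
        else
          db = 1e300;
        if (s_full < db) {
          x += s_full * ux;
          y += s_full * uy;
          z += s_full * uz;
          break;
        }
        x += db * ux;
        y += db * uy;
        z += db * uz;
        sopt -= db * mut[layer];
        if (uz < 0.0 && layer == 0) {
          const double R = fresnel_R(uz, n_medium, n_ambient);
          if (rng.unif() < R) {
            uz = -uz;
            z = 0.0;
          } else {
            exited = true;
            break;
          }
        } else if (uz > 0.0 && layer == nlay - 1) {
          dead = true;
          break;
        } else {
          layer += (uz > 0.0) ? 1 : -1;
          z = (uz > 0.0) ? zb[layer] : zb[layer + 1];
        }
      }
      if (exited || dead) break;
      w *= albedo[layer];
      double cp, sp;
      const double ct = hg_cos(g[layer], rng.unif());
      rand_azimuth(rng, cp, sp);
      spin(ct, cp, sp, ux, uy, uz);
      if ((++events & 127) == 0) renorm(ux, uy, uz);
      if (w < ROULETTE_WMIN) {
        if (rng.unif() < ROULETTE_P)
          w /= ROULETTE_P;
        else
          dead = true;
      }
    }

    if (exited) {
      const double rho = std::sqrt(x * x + y * y);
      for (int j = 0; j < nfx; ++j) {
        const double c = w * R::bessel_j(2.0 * M_PI * fx[j] * rho, 0.0);
        sum[j] += c;
        sumsq[j] += c * c;
      }
    }
  }

  NumericVector rd(nfx), se(nfx);
  for (int j = 0; j < nfx; ++j) {
    const double m = sum[j] / n_photons;
    const double v = sumsq[j] / n_photons - m * m;
    rd[j] = m;
    se[j] = std::sqrt(v > 0 ? v / n_photons : 0.0);
  }
  return List::create(_["rd"] = rd, _["se"] = se,
                      _["n_photons"] = n_photons);
}
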