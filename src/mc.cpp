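// Voxel-based Monte Carlo photon transport.
//
// MCML/MCX-style weighted-packet transport on an axis-aligned voxel grid:
// exponential dimensionless steps clipped at voxel faces, partial weight
// deposition (w * mu_a / mu_t) at each interaction, Henyey-Greenstein
// scattering, unpolarized Fresnel reflect/refract wherever the refractive
// index changes across a voxel face (including escape to the outside
// medium), and Russian-roulette termination.  Each photon owns a
// counter-based RNG stream keyed by (seed, photon index), so tallies are
// independent of execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform in (0,1)
static inline double u01(uint64_t &s) {
  return ((splitmix64(s) >> 11) + 1.0) * (1.0 / 9007199254740993.0);
}

static inline double fresnel_unpol(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double s2i = 1.0 - ci * ci;
  double s2t = (n1 / n2) * (n1 / n2) * s2i;
  if (s2t >= 1.0) return 1.0;
  double ct = std::sqrt(1.0 - s2t);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n2 * ci - n1 * ct) / (n2 * ci + n1 * ct);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double u, double g) {
  if (g < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
  return c;
}

static inline void scatter(double &ux, double &uy, double &uz,
                           double g, uint64_t &s) {
  double ct = hg_cos(u01(s), g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * u01(s);
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector medium, IntegerVector dims, double voxel,
                NumericVector med_mua, NumericVector med_mus,
                NumericVector med_g, NumericVector med_n,
                double n_out, bool lateral_mirror,
                double beam_sigma, int entry_ix, int entry_iy,
                double n_photons, double seed,
                double w_th, double rm, double max_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = voxel;
  const double Lx = nx * hx, Ly = ny * hx;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dep(nvox);
  IntegerMatrix esc_top(nx, ny);
  double spec_tot = 0.0, rd_tot = 0.0, tt_tot = 0.0, residual = 0.0;
  double capped = 0.0;
  const uint64_t base = (uint64_t)(int64_t)seed * 0x9E3779B97F4A7C15ULL;
  const double N = n_photons;

  for (double ip = 0; ip < N; ip += 1.0) {
    uint64_t s = base ^ ((uint64_t)(ip + 1.0) * 0xD1B54A32D192ED03ULL);
    // warm up the stream
    splitmix64(s); splitmix64(s);

    // launch position: centre of entry voxel on the top face (optional
    // Gaussian lateral profile)
    double x = (entry_ix + 0.5) * hx, y = (entry_iy + 0.5) * hx, z = 0.0;
    if (beam_sigma > 0) {
      double r = beam_sigma * std::sqrt(-2.0 * std::log(u01(s)));
      double th = 2.0 * M_PI * u01(s);
      x = std::min(std::max(x + r * std::cos(th), 0.5 * hx), Lx - 0.5 * hx);
      y = std::min(std::max(y + r * std::sin(th), 0.5 * hx), Ly - 0.5 * hx);
    }
    int ix = (int)(x / hx), iy = (int)(y / hx), iz = 0;
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    double ux = 0.0, uy = 0.0, uz = 1.0;

    int m = medium[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)] - 1;
    double w = 1.0;
    double rs = fresnel_unpol(n_out, med_n[m], 1.0);
    spec_tot += rs;
    w -= rs;

    double sleft = -std::log(u01(s));
    double events = 0.0;
    bool alive = true;

    while (alive) {
      R_xlen_t vid = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      m = medium[vid] - 1;
      double mua = med_mua[m], mus = med_mus[m];
      double mut = mua + mus;

      // distance to the nearest voxel face along the direction
      double dxb = (ux > 0) ? (((ix + 1) * hx - x) / ux)
                 : (ux < 0) ? ((ix * hx - x) / ux) : 1e30;
      double dyb = (uy > 0) ? (((iy + 1) * hx - y) / uy)
                 : (uy < 0) ? ((iy * hx - y) / uy) : 1e30;
      double dzb = (uz > 0) ? (((iz + 1) * hx - z) / uz)
                 : (uz < 0) ? ((iz * hx - z) / uz) : 1e30;
      double db = std::min(dxb, std::min(dyb, dzb));
      if (db < 0) db = 0;
      int axis = (db == dxb) ? 0 : (db == dyb) ? 1 : 2;

      double dneed = (mut > 0) ? (sleft / mut) : 1e30;

      if (db < dneed) {
        // advance to the face
        x += ux * db; y += uy * db; z += uz * db;
        if (mut > 0) sleft -= db * mut;

        int step = (axis == 0 ? (ux > 0 ? 1 : -1)
                  : axis == 1 ? (uy > 0 ? 1 : -1)
                              : (uz > 0 ? 1 : -1));
        int jx = ix + (axis == 0 ? step : 0);
        int jy = iy + (axis == 1 ? step : 0);
        int jz = iz + (axis == 2 ? step : 0);
        bool outside = (jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                        jz < 0 || jz >= nz);

        if (outside && lateral_mirror && axis != 2) {
          // mirror side walls: laterally infinite homogeneous medium
          if (axis == 0) ux = -ux; else uy = -uy;
          continue;
        }

        double n1 = med_n[m];
        double n2;
        int mj = -1;
        if (outside) n2 = n_out;
        else {
          mj = medium[(R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz)] - 1;
          n2 = med_n[mj];
        }

        if (n1 != n2) {
          double ci = (axis == 0) ? std::fabs(ux)
                    : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
          double R = fresnel_unpol(n1, n2, ci);
          if (u01(s) < R) {
            // reflect: flip the normal component, stay in current voxel
            if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
            continue;
          }
          // refract: bend transverse components by n1/n2
          double ratio = n1 / n2;
          double ct = std::sqrt(std::max(0.0, 1.0 - ratio * ratio * (1.0 - ci * ci)));
          if (axis == 0) {
            uy *= ratio; uz *= ratio; ux = (ux > 0 ? ct : -ct);
          } else if (axis == 1) {
            ux *= ratio; uz *= ratio; uy = (uy > 0 ? ct : -ct);
          } else {
            ux *= ratio; uy *= ratio; uz = (uz > 0 ? ct : -ct);
          }
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
        }

        if (outside) {
          // escaped: classify by exit face (sides by direction sign)
          if (axis == 2) {
            if (step < 0) {
              rd_tot += w;
              if (ix >= 0 && ix < nx && iy >= 0 && iy < ny)
                esc_top(ix, iy) += 1;
            } else tt_tot += w;
          } else {
            if (uz < 0) rd_tot += w; else tt_tot += w;
          }
          alive = false;
          continue;
        }
        ix = jx; iy = jy; iz = jz;
        continue;
      }

      // interaction inside the voxel
      x += ux * dneed; y += uy * dneed; z += uz * dneed;
      double dw = w * mua / mut;
      dep[vid] += dw;
      w -= dw;
      scatter(ux, uy, uz, med_g[m], s);
      events += 1.0;

      if (w <= 0.0) { alive = false; continue; }
      if (w < w_th) {
        if (u01(s) < 1.0 / rm) {
          residual -= (rm - 1.0) * w;   // survivor boost is un-launched weight
          w *= rm;
        } else {
          residual += w;                // killed weight never tallied
          alive = false;
          continue;
        }
      }
      if (events >= max_events) {
        dep[vid] += w;                  // conservative forced termination
        capped += 1.0;
        alive = false;
        continue;
      }
      sleft = -std::log(u01(s));
    }
  }

  double dep_sum = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) dep_sum += dep[i];
  for (R_xlen_t i = 0; i < nvox; ++i) dep[i] /= N;

  return List::create(
    _["specular"] = spec_tot / N,
    _["R_d"] = rd_tot / N,
    _["T"] = tt_tot / N,
    _["A"] = (dep_sum + residual) / N,
    _["deposited"] = dep,
    _["roulette_residual"] = residual / N,
    _["escape_top_counts"] = esc_top,
    _["n_capped"] = capped);
}
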