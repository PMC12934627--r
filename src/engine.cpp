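#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Core stepping engine for the membrane simulation: immobile two-state
// receptors on a sphere, G proteins doing tangent-step Brownian motion,
// per-step proximity encounters within great-circle radius r*.
//
// Randomness: a fast counter-seeded xoshiro256++ stream, seeded from R's RNG
// so that set.seed() in R controls the whole simulation.

namespace {

struct Xoshiro256 {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro256(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia polar method (no trig); returns pairs, caches the spare
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

// 64 bits drawn from R's stream so C++ results follow set.seed()
uint64_t seed_from_R() {
  const uint64_t hi = (uint64_t)std::floor(unif_rand() * 4294967296.0);
  const uint64_t lo = (uint64_t)std::floor(unif_rand() * 4294967296.0);
  return (hi << 32) ^ lo;
}

// Receptors sorted by z and bucketed into z-bins at least one chord of r*
// wide, so the encounter search scans only the three bins around a query.
struct ReceptorIndex {
  int n, nbins;
  std::vector<double> x, y, z;  // sorted by z
  std::vector<int> orig;        // original (0-based) receptor index
  std::vector<int> bin_start;   // offsets into the sorted arrays, size nbins+1
  double dotmin;                // L^2 cos(r*/L): dot >= dotmin <=> within r*
  double zband;                 // chord of r*; |dz| <= zband is necessary
  double L_, zlo_, binw_inv;

  ReceptorIndex(const NumericMatrix &rpos, double rstar, double L) {
    n = rpos.nrow();
    L_ = L;
    dotmin = L * L * std::cos(rstar / L);
    zband = 2.0 * L * std::sin(rstar / (2.0 * L));
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return rpos(a, 2) < rpos(b, 2);
    });
    x.resize(n);
    y.resize(n);
    z.resize(n);
    orig.resize(n);
    for (int k = 0; k < n; ++k) {
      x[k] = rpos(ord[k], 0);
      y[k] = rpos(ord[k], 1);
      z[k] = rpos(ord[k], 2);
      orig[k] = ord[k];
    }
    nbins = std::max(1, std::min((int)(2.0 * L / zband), 4096));
    zlo_ = -L;
    binw_inv = nbins / (2.0 * L);
    bin_start.assign(nbins + 1, 0);
    std::vector<int> count(nbins, 0);
    for (int k = 0; k < n; ++k) ++count[bin_of(z[k])];
    for (int b = 0; b < nbins; ++b) bin_start[b + 1] = bin_start[b] + count[b];
  }

  int bin_of(double zz) const {
    int b = (int)((zz - zlo_) * binw_inv);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    return b;
  }

  // Nearest receptor (original index) within r* of (px,py,pz), or -1.
  // Ties in the dot product break to the lowest original index.
  int nearest(double px, double py, double pz) const {
    if (n == 0) return -1;
    const int b = bin_of(pz);
    const int k0 = bin_start[b > 0 ? b - 1 : 0];
    const int k1 = bin_start[b + 2 <= nbins ? b + 2 : nbins];
    const double zlo = pz - zband, zhi = pz + zband;
    int best = -1;
    double best_dot = dotmin;
    for (int k = k0; k < k1; ++k) {
      if (z[k] < zlo || z[k] > zhi) continue;
      const double d = px * x[k] + py * y[k] + pz * z[k];
      if (d > best_dot || (d == best_dot && best >= 0 && orig[k] < best)) {
        best_dot = d;
        best = orig[k];
      }
    }
    return best;
  }
};

inline void tangent_step(double &px, double &py, double &pz, double L,
                         double sd, Xoshiro256 &rng) {
  const double invL = 1.0 / L;
  const double nx = px * invL, ny = py * invL, nz = pz * invL;
  // orthonormal tangent basis (e1, e2) at n
  double ux, uy, uz;
  if (std::fabs(nz) < 0.9) {
    ux = 0.0; uy = 0.0; uz = 1.0;
  } else {
    ux = 1.0; uy = 0.0; uz = 0.0;
  }
  double e1x = uy * nz - uz * ny;
  double e1y = uz * nx - ux * nz;
  double e1z = ux * ny - uy * nx;
  const double inv1 = 1.0 / std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x *= inv1; e1y *= inv1; e1z *= inv1;
  const double e2x = ny * e1z - nz * e1y;
  const double e2y = nz * e1x - nx * e1z;
  const double e2z = nx * e1y - ny * e1x;
  const double s1 = sd * rng.norm(), s2 = sd * rng.norm();
  px += s1 * e1x + s2 * e2x;
  py += s1 * e1y + s2 * e2y;
  pz += s1 * e1z + s2 * e2z;
  const double scale = L / std::sqrt(px * px + py * py + pz * pz);
  px *= scale; py *= scale; pz *= scale;
}

}  // namespace

// Run one simulation segment. Per step: diffuse G proteins, update receptor
// states, resolve encounters, apply the G-state rule (mode 0 = ratiometric,
// mode 1 = classical with decay before encounter-activation).
//
// conc: per-receptor ligand concentration (fixed while the gradient is fixed).
// Returns snapshots every snap_every steps plus the final mutable state; when
// record_ages, also the per-G time since the last active-receptor encounter
// at each snapshot (-1 = never encountered an active receptor).
// [[Rcpp::export]]
List sim_segment_cpp(NumericMatrix rpos, IntegerVector ractive,
                     NumericMatrix gpos, IntegerVector gactive,
                     NumericVector conc, double kon, double koff, double kgi,
                     double DG, double rstar, double L, double dt, int nsteps,
                     int snap_every, int skip_steps, int mode,
                     bool record_ages, double t0) {
  const int nR = rpos.nrow(), nG = gpos.nrow();
  if (ractive.size() != nR || gactive.size() != nG || conc.size() != nR)
    stop("inconsistent state dimensions");
  Xoshiro256 rng(seed_from_R());
  ReceptorIndex idx(rpos, rstar, L);

  std::vector<double> gx(nG), gy(nG), gz(nG);
  for (int g = 0; g < nG; ++g) {
    gx[g] = gpos(g, 0);
    gy[g] = gpos(g, 1);
    gz[g] = gpos(g, 2);
  }
  std::vector<int> rstate(ractive.begin(), ractive.end());
  std::vector<int> gstate(gactive.begin(), gactive.end());
  std::vector<double> last_act(nG, -1.0);  // absolute time of last active encounter

  std::vector<double> p_act(nR);
  for (int i = 0; i < nR; ++i) p_act[i] = 1.0 - std::exp(-kon * conc[i] * dt);
  const double p_deact = 1.0 - std::exp(-koff * dt);
  const double p_decay = (mode == 1) ? 1.0 - std::exp(-kgi * dt) : 0.0;
  const double sd = std::sqrt(2.0 * DG * dt);

  if (skip_steps < 0) skip_steps = 0;
  const int nsnap =
      (snap_every > 0 && nsteps > skip_steps)
          ? (nsteps - skip_steps) / snap_every
          : 0;
  NumericMatrix snaps(nsnap, 15);
  NumericMatrix ages;
  if (record_ages) ages = NumericMatrix(nsnap, nG);
  int isnap = 0;

  for (int step = 1; step <= nsteps; ++step) {
    const double t = t0 + step * dt;
    // 1. diffuse G proteins
    if (DG > 0.0)
      for (int g = 0; g < nG; ++g) tangent_step(gx[g], gy[g], gz[g], L, sd, rng);
    // 2. receptor telegraph switching
    for (int i = 0; i < nR; ++i) {
      if (rstate[i]) {
        if (rng.unif() < p_deact) rstate[i] = 0;
      } else {
        if (rng.unif() < p_act[i]) rstate[i] = 1;
      }
    }
    // 3.+4. encounters and G-state update
    for (int g = 0; g < nG; ++g) {
      if (mode == 1 && gstate[g] && rng.unif() < p_decay) gstate[g] = 0;
      const int r = idx.nearest(gx[g], gy[g], gz[g]);
      if (r >= 0) {
        if (mode == 0) {
          gstate[g] = rstate[r];
        } else if (rstate[r]) {
          gstate[g] = 1;
        }
        if (rstate[r]) last_act[g] = t;
      }
    }
    // snapshot
    if (snap_every > 0 && step > skip_steps && isnap < nsnap &&
        (step - skip_steps) % snap_every == 0) {
      double vrl[3] = {0, 0, 0}, vr[3] = {0, 0, 0}, vg[3] = {0, 0, 0};
      int nRa = 0, nGa = 0;
      for (int i = 0; i < nR; ++i) {
        if (rstate[i]) {
          vrl[0] += rpos(i, 0); vrl[1] += rpos(i, 1); vrl[2] += rpos(i, 2);
          ++nRa;
        } else {
          vr[0] += rpos(i, 0); vr[1] += rpos(i, 1); vr[2] += rpos(i, 2);
        }
      }
      for (int g = 0; g < nG; ++g) {
        if (gstate[g]) {
          vg[0] += gx[g]; vg[1] += gy[g]; vg[2] += gz[g];
          ++nGa;
        }
      }
      snaps(isnap, 0) = t;
      for (int a = 0; a < 3; ++a) {
        snaps(isnap, 1 + a) = vrl[a];
        snaps(isnap, 4 + a) = vr[a];
        snaps(isnap, 7 + a) = vrl[a] - vr[a];
        snaps(isnap, 10 + a) = vg[a];
      }
      snaps(isnap, 13) = nR > 0 ? (double)nRa / nR : NA_REAL;
      snaps(isnap, 14) = nG > 0 ? (double)nGa / nG : NA_REAL;
      if (record_ages)
        for (int g = 0; g < nG; ++g)
          ages(isnap, g) = last_act[g] < 0 ? -1.0 : t - last_act[g];
      ++isnap;
    }
  }

  NumericMatrix gpos_out(nG, 3);
  for (int g = 0; g < nG; ++g) {
    gpos_out(g, 0) = gx[g];
    gpos_out(g, 1) = gy[g];
    gpos_out(g, 2) = gz[g];
  }
  List out = List::create(
      _["snapshots"] = snaps, _["g_positions"] = gpos_out,
      _["g_active"] = IntegerVector(gstate.begin(), gstate.end()),
      _["receptor_active"] = IntegerVector(rstate.begin(), rstate.end()),
      _["t_end"] = t0 + (double)nsteps * dt);
  if (record_ages) out["ages"] = ages;
  return out;
}

// Nearest receptor within great-circle distance r* for each G protein
// (1-based receptor index, NA if none); ties break to the lowest index.
// [[Rcpp::export]]
IntegerVector find_encounters_cpp(NumericMatrix rpos, NumericMatrix gpos,
                                  double rstar, double L) {
  ReceptorIndex idx(rpos, rstar, L);
  const int nG = gpos.nrow();
  IntegerVector out(nG);
  for (int g = 0; g < nG; ++g) {
    const int r = idx.nearest(gpos(g, 0), gpos(g, 1), gpos(g, 2));
    out[g] = (r >= 0) ? r + 1 : NA_INTEGER;
  }
  return out;
}

// Time of first receptor encounter for each independently diffusing G
// protein (checked every dt), NA if none before tmax. Used to measure the
// diffusive encounter timescale tau_dif.
// [[Rcpp::export]]
NumericVector first_encounter_cpp(NumericMatrix rpos, NumericMatrix gpos,
                                  double DG, double rstar, double L, double dt,
                                  double tmax) {
  Xoshiro256 rng(seed_from_R());
  ReceptorIndex idx(rpos, rstar, L);
  const int nG = gpos.nrow();
  const double sd = std::sqrt(2.0 * DG * dt);
  const int nsteps = (int)std::ceil(tmax / dt);
  NumericVector out(nG, NA_REAL);
  for (int g = 0; g < nG; ++g) {
    double px = gpos(g, 0), py = gpos(g, 1), pz = gpos(g, 2);
    if (idx.nearest(px, py, pz) >= 0) {
      out[g] = 0.0;
      continue;
    }
    for (int step = 1; step <= nsteps; ++step) {
      tangent_step(px, py, pz, L, sd, rng);
      if (idx.nearest(px, py, pz) >= 0) {
        out[g] = step * dt;
        break;
      }
    }
  }
  return out;
}
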