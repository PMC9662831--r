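// Discrete-time (dt) stepper for the hopping-and-relay model.
//
// State arrays live in R lists (so runs can be paused, inspected and
// resumed from R, e.g. around a plasmid replication event); this file only
// advances them.  Per step, in fixed order: cytosolic association, basal
// dissociation, tether breakage, bound-dimer elastic + hopping motion,
// tether formation on contact, plasmid motion under the resultant tether
// spring (tethered dimers translate rigidly), and reflection at the
// nucleoid rectangle boundary.
//
// Elastic moves use the exact over-damped-spring (OU) transition density,
// not an Euler approximation, so dt only enters through the event
// probabilities (rate * dt, enforced << 1 at validation).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ (public-domain algorithm by Blackman & Vigna) with a
// Marsaglia-Tsang ziggurat normal sampler.  R's RNG is not used inside the
// stepper: the generator state is carried in the simulation state itself
// (32 raw bytes), which makes runs bit-reproducible and resumable
// independently of R's global .Random.seed.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    // splitmix64 expansion; guards against the all-zero state
    for (int i = 0; i < 4; i++) s[i] = splitmix64(sd);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {              // uniform on (0,1), 53-bit
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline uint32_t u32() { return (uint32_t)(next() >> 32); }
};

// Ziggurat tables (128 layers), built once.
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

static double zig_nfix(Xoshiro &rng, int32_t hz, uint32_t iz) {
  const double r = 3.442619855899;
  double x, y;
  for (;;) {
    x = hz * zig_wn[iz];
    if (iz == 0) {                    // base strip: sample the tail
      do {
        x = -std::log(rng.unif()) / r;
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -r - x;
    }
    if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    hz = (int32_t)rng.u32();
    iz = hz & 127;
    if ((uint32_t)std::abs(hz) < zig_kn[iz]) return hz * zig_wn[iz];
  }
}

static inline double rnorm_fast(Xoshiro &rng) {
  int32_t hz = (int32_t)rng.u32();
  uint32_t iz = hz & 127;
  return ((uint32_t)std::abs(hz) < zig_kn[iz]) ? hz * zig_wn[iz]
                                               : zig_nfix(rng, hz, iz);
}

// [[Rcpp::export]]
RawVector cpp_rng_state(int seed) {
  Xoshiro rng;
  rng.seed((uint64_t)seed);
  RawVector out(32);
  std::memcpy(RAW(out), rng.s, 32);
  return out;
}

// Moment/sanity access to the internal normal sampler (used by tests only).
// [[Rcpp::export]]
NumericVector cpp_rnorm_stream(RawVector rng_state, int n) {
  if (!zig_ready) zig_init();
  Xoshiro rng;
  std::memcpy(rng.s, RAW(rng_state), 32);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rnorm_fast(rng);
  return out;
}

static inline double reflect(double v, double hi) {
  while (v < 0.0 || v > hi) v = (v < 0.0) ? -v : 2.0 * hi - v;
  return v;
}

// Advance the simulation n_steps.  If record_every > 0, samples are taken
// before the first step and after every record_every-th step
// (n_steps / record_every + 1 samples in total).  Dimer long-axis positions
// of nucleoid-associated dimers are additionally recorded per sample when
// record_dimers is true.
// tether_mode selects how tethered dimers move:
//   0 "hopping": pinned to the plasmid surface (translate rigidly with
//     it), but their home positions keep hopping on the nucleoid --
//     the tether anchor diffuses with Dh while the tether relaxes
//     through plasmid motion.
//   1 "fixed": as 0 but the home position is frozen while tethered.
//   2 "relay": tethered dimers keep fluctuating elastically about a
//     frozen home like any bound dimer; the tether only transmits the
//     spring force to the plasmid (no pinning).
// [[Rcpp::export]]
List cpp_run(List state, List params, double n_steps_d, int record_every,
             bool record_dimers, int tether_mode) {
  if (!zig_ready) zig_init();
  const long long n_steps = (long long)n_steps_d;

  // parameters
  const double ka = as<double>(params["ka"]), kd = as<double>(params["kd"]),
               kh = as<double>(params["kh"]), Dp = as<double>(params["Dp"]),
               Dh = as<double>(params["Dh"]), DA = as<double>(params["DA"]),
               sx = as<double>(params["sigma_x"]),
               sy = as<double>(params["sigma_y"]),
               Rp = as<double>(params["Rp"]), RA = as<double>(params["RA"]),
               L = as<double>(params["L"]), W = as<double>(params["W"]),
               dt = as<double>(params["dt"]);

  // state (copied: the input list is left untouched)
  IntegerVector st = clone(as<IntegerVector>(state["state"]));
  NumericVector x = clone(as<NumericVector>(state["x"]));
  NumericVector y = clone(as<NumericVector>(state["y"]));
  NumericVector hx = clone(as<NumericVector>(state["hx"]));
  NumericVector hy = clone(as<NumericVector>(state["hy"]));
  IntegerVector partner = clone(as<IntegerVector>(state["partner"]));
  NumericVector px = clone(as<NumericVector>(state["px"]));
  NumericVector py = clone(as<NumericVector>(state["py"]));
  NumericVector counters = clone(as<NumericVector>(state["counters"]));
  double time = as<double>(state["time"]);
  Xoshiro rng;
  { RawVector rs = as<RawVector>(state["rng"]); std::memcpy(rng.s, RAW(rs), 32); }

  const int nA = st.size(), np = px.size();

  // per-step constants
  const double pa = ka * dt, pd = kd * dt, ph = kh * dt;
  const double sx2 = sx * sx, sy2 = sy * sy;
  const double ex = std::exp(-dt * DA / sx2), ey = std::exp(-dt * DA / sy2);
  const double sdx = sx * std::sqrt(1.0 - ex * ex),
               sdy = sy * std::sqrt(1.0 - ey * ey);
  const double hop_sd = std::sqrt(2.0 * Dh * dt);
  const double dif_sd = std::sqrt(2.0 * Dp * dt);
  const double R2 = (Rp + RA) * (Rp + RA);
  const double cpx = dt * Dp / sx2, cpy = dt * Dp / sy2; // dt/tau per tether

  // sampling storage
  const long long n_samp =
      record_every > 0 ? n_steps / record_every + 1 : 0;
  NumericMatrix samp_px(record_every > 0 ? n_samp : 0, np);
  IntegerMatrix samp_nt(record_every > 0 ? n_samp : 0, np);
  NumericVector samp_t(record_every > 0 ? n_samp : 0);
  IntegerVector samp_bound(record_every > 0 ? n_samp : 0);
  List samp_dimers(record_dimers && record_every > 0 ? n_samp : 0);

  std::vector<double> sum_fx(np), sum_fy(np);
  std::vector<int> nt(np);

  long long isamp = 0;
  auto take_sample = [&]() {
    samp_t[isamp] = time;
    int bound = 0;
    std::fill(nt.begin(), nt.end(), 0);
    for (int i = 0; i < nA; i++) {
      if (st[i] != 0) bound++;
      if (st[i] == 2) nt[partner[i]]++;
    }
    samp_bound[isamp] = bound;
    for (int j = 0; j < np; j++) {
      samp_px(isamp, j) = px[j];
      samp_nt(isamp, j) = nt[j];
    }
    if (record_dimers) {
      NumericVector dx(bound);
      int k = 0;
      for (int i = 0; i < nA; i++) if (st[i] != 0) dx[k++] = x[i];
      samp_dimers[isamp] = dx;
    }
    isamp++;
  };

  if (record_every > 0) take_sample();

  for (long long s = 1; s <= n_steps; s++) {
    // (1) association, (2) basal dissociation, (3) tether breakage
    for (int i = 0; i < nA; i++) {
      if (st[i] == 0) {
        if (rng.unif() < pa) {
          st[i] = 1;
          x[i] = hx[i] = rng.unif() * L;
          y[i] = hy[i] = rng.unif() * W;
          counters[0] += 1;
        }
      } else if (st[i] == 1) {
        if (rng.unif() < pd) { st[i] = 0; counters[1] += 1; }
      } else {
        if (rng.unif() < ph) { st[i] = 0; partner[i] = -1; counters[2] += 1; }
      }
    }

    // (4) nucleoid-bound dimer motion: elastic relaxation about the home
    // position, then (untethered dimers only) a hopping offset applied to
    // both position and home.  In rigid mode tethered dimers do not move
    // on their own at all.
    for (int i = 0; i < nA; i++) {
      if (st[i] == 0) continue;
      if (st[i] == 2) {
        if (tether_mode == 0 && hop_sd > 0.0) {
          // anchor keeps hopping; the dimer itself stays on the plasmid
          hx[i] = reflect(hx[i] + hop_sd * rnorm_fast(rng), L);
          hy[i] = reflect(hy[i] + hop_sd * rnorm_fast(rng), W);
        }
        if (tether_mode != 2) continue;
        x[i] = hx[i] + (x[i] - hx[i]) * ex + sdx * rnorm_fast(rng);
        y[i] = hy[i] + (y[i] - hy[i]) * ey + sdy * rnorm_fast(rng);
        x[i] = reflect(x[i], L);
        y[i] = reflect(y[i], W);
        continue;
      }
      x[i] = hx[i] + (x[i] - hx[i]) * ex + sdx * rnorm_fast(rng);
      y[i] = hy[i] + (y[i] - hy[i]) * ey + sdy * rnorm_fast(rng);
      if (hop_sd > 0.0) {
        double ox = hop_sd * rnorm_fast(rng), oy = hop_sd * rnorm_fast(rng);
        x[i] += ox; hx[i] += ox;
        y[i] += oy; hy[i] += oy;
        hx[i] = reflect(hx[i], L);
        hy[i] = reflect(hy[i], W);
      }
      x[i] = reflect(x[i], L);
      y[i] = reflect(y[i], W);
    }

    // (5) tether formation on contact
    if (np > 0) {
      for (int i = 0; i < nA; i++) {
        if (st[i] != 1) continue;
        for (int j = 0; j < np; j++) {
          double dx = x[i] - px[j], dy = y[i] - py[j];
          if (dx * dx + dy * dy <= R2) {
            st[i] = 2;
            partner[i] = j;
            break;
          }
        }
      }
    }

    // (6) plasmid motion
    if (np > 0) {
      std::fill(nt.begin(), nt.end(), 0);
      std::fill(sum_fx.begin(), sum_fx.end(), 0.0);
      std::fill(sum_fy.begin(), sum_fy.end(), 0.0);
      for (int i = 0; i < nA; i++) {
        if (st[i] != 2) continue;
        int j = partner[i];
        nt[j]++;
        sum_fx[j] += hx[i] - x[i];
        sum_fy[j] += hy[i] - y[i];
      }
      for (int j = 0; j < np; j++) {
        double npx, npy;
        if (nt[j] == 0) {
          npx = px[j] + dif_sd * rnorm_fast(rng);
          npy = py[j] + dif_sd * rnorm_fast(rng);
        } else {
          // n tethers: spring constant n/sigma^2 towards the equilibrium
          // point displaced by the mean tether extension
          const double n = (double)nt[j];
          const double ax = std::exp(-n * cpx), ay = std::exp(-n * cpy);
          const double vx = (sx2 / n) * (1.0 - ax * ax),
                       vy = (sy2 / n) * (1.0 - ay * ay);
          const double eqx = px[j] + sum_fx[j] / n,
                       eqy = py[j] + sum_fy[j] / n;
          npx = eqx + (px[j] - eqx) * ax + std::sqrt(vx) * rnorm_fast(rng);
          npy = eqy + (py[j] - eqy) * ay + std::sqrt(vy) * rnorm_fast(rng);
        }
        npx = reflect(npx, L);
        npy = reflect(npy, W);
        const double shx = npx - px[j], shy = npy - py[j];
        px[j] = npx; py[j] = npy;
        if (tether_mode != 2 && nt[j] > 0 && (shx != 0.0 || shy != 0.0)) {
          // tethered dimers (bound at the plasmid surface) translate
          // rigidly with it; their home positions are chromosomal loci and
          // stay fixed, so each tether spring relaxes as the plasmid moves
          for (int i = 0; i < nA; i++) {
            if (st[i] == 2 && partner[i] == j) {
              x[i] = reflect(x[i] + shx, L);
              y[i] = reflect(y[i] + shy, W);
            }
          }
        }
      }
    }

    time += dt;
    if (record_every > 0 && s % record_every == 0) take_sample();
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  RawVector rs(32);
  std::memcpy(RAW(rs), rng.s, 32);
  List new_state = List::create(
      _["time"] = time, _["state"] = st, _["x"] = x, _["y"] = y,
      _["hx"] = hx, _["hy"] = hy, _["partner"] = partner, _["px"] = px,
      _["py"] = py, _["counters"] = counters, _["rng"] = rs);

  List out = List::create(_["state"] = new_state);
  if (record_every > 0) {
    out["times"] = samp_t;
    out["pos"] = samp_px;
    out["tethers"] = samp_nt;
    out["bound"] = samp_bound;
    if (record_dimers) out["dimer_x"] = samp_dimers;
  }
  return out;
}
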