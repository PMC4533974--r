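#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Randomness: each exported routine seeds a fast internal xoshiro256++ stream
// from R's RNG (two unif_rand draws), so set.seed() in R fully determines
// every draw while keeping the per-offspring cost of the inner loop small.
// Draw order within a call is fixed: for each parent, for each of its
// offspring, in input order: (1) niche-shift decision (the same uniform,
// rescaled, picks the direction), (2) evolvability-mutation decision,
// (3) perturbation if mutating; then, during capacity enforcement, one draw
// per candidate facing an undecided subset selection, in input order.

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  // seed from R's RNG so the R-level seed governs the stream
  void seed_from_r() {
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t x = (a << 32) ^ b;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
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

  inline double runif() { // uniform on [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

inline int wrap(int v, int n) {
  if (v < 0) return v + n;
  if (v >= n) return v - n;
  return v;
}

// One offspring from one parent; writes into the out arguments.
inline void one_offspring(Xoshiro256 &rng, int px, int py, double pev,
                          int width, int height,
                          double mut_rate, double half_width,
                          int &ox, int &oy, double &oev, bool &shifted) {
  ox = px;
  oy = py;
  double u = rng.runif();
  shifted = u < pev;
  if (shifted) {
    // u | u < pev, rescaled, is again uniform and picks the direction
    int dir = (int)(u / pev * 4.0);
    if (dir > 3) dir = 3;
    switch (dir) {
      case 0: ox = wrap(px - 1, width);  break;
      case 1: ox = wrap(px + 1, width);  break;
      case 2: oy = wrap(py - 1, height); break;
      default: oy = wrap(py + 1, height);
    }
  }
  oev = pev;
  if (rng.runif() < mut_rate) {
    oev += (rng.runif() * 2.0 - 1.0) * half_width;
    if (oev < 0.0) oev = 0.0;
    if (oev > 1.0) oev = 1.0;
  }
}

// Resident-priority capacity rule: residents (offspring staying in the
// parent's niche) are admitted first; immigrants only fill leftover slots.
// Within each class survivors are a uniform random subset (sequential
// sampling). Returns one keep flag per candidate.
std::vector<uint8_t> capacity_flags(Xoshiro256 &rng,
                                    const std::vector<int> &key,
                                    const std::vector<uint8_t> &resident,
                                    int ncell, int capacity) {
  const int n = (int)key.size();
  std::vector<int> nres(ncell, 0), nimm(ncell, 0);
  std::vector<int> touched;
  touched.reserve(256);
  for (int i = 0; i < n; ++i) {
    int k = key[i];
    if (nres[k] == 0 && nimm[k] == 0) touched.push_back(k);
    if (resident[i]) ++nres[k]; else ++nimm[k];
  }
  std::vector<int> need_res(ncell, 0), need_imm(ncell, 0);
  std::vector<int> rem_res(ncell, 0), rem_imm(ncell, 0);
  for (int k : touched) {
    int qr = nres[k] < capacity ? nres[k] : capacity;
    int spare = capacity - qr;
    int qi = nimm[k] < spare ? nimm[k] : spare;
    need_res[k] = qr;
    need_imm[k] = qi;
    rem_res[k] = nres[k];
    rem_imm[k] = nimm[k];
  }
  std::vector<uint8_t> keep(n, 0);
  for (int i = 0; i < n; ++i) {
    int k = key[i];
    int *need = resident[i] ? &need_res[k] : &need_imm[k];
    int *rem = resident[i] ? &rem_res[k] : &rem_imm[k];
    bool take;
    if (*need <= 0) {
      take = false;
    } else if (*need >= *rem) {
      take = true;
    } else {
      take = rng.runif() * (*rem) < *need;
    }
    if (take) {
      keep[i] = 1;
      --(*need);
    }
    --(*rem);
  }
  return keep;
}

} // namespace

// Full run loop with reused buffers. `events` are 1-based generations at
// which an extinction strikes before reproduction; `snap_gens` are 1-based
// generations whose end-of-generation population is returned as a snapshot.
// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector x0, IntegerVector y0, NumericVector ev0,
                        int width, int height, int capacity,
                        int offspring_per_parent,
                        double mut_rate, double half_width,
                        int generations, IntegerVector events, int severity,
                        IntegerVector snap_gens) {
  Xoshiro256 rng;
  rng.seed_from_r();
  const int ncell = width * height;
  const size_t max_pop = (size_t)ncell * capacity;
  const size_t max_off = max_pop * offspring_per_parent;

  // parent and offspring buffers, reused across generations; np tracks the
  // live population size within the fixed-size parent buffers
  std::vector<int> px(max_pop), py(max_pop);
  std::vector<double> pev(max_pop);
  size_t np = x0.size();
  if (np == 0 || np > max_pop) stop("invalid founder population size");
  std::copy(x0.begin(), x0.end(), px.begin());
  std::copy(y0.begin(), y0.end(), py.begin());
  std::copy(ev0.begin(), ev0.end(), pev.begin());
  std::vector<int> ox(max_off), oy(max_off), key(max_off);
  std::vector<double> oev(max_off);
  std::vector<uint8_t> resf(max_off);
  std::vector<int> nres(ncell, 0), nimm(ncell, 0);
  std::vector<int> need_res(ncell, 0), need_imm(ncell, 0);
  std::vector<int> rem_res(ncell, 0), rem_imm(ncell, 0);
  std::vector<uint8_t> seen(ncell, 0);
  std::vector<int> touched;
  touched.reserve(ncell);

  NumericVector avg(generations + 1);
  IntegerVector occ_series(generations + 1), size_series(generations + 1);
  {
    double s = 0.0;
    touched.clear();
    for (size_t i = 0; i < np; ++i) {
      s += pev[i];
      int k = py[i] * width + px[i];
      if (!seen[k]) { seen[k] = 1; touched.push_back(k); }
    }
    avg[0] = s / (double)np;
    occ_series[0] = (int)touched.size();
    size_series[0] = (int)np;
    for (int k : touched) seen[k] = 0;
  }

  std::vector<uint8_t> is_event(generations + 1, 0);
  for (int e : events) if (e >= 1 && e <= generations) is_event[e] = 1;
  std::vector<uint8_t> want_snap(generations + 1, 0);
  for (int g : snap_gens) if (g >= 1 && g <= generations) want_snap[g] = 1;

  std::vector<int> ext_gen, ext_before, ext_after;
  List snapshots;
  CharacterVector snap_names;

  for (int g = 1; g <= generations; ++g) {
    if (is_event[g]) {
      // occupied niches in first-encounter order
      touched.clear();
      for (size_t i = 0; i < np; ++i) {
        int k = py[i] * width + px[i];
        if (!seen[k]) { seen[k] = 1; touched.push_back(k); }
      }
      int nocc = (int)touched.size();
      ext_gen.push_back(g);
      ext_before.push_back(nocc);
      if (nocc > severity) {
        // partial Fisher-Yates: spare `severity` occupied niches uniformly
        for (int j = 0; j < severity; ++j) {
          int pick = j + (int)(rng.runif() * (nocc - j));
          if (pick > nocc - 1) pick = nocc - 1;
          std::swap(touched[j], touched[pick]);
        }
        std::vector<uint8_t> spared(ncell, 0);
        for (int j = 0; j < severity; ++j) spared[touched[j]] = 1;
        size_t w = 0;
        for (size_t i = 0; i < np; ++i) {
          int k = py[i] * width + px[i];
          seen[k] = 0;
          if (spared[k]) {
            px[w] = px[i]; py[w] = py[i]; pev[w] = pev[i];
            ++w;
          }
        }
        np = w;
        ext_after.push_back(severity);
      } else {
        for (int k : touched) seen[k] = 0;
        ext_after.push_back(nocc);
      }
    }

    // reproduction
    if (np == 0) stop("population went extinct");
    const size_t n = np * offspring_per_parent;
    size_t idx = 0;
    touched.clear();
    for (size_t i = 0; i < np; ++i) {
      const int cpx = px[i], cpy = py[i];
      const double cpev = pev[i];
      for (int j = 0; j < offspring_per_parent; ++j, ++idx) {
        int cx, cy;
        double cev;
        bool shifted;
        one_offspring(rng, cpx, cpy, cpev, width, height, mut_rate, half_width,
                      cx, cy, cev, shifted);
        ox[idx] = cx;
        oy[idx] = cy;
        oev[idx] = cev;
        resf[idx] = shifted ? 0 : 1;
        int k = cy * width + cx;
        key[idx] = k;
        if (nres[k] == 0 && nimm[k] == 0) touched.push_back(k);
        if (shifted) ++nimm[k]; else ++nres[k];
      }
    }
    for (int k : touched) {
      int qr = nres[k] < capacity ? nres[k] : capacity;
      int spare = capacity - qr;
      int qi = nimm[k] < spare ? nimm[k] : spare;
      need_res[k] = qr;
      need_imm[k] = qi;
      rem_res[k] = nres[k];
      rem_imm[k] = nimm[k];
    }
    size_t w = 0;
    double s = 0.0;
    for (size_t i = 0; i < n; ++i) {
      int k = key[i];
      int *need = resf[i] ? &need_res[k] : &need_imm[k];
      bool take;
      if (*need <= 0) {
        take = false;
      } else {
        int *rem = resf[i] ? &rem_res[k] : &rem_imm[k];
        if (*need >= *rem) {
          take = true;
        } else {
          take = rng.runif() * (*rem) < *need;
        }
        if (take) --(*need);
        --(*rem);
      }
      if (take) {
        px[w] = ox[i]; py[w] = oy[i]; pev[w] = oev[i];
        s += oev[i];
        ++w;
      }
    }
    np = w;
    for (int k : touched) { nres[k] = 0; nimm[k] = 0; }
    avg[g] = s / (double)w;
    occ_series[g] = (int)touched.size();
    size_series[g] = (int)w;

    if (want_snap[g]) {
      snapshots.push_back(List::create(
        _["niche_x"] = IntegerVector(px.begin(), px.begin() + np),
        _["niche_y"] = IntegerVector(py.begin(), py.begin() + np),
        _["evolvability"] = NumericVector(pev.begin(), pev.begin() + np)));
      snap_names.push_back(std::to_string(g));
    }
  }
  if (snapshots.size() > 0) snapshots.names() = snap_names;

  return List::create(
    _["avg_evolvability"] = avg,
    _["occupied_niches"] = occ_series,
    _["population_size"] = size_series,
    _["ext_generation"] = IntegerVector(ext_gen.begin(), ext_gen.end()),
    _["ext_before"] = IntegerVector(ext_before.begin(), ext_before.end()),
    _["ext_after"] = IntegerVector(ext_after.begin(), ext_after.end()),
    _["snapshots"] = snapshots,
    _["final_x"] = IntegerVector(px.begin(), px.begin() + np),
    _["final_y"] = IntegerVector(py.begin(), py.begin() + np),
    _["final_ev"] = NumericVector(pev.begin(), pev.begin() + np));
}

// [[Rcpp::export]]
List cpp_make_offspring(IntegerVector x, IntegerVector y, NumericVector ev,
                        int width, int height,
                        double mut_rate, double half_width) {
  Xoshiro256 rng;
  rng.seed_from_r();
  const int n = x.size();
  IntegerVector ox(n), oy(n);
  NumericVector oev(n);
  LogicalVector resident(n);
  for (int i = 0; i < n; ++i) {
    int cx, cy;
    double cev;
    bool shifted;
    one_offspring(rng, x[i], y[i], ev[i], width, height, mut_rate, half_width,
                  cx, cy, cev, shifted);
    ox[i] = cx;
    oy[i] = cy;
    oev[i] = cev;
    resident[i] = !shifted;
  }
  return List::create(_["niche_x"] = ox, _["niche_y"] = oy,
                      _["evolvability"] = oev, _["resident"] = resident);
}

// [[Rcpp::export]]
LogicalVector cpp_enforce_capacity(IntegerVector x, IntegerVector y,
                                   LogicalVector resident,
                                   int width, int height, int capacity) {
  Xoshiro256 rng;
  rng.seed_from_r();
  const int n = x.size();
  std::vector<int> key(n);
  std::vector<uint8_t> res(n);
  for (int i = 0; i < n; ++i) {
    key[i] = y[i] * width + x[i];
    res[i] = resident[i] ? 1 : 0;
  }
  std::vector<uint8_t> keep = capacity_flags(rng, key, res, width * height, capacity);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = keep[i] != 0;
  return out;
}

// [[Rcpp::export]]
List cpp_step_generation(IntegerVector x, IntegerVector y, NumericVector ev,
                         int width, int height, int capacity,
                         int offspring_per_parent,
                         double mut_rate, double half_width) {
  // separate streams for reproduction and capacity enforcement, seeded in
  // that order, so a step decomposes exactly into make_offspring followed by
  // enforce_capacity under the same R seed
  Xoshiro256 rng;
  rng.seed_from_r();
  const int np = x.size();
  const int n = np * offspring_per_parent;
  std::vector<int> ox(n), oy(n), key(n);
  std::vector<double> oev(n);
  std::vector<uint8_t> res(n);
  int idx = 0;
  for (int i = 0; i < np; ++i) {
    const int px = x[i], py = y[i];
    const double pev = ev[i];
    for (int j = 0; j < offspring_per_parent; ++j, ++idx) {
      int cx, cy;
      double cev;
      bool shifted;
      one_offspring(rng, px, py, pev, width, height, mut_rate, half_width,
                    cx, cy, cev, shifted);
      ox[idx] = cx;
      oy[idx] = cy;
      oev[idx] = cev;
      res[idx] = shifted ? 0 : 1;
      key[idx] = cy * width + cx;
    }
  }
  Xoshiro256 rng2;
  rng2.seed_from_r();
  std::vector<uint8_t> keep = capacity_flags(rng2, key, res, width * height, capacity);
  int nkeep = 0;
  for (int i = 0; i < n; ++i) nkeep += keep[i];
  IntegerVector sx(nkeep), sy(nkeep);
  NumericVector sev(nkeep);
  std::vector<uint8_t> seen(width * height, 0);
  int occ = 0;
  idx = 0;
  for (int i = 0; i < n; ++i) {
    if (!keep[i]) continue;
    sx[idx] = ox[i];
    sy[idx] = oy[i];
    sev[idx] = oev[i];
    if (!seen[key[i]]) {
      seen[key[i]] = 1;
      ++occ;
    }
    ++idx;
  }
  return List::create(_["niche_x"] = sx, _["niche_y"] = sy,
                      _["evolvability"] = sev, _["occupied"] = occ);
}
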