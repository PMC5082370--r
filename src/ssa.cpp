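#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Counter-based seeding: every cell of an ensemble gets its own RNG stream
// derived from (master seed, cell index), so ensembles are order-independent.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD2B74407B1CE6E93ULL + 0x8D51E4BD9AE26AB1ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0, safe for log()
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Rate-law kinds (kept in sync with the R-side constants in network.R):
// 0 = mass action; 1 = Hill activation by species `reg`;
// 2 = Hill repression by species `reg`.  Hill kinds multiply the
// mass-action factor of the reactants (usually a 0/1 gene state).

// sparse, preprocessed reaction system for the hot loop
struct SparseSystem {
  int nr, ns;
  std::vector<std::vector<std::pair<int, int>>> react;   // (species, stoich)
  std::vector<std::vector<std::pair<int, int>>> delta;   // (species, net change)
  std::vector<int> kind, reg;
  std::vector<double> rate, Khalf, hcoef, Kh;            // Kh = K^h cached
  std::vector<bool> int_h;
  SparseSystem(const IntegerMatrix &nu_react, const IntegerMatrix &nu_prod,
               const IntegerVector &kind_, const NumericVector &rate_,
               const IntegerVector &reg_, const NumericVector &Khalf_,
               const NumericVector &hcoef_) {
    nr = nu_react.nrow();
    ns = nu_react.ncol();
    react.resize(nr);
    delta.resize(nr);
    for (int j = 0; j < nr; ++j) {
      for (int s = 0; s < ns; ++s) {
        if (nu_react(j, s) > 0) react[j].push_back({s, nu_react(j, s)});
        int d = nu_prod(j, s) - nu_react(j, s);
        if (d != 0) delta[j].push_back({s, d});
      }
      kind.push_back(kind_[j]);
      reg.push_back(reg_[j]);
      rate.push_back(rate_[j]);
      Khalf.push_back(Khalf_[j]);
      hcoef.push_back(hcoef_[j]);
      Kh.push_back(std::pow(Khalf_[j], hcoef_[j]));
      int_h.push_back(hcoef_[j] == std::floor(hcoef_[j]) && hcoef_[j] <= 32);
    }
  }
  inline double xpow(double x, int j) const {
    if (!int_h[j]) return std::pow(x, hcoef[j]);
    double r = 1.0, b = x;
    int e = (int)hcoef[j];
    while (e) { if (e & 1) r *= b; b *= b; e >>= 1; }
    return r;
  }
  inline double propensity(int j, const std::vector<double> &x) const {
    double a = rate[j];
    for (const auto &p : x_react(j)) {
      // falling-factorial combinatorics for identical reactant copies
      double f = 1.0;
      for (int q = 0; q < p.second; ++q) f *= (x[p.first] - q) / (double)(q + 1);
      a *= (f > 0.0) ? f : 0.0;
    }
    if (kind[j] != 0) {
      double num = xpow(x[reg[j]], j);
      double den = Kh[j] + num;
      double hill = (den > 0.0) ? ((kind[j] == 1) ? num / den : Kh[j] / den)
                                : ((kind[j] == 1) ? 0.0 : 1.0);
      a *= hill;
    }
    return a;
  }
  inline const std::vector<std::pair<int, int>> &x_react(int j) const {
    return react[j];
  }
};

static void ssa_one(const SparseSystem &sys, const IntegerVector &x0,
                    double t_end, double frame_dt,
                    uint64_t seed, uint64_t stream,
                    int *out, int n_frames, int out_stride) {
  const int nr = sys.nr;
  const int ns = sys.ns;
  std::vector<double> x(ns);
  for (int s = 0; s < ns; ++s) x[s] = (double)x0[s];
  std::vector<double> a(nr);

  Xoshiro256 rng(seed, stream);
  double t = 0.0;
  int frame = 0;
  // state at t = 0 is frame 0
  for (int s = 0; s < ns; ++s) out[frame + s * out_stride] = (int)x[s];
  ++frame;

  while (frame < n_frames) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = sys.propensity(j, x);
      if (a[j] < 0.0) stop("negative propensity for reaction %d at t = %g", j + 1, t);
      a0 += a[j];
    }
    double t_next;
    int jfire = -1;
    if (a0 <= 0.0) {
      t_next = t_end + frame_dt;  // frozen state to the end
    } else {
      t_next = t - std::log(rng.unif()) / a0;
      double u = rng.unif() * a0, c = 0.0;
      for (int j = 0; j < nr; ++j) {
        c += a[j];
        if (u <= c) { jfire = j; break; }
      }
      if (jfire < 0) jfire = nr - 1;
    }
    // record the state immediately preceding each crossed frame boundary
    while (frame < n_frames && frame * frame_dt <= t_next) {
      for (int s = 0; s < ns; ++s) out[frame + s * out_stride] = (int)x[s];
      ++frame;
    }
    if (a0 <= 0.0) break;
    t = t_next;
    if (t > t_end && frame >= n_frames) break;
    for (const auto &p : sys.delta[jfire]) x[p.first] += p.second;
  }
}

// [[Rcpp::export(name = ".ssa_run_cpp")]]
IntegerMatrix ssa_run_cpp(IntegerMatrix nu_react, IntegerMatrix nu_prod,
                          IntegerVector kind, NumericVector rate,
                          IntegerVector reg, NumericVector Khalf,
                          NumericVector hcoef, IntegerVector x0,
                          double t_end, double frame_dt,
                          double seed, double stream) {
  const int ns = nu_react.ncol();
  const int n_frames = (int)std::floor(t_end / frame_dt + 1e-9) + 1;
  IntegerMatrix out(n_frames, ns);  // frames x species
  SparseSystem sys(nu_react, nu_prod, kind, rate, reg, Khalf, hcoef);
  ssa_one(sys, x0, t_end, frame_dt, (uint64_t)seed, (uint64_t)stream,
          &out(0, 0), n_frames, n_frames);
  return out;
}

// Ensemble run; if obs >= 0 (0-based species index) returns a cells x frames
// matrix of that species only, otherwise a list of frames x species matrices.
// [[Rcpp::export(name = ".ssa_ensemble_cpp")]]
SEXP ssa_ensemble_cpp(IntegerMatrix nu_react, IntegerMatrix nu_prod,
                      IntegerVector kind, NumericVector rate,
                      IntegerVector reg, NumericVector Khalf,
                      NumericVector hcoef, IntegerVector x0,
                      int n_cells, double t_end, double frame_dt,
                      double seed, int obs) {
  const int ns = nu_react.ncol();
  const int n_frames = (int)std::floor(t_end / frame_dt + 1e-9) + 1;
  SparseSystem sys(nu_react, nu_prod, kind, rate, reg, Khalf, hcoef);
  if (obs >= 0) {
    IntegerMatrix res(n_cells, n_frames);
    std::vector<int> buf((size_t)n_frames * ns);
    for (int i = 0; i < n_cells; ++i) {
      ssa_one(sys, x0, t_end, frame_dt, (uint64_t)seed, (uint64_t)(i + 1),
              buf.data(), n_frames, n_frames);
      for (int tix = 0; tix < n_frames; ++tix)
        res(i, tix) = buf[tix + (size_t)obs * n_frames];
      if ((i & 63) == 0) Rcpp::checkUserInterrupt();
    }
    return res;
  }
  List res(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    IntegerMatrix m(n_frames, ns);
    ssa_one(sys, x0, t_end, frame_dt, (uint64_t)seed, (uint64_t)(i + 1),
            &m(0, 0), n_frames, n_frames);
    res[i] = m;
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}
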