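#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-seeded xoshiro256++ streams.
//
// Every simulator draws from named streams identified by (seed, stream_id):
// the same pair always reproduces the same variate sequence, independently of
// any other stream. This is what makes the common-reaction-path and coupled
// finite-difference constructions exact stream-sharing schemes: the per-
// reaction (or per-channel) unit-rate Poisson processes are realized as
// cumulative sums of Exp(1) increments drawn from their own stream.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RngStream {
  uint64_t s[4];
  RngStream(uint64_t seed, uint64_t stream_id) {
    uint64_t x = seed ^ (stream_id * 0xD2B74407B1CE6E93ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1), never exactly 0 or 1
  inline double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  inline double expo() { return -std::log(unif()); }
  inline double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// ---------------------------------------------------------------------------
// Reaction network: propensities and analytic derivatives.
// kind codes: 0 zeroth, 1 first, 2 second_hetero, 3 second_homo,
//             4 rational_repression  a = p / (1 + x_reg^q)
// rate index -1 means a fixed unit coefficient (reaction carries no slot).
// ---------------------------------------------------------------------------

struct Net {
  int N, M, P;
  std::vector<int> nu;      // N x M, column-major
  std::vector<int> kind, r1, r2, ratep, expp, reg;
  std::vector<double> par;

  Net(IntegerMatrix nu_, IntegerVector kind_, IntegerVector r1_, IntegerVector r2_,
      IntegerVector ratep_, IntegerVector expp_, IntegerVector reg_, NumericVector par_) {
    N = nu_.nrow(); M = nu_.ncol(); P = par_.size();
    nu.assign(nu_.begin(), nu_.end());
    kind.assign(kind_.begin(), kind_.end());
    r1.assign(r1_.begin(), r1_.end());
    r2.assign(r2_.begin(), r2_.end());
    ratep.assign(ratep_.begin(), ratep_.end());
    expp.assign(expp_.begin(), expp_.end());
    reg.assign(reg_.begin(), reg_.end());
    par.assign(par_.begin(), par_.end());
  }

  inline double rate(int j, const std::vector<double> &p) const {
    return ratep[j] >= 0 ? p[ratep[j]] : 1.0;
  }

  // x^q with the boundary conventions x^q -> 0 as x -> 0+ (q > 0), 0^0 = 1
  static inline double powq(double x, double q) {
    if (x <= 0.0) return q == 0.0 ? 1.0 : 0.0;
    return std::pow(x, q);
  }

  inline double prop(const double *x, int j, const std::vector<double> &p) const {
    const double c = rate(j, p);
    switch (kind[j]) {
      case 0: return c;
      case 1: return c * x[r1[j]];
      case 2: return c * x[r1[j]] * x[r2[j]];
      case 3: return 0.5 * c * x[r1[j]] * (x[r1[j]] - 1.0);
      case 4: return c / (1.0 + powq(x[reg[j]], p[expp[j]]));
    }
    return 0.0;
  }

  // row j of da/dx into dadx (length N) and da/dc into dadc (length P)
  inline void derivs(const double *x, int j, const std::vector<double> &p,
                     double *dadx, double *dadc) const {
    for (int i = 0; i < N; ++i) dadx[i] = 0.0;
    for (int k = 0; k < P; ++k) dadc[k] = 0.0;
    const double c = rate(j, p);
    switch (kind[j]) {
      case 0:
        if (ratep[j] >= 0) dadc[ratep[j]] = 1.0;
        break;
      case 1:
        dadx[r1[j]] = c;
        if (ratep[j] >= 0) dadc[ratep[j]] = x[r1[j]];
        break;
      case 2:
        dadx[r1[j]] = c * x[r2[j]];
        dadx[r2[j]] = c * x[r1[j]];
        if (ratep[j] >= 0) dadc[ratep[j]] = x[r1[j]] * x[r2[j]];
        break;
      case 3:
        dadx[r1[j]] = 0.5 * c * (2.0 * x[r1[j]] - 1.0);
        if (ratep[j] >= 0) dadc[ratep[j]] = 0.5 * x[r1[j]] * (x[r1[j]] - 1.0);
        break;
      case 4: {
        const double q = p[expp[j]], xv = x[reg[j]];
        const double xq = powq(xv, q), den = (1.0 + xq) * (1.0 + xq);
        // all three limits vanish as x -> 0+ (q > 0)
        dadx[reg[j]] = (xv <= 0.0) ? 0.0 : -c * q * std::pow(xv, q - 1.0) / den;
        if (ratep[j] >= 0) dadc[ratep[j]] = 1.0 / (1.0 + xq);
        dadc[expp[j]] = (xv <= 0.0) ? 0.0 : -c * xq * std::log(xv) / den;
        break;
      }
    }
  }
};

static Net make_net(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                    IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                    IntegerVector reg, NumericVector par) {
  return Net(nu, kind, r1, r2, ratep, expp, reg, par);
}

static inline void check_finite(double a0, double t, const std::vector<double> &x) {
  if (!std::isfinite(a0)) {
    std::string msg = "propensity overflow/NaN at t=" + std::to_string(t) + ", state=(";
    for (size_t i = 0; i < x.size(); ++i)
      msg += std::to_string(x[i]) + (i + 1 < x.size() ? "," : ")");
    stop(msg);
  }
}

// ---------------------------------------------------------------------------
// Gillespie SSA. One uniform stream per path; eta1 (waiting time) then eta2
// (reaction index) are consumed per event. The state reported at grid point
// t_l reflects every event with event time <= t_l; when the total propensity
// vanishes the state is absorbing.
// ---------------------------------------------------------------------------

static long ssa_run(const Net &net, const std::vector<double> &p,
                    const std::vector<double> &x0, const NumericVector &grid,
                    RngStream &rng, double max_events, int *out /* L x N */) {
  const int N = net.N, M = net.M, L = grid.size();
  std::vector<double> x(x0), a(M);
  double t = grid[0];
  int l = 0;
  long nev = 0;
  while (l < L) {
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = net.prop(x.data(), j, p); a0 += a[j]; }
    check_finite(a0, t, x);
    double tnext = (a0 <= 0.0) ? std::numeric_limits<double>::infinity()
                               : t - std::log(rng.unif()) / a0;
    while (l < L && grid[l] < tnext) {
      for (int i = 0; i < N; ++i) out[l + (size_t)L * i] = (int)x[i];
      ++l;
    }
    if (l >= L) break;
    t = tnext;
    const double u2 = rng.unif() * a0;
    int j = 0; double cum = a[0];
    while (cum <= u2 && j < M - 1) { ++j; cum += a[j]; }
    for (int i = 0; i < N; ++i) x[i] += net.nu[i + (size_t)N * j];
    if (++nev > (long)max_events) stop("event cap exceeded at t=" + std::to_string(t));
  }
  return nev;
}

// [[Rcpp::export(name = ".cpp_ssa")]]
List cpp_ssa(IntegerMatrix nu, IntegerVector kind, IntegerVector r1, IntegerVector r2,
             IntegerVector ratep, IntegerVector expp, IntegerVector reg,
             NumericVector par, NumericVector x0, NumericVector grid,
             double seed, double stream, double max_events) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  RngStream rng((uint64_t)seed, (uint64_t)stream);
  IntegerMatrix out(grid.size(), net.N);
  std::vector<double> x0v(x0.begin(), x0.end());
  long nev = ssa_run(net, net.par, x0v, grid, rng, max_events, out.begin());
  return List::create(_["states"] = out, _["n_events"] = (double)nev);
}

// ---------------------------------------------------------------------------
// Random time change / modified next reaction method. One Exp(1) stream per
// reaction; reaction j fires when its internal clock T_j = int a_j ds reaches
// the next level of its unit-rate Poisson process.
// ---------------------------------------------------------------------------

static long rtc_run(const Net &net, const std::vector<double> &p,
                    const std::vector<double> &x0, const NumericVector &grid,
                    std::vector<RngStream> &streams, double max_events, int *out) {
  const int N = net.N, M = net.M, L = grid.size();
  std::vector<double> x(x0), a(M), Tj(M, 0.0), Pj(M);
  for (int j = 0; j < M; ++j) Pj[j] = streams[j].expo();
  double t = grid[0];
  int l = 0;
  long nev = 0;
  while (l < L) {
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = net.prop(x.data(), j, p); a0 += a[j]; }
    check_finite(a0, t, x);
    double dmin = std::numeric_limits<double>::infinity();
    int mu = -1;
    for (int j = 0; j < M; ++j) {
      if (a[j] > 0.0) {
        double d = (Pj[j] - Tj[j]) / a[j];
        if (d < dmin) { dmin = d; mu = j; }
      }
    }
    double tnext = (mu < 0) ? std::numeric_limits<double>::infinity() : t + dmin;
    while (l < L && grid[l] < tnext) {
      for (int i = 0; i < N; ++i) out[l + (size_t)L * i] = (int)x[i];
      ++l;
    }
    if (l >= L) break;
    for (int j = 0; j < M; ++j) Tj[j] += a[j] * dmin;
    Pj[mu] += streams[mu].expo();
    for (int i = 0; i < N; ++i) x[i] += net.nu[i + (size_t)N * mu];
    t = tnext;
    if (++nev > (long)max_events) stop("event cap exceeded at t=" + std::to_string(t));
  }
  return nev;
}

// [[Rcpp::export(name = ".cpp_rtc")]]
List cpp_rtc(IntegerMatrix nu, IntegerVector kind, IntegerVector r1, IntegerVector r2,
             IntegerVector ratep, IntegerVector expp, IntegerVector reg,
             NumericVector par, NumericVector x0, NumericVector grid,
             double seed, double stream_base, double max_events) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  std::vector<RngStream> streams;
  for (int j = 0; j < net.M; ++j)
    streams.emplace_back((uint64_t)seed, (uint64_t)stream_base + j);
  IntegerMatrix out(grid.size(), net.N);
  std::vector<double> x0v(x0.begin(), x0.end());
  long nev = rtc_run(net, net.par, x0v, grid, streams, max_events, out.begin());
  return List::create(_["states"] = out, _["n_events"] = (double)nev);
}

// ---------------------------------------------------------------------------
// Coupled pair ensembles for finite-difference sensitivity estimation.
// Pair r of ensemble (seed, param k): perturbed path uses c with slot k set
// to c_k + theta. Accumulates sums of Z = (X' - X)/theta and of the
// unperturbed path; optionally keeps the sampled paths.
// ---------------------------------------------------------------------------

struct EnsembleAcc {
  int L, N, R;
  bool keep;
  std::vector<double> sumZ, sumZ2, sumX, sumX2;
  IntegerVector pathsU, pathsP; // L x N x R when kept
  EnsembleAcc(int L_, int N_, int R_, bool keep_) : L(L_), N(N_), R(R_), keep(keep_),
      sumZ((size_t)L_ * N_, 0.0), sumZ2((size_t)L_ * N_, 0.0),
      sumX((size_t)L_ * N_, 0.0), sumX2((size_t)L_ * N_, 0.0) {
    if (keep) {
      pathsU = IntegerVector((size_t)L_ * N_ * R_);
      pathsP = IntegerVector((size_t)L_ * N_ * R_);
    }
  }
  void add(int r, const int *xu, const int *xp, double theta) {
    const size_t LN = (size_t)L * N;
    for (size_t i = 0; i < LN; ++i) {
      const double z = (xp[i] - xu[i]) / theta;
      sumZ[i] += z; sumZ2[i] += z * z;
      sumX[i] += xu[i]; sumX2[i] += (double)xu[i] * xu[i];
      if (keep) { pathsU[i + LN * r] = xu[i]; pathsP[i + LN * r] = xp[i]; }
    }
  }
  List result(double nev) const {
    List out = List::create(
      _["sumZ"] = NumericVector(sumZ.begin(), sumZ.end()),
      _["sumZ2"] = NumericVector(sumZ2.begin(), sumZ2.end()),
      _["sumX"] = NumericVector(sumX.begin(), sumX.end()),
      _["sumX2"] = NumericVector(sumX2.begin(), sumX2.end()),
      _["n_events"] = nev);
    if (keep) { out["paths_unperturbed"] = pathsU; out["paths_perturbed"] = pathsP; }
    return out;
  }
};

// CRN: both paths are plain SSA runs consuming the *same* uniform stream
// (each path its own cursor over an identical sequence).
// [[Rcpp::export(name = ".cpp_crn_ensemble")]]
List cpp_crn_ensemble(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                      IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                      IntegerVector reg, NumericVector par, NumericVector x0,
                      NumericVector grid, int k, double theta, int R,
                      double seed, double max_events, bool keep_paths) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  std::vector<double> pu(net.par), pp(net.par);
  pp[k] += theta;
  const int L = grid.size(), N = net.N;
  std::vector<double> x0v(x0.begin(), x0.end());
  std::vector<int> xu((size_t)L * N), xp((size_t)L * N);
  EnsembleAcc acc(L, N, R, keep_paths);
  double nev = 0.0;
  for (int r = 0; r < R; ++r) {
    RngStream sU((uint64_t)seed, (uint64_t)(r + 1) * 4096ULL);
    RngStream sP((uint64_t)seed, (uint64_t)(r + 1) * 4096ULL); // identical sequence
    nev += ssa_run(net, pu, x0v, grid, sU, max_events, xu.data());
    nev += ssa_run(net, pp, x0v, grid, sP, max_events, xp.data());
    acc.add(r, xu.data(), xp.data(), theta);
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return acc.result(nev);
}

// CRP: both paths are RTC runs sharing the M per-reaction Exp(1) streams.
// [[Rcpp::export(name = ".cpp_crp_ensemble")]]
List cpp_crp_ensemble(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                      IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                      IntegerVector reg, NumericVector par, NumericVector x0,
                      NumericVector grid, int k, double theta, int R,
                      double seed, double max_events, bool keep_paths) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  std::vector<double> pu(net.par), pp(net.par);
  pp[k] += theta;
  const int L = grid.size(), N = net.N, M = net.M;
  std::vector<double> x0v(x0.begin(), x0.end());
  std::vector<int> xu((size_t)L * N), xp((size_t)L * N);
  EnsembleAcc acc(L, N, R, keep_paths);
  double nev = 0.0;
  for (int r = 0; r < R; ++r) {
    const uint64_t base = (uint64_t)(r + 1) * 4096ULL;
    std::vector<RngStream> sU, sP;
    for (int j = 0; j < M; ++j) {
      sU.emplace_back((uint64_t)seed, base + j);
      sP.emplace_back((uint64_t)seed, base + j); // same streams, own cursors
    }
    nev += rtc_run(net, pu, x0v, grid, sU, max_events, xu.data());
    nev += rtc_run(net, pp, x0v, grid, sP, max_events, xp.data());
    acc.add(r, xu.data(), xp.data(), theta);
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return acc.result(nev);
}

// CFD: one joint jump process on (X, X') with 3 channels per reaction:
// channel (j,1), rate min(a_j, a_j'), fires both paths; channel (j,2), rate
// a_j - min, fires only X; channel (j,3), rate a_j' - min, fires only X'.
// Simulated by the next reaction method with one Exp(1) stream per channel;
// all 3M channel rates are recomputed after every firing.
static long cfd_pair_run(const Net &net, const std::vector<double> &pu,
                         const std::vector<double> &pp, const std::vector<double> &x0,
                         const NumericVector &grid, std::vector<RngStream> &streams,
                         double max_events, int *outU, int *outP) {
  const int N = net.N, M = net.M, L = grid.size(), C = 3 * M;
  std::vector<double> xu(x0), xp(x0), b(C), Tj(C, 0.0), Pj(C);
  for (int c = 0; c < C; ++c) Pj[c] = streams[c].expo();
  double t = grid[0];
  int l = 0;
  long nev = 0;
  while (l < L) {
    double b0 = 0.0;
    for (int j = 0; j < M; ++j) {
      const double au = net.prop(xu.data(), j, pu);
      const double ap = net.prop(xp.data(), j, pp);
      const double m = std::min(au, ap);
      b[3 * j] = m; b[3 * j + 1] = au - m; b[3 * j + 2] = ap - m;
      b0 += au + ap - m;
    }
    check_finite(b0, t, xu);
    double dmin = std::numeric_limits<double>::infinity();
    int mu = -1;
    for (int c = 0; c < C; ++c) {
      if (b[c] > 0.0) {
        double d = (Pj[c] - Tj[c]) / b[c];
        if (d < dmin) { dmin = d; mu = c; }
      }
    }
    double tnext = (mu < 0) ? std::numeric_limits<double>::infinity() : t + dmin;
    while (l < L && grid[l] < tnext) {
      for (int i = 0; i < N; ++i) {
        outU[l + (size_t)L * i] = (int)xu[i];
        outP[l + (size_t)L * i] = (int)xp[i];
      }
      ++l;
    }
    if (l >= L) break;
    for (int c = 0; c < C; ++c) Tj[c] += b[c] * dmin;
    Pj[mu] += streams[mu].expo();
    const int j = mu / 3, ch = mu % 3;
    for (int i = 0; i < N; ++i) {
      const int d = net.nu[i + (size_t)N * j];
      if (ch != 2) xu[i] += d;
      if (ch != 1) xp[i] += d;
    }
    t = tnext;
    if (++nev > (long)max_events) stop("event cap exceeded at t=" + std::to_string(t));
  }
  return nev;
}

// [[Rcpp::export(name = ".cpp_cfd_ensemble")]]
List cpp_cfd_ensemble(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                      IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                      IntegerVector reg, NumericVector par, NumericVector x0,
                      NumericVector grid, int k, double theta, int R,
                      double seed, double max_events, bool keep_paths) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  std::vector<double> pu(net.par), pp(net.par);
  pp[k] += theta;
  const int L = grid.size(), N = net.N, M = net.M;
  std::vector<double> x0v(x0.begin(), x0.end());
  std::vector<int> xu((size_t)L * N), xp((size_t)L * N);
  EnsembleAcc acc(L, N, R, keep_paths);
  double nev = 0.0;
  for (int r = 0; r < R; ++r) {
    const uint64_t base = (uint64_t)(r + 1) * 4096ULL;
    std::vector<RngStream> streams;
    for (int c = 0; c < 3 * M; ++c) streams.emplace_back((uint64_t)seed, base + c);
    nev += cfd_pair_run(net, pu, pp, x0v, grid, streams, max_events,
                        xu.data(), xp.data());
    acc.add(r, xu.data(), xp.data(), theta);
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return acc.result(nev);
}

// ---------------------------------------------------------------------------
// Chemical Langevin Equation: Euler-Maruyama with diffusion coefficient
// sqrt(max(a_j, 0)); the state is clamped at 0 after each step. One normal
// stream per path.
// ---------------------------------------------------------------------------

static void cle_step(const Net &net, const std::vector<double> &p,
                     std::vector<double> &x, double dt, double sqdt, RngStream &rng,
                     std::vector<double> &dW /* scratch, length M */) {
  const int N = net.N, M = net.M;
  std::vector<double> dx(N, 0.0);
  for (int j = 0; j < M; ++j) {
    double a = net.prop(x.data(), j, p);
    if (a < 0.0) a = 0.0;
    dW[j] = sqdt * rng.norm();
    const double incr = a * dt + std::sqrt(a) * dW[j];
    for (int i = 0; i < N; ++i) dx[i] += net.nu[i + (size_t)N * j] * incr;
  }
  for (int i = 0; i < N; ++i) {
    x[i] += dx[i];
    if (x[i] < 0.0) x[i] = 0.0;
  }
}

// [[Rcpp::export(name = ".cpp_cle")]]
NumericMatrix cpp_cle(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                      IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                      IntegerVector reg, NumericVector par, NumericVector x0,
                      NumericVector grid, double dt, double seed, double stream) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  RngStream rng((uint64_t)seed, (uint64_t)stream);
  const int L = grid.size(), N = net.N;
  NumericMatrix out(L, N);
  std::vector<double> x(x0.begin(), x0.end()), dW(net.M);
  const double sqdt = std::sqrt(dt);
  double t = grid[0];
  int l = 0;
  while (l < L) {
    while (l < L && grid[l] <= t + 1e-12) {
      for (int i = 0; i < N; ++i) out(l, i) = x[i];
      ++l;
    }
    if (l >= L) break;
    cle_step(net, net.par, x, dt, sqdt, rng, dW);
    t += dt;
  }
  return out;
}

// Pathwise sensitivities for the CLE: Euler-Maruyama on the joint system for
// (X, dX/dc). The derivative of the diffusion term uses the coefficient
// (1/(2 sqrt(a_j))) * (da_j/dX . dX/dc + da_j/dc), set to 0 when a_j <= 0.
// Returns accumulated sums over R paths of the state and of the sensitivities.
// [[Rcpp::export(name = ".cpp_cle_pathwise")]]
List cpp_cle_pathwise(IntegerMatrix nu, IntegerVector kind, IntegerVector r1,
                      IntegerVector r2, IntegerVector ratep, IntegerVector expp,
                      IntegerVector reg, NumericVector par, NumericVector x0,
                      NumericVector grid, double dt, int R, double seed) {
  Net net = make_net(nu, kind, r1, r2, ratep, expp, reg, par);
  const int L = grid.size(), N = net.N, M = net.M, P = net.P;
  const size_t LN = (size_t)L * N, LNP = (size_t)L * N * P;
  std::vector<double> sumX(LN, 0.0), sumX2(LN, 0.0), sumS(LNP, 0.0), sumS2(LNP, 0.0);
  std::vector<double> dadx(N), dadc(P);
  const double sqdt = std::sqrt(dt);
  for (int r = 0; r < R; ++r) {
    RngStream rng((uint64_t)seed, (uint64_t)(r + 1));
    std::vector<double> x(x0.begin(), x0.end());
    std::vector<double> S((size_t)N * P, 0.0);       // S[i + N*k]
    std::vector<double> dx(N), dS((size_t)N * P);
    double t = grid[0];
    int l = 0;
    while (l < L) {
      while (l < L && grid[l] <= t + 1e-12) {
        for (int i = 0; i < N; ++i) {
          sumX[l + L * (size_t)i] += x[i];
          sumX2[l + L * (size_t)i] += x[i] * x[i];
        }
        for (int k = 0; k < P; ++k)
          for (int i = 0; i < N; ++i) {
            const double v = S[i + (size_t)N * k];
            sumS[l + L * ((size_t)i + (size_t)N * k)] += v;
            sumS2[l + L * ((size_t)i + (size_t)N * k)] += v * v;
          }
        ++l;
      }
      if (l >= L) break;
      std::fill(dx.begin(), dx.end(), 0.0);
      std::fill(dS.begin(), dS.end(), 0.0);
      for (int j = 0; j < M; ++j) {
        double a = net.prop(x.data(), j, net.par);
        if (a < 0.0) a = 0.0;
        const double dW = sqdt * rng.norm();
        const double incr = a * dt + std::sqrt(a) * dW;
        net.derivs(x.data(), j, net.par, dadx.data(), dadc.data());
        const double diffc = a > 0.0 ? dW / (2.0 * std::sqrt(a)) : 0.0;
        for (int k = 0; k < P; ++k) {
          double g = dadc[k];
          for (int i = 0; i < N; ++i) g += dadx[i] * S[i + (size_t)N * k];
          const double sincr = g * (dt + diffc);
          for (int i = 0; i < N; ++i)
            dS[i + (size_t)N * k] += net.nu[i + (size_t)N * j] * sincr;
        }
        for (int i = 0; i < N; ++i) dx[i] += net.nu[i + (size_t)N * j] * incr;
      }
      for (int i = 0; i < N; ++i) {
        x[i] += dx[i];
        if (x[i] < 0.0) x[i] = 0.0;
      }
      for (size_t q = 0; q < (size_t)N * P; ++q) S[q] += dS[q];
      t += dt;
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["sumX"] = NumericVector(sumX.begin(), sumX.end()),
    _["sumX2"] = NumericVector(sumX2.begin(), sumX2.end()),
    _["sumS"] = NumericVector(sumS.begin(), sumS.end()),
    _["sumS2"] = NumericVector(sumS2.begin(), sumS2.end()));
}
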