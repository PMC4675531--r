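// Fixed-step Euler-Maruyama integrator for the coupled bistable
// stochastic delay system. One call integrates one realization.
//
// State per node: complex z. Update per step:
//   z_i += [f(z_i) + beta * sum_j M(j,i) * (z_j(t - tau_ij) - z_i)] * dt
//          + alpha * (xi1 + i*xi2) * sqrt(dt)
// with f(z) = (lambda_i - 1 + i*omega) z + 2 z |z|^2 - z |z|^4.
//
// Inactive (resected) nodes are frozen at z = 0, never escape, and are
// skipped in the coupling sums. Noise is drawn for every node in fixed
// node order each step, whether active or not, so that a given seed yields
// the same per-node streams under any resection mask.
//
// Noise generator: xoshiro256++ seeded via splitmix64, shaped by
// Box-Muller (exactly two uniforms per normal pair), so realizations are
// bit-reproducible across platforms for a given seed.
//
// Escape: first step at which |z_i| > threshold (active nodes only).
// Integration stops once k_stop distinct active nodes have escaped, or
// after n_steps.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
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
  // uniform in (0, 1]
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // one standard normal pair via Box-Muller
  inline void norm_pair(double& n1, double& n2) {
    const double u1 = unif();
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    n1 = r * std::cos(a);
    n2 = r * std::sin(a);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix M, NumericVector lambda, IntegerMatrix delay_steps,
              LogicalVector active, double beta, double alpha, double omega,
              double dt, int n_steps, int k_stop, double threshold,
              double seed, Nullable<NumericMatrix> noise = R_NilValue,
              Nullable<ComplexVector> z0 = R_NilValue) {
  const int n = lambda.size();
  const double sqdt = std::sqrt(dt);

  // flat CSR adjacency over active-active edges (column i's inputs)
  std::vector<int> row_start(n + 1, 0);
  std::vector<int> e_src; std::vector<double> e_w; std::vector<int> e_d;
  int maxdel = 0;
  for (int i = 0; i < n; ++i) {
    row_start[i] = (int)e_src.size();
    if (active[i]) {
      for (int j = 0; j < n; ++j) {
        if (j == i || !active[j]) continue;
        const double w = M(j, i);
        if (w != 0.0) {
          int d = delay_steps(j, i);
          if (d < 0) stop("negative delay");
          e_src.push_back(j); e_w.push_back(w); e_d.push_back(d);
          if (d > maxdel) maxdel = d;
        }
      }
    }
  }
  row_start[n] = (int)e_src.size();

  const int H = maxdel + 1;               // ring buffer depth
  std::vector<double> hr((size_t)H * n, 0.0), hi((size_t)H * n, 0.0);
  std::vector<double> zr(n, 0.0), zi(n, 0.0);
  std::vector<double> fr(n, 0.0), fi(n, 0.0);
  std::vector<char> act(n);
  std::vector<double> lam(n);
  for (int i = 0; i < n; ++i) { act[i] = active[i] ? 1 : 0; lam[i] = lambda[i]; }

  if (z0.isNotNull()) {
    ComplexVector zz(z0);
    if (zz.size() != n) stop("z0 must have one entry per node");
    for (int i = 0; i < n; ++i) {
      if (act[i]) { zr[i] = zz[i].r; zi[i] = zz[i].i; }
    }
    for (int h = 0; h < H; ++h)
      for (int i = 0; i < n; ++i) {
        hr[(size_t)h * n + i] = zr[i];
        hi[(size_t)h * n + i] = zi[i];
      }
  }

  const bool use_noise = noise.isNotNull();
  NumericMatrix nz;
  if (use_noise) {
    nz = NumericMatrix(noise);
    if (nz.nrow() < n_steps || nz.ncol() != 2 * n)
      stop("noise must be an n_steps x 2n matrix");
  }
  Xoshiro256pp rng((uint64_t)seed);

  std::vector<int> escape_step(n, -1);
  std::vector<size_t> dbase(H);
  int n_escaped = 0;
  // a supplied initial state may already be in the seizure region
  for (int i = 0; i < n; ++i) {
    if (act[i] && zr[i] * zr[i] + zi[i] * zi[i] > threshold * threshold) {
      escape_step[i] = 0;
      ++n_escaped;
    }
  }
  int cur = 0;                            // ring slot holding state at step s
  int step_done = 0;
  const double thr2 = threshold * threshold;
  const double asq = alpha * sqdt;

  for (int step = 1; step <= n_steps && n_escaped < k_stop; ++step) {
    for (int d = 0; d < H; ++d) {
      int slot = cur - d;
      if (slot < 0) slot += H;
      dbase[d] = (size_t)slot * n;
    }
    for (int i = 0; i < n; ++i) {
      double x1, x2;
      if (use_noise) { x1 = nz(step - 1, 2 * i); x2 = nz(step - 1, 2 * i + 1); }
      else rng.norm_pair(x1, x2);
      if (!act[i]) continue;
      const double a2 = zr[i] * zr[i] + zi[i] * zi[i];
      const double g = (lam[i] - 1.0) + a2 * (2.0 - a2);
      double dre = g * zr[i] - omega * zi[i];
      double dim = g * zi[i] + omega * zr[i];
      double cre = 0.0, cim = 0.0, wsum = 0.0;
      const int e0 = row_start[i], e1 = row_start[i + 1];
      for (int e = e0; e < e1; ++e) {
        const size_t off = dbase[e_d[e]] + e_src[e];
        const double w = e_w[e];
        cre += w * hr[off];
        cim += w * hi[off];
        wsum += w;
      }
      cre -= wsum * zr[i];
      cim -= wsum * zi[i];
      fr[i] = zr[i] + (dre + beta * cre) * dt + asq * x1;
      fi[i] = zi[i] + (dim + beta * cim) * dt + asq * x2;
    }
    // commit, record escapes, push history
    cur = (cur + 1) % H;
    const size_t off = (size_t)cur * n;
    for (int i = 0; i < n; ++i) {
      if (act[i]) { zr[i] = fr[i]; zi[i] = fi[i]; }
      hr[off + i] = zr[i];
      hi[off + i] = zi[i];
      if (act[i]) {
        const double a2 = zr[i] * zr[i] + zi[i] * zi[i];
        if (!std::isfinite(a2) || a2 > 1e12)
          stop("state blow-up at step %d, node %d", step, i + 1);
        if (escape_step[i] < 0 && a2 > thr2) {
          escape_step[i] = step;
          ++n_escaped;
        }
      }
    }
    step_done = step;
    if (n_escaped >= k_stop) break;
  }

  IntegerVector esc(n);
  ComplexVector zfin(n);
  for (int i = 0; i < n; ++i) {
    esc[i] = escape_step[i] < 0 ? NA_INTEGER : escape_step[i];
    zfin[i].r = zr[i]; zfin[i].i = zi[i];
  }
  return List::create(_["escape_step"] = esc,
                      _["n_steps_done"] = step_done,
                      _["z_final"] = zfin);
}
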