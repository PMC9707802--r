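// Compiled core: simulation-scale Monte Carlo loop, smoothing, probe-voxel
// eigenscore statistics, and a vectorised Wilks-Lambda map used by the
// permutation machinery. All routines here have pure-R counterparts in R/
// against which they are equivalence-tested; this file exists purely so that
// 10,000-replicate Monte Carlo studies run in minutes rather than hours.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ (Blackman & Vigna, public domain) seeded via splitmix64,
// with Marsaglia-Tsang 128-layer ziggurat for standard normals. The R-level
// test suite checks moments, tail quantiles and a Kolmogorov-Smirnov fit of
// this sampler against N(0,1).
// ---------------------------------------------------------------------------
struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return res;
  }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

struct ZigguratNormal {
  Xoshiro256 rng;
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit ZigguratNormal(uint64_t seed) : rng(seed) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double draw() {
    for (;;) {
      int32_t hz = (int32_t)rng.next32();
      int iz = hz & 127;
      if ((uint32_t)std::abs((long)hz) < kn[iz]) return hz * wn[iz];
      // slow path
      const double r = 3.442619855899;
      for (;;) {
        double x = hz * wn[iz];
        if (iz == 0) {
          double y;
          do {
            x = -std::log(rng.unif()) / r;
            y = -std::log(rng.unif());
          } while (y + y < x * x);
          return (hz > 0) ? r + x : -(r + x);
        }
        if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
            std::exp(-0.5 * x * x))
          return x;
        hz = (int32_t)rng.next32();
        iz = hz & 127;
        if ((uint32_t)std::abs((long)hz) < kn[iz]) return hz * wn[iz];
      }
    }
  }
  inline void fill(double* p, size_t n) {
    for (size_t i = 0; i < n; ++i) p[i] = draw();
  }
};

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ziggurat_normal(int n, double seed) {
  ZigguratNormal z((uint64_t)seed);
  Rcpp::NumericVector out(n);
  z.fill(out.begin(), (size_t)n);
  return out;
}

// ---------------------------------------------------------------------------
// Smoothing along the voxel axis (columns of a time-by-voxel matrix), with
// zero padding at the edges and per-voxel rescaling so that unit-variance
// white noise input keeps exactly unit marginal variance after smoothing.
// ---------------------------------------------------------------------------
static void smooth_in_place(mat& out, const mat& in, const vec& kernel) {
  const int V = in.n_cols, T = in.n_rows;
  const int hw = ((int)kernel.n_elem - 1) / 2;
  // per output column: accumulate over kernel taps while the sliding input
  // window stays in cache (a single pass over the data, which matters at
  // simulation scale), then rescale so unit-variance input stays unit
  for (int v = 0; v < V; ++v) {
    int j0 = std::max(0, v - hw), j1 = std::min(V - 1, v + hw);
    double* o = out.colptr(v);
    double ss = 0;
    {
      double w0 = kernel(j0 - v + hw);
      const double* c = in.colptr(j0);
      for (int t = 0; t < T; ++t) o[t] = w0 * c[t];
      ss = w0 * w0;
    }
    for (int j = j0 + 1; j <= j1; ++j) {
      double w = kernel(j - v + hw);
      const double* c = in.colptr(j);
      for (int t = 0; t < T; ++t) o[t] += w * c[t];
      ss += w * w;
    }
    double inv = 1.0 / std::sqrt(ss);
    for (int t = 0; t < T; ++t) o[t] *= inv;
  }
}

// [[Rcpp::export]]
arma::mat cpp_smooth_voxels(const arma::mat& data, const arma::vec& kernel) {
  if (kernel.n_elem % 2 == 0)
    Rcpp::stop("smoothing kernel must have odd length");
  mat out(data.n_rows, data.n_cols);
  smooth_in_place(out, data, kernel);
  return out;
}

// centre each column and scale to unit Euclidean norm (Pearson prerequisite)
static void normalize_columns(mat& Z) {
  const int V = Z.n_cols, T = Z.n_rows;
  for (int v = 0; v < V; ++v) {
    double* q = Z.colptr(v);
    double mu = 0;
    for (int t = 0; t < T; ++t) mu += q[t];
    mu /= T;
    double ss = 0;
    for (int t = 0; t < T; ++t) { q[t] -= mu; ss += q[t] * q[t]; }
    if (ss > 0) {
      double inv = 1.0 / std::sqrt(ss);
      for (int t = 0; t < T; ++t) q[t] *= inv;
    }
  }
}

// ---------------------------------------------------------------------------
// Wilks-Lambda likelihood-ratio F (Rao's approximation) for a single
// responses matrix Y (subjects x k) given precomputed design quantities.
// ---------------------------------------------------------------------------
struct DesignPre {
  mat G, C, pinvG, Minv;
  double b, c;
  int N;
};

static DesignPre design_precompute(const mat& G, const mat& C) {
  DesignPre d;
  d.G = G;
  d.C = C;
  d.N = G.n_rows;
  d.pinvG = pinv(G);
  double rG = (double)arma::rank(G);
  d.b = d.N - rG;
  d.c = (double)arma::rank(C);
  mat GtGinv = pinv(G.t() * G);
  mat M = C * GtGinv * C.t();
  if (arma::rcond(M) < 1e-12)
    Rcpp::stop("contrast is not estimable under this design");
  d.Minv = inv(M);
  return d;
}

// returns (F, p, lambda); sets p = NA on numerical degeneracy
static void wilks_one(const mat& Y, const DesignPre& d, double& F, double& p,
                      double& lambda) {
  const double a = (double)Y.n_cols;
  if (a >= d.b) Rcpp::stop(
      "number of response dimensions must stay below the error degrees of "
      "freedom: likelihood ratio test assumptions no longer hold");
  mat B = d.pinvG * Y;
  mat E = Y - d.G * B;
  mat W = E.t() * E;
  mat CB = d.C * B;
  mat H = CB.t() * d.Minv * CB;
  double ldW, ldWH, sign1, sign2;
  bool ok1 = log_det(ldW, sign1, W);
  bool ok2 = log_det(ldWH, sign2, W + H);
  if (!ok1 || !ok2 || sign1 <= 0 || sign2 <= 0) {
    F = NA_REAL; p = NA_REAL; lambda = NA_REAL;
    return;
  }
  double loglam = ldW - ldWH;
  if (loglam > 0) loglam = 0;  // numerical guard, lambda <= 1 by construction
  lambda = std::exp(loglam);
  const double c = d.c, b = d.b;
  double num = a * a * c * c - 4.0, den = a * a + c * c - 5.0;
  double e = (num > 0 && den > 0) ? std::sqrt(num / den) : 1.0;
  double df2 = (b - (a - c + 1.0) / 2.0) * e - a * c / 2.0 + 1.0;
  double df1 = a * c;
  double le = std::exp(loglam / e);
  F = df2 / df1 * (1.0 - le) / le;
  if (F < 0) F = 0;
  p = R::pf(F, df1, df2, 0, 0);
}

// ---------------------------------------------------------------------------
// Probe-voxel statistics: given normalised sessions, build the stacked
// connectivity matrix R(x) for each probe voxel, obtain eigenpattern scores
// from the eigendecomposition of R(x) R(x)^t, and evaluate the Wilks-Lambda
// F test of the between-subjects contrast for each requested k.
// ---------------------------------------------------------------------------
static void probe_stats_core(const std::vector<mat>& Z,
                             const std::vector<int>& probes,
                             const std::vector<int>& ks, const DesignPre& d,
                             mat& Fout, mat& Pout, mat& R, mat& K) {
  const int N = (int)Z.size();
  const int nk = (int)ks.size();
  int kmax = 0;
  for (int k : ks) kmax = std::max(kmax, k);
  for (size_t pi = 0; pi < probes.size(); ++pi) {
    const int x = probes[pi];
    for (int n = 0; n < N; ++n)
      R.row(n) = Z[n].col(x).t() * Z[n];
    K = R * R.t();
    vec ev;
    mat evec;
    eig_sym(ev, evec, K);  // ascending
    // scores: leading kmax eigenvectors, descending eigenvalue order
    mat S(N, kmax);
    for (int j = 0; j < kmax; ++j) S.col(j) = evec.col(N - 1 - j);
    for (int j = 0; j < nk; ++j) {
      double F, p, lam;
      wilks_one(S.cols(0, ks[j] - 1), d, F, p, lam);
      Fout(pi, j) = F;
      Pout(pi, j) = p;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_probe_stats(Rcpp::List sessions, Rcpp::IntegerVector probes,
                           Rcpp::IntegerVector ks, const arma::mat& G,
                           const arma::mat& C) {
  const int N = sessions.size();
  std::vector<mat> Z(N);
  for (int n = 0; n < N; ++n) {
    Z[n] = Rcpp::as<mat>(sessions[n]);
    normalize_columns(Z[n]);
  }
  DesignPre d = design_precompute(G, C);
  std::vector<int> pr(probes.begin(), probes.end());
  std::vector<int> kk(ks.begin(), ks.end());
  const int V = Z[0].n_cols;
  mat Fout(pr.size(), kk.size()), Pout(pr.size(), kk.size());
  mat R(N, V), K(N, N);
  probe_stats_core(Z, pr, kk, d, Fout, Pout, R, K);
  return Rcpp::List::create(Rcpp::Named("F") = Fout, Rcpp::Named("p") = Pout);
}

// ---------------------------------------------------------------------------
// Full Monte Carlo driver. Per replicate: simulate smoothed Gaussian noise
// for every subject, add the shared signal series to the signal voxels of the
// signal-group subjects, and evaluate the probe-voxel tests for every k.
// Draw order (fixed, documented): per subject the time-by-voxel noise block
// in column-major order; then, per signal subject, its signal timeseries.
// Returns p-values, dim (n_reps, n_probes, n_k).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::NumericVector cpp_mc_run(int n_reps, int N, int T, int V,
                               const arma::vec& kernel, int sig_lo,
                               int sig_hi, Rcpp::IntegerVector signal_subjects,
                               double signal_weight,
                               Rcpp::IntegerVector probes,
                               Rcpp::IntegerVector ks, const arma::mat& G,
                               const arma::mat& C, double seed) {
  ZigguratNormal z((uint64_t)seed);
  DesignPre d = design_precompute(G, C);
  std::vector<int> pr(probes.begin(), probes.end());
  std::vector<int> kk(ks.begin(), ks.end());
  const int np = (int)pr.size(), nk = (int)kk.size();
  std::vector<bool> is_sig(N, false);
  for (int i = 0; i < signal_subjects.size(); ++i)
    is_sig[signal_subjects[i]] = true;
  Rcpp::NumericVector out(n_reps * np * nk);
  out.attr("dim") = Rcpp::IntegerVector::create(n_reps, np, nk);
  std::vector<mat> Z(N, mat(T, V));
  mat noise(T, V), R(N, V), K(N, N), Fout(np, nk), Pout(np, nk);
  vec sig(T);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    for (int n = 0; n < N; ++n) {
      z.fill(noise.memptr(), (size_t)T * V);
      smooth_in_place(Z[n], noise, kernel);
    }
    if (signal_weight != 0.0) {
      for (int n = 0; n < N; ++n) {
        if (!is_sig[n]) continue;
        z.fill(sig.memptr(), (size_t)T);
        for (int v = sig_lo; v <= sig_hi; ++v)
          Z[n].col(v) += signal_weight * sig;
      }
    }
    for (int n = 0; n < N; ++n) normalize_columns(Z[n]);
    probe_stats_core(Z, pr, kk, d, Fout, Pout, R, K);
    for (int pi = 0; pi < np; ++pi)
      for (int j = 0; j < nk; ++j)
        out[r + n_reps * (pi + np * j)] = Pout(pi, j);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Vectorised Wilks-Lambda map over voxels: scores is a subjects x k x voxels
// cube; returns F, p and lambda per voxel. Used by the permutation engine.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_wilks_map(const arma::cube& scores, const arma::mat& G,
                         const arma::mat& C) {
  DesignPre d = design_precompute(G, C);
  const int V = scores.n_slices;
  vec F(V), P(V), L(V);
  for (int v = 0; v < V; ++v) {
    double f, p, lam;
    wilks_one(scores.slice(v), d, f, p, lam);
    F(v) = f; P(v) = p; L(v) = lam;
  }
  const double a = (double)scores.n_cols, c = d.c, b = d.b;
  double num = a * a * c * c - 4.0, den = a * a + c * c - 5.0;
  double e = (num > 0 && den > 0) ? std::sqrt(num / den) : 1.0;
  double df2 = (b - (a - c + 1.0) / 2.0) * e - a * c / 2.0 + 1.0;
  return Rcpp::List::create(
      Rcpp::Named("F") = F, Rcpp::Named("p") = P, Rcpp::Named("lambda") = L,
      Rcpp::Named("df1") = a * c, Rcpp::Named("df2") = df2);
}
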