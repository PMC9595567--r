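// Stochastic individual-based simulator core.
//
// The per-step scheme is: (1) compute the density field D and public-good
// field A from the pre-step state by circular convolution; (2) each
// individual reproduces with probability g*dt (offspring at the parent's
// cell, trait mutated with probability mu); (3) every individual, newborns
// included, dies with probability d*dt; (4) survivors are displaced per
// dimension by a rounded draw from Normal(0, sqrt(2*kD*dt)), wrapped
// periodically.  Alongside the dynamics the step-wise Price decomposition of
// the change in mean trait (selection / drift / transmission bias) is
// accumulated exactly.
//
// Performance notes: both convolutions are done with one forward and one
// inverse complex FFT per step by packing the occupancy and trait-weighted
// occupancy into the real and imaginary parts.  For power-of-two grids a
// plan (twiddle factors + bit reversal) is computed once per run; other
// sizes fall back to Armadillo's FFT.  Random numbers come from a
// xoshiro256++ generator (uniforms), the polar method (normals), and
// inversion (exponentials), all seeded deterministically.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <complex>
#include <cstdint>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

// ----------------------------------------------------------------- RNG ----
struct Rng {
  std::uint64_t s[4];
  double spare;
  bool has_spare;

  explicit Rng(std::uint64_t seed) : has_spare(false) {
    // splitmix64 seeding
    std::uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {  // Marsaglia polar
    if (has_spare) { has_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
  double expo(double mean) { return -std::log(unif()) * mean; }
};

// Discretized Gaussian displacement sampler: the per-step shift is
// round(Normal(0, sd)) in cells, drawn via an alias table over the exact
// rounded-normal pmf p_k = Phi((k+1/2)/sd) - Phi((k-1/2)/sd).
struct DiscreteNormal {
  int M;
  std::vector<double> prob;
  std::vector<int> alias;

  explicit DiscreteNormal(double sd) {
    M = (sd > 0) ? static_cast<int>(std::ceil(8.0 * sd)) + 1 : 0;
    const int n = 2 * M + 1;
    std::vector<double> p(n);
    auto Phi = [](double z) { return 0.5 * std::erfc(-z / std::sqrt(2.0)); };
    double tot = 0.0;
    for (int k = -M; k <= M; ++k) {
      double pk = (sd > 0)
          ? Phi((k + 0.5) / sd) - Phi((k - 0.5) / sd)
          : (k == 0 ? 1.0 : 0.0);
      p[k + M] = pk;
      tot += pk;
    }
    for (double& x : p) x /= tot;
    // Vose alias construction
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    std::vector<int> small, large;
    std::vector<double> scaled(n);
    for (int i = 0; i < n; ++i) {
      scaled[i] = p[i] * n;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int l : large) prob[l] = 1.0;
    for (int s : small) prob[s] = 1.0;
  }

  int draw(Rng& rng) {
    const int n = 2 * M + 1;
    double u = rng.unif() * n;
    int i = static_cast<int>(u);
    if (i >= n) i = n - 1;
    double f = u - i;
    return ((f < prob[i]) ? i : alias[i]) - M;
  }
};

// ----------------------------------------------------------------- FFT ----
struct FFTPlan {
  int n;
  bool pow2;
  std::vector<int> rev;
  std::vector<cplx> w;   // forward twiddles, bit-level tables per stage
  std::vector<cplx> wi;  // inverse twiddles

  explicit FFTPlan(int n_) : n(n_) {
    pow2 = (n > 0) && ((n & (n - 1)) == 0);
    if (!pow2) return;
    int lg = 0;
    while ((1 << lg) < n) ++lg;
    rev.resize(n);
    for (int i = 0; i < n; ++i) {
      rev[i] = (rev[i >> 1] >> 1) | ((i & 1) << (lg - 1));
    }
    w.resize(n);
    wi.resize(n);
    for (int k = 0; k < n; ++k) {
      double ang = -2.0 * M_PI * k / n;
      w[k] = cplx(std::cos(ang), std::sin(ang));
      wi[k] = std::conj(w[k]);
    }
  }

  // in-place transform; inverse is unnormalized
  void run(cplx* a, bool inverse) const {
    const std::vector<cplx>& tw = inverse ? wi : w;
    for (int i = 0; i < n; ++i) {
      if (i < rev[i]) std::swap(a[i], a[rev[i]]);
    }
    for (int len = 2; len <= n; len <<= 1) {
      int stride = n / len, half = len >> 1;
      for (int i = 0; i < n; i += len) {
        const cplx* tp = tw.data();
        for (int j = 0; j < half; ++j) {
          cplx u = a[i + j];
          cplx v = a[i + j + half] * (*tp);
          a[i + j] = u + v;
          a[i + j + half] = u - v;
          tp += stride;
        }
      }
    }
  }
};

void fft_1d(const FFTPlan& plan, std::vector<cplx>& buf, bool inverse) {
  if (plan.pow2) {
    plan.run(buf.data(), inverse);
    if (inverse) {
      double f = 1.0 / plan.n;
      for (int i = 0; i < plan.n; ++i) buf[i] *= f;
    }
  } else {
    arma::cx_vec v(buf.data(), plan.n, false, true);
    arma::cx_vec out = inverse ? arma::cx_vec(arma::ifft(v)) : arma::cx_vec(arma::fft(v));
    std::copy(out.begin(), out.end(), buf.begin());
  }
}

// -------------------------------------------------------------- fields ----
struct FieldWork {
  int dim, X, Xtot;
  FFTPlan plan;
  std::vector<cplx> khat_rc, khat_a;  // kernel transforms
  std::vector<cplx> buf;
  std::vector<double> D, A;
  arma::cx_mat khat_rc2, khat_a2;     // 2D path

  FieldWork(int dim_, int X_, const arma::vec& krc, const arma::vec& ka)
      : dim(dim_), X(X_), Xtot(dim_ == 1 ? X_ : X_ * X_), plan(X_) {
    D.resize(Xtot);
    A.resize(Xtot);
    if (dim == 1) {
      buf.resize(X);
      khat_rc.resize(X);
      khat_a.resize(X);
      for (int i = 0; i < X; ++i) buf[i] = cplx(krc[i], 0.0);
      fft_1d(plan, buf, false);
      std::copy(buf.begin(), buf.end(), khat_rc.begin());
      for (int i = 0; i < X; ++i) buf[i] = cplx(ka[i], 0.0);
      fft_1d(plan, buf, false);
      std::copy(buf.begin(), buf.end(), khat_a.begin());
    } else {
      arma::mat z(X, X, arma::fill::zeros);
      khat_rc2 = arma::fft2(arma::cx_mat(arma::reshape(krc, X, X), z));
      khat_a2 = arma::fft2(arma::cx_mat(arma::reshape(ka, X, X), z));
    }
  }

  // occ and wocc packed as real/imaginary parts; on return D and A hold the
  // two convolutions.
  void compute(const std::vector<double>& occ, const std::vector<double>& wocc) {
    const cplx I(0.0, 1.0);
    if (dim == 1) {
      for (int i = 0; i < X; ++i) buf[i] = cplx(occ[i], wocc[i]);
      fft_1d(plan, buf, false);
      // split the two real transforms via Hermitian symmetry, multiply by the
      // kernel transforms, and repack as D + i*A
      std::vector<cplx>& Z = buf;
      std::vector<cplx> C(X);
      for (int k = 0; k < X; ++k) {
        int nk = (X - k) % X;
        cplx zk = Z[k], znk = std::conj(Z[nk]);
        cplx Oh = 0.5 * (zk + znk);
        cplx Wh = -0.5 * I * (zk - znk);
        C[k] = Oh * khat_rc[k] + I * (Wh * khat_a[k]);
      }
      std::copy(C.begin(), C.end(), buf.begin());
      fft_1d(plan, buf, true);
      for (int i = 0; i < X; ++i) {
        D[i] = buf[i].real();
        A[i] = buf[i].imag();
      }
    } else {
      arma::cx_mat Z(X, X);
      for (int j = 0; j < X; ++j)
        for (int i = 0; i < X; ++i)
          Z(i, j) = cplx(occ[i + X * j], wocc[i + X * j]);
      arma::cx_mat Zh = arma::fft2(Z);
      arma::cx_mat Ch(X, X);
      for (int j = 0; j < X; ++j) {
        int nj = (X - j) % X;
        for (int i = 0; i < X; ++i) {
          int ni = (X - i) % X;
          cplx zk = Zh(i, j), znk = std::conj(Zh(ni, nj));
          cplx Oh = 0.5 * (zk + znk);
          cplx Wh = -0.5 * I * (zk - znk);
          Ch(i, j) = Oh * khat_rc2(i, j) + I * (Wh * khat_a2(i, j));
        }
      }
      arma::cx_mat C = arma::ifft2(Ch);
      for (int j = 0; j < X; ++j)
        for (int i = 0; i < X; ++i) {
          D[i + X * j] = C(i, j).real();
          A[i + X * j] = C(i, j).imag();
        }
    }
  }
};

inline double phi_eff(double phi) { return phi > 0.0 ? phi : 0.0; }

}  // namespace

// Compute the density and public-good fields from occupancy vectors;
// exposed so the R-level field constructors can be cross-checked against
// the engine's internal path.
// [[Rcpp::export]]
List fields_from_counts_cpp(std::vector<double> occ, std::vector<double> wocc,
                            arma::vec krc, arma::vec ka, int dim, int X) {
  FieldWork fw(dim, X, krc, ka);
  fw.compute(occ, wocc);
  return List::create(_["D"] = NumericVector(fw.D.begin(), fw.D.end()),
                      _["A"] = NumericVector(fw.A.begin(), fw.A.end()));
}

// Main driver.  `cell0` holds 0-based linear cell indices (ix + X*iy in 2D),
// `tag0` the interval-ancestor tags (0-based indices into the previous
// boundary roster).  Returns the recorded time series, boundary snapshots
// (taken *before* tags are reset), the final state, and an extinction flag.
// [[Rcpp::export]]
List run_sim_cpp(List par, arma::vec krc, arma::vec ka,
                 IntegerVector cell0, NumericVector phi0, IntegerVector tag0,
                 int n_steps, int record_every, int interval_steps,
                 bool keep_snapshots, double seed,
                 bool newborn_death = true) {
  const int dim = as<int>(par["dim"]);
  const int X = as<int>(par["X"]);
  const double dt = as<double>(par["dt"]);
  const double d = as<double>(par["d"]);
  const double g0 = as<double>(par["g0"]);
  const double K = as<double>(par["K"]);
  const double c = as<double>(par["c"]);
  const double b0 = as<double>(par["b0"]);
  const double bmax = as<double>(par["b_max"]);
  const double mu = as<double>(par["mu"]);
  const double m = as<double>(par["m"]);
  const double kD = as<double>(par["k_D"]);
  const double dx = as<double>(par["dx"]);
  const bool truncate_mode = as<std::string>(par["trait_mode"]) == "truncate";

  const double p_death = d * dt;
  if (p_death < 0.0 || p_death > 1.0) stop("d*dt must lie in [0, 1]");
  const double step_sd = std::sqrt(2.0 * kD * dt) / dx;  // in cells
  const double bb = bmax / b0;

  FieldWork fw(dim, X, krc, ka);
  const int Xtot = fw.Xtot;

  std::vector<int> cell(cell0.begin(), cell0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<int> tag(tag0.begin(), tag0.end());

  Rng rng(static_cast<std::uint64_t>(seed));
  DiscreteNormal dnorm_step(step_sd);

  auto mutate = [&](double parent) {
    if (rng.unif() >= mu) return parent;
    double delta = rng.expo(m);
    if (rng.unif() < 0.5) delta = -delta;
    double child = parent + delta;
    if (truncate_mode && child < 0.0) child = 0.0;
    return child;
  };

  std::vector<double> rec_t, rec_n, rec_phi, rec_phieff, rec_sel, rec_drift, rec_bias;
  double cum_sel = 0.0, cum_drift = 0.0, cum_bias = 0.0;
  bool extinct = false;

  auto record = [&](int step) {
    double sp = 0.0, spe = 0.0;
    for (double x : phi) {
      sp += x;
      spe += (x > 0.0 ? x : 0.0);
    }
    double n = static_cast<double>(phi.size());
    rec_t.push_back(step * dt);
    rec_n.push_back(n);
    rec_phi.push_back(n > 0 ? sp / n : 0.0);
    rec_phieff.push_back(n > 0 ? spe / n : 0.0);
    rec_sel.push_back(cum_sel);
    rec_drift.push_back(cum_drift);
    rec_bias.push_back(cum_bias);
  };

  List snapshots;
  auto snapshot = [&](int step) {
    if (keep_snapshots) {
      snapshots.push_back(List::create(
          _["t"] = step * dt,
          _["cell"] = IntegerVector(cell.begin(), cell.end()),
          _["phi"] = NumericVector(phi.begin(), phi.end()),
          _["anc"] = IntegerVector(tag.begin(), tag.end())));
    }
    for (std::size_t i = 0; i < tag.size(); ++i) tag[i] = static_cast<int>(i);
  };

  record(0);
  snapshot(0);

  std::vector<double> occ(Xtot), wocc(Xtot), child_phi;
  std::vector<int> cell2, tag2;
  std::vector<double> phi2;
  std::vector<char> has_child;

  for (int step = 1; step <= n_steps; ++step) {
    const int N = static_cast<int>(cell.size());
    if (N == 0) { extinct = true; break; }

    // Step 1: fields and rates from the pre-step state.
    std::fill(occ.begin(), occ.end(), 0.0);
    std::fill(wocc.begin(), wocc.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      occ[cell[i]] += 1.0;
      wocc[cell[i]] += phi_eff(phi[i]);
    }
    fw.compute(occ, wocc);

    // Step 2 (with rates computed on the fly): reproduction and mutation.
    has_child.assign(N, 0);
    child_phi.assign(N, 0.0);
    double sum_phi = 0.0, sum_ew = 0.0, sum_phi_ew = 0.0;
    for (int i = 0; i < N; ++i) {
      double pE = phi_eff(phi[i]);
      double Ai = fw.A[cell[i]], Di = fw.D[cell[i]];
      double gi = g0 * (1.0 - c * pE + bmax * Ai / (bb + Ai)) * (1.0 - Di / K);
      if (gi < 0.0) gi = 0.0;
      if (gi * dt > 1.0) stop("reproduction probability g*dt exceeded 1; reduce dt");
      double ewi = newborn_death ? (1.0 + gi * dt) * (1.0 - p_death)
                                 : (1.0 - p_death) + gi * dt;
      sum_phi += phi[i];
      sum_ew += ewi;
      sum_phi_ew += phi[i] * ewi;
      if (rng.unif() < gi * dt) {
        has_child[i] = 1;
        child_phi[i] = mutate(phi[i]);
      }
    }
    const double phibar = sum_phi / N;

    // Step 3: death (newborns included by default), Price bookkeeping, and
    // construction of the post-step population.
    double sum_W_phi = 0.0, sum_phi_new = 0.0;
    cell2.clear(); phi2.clear(); tag2.clear();
    for (int i = 0; i < N; ++i) {
      int W = 0;
      if (rng.unif() >= p_death) {  // parent survives
        ++W;
        cell2.push_back(cell[i]);
        phi2.push_back(phi[i]);
        tag2.push_back(tag[i]);
        sum_phi_new += phi[i];
      }
      if (has_child[i]) {
        bool alive = newborn_death ? (rng.unif() >= p_death) : true;
        if (alive) {
          ++W;
          cell2.push_back(cell[i]);
          phi2.push_back(child_phi[i]);
          tag2.push_back(tag[i]);
          sum_phi_new += child_phi[i];
        }
      }
      sum_W_phi += W * phi[i];
    }
    const int N2 = static_cast<int>(cell2.size());

    if (N2 > 0) {
      const double phibar2 = sum_phi_new / N2;
      const double ewbar = sum_ew / N;
      double selection = (sum_phi_ew / N - phibar * ewbar) / ewbar;
      double cov_w = sum_W_phi / N2 - phibar;  // N * Wbar == N2
      double bias = phibar2 - sum_W_phi / N2;
      cum_sel += selection;
      cum_drift += cov_w - selection;
      cum_bias += bias;
    }

    // Step 4: motility of survivors.
    if (dim == 1) {
      for (int i = 0; i < N2; ++i) {
        int cc = (cell2[i] + dnorm_step.draw(rng)) % X;
        if (cc < 0) cc += X;
        cell2[i] = cc;
      }
    } else {
      for (int i = 0; i < N2; ++i) {
        int ix = cell2[i] % X, iy = cell2[i] / X;
        ix = (ix + dnorm_step.draw(rng)) % X; if (ix < 0) ix += X;
        iy = (iy + dnorm_step.draw(rng)) % X; if (iy < 0) iy += X;
        cell2[i] = ix + X * iy;
      }
    }

    cell.swap(cell2);
    phi.swap(phi2);
    tag.swap(tag2);

    if (cell.empty()) {
      extinct = true;
      record(step);
      break;
    }
    if (step % record_every == 0 || step == n_steps) record(step);
    if (interval_steps > 0 && step % interval_steps == 0) snapshot(step);
  }

  const int nr = static_cast<int>(rec_t.size());
  NumericMatrix series(nr, 7);
  colnames(series) = CharacterVector::create("t", "n", "mean_phi", "mean_phi_eff",
                                             "cum_selection", "cum_drift", "cum_bias");
  for (int r = 0; r < nr; ++r) {
    series(r, 0) = rec_t[r];
    series(r, 1) = rec_n[r];
    series(r, 2) = rec_phi[r];
    series(r, 3) = rec_phieff[r];
    series(r, 4) = rec_sel[r];
    series(r, 5) = rec_drift[r];
    series(r, 6) = rec_bias[r];
  }

  return List::create(
      _["series"] = series,
      _["snapshots"] = snapshots,
      _["extinct"] = extinct,
      _["final"] = List::create(
          _["cell"] = IntegerVector(cell.begin(), cell.end()),
          _["phi"] = NumericVector(phi.begin(), phi.end()),
          _["anc"] = IntegerVector(tag.begin(), tag.end())));
}
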