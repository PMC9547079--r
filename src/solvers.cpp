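#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Energy of an upper-triangular QUBO: sum_i Q_ii q_i + sum_{i<j} Q_ij q_i q_j
// [[Rcpp::export]]
double qubo_energy_cpp(const NumericMatrix& Q, const IntegerVector& bits) {
  const int n = Q.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!bits[i]) continue;
    e += Q(i, i);
    for (int j = i + 1; j < n; ++j) {
      if (bits[j]) e += Q(i, j);
    }
  }
  return e;
}

static double energy_of(const NumericMatrix& Q, const std::vector<int>& q);

// symmetrize once so single-flip energy deltas are O(n)
static std::vector<double> make_sym(const NumericMatrix& Q) {
  const int n = Q.nrow();
  std::vector<double> S((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      S[(size_t)i * n + j] = Q(i, j);
      S[(size_t)j * n + i] = Q(i, j);
    }
  return S;
}

static inline double flip_delta(const std::vector<double>& S,
                                const NumericMatrix& Q,
                                const std::vector<int>& q, int n, int k) {
  double field = Q(k, k);
  const double* row = &S[(size_t)k * n];
  for (int i = 0; i < n; ++i)
    if (q[i]) field += row[i];
  return q[k] ? -field : field;
}

// Exhaustive minimization by Gray-code enumeration. Ties in energy are
// broken toward the state whose little-endian integer value (bit 1 = least
// significant) is smallest.
// [[Rcpp::export]]
List exhaustive_min_cpp(const NumericMatrix& Q) {
  const int n = Q.nrow();
  if (n > 30) stop("exhaustive enumeration limited to 30 bits");
  std::vector<double> S = make_sym(Q);
  std::vector<int> q(n, 0);
  double e = 0.0;
  double best_e = 0.0;
  uint32_t best_val = 0;
  std::vector<int> best_q(n, 0);
  const uint64_t total = (uint64_t)1 << n;
  uint32_t state_val = 0;
  for (uint64_t g = 1; g < total; ++g) {
    // bit flipped between gray(g-1) and gray(g) is ctz(g)
    int k = 0;
    uint64_t t = g;
    while (!(t & 1)) { t >>= 1; ++k; }
    e += flip_delta(S, Q, q, n, k);
    q[k] = 1 - q[k];
    state_val ^= ((uint32_t)1 << k);
    if (e < best_e || (e == best_e && state_val < best_val)) {
      best_e = e;
      best_val = state_val;
      best_q = q;
    }
  }
  return List::create(_["bits"] = IntegerVector(best_q.begin(), best_q.end()),
                      _["energy"] = energy_of(Q, best_q));
}

static double energy_of(const NumericMatrix& Q, const std::vector<int>& q) {
  const int n = Q.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!q[i]) continue;
    e += Q(i, i);
    for (int j = i + 1; j < n; ++j)
      if (q[j]) e += Q(i, j);
  }
  return e;
}

static int greedy_polish(const NumericMatrix& Q, const std::vector<double>& S,
                         std::vector<int>& q) {
  const int n = Q.nrow();
  int n_flips = 0;
  for (;;) {
    int best_k = -1;
    double best_de = 0.0;
    for (int k = 0; k < n; ++k) {
      double de = flip_delta(S, Q, q, n, k);
      if (de < best_de) { best_de = de; best_k = k; }
    }
    if (best_k < 0) break;
    q[best_k] = 1 - q[best_k];
    ++n_flips;
  }
  return n_flips;
}

// Single-bit-flip Metropolis annealing with geometric cooling. Uses R's RNG
// so runs are reproducible under set.seed(). Each read is an independent
// restart from a random state; with polish = true the best state of every
// read is driven to its 1-flip local minimum by greedy descent before the
// reads are compared. Final energies are recomputed from scratch so equal
// states always report equal energies.
// [[Rcpp::export]]
List sa_min_cpp(const NumericMatrix& Q, int reads, int sweeps,
                double t_initial, double t_final, bool polish = false) {
  const int n = Q.nrow();
  std::vector<double> S = make_sym(Q);
  RNGScope scope;
  std::vector<int> q(n), best_q(n, 0);
  double best_e = R_PosInf;
  NumericVector read_energies(reads);
  const double ratio = (sweeps > 1) ? std::pow(t_final / t_initial,
                                               1.0 / (sweeps - 1)) : 1.0;
  for (int r = 0; r < reads; ++r) {
    for (int i = 0; i < n; ++i) q[i] = (unif_rand() < 0.5) ? 1 : 0;
    double e = energy_of(Q, q);
    double read_best = e;
    std::vector<int> read_best_q = q;
    double temp = t_initial;
    for (int s = 0; s < sweeps; ++s) {
      for (int k = 0; k < n; ++k) {
        double de = flip_delta(S, Q, q, n, k);
        if (de <= 0.0 || unif_rand() < std::exp(-de / temp)) {
          q[k] = 1 - q[k];
          e += de;
          if (e < read_best) { read_best = e; read_best_q = q; }
        }
      }
      temp *= ratio;
    }
    if (polish) greedy_polish(Q, S, read_best_q);
    read_best = energy_of(Q, read_best_q);
    read_energies[r] = read_best;
    if (read_best < best_e) { best_e = read_best; best_q = read_best_q; }
  }
  return List::create(_["bits"] = IntegerVector(best_q.begin(), best_q.end()),
                      _["energy"] = best_e,
                      _["read_energies"] = read_energies);
}

// Steepest-descent single-bit-flip local search: repeatedly applies the flip
// with the largest energy decrease (ties: lowest bit index) until no flip
// decreases the energy. Deterministic.
// [[Rcpp::export]]
List greedy_descent_cpp(const NumericMatrix& Q, const IntegerVector& start) {
  std::vector<double> S = make_sym(Q);
  std::vector<int> q(start.begin(), start.end());
  int n_flips = greedy_polish(Q, S, q);
  return List::create(_["bits"] = IntegerVector(q.begin(), q.end()),
                      _["energy"] = energy_of(Q, q),
                      _["n_flips"] = n_flips);
}

// Largest single-flip |dE| from a given state; used to set the default
// initial annealing temperature.
// [[Rcpp::export]]
double max_abs_flip_delta_cpp(const NumericMatrix& Q, const IntegerVector& state) {
  const int n = Q.nrow();
  std::vector<double> S = make_sym(Q);
  std::vector<int> q(state.begin(), state.end());
  double m = 0.0;
  for (int k = 0; k < n; ++k) {
    double de = std::fabs(flip_delta(S, Q, q, n, k));
    if (de > m) m = de;
  }
  return m;
}
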