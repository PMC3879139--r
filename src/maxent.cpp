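// Core numerics for maximum entropy models of binary words:
// energies, Metropolis sampling, Wang-Landau density of states,
// exact enumeration (Gray-code), greedy descent and barrier walks.
//
// Spin coding is {0,1} throughout; E(sigma) = -sum_i h_i s_i
//   - 1/2 sum_{i != j} J_ij s_i s_j + V(K), K = sum_i s_i.
// All samplers draw from R's RNG (unif_rand), so set.seed() on the
// R side makes every routine deterministic.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double word_energy(const int* s, int N,
                                 const double* h, const double* J,
                                 const double* V) {
  double E = 0.0;
  int K = 0;
  for (int i = 0; i < N; ++i) {
    if (s[i]) {
      ++K;
      E -= h[i];
      for (int j = i + 1; j < N; ++j)
        if (s[j]) E -= J[i + (size_t)N * j];
    }
  }
  E += V[K];
  return E;
}

// [[Rcpp::export]]
NumericVector energy_words_cpp(IntegerMatrix words, NumericVector h,
                               NumericMatrix J, NumericVector V) {
  int nw = words.nrow(), N = words.ncol();
  NumericVector out(nw);
  std::vector<int> s(N);
  for (int w = 0; w < nw; ++w) {
    for (int i = 0; i < N; ++i) s[i] = words(w, i);
    out[w] = word_energy(s.data(), N, h.begin(), J.begin(), V.begin());
  }
  return out;
}

// Local fields L[i] = sum_j J_ij s_j for the current state.
static void local_fields(const std::vector<int>& s, int N, const double* J,
                         std::vector<double>& L) {
  std::fill(L.begin(), L.end(), 0.0);
  for (int j = 0; j < N; ++j)
    if (s[j])
      for (int i = 0; i < N; ++i) L[i] += J[i + (size_t)N * j];
}

// Energy change for flipping site i given maintained L and K.
static inline double delta_E(const std::vector<int>& s, int i,
                             const std::vector<double>& L, int K,
                             const double* h, const double* V) {
  if (s[i] == 0) return -h[i] - L[i] + V[K + 1] - V[K];
  return h[i] + L[i] + V[K - 1] - V[K];
}

static inline void apply_flip(std::vector<int>& s, int i, int N,
                              const double* J, std::vector<double>& L,
                              int& K) {
  double sgn = s[i] ? -1.0 : 1.0;
  s[i] = 1 - s[i];
  K += s[i] ? 1 : -1;
  for (int j = 0; j < N; ++j) L[j] += sgn * J[j + (size_t)N * i];
}

// Single-spin-flip Metropolis chain at inverse temperature beta.
// burn and thin are measured in sweeps (N attempted flips each).
// [[Rcpp::export]]
List metropolis_cpp(NumericVector h, NumericMatrix J, NumericVector V,
                    int n_samples, int burn_sweeps, int thin_sweeps,
                    double beta, IntegerVector init) {
  int N = h.size();
  std::vector<int> s(init.begin(), init.end());
  std::vector<double> L(N);
  local_fields(s, N, J.begin(), L);
  int K = 0;
  for (int i = 0; i < N; ++i) K += s[i];
  double E = word_energy(s.data(), N, h.begin(), J.begin(), V.begin());

  IntegerMatrix samples(n_samples, N);
  NumericVector energies(n_samples);
  long long total_sweeps = (long long)burn_sweeps +
                           (long long)n_samples * thin_sweeps;
  int rec = 0, sweeps_done = 0;
  for (long long sw = 0; sw < total_sweeps; ++sw) {
    for (int a = 0; a < N; ++a) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double dE = delta_E(s, i, L, K, h.begin(), V.begin());
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        apply_flip(s, i, N, J.begin(), L, K);
        E += dE;
      }
    }
    ++sweeps_done;
    if (sweeps_done > burn_sweeps &&
        (sweeps_done - burn_sweeps) % thin_sweeps == 0 && rec < n_samples) {
      for (int i = 0; i < N; ++i) samples(rec, i) = s[i];
      energies[rec] = E;
      ++rec;
    }
  }
  return List::create(_["samples"] = samples, _["energies"] = energies);
}

// Wang-Landau flat-histogram estimate of log g(E) on fixed bin edges.
// Proposals falling outside the bracketed range are rejected (current
// bin re-weighted), the standard bounded-range WL rule.
// [[Rcpp::export]]
List wang_landau_cpp(NumericVector h, NumericMatrix J, NumericVector V,
                     NumericVector edges, double flatness,
                     double ln_f_final, int sweeps_per_check,
                     int max_checks, IntegerVector init) {
  int N = h.size();
  int nb = edges.size() - 1;
  double e_lo = edges[0], e_hi = edges[nb];
  double bw = (e_hi - e_lo) / nb;
  std::vector<int> s(init.begin(), init.end());
  std::vector<double> L(N);
  local_fields(s, N, J.begin(), L);
  int K = 0;
  for (int i = 0; i < N; ++i) K += s[i];
  double E = word_energy(s.data(), N, h.begin(), J.begin(), V.begin());
  if (E < e_lo || E >= e_hi) stop("initial state outside energy range");

  std::vector<double> lng(nb, 0.0);
  std::vector<double> H(nb, 0.0);
  std::vector<double> Esum(nb, 0.0), Ecnt(nb, 0.0);
  std::vector<bool> visited(nb, false);
  double ln_f = 1.0;
  int cur = (int)((E - e_lo) / bw);
  if (cur >= nb) cur = nb - 1;
  visited[cur] = true;
  int checks = 0, n_refine = 0;
  bool converged = false;
  // exploration phase: hold ln f = 1 until the set of reachable bins
  // stops growing, so refinement cannot start before the walk has
  // seen the whole spectrum (otherwise late-found bins accumulate
  // log g at a tiny ln f and the tails come out biased)
  bool exploring = true;
  int stable_checks = 0, last_nvis = 1;

  while (checks < max_checks) {
    for (int sw = 0; sw < sweeps_per_check; ++sw) {
      for (int a = 0; a < N; ++a) {
        int i = (int)(unif_rand() * N);
        if (i == N) i = N - 1;
        double dE = delta_E(s, i, L, K, h.begin(), V.begin());
        double Enew = E + dE;
        if (Enew >= e_lo && Enew < e_hi) {
          int nbin = (int)((Enew - e_lo) / bw);
          if (nbin >= nb) nbin = nb - 1;
          // once the support is frozen, moves into bins outside it
          // are rejected like out-of-range proposals (guards against
          // boundary-straddling artifacts of float accumulation)
          if (exploring || visited[nbin]) {
            double dlg = lng[cur] - lng[nbin];
            if (dlg >= 0.0 || unif_rand() < std::exp(dlg)) {
              apply_flip(s, i, N, J.begin(), L, K);
              E = Enew;
              cur = nbin;
              visited[cur] = true;
            }
          }
        }
        lng[cur] += ln_f;
        H[cur] += 1.0;
        if (!exploring) {   // g-weighted in-bin energy representative
          Esum[cur] += E;
          Ecnt[cur] += 1.0;
        }
      }
    }
    ++checks;
    // flatness test over bins visited so far
    double hmin = R_PosInf, hsum = 0.0;
    int nvis = 0;
    for (int b = 0; b < nb; ++b)
      if (visited[b]) {
        ++nvis;
        hsum += H[b];
        if (H[b] < hmin) hmin = H[b];
      }
    if (exploring) {
      if (nvis == last_nvis) ++stable_checks; else stable_checks = 0;
      last_nvis = nvis;
      double hbar = hsum / std::max(1, nvis);
      // only freeze once the walker itself sits in a well-visited bin
      if (stable_checks >= 10 && H[cur] >= 0.01 * hbar) {
        exploring = false;
        // freeze the support: bins visited only a negligible number
        // of times during exploration are boundary artifacts (or
        // carry negligible multiplicity) and are dropped
        for (int b = 0; b < nb; ++b)
          if (visited[b] && H[b] < 0.01 * hbar && b != cur)
            visited[b] = false;
        std::fill(H.begin(), H.end(), 0.0);
      }
      continue;
    }
    if (nvis > 0 && hmin >= flatness * (hsum / nvis)) {
      ln_f *= 0.5;
      ++n_refine;
      std::fill(H.begin(), H.end(), 0.0);
      if (ln_f < ln_f_final) {
        converged = true;
        break;
      }
    }
  }
  NumericVector emean(nb, NA_REAL);
  for (int b = 0; b < nb; ++b)
    if (Ecnt[b] > 0) emean[b] = Esum[b] / Ecnt[b];
  return List::create(_["log_g"] = NumericVector(lng.begin(), lng.end()),
                      _["histogram"] = NumericVector(H.begin(), H.end()),
                      _["visited"] = LogicalVector(visited.begin(), visited.end()),
                      _["e_visit_mean"] = emean,
                      _["ln_f"] = ln_f, _["n_refinements"] = n_refine,
                      _["converged"] = converged);
}

// Greedy descent: sweep sites in ascending index, retain flips that
// strictly lower the energy, repeat until a full sweep is quiet.
static void descend_one(std::vector<int>& s, int N, const double* h,
                        const double* J, const double* V,
                        std::vector<double>& L, int& K) {
  local_fields(s, N, J, L);
  K = 0;
  for (int i = 0; i < N; ++i) K += s[i];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < N; ++i) {
      double dE = delta_E(s, i, L, K, h, V);
      if (dE < 0.0) {
        apply_flip(s, i, N, J, L, K);
        changed = true;
      }
    }
  }
}

// [[Rcpp::export]]
List descend_cpp(NumericVector h, NumericMatrix J, NumericVector V,
                 IntegerMatrix words) {
  int nw = words.nrow(), N = words.ncol();
  IntegerMatrix out(nw, N);
  NumericVector E(nw);
  std::vector<int> s(N);
  std::vector<double> L(N);
  int K;
  for (int w = 0; w < nw; ++w) {
    for (int i = 0; i < N; ++i) s[i] = words(w, i);
    descend_one(s, N, h.begin(), J.begin(), V.begin(), L, K);
    for (int i = 0; i < N; ++i) out(w, i) = s[i];
    E[w] = word_energy(s.data(), N, h.begin(), J.begin(), V.begin());
  }
  return List::create(_["states"] = out, _["energies"] = E);
}

// Metropolis walks from a metastable state until the basin is left.
// After every accepted flip the current word is descended; the walk
// stops when descent no longer returns the start. Barrier is the
// path maximum energy minus the start energy; L counts attempts.
// [[Rcpp::export]]
List explore_transitions_cpp(NumericVector h, NumericMatrix J,
                             NumericVector V, IntegerVector start,
                             int n_walks, int max_attempts, double beta) {
  int N = h.size();
  IntegerMatrix ends(n_walks, N);
  NumericVector barrier(n_walks);
  IntegerVector Lsteps(n_walks);
  LogicalVector exited(n_walks);
  double E0 = word_energy(start.begin(), N, h.begin(), J.begin(), V.begin());

  std::vector<int> s(N), d(N);
  std::vector<double> L(N), Ld(N);
  int K, Kd;
  for (int w = 0; w < n_walks; ++w) {
    for (int i = 0; i < N; ++i) s[i] = start[i];
    local_fields(s, N, J.begin(), L);
    K = 0;
    for (int i = 0; i < N; ++i) K += s[i];
    double E = E0, Emax = E0;
    bool out = false;
    int att = 0;
    while (att < max_attempts && !out) {
      ++att;
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double dE = delta_E(s, i, L, K, h.begin(), V.begin());
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        apply_flip(s, i, N, J.begin(), L, K);
        E += dE;
        if (E > Emax) Emax = E;
        d = s;
        descend_one(d, N, h.begin(), J.begin(), V.begin(), Ld, Kd);
        bool same = true;
        for (int q = 0; q < N; ++q)
          if (d[q] != start[q]) { same = false; break; }
        if (!same) {
          out = true;
          for (int q = 0; q < N; ++q) ends(w, q) = d[q];
          barrier[w] = Emax - E0;
          Lsteps[w] = att;
        }
      }
    }
    exited[w] = out;
    if (!out) {
      for (int q = 0; q < N; ++q) ends(w, q) = NA_INTEGER;
      barrier[w] = NA_REAL;
      Lsteps[w] = att;
    }
  }
  return List::create(_["ends"] = ends, _["barrier"] = barrier,
                      _["L"] = Lsteps, _["exited"] = exited);
}

// Non-stationary chain for repeat-locked drive: the field of neuron i
// in bin b (same for all repeats) is h_i + drive_i * a_b. The chain
// runs continuously; each bin gets `sweeps_per_bin` sweeps and its
// final state is recorded.
// [[Rcpp::export]]
IntegerMatrix generate_modulated_cpp(NumericVector h, NumericMatrix J,
                                     NumericVector V, NumericVector drive,
                                     NumericVector a, int R,
                                     int sweeps_per_bin,
                                     IntegerVector init) {
  int N = h.size(), B = a.size();
  IntegerMatrix out((long long)R * B, N);
  std::vector<int> s(init.begin(), init.end());
  std::vector<double> L(N), hb(N);
  local_fields(s, N, J.begin(), L);
  int K = 0;
  for (int i = 0; i < N; ++i) K += s[i];
  long long t = 0;
  for (int r = 0; r < R; ++r) {
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < N; ++i) hb[i] = h[i] + drive[i] * a[b];
      for (int sw = 0; sw < sweeps_per_bin; ++sw) {
        for (int att = 0; att < N; ++att) {
          int i = (int)(unif_rand() * N);
          if (i == N) i = N - 1;
          double dE = delta_E(s, i, L, K, hb.data(), V.begin());
          if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
            apply_flip(s, i, N, J.begin(), L, K);
          }
        }
      }
      for (int i = 0; i < N; ++i) out(t, i) = s[i];
      ++t;
    }
  }
  return out;
}

// Exact enumeration of all 2^N words by Gray code (one spin flips per
// step, O(N) update). Returns log Z, <E>, Var(E), P(K), and, when
// requested, the first and second moments and/or the full energy
// vector indexed by sum_i s_i 2^i (neuron 1 = least significant bit).
// [[Rcpp::export]]
List enumerate_gray_cpp(NumericVector h, NumericMatrix J, NumericVector V,
                        bool want_moments, bool want_energies) {
  int N = h.size();
  if (N > 30) stop("enumeration limited to N <= 30 bits");
  unsigned long long M = 1ULL << N;

  std::vector<int> s(N, 0);
  std::vector<double> L(N, 0.0);
  int K = 0;
  double E = V[0];

  // pass 1: minimum energy for a stable exp() shift
  double Emin = E;
  for (unsigned long long t = 1; t < M; ++t) {
    int bit = __builtin_ctzll(t);
    double dE = delta_E(s, bit, L, K, h.begin(), V.begin());
    apply_flip(s, bit, N, J.begin(), L, K);
    E += dE;
    if (E < Emin) Emin = E;
  }
  // state returns to... Gray code does not end at zero; reset.
  std::fill(s.begin(), s.end(), 0);
  std::fill(L.begin(), L.end(), 0.0);
  K = 0;
  E = V[0];

  long double Z = 0.0L, EZ = 0.0L, E2Z = 0.0L;
  std::vector<long double> p, m;
  std::vector<long double> pk(N + 1, 0.0L);
  if (want_moments) {
    p.assign(N, 0.0L);
    m.assign((size_t)N * N, 0.0L);
  }
  NumericVector energies;
  if (want_energies) energies = NumericVector(M);
  std::vector<int> act;
  act.reserve(N);
  unsigned long long idx = 0;

  for (unsigned long long t = 0; t < M; ++t) {
    if (t > 0) {
      int bit = __builtin_ctzll(t);
      double dE = delta_E(s, bit, L, K, h.begin(), V.begin());
      apply_flip(s, bit, N, J.begin(), L, K);
      E += dE;
      idx ^= (1ULL << bit);
      if (s[bit]) act.push_back(bit);
      else act.erase(std::find(act.begin(), act.end(), bit));
    }
    double w = std::exp(-(E - Emin));
    Z += w;
    EZ += (long double)E * w;
    E2Z += (long double)E * E * w;
    pk[K] += w;
    if (want_moments) {
      for (size_t u = 0; u < act.size(); ++u) {
        int i = act[u];
        p[i] += w;
        for (size_t v = u + 1; v < act.size(); ++v) {
          int j = act[v];
          m[std::min(i, j) + (size_t)N * std::max(i, j)] += w;
        }
      }
    }
    if (want_energies) energies[idx] = E;
  }

  double logZ = std::log((double)Z) - Emin;
  double meanE = (double)(EZ / Z);
  double varE = (double)(E2Z / Z) - meanE * meanE;
  NumericVector pk_out(N + 1);
  for (int k = 0; k <= N; ++k) pk_out[k] = (double)(pk[k] / Z);
  List out = List::create(_["log_z"] = logZ, _["mean_E"] = meanE,
                          _["var_E"] = varE, _["pk"] = pk_out,
                          _["e_min"] = Emin);
  if (want_moments) {
    NumericVector pv(N);
    NumericMatrix mv(N, N);
    for (int i = 0; i < N; ++i) pv[i] = (double)(p[i] / Z);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        mv(i, j) = mv(j, i) = (double)(m[i + (size_t)N * j] / Z);
    for (int i = 0; i < N; ++i) mv(i, i) = pv[i];
    out["p"] = pv;
    out["m"] = mv;
  }
  if (want_energies) out["energies"] = energies;
  return out;
}
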