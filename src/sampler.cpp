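// Metropolis sampling over labeled user/item partitions, posterior
// accumulation over stored samples, and the SGD loop of the Funk-SVD
// baseline. All randomness comes from R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Tables {
  std::vector<double> lg1;  // lgamma(x + 1), x = 0..n
  std::vector<double> lgK;  // lgamma(x + K), x = 0..n
  double lgamK;
  int K;
  Tables(int n, int K_) : lg1(n + 2), lgK(n + 2), lgamK(::lgamma((double)K_)), K(K_) {
    for (int x = 0; x <= n + 1; ++x) {
      lg1[x] = ::lgamma(x + 1.0);
      lgK[x] = ::lgamma((double)(x + K_));
    }
  }
};

// Hamiltonian term of one block given its class counts.
inline double block_term(const int* c, int K, const Tables& T) {
  int n = 0;
  for (int r = 0; r < K; ++r) n += c[r];
  if (n == 0) return 0.0;
  double v = T.lgK[n] - T.lgamK;
  for (int r = 0; r < K; ++r) v -= T.lg1[c[r]];
  return v;
}

inline int iunif(int n) {  // uniform integer in [0, n)
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

struct State {
  int Nu, Ni, K;
  std::vector<int> ua, ia;          // labels
  std::vector<int> cnt;             // Nu*Ni*K class counts
  std::vector<int> tot;             // Nu*Ni block totals
  std::vector<int> sizeU, sizeI;    // nodes per label
  int gU, gI;
  double H;                          // uncorrected Hamiltonian
  // adjacency (CSR): per user the (item, rating) pairs and per item the
  // (user, rating) pairs
  std::vector<int> uptr, uadj, urat, iptr, iadj, irat;

  inline int* block(int a, int b) { return &cnt[(size_t)(a * (size_t)Ni + b) * K]; }
  inline int& total(int a, int b) { return tot[(size_t)a * Ni + b]; }
};

void build_state(State& S, int Nu, int Ni, int K,
                 const IntegerVector& u, const IntegerVector& i,
                 const IntegerVector& r,
                 const IntegerVector& init_u, const IntegerVector& init_i,
                 const Tables& T) {
  S.Nu = Nu; S.Ni = Ni; S.K = K;
  S.ua.assign(init_u.begin(), init_u.end());
  S.ia.assign(init_i.begin(), init_i.end());
  S.cnt.assign((size_t)Nu * Ni * K, 0);
  S.tot.assign((size_t)Nu * Ni, 0);
  S.sizeU.assign(Nu, 0); S.sizeI.assign(Ni, 0);
  for (int a : S.ua) S.sizeU[a]++;
  for (int b : S.ia) S.sizeI[b]++;
  S.gU = 0; for (int s : S.sizeU) if (s > 0) S.gU++;
  S.gI = 0; for (int s : S.sizeI) if (s > 0) S.gI++;
  int n = u.size();
  // CSR adjacency
  S.uptr.assign(Nu + 1, 0); S.iptr.assign(Ni + 1, 0);
  for (int k = 0; k < n; ++k) { S.uptr[u[k] + 1]++; S.iptr[i[k] + 1]++; }
  for (int a = 0; a < Nu; ++a) S.uptr[a + 1] += S.uptr[a];
  for (int b = 0; b < Ni; ++b) S.iptr[b + 1] += S.iptr[b];
  S.uadj.assign(n, 0); S.urat.assign(n, 0);
  S.iadj.assign(n, 0); S.irat.assign(n, 0);
  std::vector<int> cu(S.uptr.begin(), S.uptr.end() - 1);
  std::vector<int> ci(S.iptr.begin(), S.iptr.end() - 1);
  for (int k = 0; k < n; ++k) {
    S.uadj[cu[u[k]]] = i[k]; S.urat[cu[u[k]]++] = r[k] - 1;
    S.iadj[ci[i[k]]] = u[k]; S.irat[ci[i[k]]++] = r[k] - 1;
  }
  for (int k = 0; k < n; ++k) {
    int a = S.ua[u[k]], b = S.ia[i[k]];
    S.block(a, b)[r[k] - 1]++;
    S.total(a, b)++;
  }
  // full Hamiltonian
  S.H = 0.0;
  for (int a = 0; a < Nu; ++a)
    for (int b = 0; b < Ni; ++b)
      if (S.total(a, b) > 0) S.H += block_term(S.block(a, b), K, T);
}

// Attempt one single-node Metropolis move; returns true if accepted.
// corr[g] = ln(N!/(N-g)!) per side, precomputed by caller.
bool attempt_move(State& S, const Tables& T,
                  const std::vector<double>& corrU,
                  const std::vector<double>& corrI,
                  std::vector<int>& dcnt, std::vector<int>& dtot,
                  std::vector<int>& touched) {
  int total_nodes = S.Nu + S.Ni;
  int pick = iunif(total_nodes);
  bool user_side = pick < S.Nu;
  int node = user_side ? pick : pick - S.Nu;
  int N = user_side ? S.Nu : S.Ni;
  int target = iunif(N);
  std::vector<int>& assign = user_side ? S.ua : S.ia;
  std::vector<int>& sizes = user_side ? S.sizeU : S.sizeI;
  int old = assign[node];
  if (target == old) return false;

  // class counts of the node toward each opposite-side group it rates
  const std::vector<int>& ptr = user_side ? S.uptr : S.iptr;
  const std::vector<int>& adj = user_side ? S.uadj : S.iadj;
  const std::vector<int>& rat = user_side ? S.urat : S.irat;
  const std::vector<int>& opp = user_side ? S.ia : S.ua;
  touched.clear();
  for (int k = ptr[node]; k < ptr[node + 1]; ++k) {
    int b = opp[adj[k]];
    if (dtot[b] == 0) touched.push_back(b);
    dcnt[b * S.K + rat[k]]++;
    dtot[b]++;
  }
  int K = S.K;
  double dH = 0.0;
  std::vector<int> tmp(K);
  for (int b : touched) {
    int* co = user_side ? S.block(old, b) : S.block(b, old);
    int* ct = user_side ? S.block(target, b) : S.block(b, target);
    const int* d = &dcnt[b * K];
    dH -= block_term(co, K, T) + block_term(ct, K, T);
    for (int r = 0; r < K; ++r) tmp[r] = co[r] - d[r];
    dH += block_term(tmp.data(), K, T);
    for (int r = 0; r < K; ++r) tmp[r] = ct[r] + d[r];
    dH += block_term(tmp.data(), K, T);
  }
  int g = user_side ? S.gU : S.gI;
  int g_new = g - (sizes[old] == 1 ? 1 : 0) + (sizes[target] == 0 ? 1 : 0);
  const std::vector<double>& corr = user_side ? corrU : corrI;
  double delta = dH + corr[g_new] - corr[g];

  bool accept = delta <= 0.0 || unif_rand() < std::exp(-delta);
  if (accept) {
    for (int b : touched) {
      int* co = user_side ? S.block(old, b) : S.block(b, old);
      int* ct = user_side ? S.block(target, b) : S.block(b, target);
      const int* d = &dcnt[b * K];
      int dt = dtot[b];
      for (int r = 0; r < K; ++r) { co[r] -= d[r]; ct[r] += d[r]; }
      if (user_side) { S.total(old, b) -= dt; S.total(target, b) += dt; }
      else           { S.total(b, old) -= dt; S.total(b, target) += dt; }
    }
    assign[node] = target;
    sizes[old]--; sizes[target]++;
    if (user_side) S.gU = g_new; else S.gI = g_new;
    S.H += dH;
  }
  // clear scratch
  for (int b : touched) {
    dtot[b] = 0;
    for (int r = 0; r < K; ++r) dcnt[b * K + r] = 0;
  }
  return accept;
}

std::vector<double> label_corr(int N) {
  std::vector<double> corr(N + 1, 0.0);
  for (int g = 1; g <= N; ++g) corr[g] = corr[g - 1] + std::log((double)(N - g + 1));
  return corr;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_chain(int n_users, int n_items, int K,
                   IntegerVector u, IntegerVector i, IntegerVector r,
                   IntegerVector init_users, IntegerVector init_items,
                   int sweeps, int burn_in, int interval) {
  Tables T(u.size(), K);
  State S;
  build_state(S, n_users, n_items, K, u, i, r, init_users, init_items, T);
  std::vector<double> corrU = label_corr(n_users), corrI = label_corr(n_items);
  std::vector<int> dcnt((size_t)std::max(n_users, n_items) * K, 0);
  std::vector<int> dtot(std::max(n_users, n_items), 0);
  std::vector<int> touched;
  touched.reserve(n_items + n_users);

  int n_samples = (sweeps > burn_in) ? (sweeps - burn_in) / interval : 0;
  IntegerMatrix out_u(n_samples, n_users), out_i(n_samples, n_items);
  NumericVector out_H(n_samples);
  IntegerVector out_sweep(n_samples);
  long accepted = 0, attempted = 0;
  int moves_per_sweep = n_users + n_items;
  bool exact_H = (double)n_users * n_items * K <= 2e6;

  GetRNGstate();
  int s = 0;
  for (int sw = 1; sw <= sweeps; ++sw) {
    for (int m = 0; m < moves_per_sweep; ++m) {
      attempted++;
      if (attempt_move(S, T, corrU, corrI, dcnt, dtot, touched)) accepted++;
    }
    if (sw > burn_in && (sw - burn_in) % interval == 0 && s < n_samples) {
      for (int a = 0; a < n_users; ++a) out_u(s, a) = S.ua[a];
      for (int b = 0; b < n_items; ++b) out_i(s, b) = S.ia[b];
      if (exact_H) {
        double H = 0.0;
        for (int a = 0; a < n_users; ++a)
          for (int b = 0; b < n_items; ++b)
            if (S.total(a, b) > 0) H += block_term(S.block(a, b), K, T);
        S.H = H;  // resync; also guards incremental drift on long runs
      }
      out_H[s] = S.H;
      out_sweep[s] = sw;
      s++;
    }
  }
  PutRNGstate();
  return List::create(_["users"] = out_u, _["items"] = out_i,
                      _["H"] = out_H, _["sweep"] = out_sweep,
                      _["acceptance_rate"] = (double)accepted / attempted);
}

// Average Laplace-rule predictive over stored partition samples.
// [[Rcpp::export]]
NumericMatrix cpp_posterior(IntegerMatrix sample_u, IntegerMatrix sample_i,
                            IntegerVector u, IntegerVector i, IntegerVector r,
                            int K, IntegerVector qu, IntegerVector qi) {
  int S = sample_u.nrow(), Q = qu.size(), n = u.size();
  int Ni = sample_i.ncol();
  NumericMatrix post(Q, K);
  std::unordered_map<long long, int> row_of;
  std::vector<int> bc;     // compacted per-block class counts
  std::vector<int> btot;
  std::vector<long long> qkey(Q);
  for (int s = 0; s < S; ++s) {
    row_of.clear();
    for (int q = 0; q < Q; ++q) {
      long long key = (long long)sample_u(s, qu[q]) * Ni + sample_i(s, qi[q]);
      qkey[q] = key;
      if (!row_of.count(key)) row_of[key] = (int)row_of.size();
    }
    int nb = (int)row_of.size();
    bc.assign((size_t)nb * K, 0);
    btot.assign(nb, 0);
    for (int k = 0; k < n; ++k) {
      long long key = (long long)sample_u(s, u[k]) * Ni + sample_i(s, i[k]);
      auto it = row_of.find(key);
      if (it != row_of.end()) {
        bc[(size_t)it->second * K + r[k] - 1]++;
        btot[it->second]++;
      }
    }
    for (int q = 0; q < Q; ++q) {
      int row = row_of[qkey[q]];
      double denom = btot[row] + K;
      for (int c = 0; c < K; ++c)
        post(q, c) += (bc[(size_t)row * K + c] + 1.0) / denom;
    }
  }
  for (int q = 0; q < Q; ++q)
    for (int c = 0; c < K; ++c) post(q, c) /= S;
  return post;
}

// Per-sample co-classification accumulation for one side.
// [[Rcpp::export]]
NumericMatrix cpp_coclass(IntegerMatrix assign) {
  int S = assign.nrow(), N = assign.ncol();
  NumericMatrix M(N, N);
  for (int s = 0; s < S; ++s)
    for (int a = 0; a < N; ++a)
      for (int b = a; b < N; ++b)
        if (assign(s, a) == assign(s, b)) { M(a, b) += 1.0; }
  for (int a = 0; a < N; ++a)
    for (int b = a; b < N; ++b) {
      M(a, b) /= S;
      M(b, a) = M(a, b);
    }
  return M;
}

// Funk-SVD with bias terms, trained by per-observation stochastic gradient
// descent over shuffled observations. Factors are pre-initialized in R so
// seeding stays in one place; the shuffle uses R's RNG.
// [[Rcpp::export]]
List cpp_svd_fit(IntegerVector u, IntegerVector i, NumericVector r,
                 int n_users, int n_items, int f,
                 double rate, double reg, int epochs,
                 NumericMatrix P0, NumericMatrix Q0) {
  int n = u.size();
  double mu = 0.0;
  for (int k = 0; k < n; ++k) mu += r[k];
  mu /= n;
  std::vector<double> bu(n_users, 0.0), bi(n_items, 0.0);
  NumericMatrix P(clone(P0)), Q(clone(Q0));
  std::vector<int> order(n);
  for (int k = 0; k < n; ++k) order[k] = k;
  NumericVector objective(epochs + 1);

  auto compute_objective = [&]() {
    double sse = 0.0;
    for (int k = 0; k < n; ++k) {
      double pred = mu + bu[u[k]] + bi[i[k]];
      for (int d = 0; d < f; ++d) pred += P(u[k], d) * Q(i[k], d);
      double e = r[k] - pred;
      sse += e * e;
    }
    double pen = 0.0;
    for (int a = 0; a < n_users; ++a) {
      pen += bu[a] * bu[a];
      for (int d = 0; d < f; ++d) pen += P(a, d) * P(a, d);
    }
    for (int b = 0; b < n_items; ++b) {
      pen += bi[b] * bi[b];
      for (int d = 0; d < f; ++d) pen += Q(b, d) * Q(b, d);
    }
    return sse + reg * pen;
  };

  GetRNGstate();
  objective[0] = compute_objective();
  for (int ep = 0; ep < epochs; ++ep) {
    for (int k = n - 1; k > 0; --k) {  // Fisher-Yates
      int j = iunif(k + 1);
      std::swap(order[k], order[j]);
    }
    for (int kk = 0; kk < n; ++kk) {
      int k = order[kk];
      int a = u[k], b = i[k];
      double pred = mu + bu[a] + bi[b];
      for (int d = 0; d < f; ++d) pred += P(a, d) * Q(b, d);
      double e = r[k] - pred;
      bu[a] += rate * (e - reg * bu[a]);
      bi[b] += rate * (e - reg * bi[b]);
      for (int d = 0; d < f; ++d) {
        double pu = P(a, d), qi = Q(b, d);
        P(a, d) += rate * (e * qi - reg * pu);
        Q(b, d) += rate * (e * pu - reg * qi);
      }
    }
    objective[ep + 1] = compute_objective();
  }
  PutRNGstate();
  return List::create(_["mu"] = mu, _["b_u"] = NumericVector(bu.begin(), bu.end()),
                      _["b_i"] = NumericVector(bi.begin(), bi.end()),
                      _["P"] = P, _["Q"] = Q, _["objective"] = objective);
}
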