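// Core search machinery for the shortest common supersequence problem.
//
// Symbols are 0-based integer codes (the R layer maps characters to codes
// via the instance alphabet). All stochastic routines draw from R's RNG
// (unif_rand), so set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> IVec;
typedef std::vector<IVec> Strings;

static Strings as_strings(const List& strs) {
  Strings S;
  S.reserve(strs.size());
  for (R_xlen_t i = 0; i < strs.size(); ++i) {
    IntegerVector v = strs[i];
    S.emplace_back(v.begin(), v.end());
  }
  return S;
}

// ---------------------------------------------------------------------------
// Embedding-probability table.
// P[i][j] = probability that a fixed string of length i is a subsequence of
// a uniform random string of length j over an alphabet of size q:
//   P[0][j] = 1;  P[i][j] = 0 for i > j;
//   P[i][j] = (1/q) P[i-1][j-1] + (1 - 1/q) P[i][j-1].
// ---------------------------------------------------------------------------

static std::vector<double> build_P(int q, int imax, int jmax) {
  std::vector<double> P((size_t)(imax + 1) * (jmax + 1), 0.0);
  const size_t w = jmax + 1;
  for (int j = 0; j <= jmax; ++j) P[j] = 1.0;  // i = 0
  const double invq = 1.0 / q;
  for (int i = 1; i <= imax; ++i) {
    double* Pi = &P[(size_t)i * w];
    const double* Pm = &P[(size_t)(i - 1) * w];
    Pi[0] = 0.0;
    for (int j = 1; j <= jmax; ++j)
      Pi[j] = (i > j) ? 0.0 : invq * Pm[j - 1] + (1.0 - invq) * Pi[j - 1];
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix prob_table_cpp(int q, int imax, int jmax) {
  if (q < 1) stop("alphabet size q must be >= 1");
  if (imax < 0 || jmax < 0) stop("table bounds must be nonnegative");
  std::vector<double> P = build_P(q, imax, jmax);
  NumericMatrix M(imax + 1, jmax + 1);
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j) M(i, j) = P[(size_t)i * (jmax + 1) + j];
  return M;
}

// ---------------------------------------------------------------------------
// Probabilistic Beam Search.
// ---------------------------------------------------------------------------

struct Cand {
  IVec seq;
  IVec lam;
  long slam;   // sum of lambdas, used as tie-break
  double h;    // log heuristic value
};

struct PBSParams {
  int kw;        // beam width
  int kb;        // number of dominators
  double mu;     // probability of the linear-ranking branch
  int jmode;     // -1: j = max remaining length; >=0: fixed j
  long max_levels;  // 0: auto (total length + 1)
};

// Linear ranking (Baker): rank r in 1..N has weight N - r + 1.
// Returns a 0-based index into the ranked pool.
static size_t lr_draw(size_t N) {
  double tot = (double)N * (N + 1) / 2.0;
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t r = 0; r < N; ++r) {
    acc += (double)(N - r);
    if (u < acc) return r;
  }
  return N - 1;
}

// [[Rcpp::export]]
int lr_sample_cpp(int n) {
  if (n < 1) stop("empty pool");
  return (int)lr_draw((size_t)n) + 1;  // 1-based rank
}

// Runs PBS on strings S over an alphabet of size q. On success stores the
// constructed supersequence in `out` and returns true; returns false only
// if the level guard is exceeded (cannot happen for valid instances).
static bool run_pbs(const Strings& S, int q, const PBSParams& par, IVec& out) {
  const int m = (int)S.size();
  out.clear();
  if (m == 0) return true;  // vacuous instance
  int imax = 0;
  long total = 0;
  for (const IVec& s : S) {
    imax = std::max(imax, (int)s.size());
    total += (long)s.size();
  }
  if (imax == 0) return true;
  const int jmax = (par.jmode > imax) ? par.jmode : imax;
  std::vector<double> logP = build_P(q, imax, jmax);
  for (double& x : logP) x = std::log(x);
  const size_t w = jmax + 1;
  const std::vector<double>& LP = logP;

  // log heuristic of a lambda vector (Eq.-style product in log space)
  std::vector<int> len(m);
  for (int i = 0; i < m; ++i) len[i] = (int)S[i].size();
  const int jmode = par.jmode;
  auto heval = [&](const IVec& lam) -> double {
    int jj;
    if (jmode < 0) {
      jj = 0;
      for (int i = 0; i < m; ++i) jj = std::max(jj, len[i] - lam[i]);
    } else {
      jj = std::min(jmode, jmax);
    }
    double h = 0.0;
    for (int i = 0; i < m; ++i) {
      int r = len[i] - lam[i];
      if (r > jj) return R_NegInf;
      h += LP[(size_t)r * w + jj];
    }
    return h;
  };

  std::vector<Cand> beam(1);
  beam[0].lam.assign(m, 0);
  beam[0].slam = 0;
  const long maxlev = par.max_levels > 0 ? par.max_levels : total + 1;

  std::vector<Cand> children;
  std::vector<int> ord, pool;
  for (long level = 0; level < maxlev; ++level) {
    children.clear();
    for (const Cand& c : beam) {
      for (int a = 0; a < q; ++a) {
        bool contrib = false;
        for (int i = 0; i < m; ++i)
          if (c.lam[i] < len[i] && S[i][c.lam[i]] == a) { contrib = true; break; }
        if (!contrib) continue;
        Cand ch;
        ch.seq = c.seq;
        ch.seq.push_back(a);
        ch.lam = c.lam;
        ch.slam = c.slam;
        bool complete = true;
        for (int i = 0; i < m; ++i) {
          if (ch.lam[i] < len[i] && S[i][ch.lam[i]] == a) { ++ch.lam[i]; ++ch.slam; }
          if (ch.lam[i] < len[i]) complete = false;
        }
        if (complete) { out = ch.seq; return true; }  // first complete child wins
        children.push_back(std::move(ch));
      }
    }
    if (children.empty()) return false;
    for (Cand& ch : children) ch.h = heval(ch.lam);

    // rank: heuristic desc, then progress (sum lambda) desc, then insertion order
    const int N = (int)children.size();
    ord.resize(N);
    for (int i = 0; i < N; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (children[a].h != children[b].h) return children[a].h > children[b].h;
      return children[a].slam > children[b].slam;
    });

    const int d = std::min(par.kb, N);
    std::vector<Cand> nb;
    nb.reserve(par.kw);
    for (int k = 0; k < d && (int)nb.size() < par.kw; ++k)
      nb.push_back(children[ord[k]]);
    pool.assign(ord.begin() + d, ord.end());
    while ((int)nb.size() < par.kw && !pool.empty()) {
      size_t pos = 0;
      if (par.mu > 0.0 && unif_rand() < par.mu) pos = lr_draw(pool.size());
      const int ci = pool[pos];
      pool.erase(pool.begin() + pos);
      bool dominated = false;
      for (int k = 0; k < d && !dominated; ++k) {
        const IVec& dl = children[ord[k]].lam;
        bool ge = true;
        for (int i = 0; i < m; ++i)
          if (dl[i] < children[ci].lam[i]) { ge = false; break; }
        dominated = ge;
      }
      if (!dominated) nb.push_back(children[ci]);
    }
    if (nb.empty()) nb.push_back(children[ord[0]]);  // liveness guard
    beam.swap(nb);
  }
  return false;
}

// [[Rcpp::export]]
List pbs_solve_cpp(List strs, int q, int kw, int kb, double mu, int jmode,
                   double max_levels) {
  Strings S = as_strings(strs);
  PBSParams par{kw, kb, mu, jmode, (long)max_levels};
  IVec out;
  bool ok = run_pbs(S, q, par, out);
  return List::create(_["seq"] = IntegerVector(out.begin(), out.end()),
                      _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// Reduction local search: for each split z = prefix|suffix, re-solve the
// sub-instance of string prefixes not embedded by the suffix; replace the
// prefix when PBS finds a strictly shorter one, then restart the scan.
// ---------------------------------------------------------------------------

// prefix of s that is not part of the longest suffix of s embeddable in y
// (right-to-left greedy scan)
static IVec suffix_nonembedded_prefix(const IVec& s, const IVec& y) {
  int k = (int)s.size();
  for (int t = (int)y.size() - 1; t >= 0 && k > 0; --t)
    if (y[t] == s[k - 1]) --k;
  return IVec(s.begin(), s.begin() + k);
}

// [[Rcpp::export]]
IntegerVector suffix_split_cpp(IntegerVector s, IntegerVector y) {
  IVec sv(s.begin(), s.end()), yv(y.begin(), y.end());
  IVec p = suffix_nonembedded_prefix(sv, yv);
  return IntegerVector(p.begin(), p.end());
}

static double elapsed_since(const std::chrono::steady_clock::time_point& t0) {
  return std::chrono::duration<double>(std::chrono::steady_clock::now() - t0)
      .count();
}

// [[Rcpp::export]]
IntegerVector reduction_cpp(List strs, int q, IntegerVector z0, int kw, int kb,
                            double mu, int jmode, double time_budget) {
  Strings S = as_strings(strs);
  IVec z(z0.begin(), z0.end());
  const auto t0 = std::chrono::steady_clock::now();
  PBSParams par{kw, kb, mu, jmode, 0};
  bool improved = true;
  while (improved) {
    improved = false;
    const int L = (int)z.size();
    for (int p = 1; p <= L; ++p) {  // p == L: empty suffix, full re-solve
      if (time_budget > 0 && elapsed_since(t0) >= time_budget)
        return IntegerVector(z.begin(), z.end());
      Rcpp::checkUserInterrupt();
      IVec y(z.begin() + p, z.end());
      Strings sub;
      int maxk = 0;
      for (const IVec& s : S) {
        IVec pre = suffix_nonembedded_prefix(s, y);
        maxk = std::max(maxk, (int)pre.size());
        if (!pre.empty()) sub.push_back(std::move(pre));
      }
      if (maxk >= p) continue;  // any supersequence of sub has length >= maxk
      IVec w;
      if (!sub.empty() && !run_pbs(sub, q, par, w)) continue;
      if ((int)w.size() < p) {
        IVec nz = w;
        nz.insert(nz.end(), y.begin(), y.end());
        z.swap(nz);
        improved = true;
        break;  // restart scan from p = 1 on the improved solution
      }
    }
  }
  return IntegerVector(z.begin(), z.end());
}

// ---------------------------------------------------------------------------
// Perturbation local search: mutate one symbol, keep the prefix up to the
// mutation, repair the rest with PBS; accept only strict improvements.
// The repair randomness mu is ramped linearly from mu_start to mu_end.
// ---------------------------------------------------------------------------

static int lambda_of(const IVec& y, const IVec& s) {
  int k = 0, n = (int)s.size();
  for (size_t t = 0; t < y.size() && k < n; ++t)
    if (y[t] == s[k]) ++k;
  return k;
}

// [[Rcpp::export]]
IntegerVector perturbation_cpp(List strs, int q, IntegerVector z0,
                               int iterations, double mu_start, double mu_end,
                               int kw, int kb, int jmode, double time_budget) {
  Strings S = as_strings(strs);
  IVec z(z0.begin(), z0.end());
  if (q < 2 || z.empty()) return z0;  // no legal mutation exists
  const auto t0 = std::chrono::steady_clock::now();
  const double step =
      (mu_end - mu_start) / (double)std::max(1, iterations - 1);
  for (int k = 1; k <= iterations; ++k) {
    if (time_budget > 0 && elapsed_since(t0) >= time_budget) break;
    Rcpp::checkUserInterrupt();
    const double mu_k = mu_start + (double)(k - 1) * step;
    const int L = (int)z.size();
    int p = (int)(unif_rand() * L);
    if (p >= L) p = L - 1;
    int a = (int)(unif_rand() * (q - 1));
    if (a >= z[p]) ++a;  // uniform over symbols != z[p]
    IVec w(z.begin(), z.begin() + p + 1);
    w[p] = a;
    Strings sub;
    for (const IVec& s : S) {
      int lam = lambda_of(w, s);
      if (lam < (int)s.size()) sub.emplace_back(s.begin() + lam, s.end());
    }
    IVec rep;
    if (!sub.empty()) {
      PBSParams par{kw, kb, mu_k, jmode, 0};
      if (!run_pbs(sub, q, par, rep)) continue;
    }
    if ((int)w.size() + (int)rep.size() < L) {
      w.insert(w.end(), rep.begin(), rep.end());
      z.swap(w);
    }
  }
  return IntegerVector(z.begin(), z.end());
}

// ---------------------------------------------------------------------------
// Exact solver: breadth-first search over the product state space
// (state = vector of embedded-prefix lengths, one edge per alphabet symbol
// that advances at least one coordinate). BFS guarantees a minimum-length
// supersequence; symbols are tried in alphabet order for determinism.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List exact_scs_cpp(List strs, int q, double state_limit) {
  Strings S = as_strings(strs);
  const int m = (int)S.size();
  if (m == 0) return List::create(_["seq"] = IntegerVector(0), _["states"] = 1.0);
  std::vector<int64_t> len(m), mult(m);
  double nstates = 1.0;
  for (int i = 0; i < m; ++i) {
    len[i] = (int64_t)S[i].size();
    nstates *= (double)(len[i] + 1);
  }
  if (nstates > state_limit)
    stop("state space (%.0f states) exceeds state_limit (%.0f)", nstates,
         state_limit);
  const int64_t NS = (int64_t)(nstates + 0.5);
  int64_t acc = 1;
  for (int i = 0; i < m; ++i) {
    mult[i] = acc;
    acc *= (len[i] + 1);
  }
  const int64_t goal = NS - 1;
  if (goal == 0) return List::create(_["seq"] = IntegerVector(0), _["states"] = 1.0);

  std::vector<int64_t> parent(NS, -1);
  std::vector<int8_t> psym(NS, -1);
  std::vector<uint8_t> seen(NS, 0);
  std::deque<int64_t> Q;
  seen[0] = 1;
  Q.push_back(0);
  IVec lam(m);
  bool found = false;
  while (!Q.empty() && !found) {
    const int64_t st = Q.front();
    Q.pop_front();
    int64_t r = st;
    for (int i = 0; i < m; ++i) {
      lam[i] = (int)(r % (len[i] + 1));
      r /= (len[i] + 1);
    }
    for (int a = 0; a < q && !found; ++a) {
      int64_t nx = st;
      bool contrib = false;
      for (int i = 0; i < m; ++i)
        if (lam[i] < len[i] && S[i][lam[i]] == a) {
          nx += mult[i];
          contrib = true;
        }
      if (!contrib || seen[nx]) continue;
      seen[nx] = 1;
      parent[nx] = st;
      psym[nx] = (int8_t)a;
      if (nx == goal) found = true;
      else Q.push_back(nx);
    }
  }
  IVec out;
  for (int64_t cur = goal; cur != 0; cur = parent[cur]) out.push_back(psym[cur]);
  std::reverse(out.begin(), out.end());
  return List::create(_["seq"] = IntegerVector(out.begin(), out.end()),
                      _["states"] = (double)NS);
}
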