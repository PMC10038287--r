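// Core numerics for Sub-SAGE on tree ensembles.
//
// The ensemble arrives as a flat node table (see .flatten_ensemble() on the
// R side): per node a 0-based split feature (-1 for leaves), a threshold,
// global child indices, and a leaf value.  Routing is "left iff x < t",
// matching XGBoost JSON dumps; ties are unreachable for the intended use
// (thresholds fall strictly between integer genotype values).
//
// Traversal probabilities are estimated per node as empirical fractions of
// the supplied rows falling in the half-open interval implied by ancestor
// splits on the *same* feature (features are assumed independent, so splits
// on other features do not constrain the law of the current one).
//
// Conditional expectations: for a tree, the Algorithm-1 value of a row
// under a coalition depends only on (a) which of the tree's own features
// are in the coalition and (b) the row's branch decisions at the tree's
// internal nodes.  For small trees both are enumerable, so per-row values
// become table lookups; the branch decisions never change under bootstrap
// resampling, which makes replicates cheap.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Flat {
  std::vector<int> ptr;        // T+1 offsets into node arrays; root first per tree
  std::vector<int> feat;       // 0-based split feature, -1 for leaf
  std::vector<double> thr;
  std::vector<int> yes, no;    // global node indices, -1 for leaf
  std::vector<double> val;     // leaf value (0 for internal)
  int T() const { return static_cast<int>(ptr.size()) - 1; }
  int n_nodes() const { return static_cast<int>(feat.size()); }
};

Flat unpack(const List& flat) {
  Flat F;
  F.ptr  = as<std::vector<int>>(flat["ptr"]);
  F.feat = as<std::vector<int>>(flat["feature"]);
  F.thr  = as<std::vector<double>>(flat["threshold"]);
  F.yes  = as<std::vector<int>>(flat["yes"]);
  F.no   = as<std::vector<int>>(flat["no"]);
  F.val  = as<std::vector<double>>(flat["value"]);
  return F;
}

// Same-feature ancestor interval [lo, hi) for every internal node.
void bounds_rec(const Flat& F, int u,
                std::vector<std::array<double, 3>>& path,  // {feature, lo, hi}
                std::vector<double>& lo, std::vector<double>& hi) {
  if (u < 0 || F.feat[u] < 0) return;
  const int f = F.feat[u];
  const double t = F.thr[u];
  double l = -INFINITY, h = INFINITY;
  for (auto it = path.rbegin(); it != path.rend(); ++it) {
    if (static_cast<int>((*it)[0]) == f) { l = (*it)[1]; h = (*it)[2]; break; }
  }
  lo[u] = l;
  hi[u] = h;
  path.push_back({static_cast<double>(f), l, std::min(t, h)});
  bounds_rec(F, F.yes[u], path, lo, hi);
  path.back() = {static_cast<double>(f), std::max(l, t), h};
  bounds_rec(F, F.no[u], path, lo, hi);
  path.pop_back();
}

// Empirical traversal probabilities from the rows given (0-based indices).
// Zero-count intervals fall back to the unconditional marginal; an empty row
// set falls back to 0.5 per child.  Fallbacks are counted, not fatal.
void est_probs(const Flat& F, const NumericMatrix& X, const std::vector<int>& rows,
               std::vector<double>& pl, std::vector<double>& pr, int& nfall) {
  const int nn = F.n_nodes();
  std::vector<double> lo(nn, -INFINITY), hi(nn, INFINITY);
  for (int t = 0; t < F.T(); ++t) {
    std::vector<std::array<double, 3>> path;
    bounds_rec(F, F.ptr[t], path, lo, hi);
  }
  pl.assign(nn, NA_REAL);
  pr.assign(nn, NA_REAL);
  const int N = static_cast<int>(rows.size());
  const int nrow = X.nrow();
  const double* xp = X.begin();
  for (int u = 0; u < nn; ++u) {
    if (F.feat[u] < 0) continue;
    const double t = F.thr[u], l = lo[u], h = hi[u];
    const double* col = xp + static_cast<size_t>(F.feat[u]) * nrow;
    int denom = 0, numer = 0, totl = 0;
    for (int i = 0; i < N; ++i) {
      const double x = col[rows[i]];
      if (x < t) ++totl;
      if (x >= l && x < h) {
        ++denom;
        if (x < t) ++numer;
      }
    }
    double p;
    if (denom > 0) {
      p = static_cast<double>(numer) / denom;
    } else if (N > 0) {
      p = static_cast<double>(totl) / N;
      ++nfall;
    } else {
      p = 0.5;
      ++nfall;
    }
    pl[u] = p;
    pr[u] = 1.0 - p;
  }
}

// Static per-tree structure shared by all probability sets and samples.
struct Prep {
  std::vector<std::vector<int>> feats;    // per tree: sorted distinct features
  std::vector<std::vector<int>> inodes;   // per tree: internal nodes, ptr order
  std::vector<char> fast;                 // table path applicable?
  std::vector<std::vector<int>> trees_of_feat;
};

Prep prep_ensemble(const Flat& F, int M) {
  Prep P;
  const int T = F.T();
  P.feats.assign(T, {});
  P.inodes.assign(T, {});
  P.fast.assign(T, 0);
  P.trees_of_feat.assign(M, {});
  for (int t = 0; t < T; ++t) {
    std::vector<int>& fs = P.feats[t];
    for (int u = F.ptr[t]; u < F.ptr[t + 1]; ++u) {
      if (F.feat[u] >= 0) {
        P.inodes[t].push_back(u);
        fs.push_back(F.feat[u]);
      }
    }
    std::sort(fs.begin(), fs.end());
    fs.erase(std::unique(fs.begin(), fs.end()), fs.end());
    if (fs.size() > 12)
      stop("tree %d splits on %d distinct features; exact subset enumeration is capped at 12",
           t + 1, static_cast<int>(fs.size()));
    for (int f : fs) P.trees_of_feat[f].push_back(t);
    P.fast[t] = (fs.size() <= 8 && P.inodes[t].size() <= 10) ? 1 : 0;
  }
  return P;
}

// Branch decisions per (tree, base row): bit j set iff the row goes left
// ("yes") at the tree's j-th internal node.  Independent of probabilities,
// so computed once per data set.
std::vector<std::vector<std::uint16_t>> branch_idx(const Flat& F, const Prep& P,
                                                   const NumericMatrix& X,
                                                   const std::vector<int>& rows) {
  const int T = F.T(), n = static_cast<int>(rows.size()), nrow = X.nrow();
  const double* xp = X.begin();
  std::vector<std::vector<std::uint16_t>> bidx(T);
  for (int t = 0; t < T; ++t) {
    if (!P.fast[t]) continue;
    bidx[t].assign(n, 0);
    for (size_t j = 0; j < P.inodes[t].size(); ++j) {
      const int u = P.inodes[t][j];
      const double thr = F.thr[u];
      const double* col = xp + static_cast<size_t>(F.feat[u]) * nrow;
      const std::uint16_t bit = static_cast<std::uint16_t>(1u << j);
      std::uint16_t* bp = bidx[t].data();
      for (int i = 0; i < n; ++i)
        if (col[rows[i]] < thr) bp[i] |= bit;
    }
  }
  return bidx;
}

// Value of one tree for (coalition mask over the tree's features, branch
// combination b): resolved nodes route by their bit in b, unresolved nodes
// mix children with the traversal probabilities.
double tab_rec(const Flat& F, const Prep& P, const std::vector<double>& pl,
               const std::vector<double>& pr, int t, int u, unsigned mask,
               unsigned b) {
  const int f = F.feat[u];
  if (f < 0) return F.val[u];
  const std::vector<int>& fs = P.feats[t];
  const unsigned pos = static_cast<unsigned>(
      std::lower_bound(fs.begin(), fs.end(), f) - fs.begin());
  if ((mask >> pos) & 1u) {
    const std::vector<int>& in = P.inodes[t];
    const unsigned j = static_cast<unsigned>(
        std::find(in.begin(), in.end(), u) - in.begin());
    const int nxt = ((b >> j) & 1u) ? F.yes[u] : F.no[u];
    return tab_rec(F, P, pl, pr, t, nxt, mask, b);
  }
  return pl[u] * tab_rec(F, P, pl, pr, t, F.yes[u], mask, b) +
         pr[u] * tab_rec(F, P, pl, pr, t, F.no[u], mask, b);
}

// Row-level Algorithm-1 evaluation (general path for large trees).
double ev_pattern(const Flat& F, const std::vector<double>& pl,
                  const std::vector<double>& pr, int u, const NumericMatrix& X,
                  int row, const std::vector<int>& feats, unsigned mask) {
  const int f = F.feat[u];
  if (f < 0) return F.val[u];
  const unsigned pos = static_cast<unsigned>(
      std::lower_bound(feats.begin(), feats.end(), f) - feats.begin());
  if ((mask >> pos) & 1u) {
    const int nxt = X(row, f) < F.thr[u] ? F.yes[u] : F.no[u];
    return ev_pattern(F, pl, pr, nxt, X, row, feats, mask);
  }
  return pl[u] * ev_pattern(F, pl, pr, F.yes[u], X, row, feats, mask) +
         pr[u] * ev_pattern(F, pl, pr, F.no[u], X, row, feats, mask);
}

// Per-tree tables of conditional expectations for every subset of the
// tree's own split features, for a given sample of base positions.
struct VTab {
  std::vector<std::vector<std::vector<double>>> V;  // [tree][mask][sample i]
  int n = 0;
};

void build_vtab(const Flat& F, const Prep& P, const std::vector<double>& pl,
                const std::vector<double>& pr, const NumericMatrix& X,
                const std::vector<int>& base_rows,                 // global row ids
                const std::vector<std::vector<std::uint16_t>>& bidx,
                const std::vector<int>& pos,                        // positions into base_rows
                VTab& W) {
  const int T = F.T();
  const int n = static_cast<int>(pos.size());
  W.n = n;
  W.V.assign(T, {});
  for (int t = 0; t < T; ++t) {
    const unsigned PM = 1u << P.feats[t].size();
    W.V[t].assign(PM, std::vector<double>(n));
    if (P.fast[t]) {
      const unsigned NB = 1u << P.inodes[t].size();
      std::vector<double> tab(NB);
      const std::uint16_t* bp = bidx[t].data();
      for (unsigned m = 0; m < PM; ++m) {
        for (unsigned b = 0; b < NB; ++b)
          tab[b] = tab_rec(F, P, pl, pr, t, F.ptr[t], m, b);
        std::vector<double>& col = W.V[t][m];
        for (int i = 0; i < n; ++i) col[i] = tab[bp[pos[i]]];
      }
    } else {
      for (unsigned m = 0; m < PM; ++m) {
        std::vector<double>& col = W.V[t][m];
        for (int i = 0; i < n; ++i)
          col[i] = ev_pattern(F, pl, pr, F.ptr[t], X, base_rows[pos[i]],
                              P.feats[t], m);
      }
    }
  }
}

unsigned mask_of(const std::vector<int>& feats, std::initializer_list<int> sub) {
  unsigned m = 0;
  for (int f : sub) {
    const auto it = std::lower_bound(feats.begin(), feats.end(), f);
    if (it != feats.end() && *it == f)
      m |= 1u << static_cast<unsigned>(it - feats.begin());
  }
  return m;
}

inline double log1pexp_neg(double m) {  // log(1 + exp(-m)), overflow-safe
  if (m > 0) return std::log1p(std::exp(-m));
  return -m + std::log1p(std::exp(m));
}

// Decomposed squared-error delta  w(S u {k}) - w(S):
//   mean[ 2 y dA + A_S^2 - A_Sk^2 - 2 (C_S + offset) dA ],  dA = A_Sk - A_S,
// where A sums trees splitting on k and C the remaining trees.
double sq_delta(const std::vector<double>& y, const std::vector<double>& AS,
                const std::vector<double>& ASk, const std::vector<double>& CS,
                double off, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dA = ASk[i] - AS[i];
    s += 2.0 * y[i] * dA + AS[i] * AS[i] - ASk[i] * ASk[i] -
         2.0 * (CS[i] + off) * dA;
  }
  return s / n;
}

// Decomposed binary cross-entropy delta on the margin scale:
//   mean[ (1-y)(A_S - A_Sk) + log(1+e^{-m_S}) - log(1+e^{-m_Sk}) ],
// with m_. the full margin (all trees + offset).
double xent_delta(const std::vector<double>& y, const std::vector<double>& AS,
                  const std::vector<double>& ASk, const std::vector<double>& CS,
                  double off, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double mS = AS[i] + CS[i] + off;
    const double mSk = ASk[i] + CS[i] + off;
    s += (1.0 - y[i]) * (AS[i] - ASk[i]) + log1pexp_neg(mS) - log1pexp_neg(mSk);
  }
  return s / n;
}

// Sub-SAGE plug-in estimate for one focal feature, given the pattern
// tables.  Coalition family: empty set, every singleton {m}, m != k, and
// the all-but-k set, with closed-form weights 1/3, 1/(3(M-1)), 1/3.
void psi_one(const Flat& F, const Prep& P, const VTab& W,
             const std::vector<double>& y, int k, int M, double off, bool xent,
             double& psi, double& d_empty, std::vector<double>& d_single,
             double& d_all) {
  const int n = W.n, T = F.T();
  std::vector<char> in_tk(T, 0);
  for (int t : P.trees_of_feat[k]) in_tk[t] = 1;

  std::vector<double> A0(n, 0.0), Ak0(n, 0.0), C0(n, 0.0);
  for (int t = 0; t < T; ++t) {
    const std::vector<double>& V0 = W.V[t][0];
    if (in_tk[t]) {
      const std::vector<double>& Vk = W.V[t][mask_of(P.feats[t], {k})];
      for (int i = 0; i < n; ++i) {
        A0[i] += V0[i];
        Ak0[i] += Vk[i];
      }
    } else {
      for (int i = 0; i < n; ++i) C0[i] += V0[i];
    }
  }
  std::vector<double> dA0(n);
  for (int i = 0; i < n; ++i) dA0[i] = Ak0[i] - A0[i];

  d_empty = xent ? xent_delta(y, A0, Ak0, C0, off, n)
                 : sq_delta(y, A0, Ak0, C0, off, n);

  d_single.assign(M, NA_REAL);
  std::vector<double> AS, ASk, CS;
  for (int m = 0; m < M; ++m) {
    if (m == k) continue;
    const std::vector<int>& tm = P.trees_of_feat[m];
    if (tm.empty()) {  // feature never split on: {m} is indistinguishable from the empty set
      d_single[m] = d_empty;
      continue;
    }
    bool shared = false;
    for (int t : tm)
      if (in_tk[t]) { shared = true; break; }
    if (!shared && !xent) {
      // A-side unchanged; only the cross term moves:
      // delta({m}) = delta(empty) - (2/n) <c_m, dA0>
      double dot = 0.0;
      for (int t : tm) {
        const std::vector<double>& Vm = W.V[t][mask_of(P.feats[t], {m})];
        const std::vector<double>& V0 = W.V[t][0];
        for (int i = 0; i < n; ++i) dot += (Vm[i] - V0[i]) * dA0[i];
      }
      d_single[m] = d_empty - 2.0 * dot / n;
      continue;
    }
    AS = A0; ASk = Ak0; CS = C0;
    for (int t : tm) {
      const std::vector<double>& V0 = W.V[t][0];
      const std::vector<double>& Vm = W.V[t][mask_of(P.feats[t], {m})];
      if (in_tk[t]) {
        const std::vector<double>& Vk = W.V[t][mask_of(P.feats[t], {k})];
        const std::vector<double>& Vmk = W.V[t][mask_of(P.feats[t], {m, k})];
        for (int i = 0; i < n; ++i) {
          AS[i] += Vm[i] - V0[i];
          ASk[i] += Vmk[i] - Vk[i];
        }
      } else {
        for (int i = 0; i < n; ++i) CS[i] += Vm[i] - V0[i];
      }
    }
    d_single[m] = xent ? xent_delta(y, AS, ASk, CS, off, n)
                       : sq_delta(y, AS, ASk, CS, off, n);
  }

  AS.assign(n, 0.0); ASk.assign(n, 0.0); CS.assign(n, 0.0);
  for (int t = 0; t < T; ++t) {
    const unsigned full = (1u << P.feats[t].size()) - 1u;
    if (in_tk[t]) {
      const unsigned nok = full & ~mask_of(P.feats[t], {k});
      const std::vector<double>& Vs = W.V[t][nok];
      const std::vector<double>& Vf = W.V[t][full];
      for (int i = 0; i < n; ++i) {
        AS[i] += Vs[i];
        ASk[i] += Vf[i];
      }
    } else {
      const std::vector<double>& Vf = W.V[t][full];
      for (int i = 0; i < n; ++i) CS[i] += Vf[i];
    }
  }
  d_all = xent ? xent_delta(y, AS, ASk, CS, off, n)
               : sq_delta(y, AS, ASk, CS, off, n);

  const double w_end = 1.0 / 3.0;
  const double w_single = 1.0 / (3.0 * (M - 1));
  double ssum = 0.0;
  for (int m = 0; m < M; ++m)
    if (m != k) ssum += d_single[m];
  psi = w_end * d_empty + w_single * ssum + w_end * d_all;
}

std::vector<int> rows_from_R(const IntegerVector& rows) {
  std::vector<int> rr(rows.begin(), rows.end());
  for (int& r : rr) --r;
  return rr;
}

std::vector<int> iota_n(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

std::vector<double> y_at(const NumericVector& y, const std::vector<int>& base_rows,
                         const std::vector<int>& pos) {
  std::vector<double> ys(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) ys[i] = y[base_rows[pos[i]]];
  return ys;
}

// splitmix64: per-replicate counter-derived substreams for the bootstrap.
inline std::uint64_t sm64(std::uint64_t& s) {
  std::uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

}  // namespace

// [[Rcpp::export]]
List cpp_estimate_probs(List flat, NumericMatrix X, IntegerVector rows) {
  Flat F = unpack(flat);
  std::vector<int> rr = rows_from_R(rows);
  std::vector<double> pl, pr;
  int nfall = 0;
  est_probs(F, X, rr, pl, pr, nfall);
  return List::create(_["p_left"] = NumericVector(pl.begin(), pl.end()),
                      _["p_right"] = NumericVector(pr.begin(), pr.end()),
                      _["n_fallback"] = nfall);
}

// [[Rcpp::export]]
NumericVector cpp_margin(List flat, NumericMatrix X, double offset) {
  Flat F = unpack(flat);
  const int n = X.nrow();
  NumericVector out(n, offset);
  for (int t = 0; t < F.T(); ++t) {
    for (int i = 0; i < n; ++i) {
      int u = F.ptr[t];
      while (F.feat[u] >= 0)
        u = X(i, F.feat[u]) < F.thr[u] ? F.yes[u] : F.no[u];
      out[i] += F.val[u];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pattern_values(List flat, NumericVector p_left, NumericVector p_right,
                        NumericMatrix X, IntegerVector rows, int M) {
  Flat F = unpack(flat);
  Prep P = prep_ensemble(F, M);
  std::vector<int> rr = rows_from_R(rows);
  std::vector<double> pl(p_left.begin(), p_left.end());
  std::vector<double> pr(p_right.begin(), p_right.end());
  VTab W;
  build_vtab(F, P, pl, pr, X, rr, branch_idx(F, P, X, rr),
             iota_n(static_cast<int>(rr.size())), W);
  List out(F.T());
  for (int t = 0; t < F.T(); ++t) {
    const unsigned PM = 1u << P.feats[t].size();
    NumericMatrix V(W.n, PM);
    for (unsigned m = 0; m < PM; ++m)
      std::copy(W.V[t][m].begin(), W.V[t][m].end(), V.column(m).begin());
    IntegerVector fs(P.feats[t].begin(), P.feats[t].end());
    for (int j = 0; j < fs.size(); ++j) fs[j] += 1;  // back to 1-based
    out[t] = List::create(_["features"] = fs, _["values"] = V);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_subsage(List flat, NumericVector p_left, NumericVector p_right,
                 NumericMatrix X, NumericVector y, IntegerVector rows,
                 IntegerVector ks, int M, double offset, bool xent) {
  Flat F = unpack(flat);
  Prep P = prep_ensemble(F, M);
  std::vector<int> rr = rows_from_R(rows);
  std::vector<double> pl(p_left.begin(), p_left.end());
  std::vector<double> pr(p_right.begin(), p_right.end());
  const std::vector<int> pos = iota_n(static_cast<int>(rr.size()));
  VTab W;
  build_vtab(F, P, pl, pr, X, rr, branch_idx(F, P, X, rr), pos, W);
  std::vector<double> ys = y_at(y, rr, pos);
  List out(ks.size());
  for (int j = 0; j < ks.size(); ++j) {
    double psi, d_empty, d_all;
    std::vector<double> d_single;
    psi_one(F, P, W, ys, ks[j] - 1, M, offset, xent, psi, d_empty, d_single, d_all);
    out[j] = List::create(_["psi"] = psi, _["d_empty"] = d_empty,
                          _["d_single"] = NumericVector(d_single.begin(), d_single.end()),
                          _["d_all"] = d_all);
  }
  return out;
}

// Paired bootstrap (Algorithm 2): resample test rows with replacement,
// re-estimate every node probability on the resample, recompute the
// plug-in estimate; the fitted model itself is never touched.  Replicate b
// uses a substream derived from (seed, b) only, so replicates are
// reproducible independently of one another.
// [[Rcpp::export]]
NumericMatrix cpp_paired_bootstrap(List flat, NumericMatrix X, NumericVector y,
                                   IntegerVector rows, IntegerVector ks, int M,
                                   double offset, bool xent, int B, double seed) {
  Flat F = unpack(flat);
  Prep P = prep_ensemble(F, M);
  std::vector<int> rr = rows_from_R(rows);
  const int n = static_cast<int>(rr.size());
  const auto bidx = branch_idx(F, P, X, rr);
  const std::uint64_t seed64 = static_cast<std::uint64_t>(seed);
  NumericMatrix out(B, ks.size());
  std::vector<int> pos(n), boot_rows(n);
  std::vector<double> pl, pr;
  for (int b = 0; b < B; ++b) {
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
    std::uint64_t st = seed64 ^ (0xD2B74407B1CE6E93ULL * static_cast<std::uint64_t>(b + 1));
    for (int i = 0; i < n; ++i) {
      const double u = (sm64(st) >> 11) * (1.0 / 9007199254740992.0);
      pos[i] = static_cast<int>(u * n);
      boot_rows[i] = rr[pos[i]];
    }
    int nfall = 0;
    est_probs(F, X, boot_rows, pl, pr, nfall);
    VTab W;
    build_vtab(F, P, pl, pr, X, rr, bidx, pos, W);
    std::vector<double> ys = y_at(y, rr, pos);
    for (int j = 0; j < ks.size(); ++j) {
      double psi, d_empty, d_all;
      std::vector<double> d_single;
      psi_one(F, P, W, ys, ks[j] - 1, M, offset, xent, psi, d_empty, d_single, d_all);
      out(b, j) = psi;
    }
  }
  return out;
}

// Leave-one-out estimates of psi_k over the test rows (for the BCa
// acceleration constant); probabilities are re-estimated for every
// leave-one-out sample, mirroring the plug-in estimator exactly.
// [[Rcpp::export]]
NumericVector cpp_jackknife_psi(List flat, NumericMatrix X, NumericVector y,
                                IntegerVector rows, int k, int M, double offset,
                                bool xent) {
  Flat F = unpack(flat);
  Prep P = prep_ensemble(F, M);
  std::vector<int> rr = rows_from_R(rows);
  const int n = static_cast<int>(rr.size());
  const auto bidx = branch_idx(F, P, X, rr);
  NumericVector out(n);
  std::vector<int> pos(n - 1), loo_rows(n - 1);
  std::vector<double> pl, pr;
  for (int i = 0; i < n; ++i) {
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
    int p = 0;
    for (int j = 0; j < n; ++j) {
      if (j != i) {
        pos[p] = j;
        loo_rows[p] = rr[j];
        ++p;
      }
    }
    int nfall = 0;
    est_probs(F, X, loo_rows, pl, pr, nfall);
    VTab W;
    build_vtab(F, P, pl, pr, X, rr, bidx, pos, W);
    std::vector<double> ys = y_at(y, rr, pos);
    double psi, d_empty, d_all;
    std::vector<double> d_single;
    psi_one(F, P, W, ys, k - 1, M, offset, xent, psi, d_empty, d_single, d_all);
    out[i] = psi;
  }
  return out;
}
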