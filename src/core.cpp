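#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Canonical triad-type order (Holland-Leinhardt MAN labels):
//  0:003 1:012 2:102 3:021D 4:021U 5:021C 6:111D 7:111U
//  8:030T 9:030C 10:201 11:120D 12:120U 13:120C 14:210 15:300
// Orientation convention: 021D = one sender to two receivers (A<-B->C),
// 021U = two senders to one receiver (A->B<-C), 111D = asymmetric arc points
// into the mutual dyad (A<->B<-C), 120D/120U analogous to 021D/021U with the
// remaining dyad mutual.

namespace {

int lut64[64];
bool lut_ready = false;

void decode(int code, int y[3][3]) {
  y[0][0] = y[1][1] = y[2][2] = 0;
  y[0][1] = code & 1;        y[1][0] = (code >> 1) & 1;
  y[0][2] = (code >> 2) & 1; y[2][0] = (code >> 3) & 1;
  y[1][2] = (code >> 4) & 1; y[2][1] = (code >> 5) & 1;
}

int classify3(const int y[3][3]) {
  static const int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  int M = 0, A = 0;
  int at[3], ah[3], na = 0;   // asymmetric arc tails/heads
  int mp[3][2], nm = 0;       // mutual dyads
  for (int d = 0; d < 3; ++d) {
    int a = pairs[d][0], b = pairs[d][1];
    int f = y[a][b], r = y[b][a];
    if (f && r)      { mp[nm][0] = a; mp[nm][1] = b; ++nm; ++M; }
    else if (f)      { at[na] = a; ah[na] = b; ++na; ++A; }
    else if (r)      { at[na] = b; ah[na] = a; ++na; ++A; }
  }
  if (M == 3) return 15;                    // 300
  if (M == 2) return A == 1 ? 14 : 10;      // 210 : 201
  if (M == 1) {
    if (A == 0) return 2;                   // 102
    if (A == 1) {
      bool head_in = (ah[0] == mp[0][0] || ah[0] == mp[0][1]);
      return head_in ? 6 : 7;               // 111D : 111U
    }
    if (at[0] == at[1]) return 11;          // 120D (common sender)
    if (ah[0] == ah[1]) return 12;          // 120U (common receiver)
    return 13;                              // 120C
  }
  if (A == 0) return 0;                     // 003
  if (A == 1) return 1;                     // 012
  if (A == 2) {
    if (at[0] == at[1]) return 3;           // 021D
    if (ah[0] == ah[1]) return 4;           // 021U
    return 5;                               // 021C
  }
  // A == 3: cycle iff the three tails are distinct
  if (at[0] != at[1] && at[0] != at[2] && at[1] != at[2]) return 9;  // 030C
  return 8;                                 // 030T
}

void build_lut() {
  if (lut_ready) return;
  int y[3][3];
  for (int c = 0; c < 64; ++c) { decode(c, y); lut64[c] = classify3(y); }
  lut_ready = true;
}

inline int code_of(const IntegerMatrix& A, int a, int b, int c) {
  return A(a, b) | (A(b, a) << 1) | (A(a, c) << 2) |
         (A(c, a) << 3) | (A(b, c) << 4) | (A(c, b) << 5);
}

inline void sort3(int& a, int& b, int& c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
}

// Mutable network state with incremental census, degree and arc-list upkeep.
struct Net {
  int n, m;
  IntegerMatrix adj;
  std::array<long, 16> census;
  std::vector<int> arcs, nonarcs;  // encoded positions i*n + j, i != j
  std::vector<int> pos;            // index of position p in its current list
  std::vector<int> indeg, outdeg;
  long mutual2;                    // ordered pairs (i,j) with both arcs
};

Net make_net(const IntegerMatrix& a0) {
  build_lut();
  Net N;
  N.n = a0.nrow();
  N.adj = clone(a0);
  N.m = 0;
  N.mutual2 = 0;
  N.indeg.assign(N.n, 0);
  N.outdeg.assign(N.n, 0);
  N.pos.assign(N.n * N.n, -1);
  N.census.fill(0);
  for (int a = 0; a < N.n - 2; ++a)
    for (int b = a + 1; b < N.n - 1; ++b)
      for (int c = b + 1; c < N.n; ++c)
        N.census[lut64[code_of(N.adj, a, b, c)]]++;
  for (int i = 0; i < N.n; ++i)
    for (int j = 0; j < N.n; ++j) {
      if (i == j) continue;
      int p = i * N.n + j;
      if (N.adj(i, j)) {
        N.arcs.push_back(p);
        N.pos[p] = (int)N.arcs.size() - 1;
        ++N.m; ++N.outdeg[i]; ++N.indeg[j];
        if (N.adj(j, i)) ++N.mutual2;
      } else {
        N.nonarcs.push_back(p);
        N.pos[p] = (int)N.nonarcs.size() - 1;
      }
    }
  return N;
}

void list_move(Net& N, int p, int newv) {
  std::vector<int>& from = newv ? N.nonarcs : N.arcs;
  std::vector<int>& to   = newv ? N.arcs : N.nonarcs;
  int idx = N.pos[p];
  int last = from.back();
  from[idx] = last;
  N.pos[last] = idx;
  from.pop_back();
  to.push_back(p);
  N.pos[p] = (int)to.size() - 1;
}

void toggle(Net& N, int i, int j) {
  int newv = 1 - N.adj(i, j);
  for (int k = 0; k < N.n; ++k) {
    if (k == i || k == j) continue;
    int a = i, b = j, c = k;
    sort3(a, b, c);
    N.census[lut64[code_of(N.adj, a, b, c)]]--;
  }
  N.adj(i, j) = newv;
  for (int k = 0; k < N.n; ++k) {
    if (k == i || k == j) continue;
    int a = i, b = j, c = k;
    sort3(a, b, c);
    N.census[lut64[code_of(N.adj, a, b, c)]]++;
  }
  int d = newv ? 1 : -1;
  N.m += d;
  N.outdeg[i] += d;
  N.indeg[j] += d;
  if (N.adj(j, i)) N.mutual2 += 2 * d;
  list_move(N, i * N.n + j, newv);
}

// Directed three-trails: walks of length 3 with distinct arcs.
double three_trails(const Net& N) {
  double tot = 0;
  for (size_t q = 0; q < N.arcs.size(); ++q) {
    int p = N.arcs[q];
    int b = p / N.n, c = p % N.n;
    tot += (double)N.indeg[b] * (double)N.outdeg[c];
  }
  return tot - (double)N.mutual2;
}

// Statistic ids: 1..16 triad types (canonical order), 17 three-paths, 18 edges.
void get_stats(const Net& N, const IntegerVector& ids, std::vector<double>& g) {
  for (int t = 0; t < ids.size(); ++t) {
    int id = ids[t];
    if (id <= 16) g[t] = (double)N.census[id - 1];
    else if (id == 17) g[t] = three_trails(N);
    else g[t] = (double)N.m;
  }
}

double sqdist(const std::vector<double>& g, const NumericVector& target) {
  double s = 0;
  for (int t = 0; t < target.size(); ++t) {
    double d = g[t] - target[t];
    s += d * d;
  }
  return s;
}

inline int runif_int(int k) {  // uniform on 0..k-1
  int r;
  do { r = (int)(unif_rand() * k); } while (r >= k);
  return r;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_triad_code_table() {
  build_lut();
  return IntegerVector(lut64, lut64 + 64);
}

// [[Rcpp::export]]
IntegerVector cpp_triad_census(const IntegerMatrix& adj) {
  build_lut();
  int n = adj.nrow();
  IntegerVector out(16);
  for (int a = 0; a < n - 2; ++a)
    for (int b = a + 1; b < n - 1; ++b)
      for (int c = b + 1; c < n; ++c)
        out[lut64[code_of(adj, a, b, c)]]++;
  return out;
}

// [[Rcpp::export]]
double cpp_three_paths(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<int> indeg(n, 0), outdeg(n, 0);
  long mut = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) {
        ++outdeg[i]; ++indeg[j];
        if (adj(j, i)) ++mut;
      }
  double tot = 0;
  for (int b = 0; b < n; ++b)
    for (int c = 0; c < n; ++c)
      if (adj(b, c)) tot += (double)indeg[b] * (double)outdeg[c];
  return tot - (double)mut;
}

// Strict variant: the four units must be pairwise distinct.
// [[Rcpp::export]]
double cpp_three_paths_strict(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<int> indeg(n, 0), outdeg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) { ++outdeg[i]; ++indeg[j]; }
  double tot = 0;
  for (int b = 0; b < n; ++b)
    for (int c = 0; c < n; ++c) {
      if (!adj(b, c)) continue;
      // a -> b -> c -> d with a != c, d != b; subtract a == d cases
      double na = indeg[b] - adj(c, b);
      double nd = outdeg[c] - adj(c, b);
      double both = 0;  // x with c -> x -> b, x not in {b, c}
      for (int x = 0; x < n; ++x)
        if (x != b && x != c && adj(c, x) && adj(x, b)) ++both;
      tot += na * nd - both;
    }
  return tot;
}

// Relocating-links generator: each iteration swaps a uniformly chosen arc
// with a uniformly chosen non-arc; the swap is kept iff the squared distance
// between the statistic vector and the target strictly decreases (CR > 1).
// [[Rcpp::export]]
List cpp_rl(const IntegerMatrix& adj0, const IntegerVector& stat_ids,
            const NumericVector& target, int iters) {
  Net N = make_net(adj0);
  if (N.arcs.empty() || N.nonarcs.empty())
    stop("initial network must have at least one arc and one non-arc");
  int g = stat_ids.size();
  std::vector<double> gv(g);
  get_stats(N, stat_ids, gv);
  double dcur = sqdist(gv, target);
  NumericVector cr(iters);
  LogicalVector acc(iters);
  for (int it = 0; it < iters; ++it) {
    int pa = N.arcs[runif_int((int)N.arcs.size())];
    int pn = N.nonarcs[runif_int((int)N.nonarcs.size())];
    int i = pa / N.n, j = pa % N.n;
    int k = pn / N.n, l = pn % N.n;
    toggle(N, i, j);   // remove arc
    toggle(N, k, l);   // add non-arc
    get_stats(N, stat_ids, gv);
    double dprop = sqdist(gv, target);
    double ratio;
    if (dprop == 0.0) ratio = (dcur == 0.0) ? 1.0 : R_PosInf;
    else ratio = dcur / dprop;
    cr[it] = ratio;
    if (ratio > 1.0) {
      dcur = dprop;
      acc[it] = true;
    } else {
      toggle(N, k, l);
      toggle(N, i, j);
      acc[it] = false;
    }
  }
  return List::create(_["adjacency"] = N.adj, _["cr"] = cr,
                      _["accepted"] = acc, _["distance"] = dcur);
}

// Fixed-coefficient ERGM Metropolis-Hastings sampler. Proposals are symmetric:
// free mode toggles a uniform ordered dyad, fixed mode swaps a uniform arc
// with a uniform non-arc (conserving the arc count). Acceptance probability
// min{1, exp(theta . (g(proposal) - g(current)))}.
// When thin > 0 and n <= 5, the bit-encoded state is recorded every `thin`
// iterations (used for exact stationary-distribution checks).
// [[Rcpp::export]]
List cpp_ergm(const IntegerMatrix& adj0, const IntegerVector& stat_ids,
              const NumericVector& theta, int iters, bool fixed_density,
              int thin = 0) {
  Net N = make_net(adj0);
  if (fixed_density && (N.arcs.empty() || N.nonarcs.empty()))
    stop("fixed-density sampling needs at least one arc and one non-arc");
  int g = stat_ids.size();
  std::vector<double> gcur(g), gprop(g);
  get_stats(N, stat_ids, gcur);
  bool record = thin > 0 && N.n <= 5;
  std::vector<int> states;
  if (record) states.reserve(iters / thin + 1);
  for (int it = 0; it < iters; ++it) {
    int i, j, k = -1, l = -1;
    if (fixed_density) {
      int pa = N.arcs[runif_int((int)N.arcs.size())];
      int pn = N.nonarcs[runif_int((int)N.nonarcs.size())];
      i = pa / N.n; j = pa % N.n;
      k = pn / N.n; l = pn % N.n;
      toggle(N, i, j);
      toggle(N, k, l);
    } else {
      int r = runif_int(N.n * (N.n - 1));
      i = r / (N.n - 1);
      int jr = r % (N.n - 1);
      j = jr + (jr >= i ? 1 : 0);
      toggle(N, i, j);
    }
    get_stats(N, stat_ids, gprop);
    double lp = 0;
    for (int t = 0; t < g; ++t) lp += theta[t] * (gprop[t] - gcur[t]);
    bool accept = (lp >= 0) || (log(unif_rand()) < lp);
    if (accept) {
      gcur = gprop;
    } else {
      if (fixed_density) { toggle(N, k, l); }
      toggle(N, i, j);
    }
    if (record && ((it + 1) % thin == 0)) {
      int code = 0, bit = 0;
      for (int a = 0; a < N.n; ++a)
        for (int b = 0; b < N.n; ++b) {
          if (a == b) continue;
          if (N.adj(a, b)) code |= (1 << bit);
          ++bit;
        }
      states.push_back(code);
    }
  }
  return List::create(_["adjacency"] = N.adj,
                      _["states"] = IntegerVector(states.begin(), states.end()));
}

namespace {

long block_errors(const std::vector<long>& a, const std::vector<int>& size,
                  const IntegerMatrix& image, int K) {
  long P = 0;
  for (int r = 0; r < K; ++r)
    for (int s = 0; s < K; ++s) {
      long poss = (long)size[r] * size[s] - (r == s ? size[r] : 0);
      long cnt = a[r * K + s];
      P += image(r, s) ? (poss - cnt) : cnt;
    }
  return P;
}

}  // namespace

// Pre-specified blockmodeling under structural equivalence: restarts of
// steepest-descent local search over single-unit moves and pairwise
// exchanges, minimizing the count of inconsistencies with the block image.
// [[Rcpp::export]]
List cpp_fit(const IntegerMatrix& adj, const IntegerMatrix& image,
             int restarts) {
  int n = adj.nrow(), K = image.nrow();
  if (n < K) stop("fewer units than clusters");
  std::vector<int> part(n), best_part(n);
  long bestP = -1;
  NumericVector restartP(restarts);

  std::vector<long> a(K * K), tmp(K * K);
  std::vector<int> size(K), tsize(K);
  std::vector<int> OU(n * K), IU(n * K);

  for (int rs = 0; rs < restarts; ++rs) {
    // uniform random partition with non-empty clusters
    for (;;) {
      std::fill(size.begin(), size.end(), 0);
      for (int u = 0; u < n; ++u) { part[u] = runif_int(K); ++size[part[u]]; }
      bool ok = true;
      for (int c = 0; c < K; ++c) if (!size[c]) { ok = false; break; }
      if (ok) break;
    }
    std::fill(a.begin(), a.end(), 0L);
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v)
        if (adj(u, v)) ++a[part[u] * K + part[v]];
    long P = block_errors(a, size, image, K);

    bool improved = true;
    while (improved && P > 0) {
      improved = false;
      // per-unit arc counts to/from each cluster under the current partition
      std::fill(OU.begin(), OU.end(), 0);
      std::fill(IU.begin(), IU.end(), 0);
      for (int u = 0; u < n; ++u)
        for (int v = 0; v < n; ++v)
          if (adj(u, v)) { ++OU[u * K + part[v]]; ++IU[v * K + part[u]]; }

      // candidates: (type 0) move u to cluster s, (type 1) exchange u and v
      std::vector<std::array<int, 3>> cand;
      for (int u = 0; u < n; ++u)
        for (int s = 0; s < K; ++s)
          if (s != part[u]) cand.push_back({0, u, s});
      for (int u = 0; u < n - 1; ++u)
        for (int v = u + 1; v < n; ++v)
          if (part[u] != part[v]) cand.push_back({1, u, v});
      for (int q = (int)cand.size() - 1; q > 0; --q)
        std::swap(cand[q], cand[runif_int(q + 1)]);

      long bestd = 0;
      int besti = -1;
      for (int q = 0; q < (int)cand.size(); ++q) {
        int u = cand[q][1];
        long Pq;
        if (cand[q][0] == 0) {
          int s = cand[q][2], r = part[u];
          if (size[r] == 1) continue;  // would empty a cluster
          tmp = a;
          tsize = size;
          for (int c = 0; c < K; ++c) {
            tmp[r * K + c] -= OU[u * K + c];
            tmp[s * K + c] += OU[u * K + c];
            tmp[c * K + r] -= IU[u * K + c];
            tmp[c * K + s] += IU[u * K + c];
          }
          --tsize[r]; ++tsize[s];
          Pq = block_errors(tmp, tsize, image, K);
        } else {
          int v = cand[q][2], r = part[u], s = part[v];
          tmp = a;
          for (int c = 0; c < K; ++c) {
            tmp[r * K + c] -= OU[u * K + c];
            tmp[s * K + c] += OU[u * K + c];
            tmp[c * K + r] -= IU[u * K + c];
            tmp[c * K + s] += IU[u * K + c];
          }
          for (int c = 0; c < K; ++c) {
            int ov = OU[v * K + c], iv = IU[v * K + c];
            if (c == r) { ov -= adj(v, u); iv -= adj(u, v); }
            if (c == s) { ov += adj(v, u); iv += adj(u, v); }
            tmp[s * K + c] -= ov;
            tmp[r * K + c] += ov;
            tmp[c * K + s] -= iv;
            tmp[c * K + r] += iv;
          }
          Pq = block_errors(tmp, size, image, K);
        }
        if (Pq - P < bestd) { bestd = Pq - P; besti = q; }
      }
      if (besti >= 0) {
        if (cand[besti][0] == 0) {
          part[cand[besti][1]] = cand[besti][2];
        } else {
          std::swap(part[cand[besti][1]], part[cand[besti][2]]);
        }
        std::fill(size.begin(), size.end(), 0);
        for (int u = 0; u < n; ++u) ++size[part[u]];
        std::fill(a.begin(), a.end(), 0L);
        for (int u = 0; u < n; ++u)
          for (int v = 0; v < n; ++v)
            if (adj(u, v)) ++a[part[u] * K + part[v]];
        P = block_errors(a, size, image, K);
        improved = true;
      }
    }
    restartP[rs] = (double)P;
    if (bestP < 0 || P < bestP) { bestP = P; best_part = part; }
  }
  IntegerVector out(n);
  for (int u = 0; u < n; ++u) out[u] = best_part[u] + 1;
  return List::create(_["partition"] = out, _["criterion"] = (double)bestP,
                      _["restart_values"] = restartP);
}
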