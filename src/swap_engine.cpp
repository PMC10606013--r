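// Swap engine for hyperedge-swapping null models.
//
// All six generators perturb the binary incidence matrix in place, one
// candidate swap at a time, each under its own eligibility rule; an accepted
// swap never empties a hyperedge and never drops a node to hyperdegree 0,
// so the hypergraph invariants (non-empty hyperedges, full node coverage)
// hold at every observable point. Randomness comes from R's RNG (unif_rand),
// so set.seed() at the R level makes generation reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

enum Outcome { ACC = 0, REJ_EQUAL, REJ_EMPTY, REJ_MEMBER, REJ_CC };

// models
enum Model { H0K = 0, H1K_HD, H1K_HED, HD_HED, H2K, H2_25K };

inline int ri(int k) {
  int x = static_cast<int>(unif_rand() * k);
  return x >= k ? k - 1 : x;
}

struct Engine {
  int n, m;
  std::vector<std::vector<int> > members; // member node ids per hyperedge
  std::vector<char> inc;                  // column-major n x m
  std::vector<int> rowdeg;
  bool trackA;                            // maintain pair counts (H2.25k)
  std::vector<int> A;                     // n x n co-membership counts

  void init(const IntegerMatrix& C, bool track_pairs) {
    n = C.nrow();
    m = C.ncol();
    trackA = track_pairs;
    inc.assign(static_cast<size_t>(n) * m, 0);
    rowdeg.assign(n, 0);
    members.assign(m, std::vector<int>());
    if (trackA) A.assign(static_cast<size_t>(n) * n, 0);
    for (int c = 0; c < m; ++c) {
      for (int r = 0; r < n; ++r) {
        if (C(r, c) != 0) {
          inc[static_cast<size_t>(c) * n + r] = 1;
          members[c].push_back(r);
          rowdeg[r]++;
        }
      }
      if (trackA) {
        const std::vector<int>& mem = members[c];
        for (size_t a = 0; a < mem.size(); ++a)
          for (size_t b = a + 1; b < mem.size(); ++b) {
            A[static_cast<size_t>(mem[a]) * n + mem[b]]++;
            A[static_cast<size_t>(mem[b]) * n + mem[a]]++;
          }
      }
    }
  }

  inline char get(int r, int c) const {
    return inc[static_cast<size_t>(c) * n + r];
  }

  void bumpA(int u, const std::vector<int>& others, int delta) {
    for (size_t i = 0; i < others.size(); ++i) {
      int w = others[i];
      if (w == u) continue;
      A[static_cast<size_t>(u) * n + w] += delta;
      A[static_cast<size_t>(w) * n + u] += delta;
    }
  }

  void add_member(int r, int c) {
    if (trackA) bumpA(r, members[c], +1);
    inc[static_cast<size_t>(c) * n + r] = 1;
    members[c].push_back(r);
    rowdeg[r]++;
  }

  void remove_member(int r, int c) {
    std::vector<int>& v = members[c];
    v.erase(std::find(v.begin(), v.end(), r));
    inc[static_cast<size_t>(c) * n + r] = 0;
    rowdeg[r]--;
    if (trackA) bumpA(r, v, -1);
  }

  // mean local clustering of the unweighted projection; nodes with fewer
  // than two neighbors contribute 0 and the mean is over all n nodes
  double mean_clustering() const {
    std::vector<int> nb;
    nb.reserve(n);
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      nb.clear();
      const int* Ai = &A[static_cast<size_t>(i) * n];
      for (int j = 0; j < n; ++j)
        if (j != i && Ai[j] > 0) nb.push_back(j);
      const int d = static_cast<int>(nb.size());
      if (d < 2) continue;
      long links = 0;
      for (int a = 0; a < d; ++a) {
        const int* Aa = &A[static_cast<size_t>(nb[a]) * n];
        for (int b = a + 1; b < d; ++b)
          if (Aa[nb[b]] > 0) ++links;
      }
      total += 2.0 * static_cast<double>(links) / (static_cast<double>(d) * (d - 1));
    }
    return total / n;
  }
};

// Rows are sampled uniformly among the entry pairs that pass the
// distinct-values eligibility test for the chosen columns (the proposal
// chain conditioned on that test); a column pair admitting no eligible
// pair is logged as an equal-entries rejection.

// pick a uniformly random row whose entry in column c is 0; the caller
// guarantees at least one exists, and incidence is sparse so rejection
// sampling terminates quickly
inline int random_nonmember(const Engine& E, int c) {
  for (;;) {
    int r = ri(E.n);
    if (!E.get(r, c)) return r;
  }
}

// H0k: two random columns, then one random (1-entry, 0-entry) pair across
// them; the membership moves between hyperedges. Preserves n, m and the
// total membership count (hence the mean hyperdegree).
int try_h0k(Engine& E) {
  if (E.m < 2) return REJ_EQUAL;
  int c1 = ri(E.m), c2 = ri(E.m);
  while (c2 == c1) c2 = ri(E.m);
  // eligible pairs with the 1 in c1 vs the 1 in c2
  const double s1 = static_cast<double>(E.members[c1].size());
  const double s2 = static_cast<double>(E.members[c2].size());
  const double n1 = s1 * (E.n - s2), n2 = s2 * (E.n - s1);
  if (n1 + n2 <= 0) return REJ_EQUAL;
  int cs, cg;
  if (unif_rand() * (n1 + n2) < n1) { cs = c1; cg = c2; }
  else                              { cs = c2; cg = c1; }
  const std::vector<int>& mem = E.members[cs];
  int rs = mem[ri(static_cast<int>(mem.size()))];
  int rg = random_nonmember(E, cg);
  if (static_cast<int>(E.members[cs].size()) == 1) return REJ_EMPTY;
  if (rs != rg && E.rowdeg[rs] == 1) return REJ_EMPTY; // node would be uncovered
  E.remove_member(rs, cs);
  E.add_member(rg, cg);
  return ACC;
}

// H1k-HD: two random columns, one random row where their entries differ
// (the symmetric difference of the two member sets); swapping the entries
// moves the node between the hyperedges. Row sums (hyperdegrees) untouched.
int try_h1k_hd(Engine& E) {
  if (E.m < 2) return REJ_EQUAL;
  int c1 = ri(E.m), c2 = ri(E.m);
  while (c2 == c1) c2 = ri(E.m);
  std::vector<int> diff;
  for (size_t i = 0; i < E.members[c1].size(); ++i)
    if (!E.get(E.members[c1][i], c2)) diff.push_back(E.members[c1][i]);
  const size_t only1 = diff.size();
  for (size_t i = 0; i < E.members[c2].size(); ++i)
    if (!E.get(E.members[c2][i], c1)) diff.push_back(E.members[c2][i]);
  if (diff.empty()) return REJ_EQUAL;
  size_t k = static_cast<size_t>(ri(static_cast<int>(diff.size())));
  int r = diff[k];
  int cs = k < only1 ? c1 : c2, cg = k < only1 ? c2 : c1;
  if (static_cast<int>(E.members[cs].size()) == 1) return REJ_EMPTY;
  E.remove_member(r, cs);
  E.add_member(r, cg);
  return ACC;
}

// H1k-HED: one random column, one random (member, non-member) row pair in
// it; the member is replaced by the non-member. Column sums (hyperedge
// degrees) untouched; the leaving node must keep hyperdegree >= 1.
int try_h1k_hed(Engine& E) {
  int c = ri(E.m);
  const std::vector<int>& mem = E.members[c];
  if (static_cast<int>(mem.size()) >= E.n) return REJ_EQUAL; // no non-member
  int rs = mem[ri(static_cast<int>(mem.size()))];
  int rg = random_nonmember(E, c);
  if (E.rowdeg[rs] == 1) return REJ_EMPTY;
  E.remove_member(rs, c);
  E.add_member(rg, c);
  return ACC;
}

// HD-HED: checkerboard swap of a 2x2 submatrix [[1,0],[0,1]] <-> [[0,1],[1,0]]
// across two random columns, with the rows drawn uniformly from the two
// one-sided member sets; preserves every row and column sum.
int try_hd_hed(Engine& E) {
  if (E.m < 2 || E.n < 2) return REJ_EQUAL;
  int c1 = ri(E.m), c2 = ri(E.m);
  while (c2 == c1) c2 = ri(E.m);
  std::vector<int> s1, s2; // rows with (1,0) and with (0,1)
  for (size_t i = 0; i < E.members[c1].size(); ++i)
    if (!E.get(E.members[c1][i], c2)) s1.push_back(E.members[c1][i]);
  for (size_t i = 0; i < E.members[c2].size(); ++i)
    if (!E.get(E.members[c2][i], c1)) s2.push_back(E.members[c2][i]);
  if (s1.empty() || s2.empty()) return REJ_EQUAL;
  int r1 = s1[ri(static_cast<int>(s1.size()))];
  int r2 = s2[ri(static_cast<int>(s2.size()))];
  E.remove_member(r1, c1); E.add_member(r1, c2);
  E.remove_member(r2, c2); E.add_member(r2, c1);
  return ACC;
}

// H2k node selection: one non-common node from each of two random hyperedges;
// eligible when the two nodes have equal hyperdegree. Exchanging them keeps
// the hyperdegree vector and every per-hyperedge hyperdegree multiset fixed.
int select_h2k(Engine& E, int& u, int& v, int& c1, int& c2) {
  if (E.m < 2) return REJ_EQUAL;
  c1 = ri(E.m); c2 = ri(E.m);
  while (c2 == c1) c2 = ri(E.m);
  std::vector<int> uc, vc;
  for (size_t i = 0; i < E.members[c1].size(); ++i)
    if (!E.get(E.members[c1][i], c2)) uc.push_back(E.members[c1][i]);
  for (size_t i = 0; i < E.members[c2].size(); ++i)
    if (!E.get(E.members[c2][i], c1)) vc.push_back(E.members[c2][i]);
  if (uc.empty() || vc.empty()) return REJ_MEMBER;
  u = uc[ri(static_cast<int>(uc.size()))];
  v = vc[ri(static_cast<int>(vc.size()))];
  if (E.rowdeg[u] != E.rowdeg[v]) return REJ_MEMBER;
  return ACC;
}

int try_h2k(Engine& E) {
  int u, v, c1, c2;
  int rc = select_h2k(E, u, v, c1, c2);
  if (rc != ACC) return rc;
  E.remove_member(u, c1); E.add_member(u, c2);
  E.remove_member(v, c2); E.add_member(v, c1);
  return ACC;
}

// H2.25k: an H2k-eligible exchange is kept only if the network mean
// clustering coefficient is unchanged (within cc_tol); otherwise reverted.
int try_h2_25k(Engine& E, double cc_tol, double& cc_cur) {
  int u, v, c1, c2;
  int rc = select_h2k(E, u, v, c1, c2);
  if (rc != ACC) return rc;
  E.remove_member(u, c1); E.add_member(u, c2);
  E.remove_member(v, c2); E.add_member(v, c1);
  double cc_new = E.mean_clustering();
  if (std::abs(cc_new - cc_cur) <= cc_tol) {
    cc_cur = cc_new;
    return ACC;
  }
  E.remove_member(u, c2); E.add_member(u, c1);
  E.remove_member(v, c1); E.add_member(v, c2);
  return REJ_CC;
}

} // namespace

// [[Rcpp::export]]
List cpp_generate_null(IntegerMatrix C, int model, int n_swaps, int max_attempts,
                       double cc_tol, IntegerVector checkpoints) {
  Engine E;
  E.init(C, model == H2_25K);
  double cc_cur = E.trackA ? E.mean_clustering() : NA_REAL;

  long attempted = 0, rej_equal = 0, rej_empty = 0, rej_member = 0, rej_cc = 0;
  int accepted = 0;
  const int K = checkpoints.size();
  IntegerMatrix snaps(E.n, K);
  int ck = 0;
  while (ck < K && checkpoints[ck] <= 0) {
    for (int i = 0; i < E.n; ++i) snaps(i, ck) = E.rowdeg[i];
    ++ck;
  }

  bool exhausted = false;
  for (int s = 0; s < n_swaps; ++s) {
    bool ok = false;
    for (int a = 0; a < max_attempts; ++a) {
      ++attempted;
      int rc;
      switch (model) {
        case H0K:     rc = try_h0k(E); break;
        case H1K_HD:  rc = try_h1k_hd(E); break;
        case H1K_HED: rc = try_h1k_hed(E); break;
        case HD_HED:  rc = try_hd_hed(E); break;
        case H2K:     rc = try_h2k(E); break;
        case H2_25K:  rc = try_h2_25k(E, cc_tol, cc_cur); break;
        default: stop("unknown model code");
      }
      if (rc == ACC) { ++accepted; ok = true; break; }
      else if (rc == REJ_EQUAL) ++rej_equal;
      else if (rc == REJ_EMPTY) ++rej_empty;
      else if (rc == REJ_MEMBER) ++rej_member;
      else ++rej_cc;
    }
    if (!ok) { exhausted = true; break; }
    while (ck < K && checkpoints[ck] == accepted) {
      for (int i = 0; i < E.n; ++i) snaps(i, ck) = E.rowdeg[i];
      ++ck;
    }
  }
  // unreached checkpoints (attempt budget exhausted): freeze at final state
  while (ck < K) {
    for (int i = 0; i < E.n; ++i) snaps(i, ck) = E.rowdeg[i];
    ++ck;
  }

  IntegerMatrix out(E.n, E.m);
  for (int c = 0; c < E.m; ++c)
    for (size_t i = 0; i < E.members[c].size(); ++i)
      out(E.members[c][i], c) = 1;

  return List::create(
    _["incidence"] = out,
    _["accepted"] = accepted,
    _["attempted"] = static_cast<double>(attempted),
    _["rejected_equal"] = static_cast<double>(rej_equal),
    _["rejected_empty"] = static_cast<double>(rej_empty),
    _["rejected_membership"] = static_cast<double>(rej_member),
    _["rejected_cc"] = static_cast<double>(rej_cc),
    _["exhausted"] = exhausted,
    _["snapshots"] = snaps,
    _["mean_clustering"] = cc_cur);
}

// [[Rcpp::export]]
double cpp_mean_clustering(IntegerMatrix C) {
  Engine E;
  E.init(C, true);
  return E.mean_clustering();
}
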