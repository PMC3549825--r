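// Core string machinery for the underlying-subword approach.
//
// All functions work on a single integer-coded "generalized" string
// x = s1 + sep + s2ext + sep, where residues are coded A=1, C=2, G=3, T=4 and
// every separator / ambiguity sentinel carries a globally unique code >= 5,
// so no match can cross a host or segment boundary.
//
// Coordinates exchanged with R are 0-based; node ids index the lcp-interval
// tree (node 0 is the root, string depth 0).

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
using namespace Rcpp;

namespace {

// suffix array by prefix doubling; fine for the desk scales this package
// targets (total input a few tens of kilobases)
std::vector<int> build_sa(const std::vector<int>& s) {
  const int n = static_cast<int>(s.size());
  std::vector<int> sa(n), rnk(n), tmp(n);
  {
    std::vector<int> vals(s);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    for (int i = 0; i < n; ++i)
      rnk[i] = static_cast<int>(
          std::lower_bound(vals.begin(), vals.end(), s[i]) - vals.begin());
  }
  for (int i = 0; i < n; ++i) sa[i] = i;
  if (n <= 1) return sa;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm; lcp[r] = lcp(suffix sa[r-1], suffix sa[r]), lcp[0] = 0
std::vector<int> build_lcp(const std::vector<int>& s,
                           const std::vector<int>& sa) {
  const int n = static_cast<int>(s.size());
  std::vector<int> rnk(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rnk[i]] = h;
      if (h) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

inline int host_color(int p, int n1, int N) {
  if (p < n1) return 1;
  if (p > n1 && p < N - 1) return 2;
  return 0;  // separator / terminal
}

// matching statistics of every suffix against the suffixes of the other
// host, via two sweeps over the suffix array with running lcp minima
std::vector<int> ms_sweeps(const std::vector<int>& sa,
                           const std::vector<int>& lcp, int n1, int N) {
  std::vector<int> ms(N, 0);
  for (int pass = 0; pass < 2; ++pass) {
    int m1 = INT_MAX, m2 = INT_MAX;
    bool seen1 = false, seen2 = false;
    if (pass == 0) {
      for (int r = 0; r < N; ++r) {
        if (r > 0) {
          m1 = std::min(m1, lcp[r]);
          m2 = std::min(m2, lcp[r]);
        }
        int p = sa[r], c = host_color(p, n1, N);
        if (c == 1) {
          if (seen2) ms[p] = std::max(ms[p], m2);
          seen1 = true;
          m1 = INT_MAX;
        } else if (c == 2) {
          if (seen1) ms[p] = std::max(ms[p], m1);
          seen2 = true;
          m2 = INT_MAX;
        }
      }
    } else {
      for (int r = N - 1; r >= 0; --r) {
        if (r < N - 1) {
          m1 = std::min(m1, lcp[r + 1]);
          m2 = std::min(m2, lcp[r + 1]);
        }
        int p = sa[r], c = host_color(p, n1, N);
        if (c == 1) {
          if (seen2) ms[p] = std::max(ms[p], m2);
          seen1 = true;
          m1 = INT_MAX;
        } else if (c == 2) {
          if (seen1) ms[p] = std::max(ms[p], m1);
          seen2 = true;
          m2 = INT_MAX;
        }
      }
    }
  }
  return ms;
}

struct Tree {
  std::vector<int> depth, lb, rb, parent;
  int add(int d, int l) {
    depth.push_back(d);
    lb.push_back(l);
    rb.push_back(-1);
    parent.push_back(-1);
    return static_cast<int>(depth.size()) - 1;
  }
};

// lcp-interval tree (the internal nodes of the generalized suffix tree),
// stack algorithm of Abouelhoda et al.
Tree build_tree(const std::vector<int>& lcp) {
  const int n = static_cast<int>(lcp.size());
  Tree t;
  t.add(0, 0);  // root
  std::vector<int> st;
  st.push_back(0);
  for (int r = 1; r < n; ++r) {
    int lb = r - 1, last = -1;
    while (lcp[r] < t.depth[st.back()]) {
      int x = st.back();
      st.pop_back();
      t.rb[x] = r - 1;
      lb = t.lb[x];
      if (t.depth[st.back()] >= lcp[r])
        t.parent[x] = st.back();
      else
        last = x;  // parent is the interval about to be created
    }
    if (lcp[r] > t.depth[st.back()]) {
      int id = t.add(lcp[r], lb);
      if (last >= 0) t.parent[last] = id;
      st.push_back(id);
    }
  }
  while (st.size() > 1) {
    int x = st.back();
    st.pop_back();
    t.rb[x] = n - 1;
    t.parent[x] = st.back();
  }
  t.rb[0] = n - 1;
  return t;
}

}  // namespace

// Matching statistics only (cheap path used by matching_statistics()).
// [[Rcpp::export]]
IntegerVector cpp_ms_only(IntegerVector xr, int n1) {
  std::vector<int> x(xr.begin(), xr.end());
  const int N = static_cast<int>(x.size());
  std::vector<int> sa = build_sa(x);
  std::vector<int> lcp = build_lcp(x, sa);
  std::vector<int> ms = ms_sweeps(sa, lcp, n1, N);
  return IntegerVector(ms.begin(), ms.end());
}

// Full pair index: suffix array, lcp, interval-tree nodes with colors,
// per-position matching statistics, lowest bicolored ancestors, irredundant
// flags and prec links.
// [[Rcpp::export]]
List cpp_pair_index(IntegerVector xr, int n1) {
  std::vector<int> x(xr.begin(), xr.end());
  const int N = static_cast<int>(x.size());
  std::vector<int> sa = build_sa(x);
  std::vector<int> lcp = build_lcp(x, sa);
  std::vector<int> ms = ms_sweeps(sa, lcp, n1, N);

  Tree t = build_tree(lcp);
  const int nn = static_cast<int>(t.depth.size());

  // colors via prefix counts over suffix-array order
  std::vector<int> c1(N + 1, 0), c2(N + 1, 0);
  for (int r = 0; r < N; ++r) {
    int c = host_color(sa[r], n1, N);
    c1[r + 1] = c1[r] + (c == 1);
    c2[r + 1] = c2[r] + (c == 2);
  }
  std::vector<int> bic(nn, 0);
  for (int v = 0; v < nn; ++v)
    bic[v] = (c1[t.rb[v] + 1] - c1[t.lb[v]]) > 0 &&
             (c2[t.rb[v] + 1] - c2[t.lb[v]]) > 0;

  // children sorted by left boundary
  std::vector<std::vector<int>> ch(nn);
  for (int v = 1; v < nn; ++v) ch[t.parent[v]].push_back(v);
  for (int v = 0; v < nn; ++v)
    std::sort(ch[v].begin(), ch[v].end(),
              [&](int a, int b) { return t.lb[a] < t.lb[b]; });

  // leaf attachment + deepest bicolored ancestor per leaf (iterative DFS)
  std::vector<int> leafAttach(N, -1), leafBic(N, -1);
  {
    struct Frame {
      int v, ci, r, bicAnc;
    };
    std::vector<Frame> stk;
    stk.push_back({0, 0, 0, -1});
    while (!stk.empty()) {
      Frame& f = stk.back();
      int v = f.v;
      int myBic = (t.depth[v] >= 1 && bic[v]) ? v : f.bicAnc;
      if (f.ci < static_cast<int>(ch[v].size())) {
        int c = ch[v][f.ci];
        while (f.r < t.lb[c]) {
          leafAttach[f.r] = v;
          leafBic[f.r] = myBic;
          ++f.r;
        }
        ++f.ci;
        f.r = t.rb[c] + 1;
        stk.push_back({c, 0, t.lb[c], myBic});
      } else {
        while (f.r <= t.rb[v]) {
          leafAttach[f.r] = v;
          leafBic[f.r] = myBic;
          ++f.r;
        }
        stk.pop_back();
      }
    }
  }

  // earliest occurrence (minimum text position over the subtree); this is
  // the priority tie-break key: s1 positions precede all s2ext positions
  std::vector<int> firstpos(nn, INT_MAX);
  for (int r = 0; r < N; ++r)
    firstpos[leafAttach[r]] = std::min(firstpos[leafAttach[r]], sa[r]);
  {
    std::vector<int> byDepth(nn);
    for (int v = 0; v < nn; ++v) byDepth[v] = v;
    std::sort(byDepth.begin(), byDepth.end(),
              [&](int a, int b) { return t.depth[a] > t.depth[b]; });
    for (int v : byDepth)
      if (t.parent[v] >= 0)
        firstpos[t.parent[v]] = std::min(firstpos[t.parent[v]], firstpos[v]);
  }

  // lowest bicolored ancestor per text position; its string depth must
  // equal the matching statistic (internal consistency check)
  std::vector<int> rnk(N);
  for (int r = 0; r < N; ++r) rnk[sa[r]] = r;
  std::vector<int> leafnode(N, -1);
  for (int p = 0; p < N; ++p) {
    if (ms[p] >= 1) {
      int v = leafBic[rnk[p]];
      if (v < 0 || t.depth[v] != ms[p])
        stop("internal error: bicolored ancestor depth mismatch");
      leafnode[p] = v;
    }
  }

  // irredundant = has at least one occurrence that is both right-maximal
  // (lowest bicolored ancestor of a suffix) and left-maximal
  // (matching statistic does not drop from the previous location)
  std::vector<int> irred(nn, 0);
  for (int p = 0; p < N; ++p) {
    if (leafnode[p] < 0) continue;
    bool leftmax = (p == 0) || (ms[p] >= ms[p - 1]);
    if (leftmax) irred[leafnode[p]] = 1;
  }

  // prec: closest irredundant proper ancestor (preorder by depth)
  std::vector<int> prec(nn, -1);
  {
    std::vector<int> byDepth(nn);
    for (int v = 0; v < nn; ++v) byDepth[v] = v;
    std::sort(byDepth.begin(), byDepth.end(),
              [&](int a, int b) { return t.depth[a] < t.depth[b]; });
    for (int v : byDepth) {
      int pa = t.parent[v];
      if (pa < 0) continue;
      prec[v] = irred[pa] ? pa : prec[pa];
    }
  }

  std::vector<int> leafprec(N, -1);
  for (int r = 0; r < N; ++r) {
    int v = leafAttach[r];
    leafprec[sa[r]] = irred[v] ? v : prec[v];
  }

  return List::create(
      _["sa"] = IntegerVector(sa.begin(), sa.end()),
      _["lcp"] = IntegerVector(lcp.begin(), lcp.end()),
      _["ms"] = IntegerVector(ms.begin(), ms.end()),
      _["node_parent"] = IntegerVector(t.parent.begin(), t.parent.end()),
      _["node_depth"] = IntegerVector(t.depth.begin(), t.depth.end()),
      _["node_lb"] = IntegerVector(t.lb.begin(), t.lb.end()),
      _["node_rb"] = IntegerVector(t.rb.begin(), t.rb.end()),
      _["node_bicolor"] = LogicalVector(bic.begin(), bic.end()),
      _["node_first"] = IntegerVector(firstpos.begin(), firstpos.end()),
      _["node_irred"] = LogicalVector(irred.begin(), irred.end()),
      _["node_prec"] = IntegerVector(prec.begin(), prec.end()),
      _["leaf_node"] = IntegerVector(leafnode.begin(), leafnode.end()),
      _["leaf_prec"] = IntegerVector(leafprec.begin(), leafprec.end()),
      _["n1"] = n1, _["N"] = N);
}

// Greedy selection of the underlying subwords with the boolean coverage
// vector Gamma, the length table chi, and per-word pending-occurrence lists
// seeded through the prec links.  `order` holds the irredundant node ids in
// priority order (descending length, ties by earliest occurrence).
// Occurrences are tested at their interval endpoints only; words are
// processed longest-first, so an accepted occurrence overlapping the
// interval must cover one of its endpoints.  A word is committed (and the
// coverage state updated) only if it keeps at least one untied occurrence
// in each host; otherwise its tentative marks are rolled back and its
// still-uncovered occurrences are forwarded to the longest irredundant
// ancestor prefix allowed by the free run, d = |w| - chi[i + |w| - 1].
// [[Rcpp::export]]
List cpp_select_underlying(IntegerVector node_depth, IntegerVector node_prec,
                           IntegerVector leaf_prec, int n1, int N,
                           IntegerVector order) {
  const int nn = node_depth.size();
  std::vector<std::vector<int>> L(nn);
  for (int p = 0; p < N; ++p)
    if (leaf_prec[p] >= 0) L[leaf_prec[p]].push_back(p);

  std::vector<uint8_t> gamma(N, 0);
  std::vector<int> chi(N, 0);
  std::vector<int> tent(N, -1);  // round id of a tentative mark

  std::vector<int> selNodes;
  std::vector<std::vector<int>> selUntied;

  auto push_ancestor = [&](int v, int d, int i) {
    if (d <= 0) return;
    int u = node_prec[v];
    while (u >= 0 && node_depth[u] > d) u = node_prec[u];
    if (u >= 0) L[u].push_back(i);
  };

  for (int k = 0; k < order.size(); ++k) {
    int v = order[k];
    int len = node_depth[v];
    std::vector<int> occ;
    occ.swap(L[v]);
    if (occ.empty()) continue;
    std::sort(occ.begin(), occ.end());

    std::vector<int> tentStarts, deferred;
    int h1 = 0, h2 = 0;
    for (int i : occ) {
      if (gamma[i]) continue;  // start already claimed: drop for all prefixes
      int j = i + len - 1;
      bool sc = (tent[i] == k);
      bool ec = gamma[j] || (tent[j] == k);
      if (!sc && !ec) {
        for (int p = i; p <= j; ++p) tent[p] = k;
        tentStarts.push_back(i);
        if (i < n1)
          ++h1;
        else
          ++h2;
      } else {
        deferred.push_back(i);
      }
    }

    bool accept = (h1 >= 1 && h2 >= 1);
    if (accept) {
      for (int i : tentStarts)
        for (int p = i; p < i + len; ++p) {
          gamma[p] = 1;
          chi[p] = p - i + 1;
        }
      selNodes.push_back(v);
      selUntied.push_back(tentStarts);
      for (int i : deferred) {
        if (gamma[i]) continue;  // covered by a committed occurrence of v
        int j = i + len - 1;
        int d = gamma[j] ? (len - chi[j]) : len;
        push_ancestor(v, d, i);
      }
    } else {
      // rejected: tentative marks evaporate (lazy, via the round id);
      // forward every occurrence whose start is still free
      for (int i : occ) {
        if (gamma[i]) continue;
        int j = i + len - 1;
        int d = gamma[j] ? (len - chi[j]) : len;
        push_ancestor(v, d, i);
      }
    }
  }

  List untied(selUntied.size());
  for (size_t m = 0; m < selUntied.size(); ++m)
    untied[m] = IntegerVector(selUntied[m].begin(), selUntied[m].end());
  return List::create(
      _["sel"] = IntegerVector(selNodes.begin(), selNodes.end()),
      _["untied"] = untied);
}
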