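#include <Rcpp.h>
using namespace Rcpp;

// Tree encoding used throughout the package (see R/tree-encoding.R):
// an unrooted binary tree on leaves 1..n is rooted at the pendant edge of
// leaf 1. The n-2 internal vertices are listed in postorder; entry 2p and
// 2p+1 of the encoding hold the two children of the internal vertex at
// postorder position p. A child value v <= n is leaf v; a value v > n is
// the internal vertex at postorder position v - n - 1. The last internal
// vertex is the one adjacent to leaf 1.

// Build encodings from stepwise-addition edge sequences. Sequence element
// j (1-based edge index) says on which edge leaf j+3 is inserted, edges
// being numbered in creation order starting from the 3-leaf star
// (1-(n+1)), (2-(n+1)), (3-(n+1)).
// [[Rcpp::export]]
IntegerMatrix build_trees_cpp(int n, IntegerMatrix seqs) {
  if (n < 3) stop("need at least 3 leaves");
  const int ntree = seqs.nrow();
  const int nint = n - 2;
  const int nedge = 2 * n - 3;
  IntegerMatrix out(ntree, 2 * nint);

  std::vector<int> eu(nedge), ev(nedge);
  // adjacency for 2n-2 vertices (1-based ids)
  std::vector<std::array<int, 3>> adj(2 * n - 1);
  std::vector<int> deg(2 * n - 1);

  for (int t = 0; t < ntree; ++t) {
    int m = n + 1;  // first internal id
    eu[0] = 1; ev[0] = m;
    eu[1] = 2; ev[1] = m;
    eu[2] = 3; ev[2] = m;
    int ne = 3;
    for (int k = 4; k <= n; ++k) {
      int e = seqs(t, k - 4) - 1;  // 0-based edge index
      if (e < 0 || e >= ne) stop("addition sequence index out of range");
      int node = n + (k - 2);
      int u = eu[e], v = ev[e];
      eu[e] = u; ev[e] = node;        // u - node
      eu[ne] = node; ev[ne] = v; ++ne; // node - v
      eu[ne] = node; ev[ne] = k; ++ne; // node - leaf k
    }
    // adjacency
    std::fill(deg.begin(), deg.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      adj[eu[e]][deg[eu[e]]++] = ev[e];
      adj[ev[e]][deg[ev[e]]++] = eu[e];
    }
    // iterative postorder DFS from the internal vertex adjacent to leaf 1
    int root = adj[1][0];
    std::vector<int> parent(2 * n - 1, 0);
    std::vector<int> post(2 * n - 1, -1);  // vertex id -> postorder pos
    parent[root] = 1;
    int pos = 0;
    // classic two-pass: collect postorder of internal vertices
    std::vector<int> st2;
    st2.push_back(root);
    std::vector<int> outstack;
    while (!st2.empty()) {
      int v = st2.back(); st2.pop_back();
      outstack.push_back(v);
      for (int i = 0; i < deg[v]; ++i) {
        int w = adj[v][i];
        if (w == parent[v]) continue;
        if (w > n) { parent[w] = v; st2.push_back(w); }
      }
    }
    for (int i = (int)outstack.size() - 1; i >= 0; --i) {
      post[outstack[i]] = pos++;
    }
    // emit children per internal vertex in postorder position order
    std::vector<int> rowbuf(2 * nint);
    for (int i = (int)outstack.size() - 1; i >= 0; --i) {
      int v = outstack[i];
      int p = post[v];
      int c = 0;
      for (int j = 0; j < deg[v]; ++j) {
        int w = adj[v][j];
        if (w == parent[v]) continue;
        int val = (w <= n) ? w : (n + 1 + post[w]);
        rowbuf[2 * p + c] = val;
        ++c;
      }
      if (c != 2) stop("internal vertex without exactly two children");
    }
    for (int j = 0; j < 2 * nint; ++j) out(t, j) = rowbuf[j];
  }
  return out;
}

// Weighted Fitch length for a batch of trees sharing one state matrix.
// states: n x nchar matrix of bitmasks over {0,1}: 1 = state 0, 2 = state 1,
// 3 = either (missing '?'). weights: per-character integer weights.
// [[Rcpp::export]]
IntegerVector fitch_lengths_cpp(IntegerMatrix trees, IntegerMatrix states,
                                IntegerVector weights) {
  const int ntree = trees.nrow();
  const int n = states.nrow();
  const int nchar = states.ncol();
  const int nint = trees.ncol() / 2;
  if (nint != n - 2) stop("tree encoding does not match taxon count");
  IntegerVector out(ntree);
  std::vector<int> mask((n - 2) * nchar);
  for (int t = 0; t < ntree; ++t) {
    long len = 0;
    for (int p = 0; p < nint; ++p) {
      const int a = trees(t, 2 * p), b = trees(t, 2 * p + 1);
      for (int c = 0; c < nchar; ++c) {
        int x = (a <= n) ? states(a - 1, c) : mask[(a - n - 1) * nchar + c];
        int y = (b <= n) ? states(b - 1, c) : mask[(b - n - 1) * nchar + c];
        int z = x & y;
        if (z == 0) { z = x | y; len += weights[c]; }
        mask[p * nchar + c] = z;
      }
    }
    // join with leaf 1
    for (int c = 0; c < nchar; ++c) {
      if ((mask[(nint - 1) * nchar + c] & states(0, c)) == 0) len += weights[c];
    }
    out[t] = (int)len;
  }
  return out;
}

// Per-character Fitch step counts on one tree (unit weights).
// [[Rcpp::export]]
IntegerVector fitch_steps_cpp(IntegerVector tree, IntegerMatrix states) {
  const int n = states.nrow();
  const int nchar = states.ncol();
  const int nint = tree.size() / 2;
  if (nint != n - 2) stop("tree encoding does not match taxon count");
  IntegerVector out(nchar);
  std::vector<int> mask(nint);
  for (int c = 0; c < nchar; ++c) {
    int steps = 0;
    for (int p = 0; p < nint; ++p) {
      int a = tree[2 * p], b = tree[2 * p + 1];
      int x = (a <= n) ? states(a - 1, c) : mask[a - n - 1];
      int y = (b <= n) ? states(b - 1, c) : mask[b - n - 1];
      int z = x & y;
      if (z == 0) { z = x | y; ++steps; }
      mask[p] = z;
    }
    if ((mask[nint - 1] & states(0, c)) == 0) ++steps;
    out[c] = steps;
  }
  return out;
}

// Subtree leaf bitmasks (doubles, leaf i contributes 2^(i-1); safe for
// n <= 52). Returns one mask per internal vertex in postorder; the mask of
// the last (root) vertex equals everything except leaf 1.
// [[Rcpp::export]]
NumericVector subtree_masks_cpp(IntegerVector tree, int n) {
  const int nint = tree.size() / 2;
  NumericVector out(nint);
  for (int p = 0; p < nint; ++p) {
    double m = 0;
    for (int j = 0; j < 2; ++j) {
      int v = tree[2 * p + j];
      m += (v <= n) ? std::ldexp(1.0, v - 1) : out[v - n - 1];
    }
    out[p] = m;
  }
  return out;
}
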