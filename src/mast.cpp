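// Maximum agreement subtree (MAST) between two unrooted binary trees, computed
// by the rooted-MAST dynamic program over all directed edges of both trees and
// maximized over every pair of edge rootings. Subproblems are pairs of directed
// edges (a directed edge = the subtree hanging off it), so the table is shared
// across rootings and the whole computation is O(#edges^2).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

struct DirTree {
  int n_nodes;
  int n_dir;                          // number of directed edges
  std::vector<int> head;              // node the directed edge points to
  std::vector<int> tail;              // node it comes from
  std::vector<int> child1, child2;    // directed-edge ids of children (-1 leaf)
  std::vector<uint64_t> leafset;      // bitset over shared leaf labels (1..64)
  std::vector<int> size;              // number of labelled leaves in subtree
  std::vector<int> leaf_label;        // per node: 0 internal, else label id
  std::vector<int> twin;              // opposite directed edge id
  std::vector<std::pair<int,int>> und; // undirected edges as (dir id, twin id)
};

static DirTree build_dir_tree(const IntegerMatrix& edge,
                              const IntegerVector& leaf_label) {
  DirTree T;
  T.n_nodes = leaf_label.size();
  int ne = edge.nrow();
  T.leaf_label.assign(leaf_label.begin(), leaf_label.end());
  std::vector<std::vector<int>> adj(T.n_nodes + 1);
  for (int e = 0; e < ne; ++e) {
    int u = edge(e, 0), v = edge(e, 1);
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  // enumerate directed edges
  T.n_dir = 2 * ne;
  T.head.resize(T.n_dir); T.tail.resize(T.n_dir);
  T.twin.resize(T.n_dir);
  std::vector<std::vector<std::pair<int,int>>> dir_at(T.n_nodes + 1);
  int id = 0;
  for (int e = 0; e < ne; ++e) {
    int u = edge(e, 0), v = edge(e, 1);
    T.tail[id] = u; T.head[id] = v;
    T.tail[id + 1] = v; T.head[id + 1] = u;
    T.twin[id] = id + 1; T.twin[id + 1] = id;
    T.und.push_back(std::make_pair(id, id + 1));
    dir_at[u].push_back(std::make_pair(v, id));
    dir_at[v].push_back(std::make_pair(u, id + 1));
    id += 2;
  }
  // children of each directed edge
  T.child1.assign(T.n_dir, -1);
  T.child2.assign(T.n_dir, -1);
  for (int d = 0; d < T.n_dir; ++d) {
    int v = T.head[d], u = T.tail[d];
    if (T.leaf_label[v - 1] != 0 || adj[v].size() == 1) continue; // leaf
    int nchild = 0;
    for (size_t k = 0; k < dir_at[v].size(); ++k) {
      int w = dir_at[v][k].first;
      if (w == u) continue;
      if (nchild == 0) T.child1[d] = dir_at[v][k].second;
      else if (nchild == 1) T.child2[d] = dir_at[v][k].second;
      ++nchild;
    }
    if (nchild != 2)
      stop("tree is not binary (an internal node has degree != 3)");
  }
  // leaf sets / sizes by increasing subtree depth (iterate until stable)
  T.leafset.assign(T.n_dir, 0);
  T.size.assign(T.n_dir, -1);
  std::vector<int> order;
  order.reserve(T.n_dir);
  // topological: repeated sweeps (tree depth bounded by n, cheap)
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < T.n_dir; ++d) {
      if (T.size[d] >= 0) continue;
      int v = T.head[d];
      if (T.child1[d] < 0) { // leaf head
        int lab = T.leaf_label[v - 1];
        T.leafset[d] = (lab > 0) ? (uint64_t(1) << (lab - 1)) : 0;
        T.size[d] = (lab > 0) ? 1 : 0;
        order.push_back(d);
        changed = true;
      } else if (T.size[T.child1[d]] >= 0 && T.size[T.child2[d]] >= 0) {
        T.leafset[d] = T.leafset[T.child1[d]] | T.leafset[T.child2[d]];
        T.size[d] = T.size[T.child1[d]] + T.size[T.child2[d]];
        order.push_back(d);
        changed = true;
      }
    }
  }
  return T;
}

// [[Rcpp::export]]
int cpp_mast_size(IntegerMatrix edge1, IntegerVector leaf_label1,
                  IntegerMatrix edge2, IntegerVector leaf_label2) {
  DirTree A = build_dir_tree(edge1, leaf_label1);
  DirTree B = build_dir_tree(edge2, leaf_label2);

  // fill rmast table in ascending (size_A + size_B) order
  std::vector<int> rm((size_t)A.n_dir * B.n_dir, 0);
  auto RM = [&](int a, int b) -> int& { return rm[(size_t)a * B.n_dir + b]; };

  std::vector<std::pair<int,int>> pairs;
  pairs.reserve((size_t)A.n_dir * B.n_dir);
  for (int a = 0; a < A.n_dir; ++a)
    for (int b = 0; b < B.n_dir; ++b)
      pairs.push_back(std::make_pair(A.size[a] + B.size[b], a * B.n_dir + b));
  std::sort(pairs.begin(), pairs.end());

  for (size_t p = 0; p < pairs.size(); ++p) {
    int a = pairs[p].second / B.n_dir, b = pairs[p].second % B.n_dir;
    bool a_leaf = A.child1[a] < 0, b_leaf = B.child1[b] < 0;
    int val = 0;
    if (a_leaf && b_leaf) {
      int la = A.leaf_label[A.head[a] - 1], lb = B.leaf_label[B.head[b] - 1];
      val = (la > 0 && la == lb) ? 1 : 0;
    } else if (a_leaf) {
      int la = A.leaf_label[A.head[a] - 1];
      val = (la > 0 && (B.leafset[b] >> (la - 1)) & 1) ? 1 : 0;
    } else if (b_leaf) {
      int lb = B.leaf_label[B.head[b] - 1];
      val = (lb > 0 && (A.leafset[a] >> (lb - 1)) & 1) ? 1 : 0;
    } else {
      int a1 = A.child1[a], a2 = A.child2[a];
      int b1 = B.child1[b], b2 = B.child2[b];
      val = std::max(RM(a1, b1) + RM(a2, b2), RM(a1, b2) + RM(a2, b1));
      val = std::max(val, std::max(RM(a1, b), RM(a2, b)));
      val = std::max(val, std::max(RM(a, b1), RM(a, b2)));
    }
    RM(a, b) = val;
  }

  // maximize over all pairs of edge rootings
  int best = 0;
  for (size_t ea = 0; ea < A.und.size(); ++ea) {
    int p1 = A.und[ea].first, q1 = A.und[ea].second;
    for (size_t eb = 0; eb < B.und.size(); ++eb) {
      int p2 = B.und[eb].first, q2 = B.und[eb].second;
      int v = std::max(RM(p1, p2) + RM(q1, q2), RM(p1, q2) + RM(q1, p2));
      if (v > best) best = v;
    }
  }
  return best;
}
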