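#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Patterns are encoded 4 bits per element (labels never exceed l+1 and
// l is capped at 12 on the R side), so a whole pattern fits in a uint64.
static uint64_t encode_pattern(const IntegerVector& p) {
  uint64_t code = 0;
  for (int i = 0; i < p.size(); ++i) code = (code << 4) | (uint64_t)p[i];
  return code;
}

static void enum_rec(std::vector<int>& cur, int maxlab, int l,
                     List& out, int& k) {
  if ((int)cur.size() == l + 1) {
    out[k++] = IntegerVector(cur.begin(), cur.end());
    return;
  }
  int last = cur.back();
  for (int v = 1; v <= maxlab + 1; ++v) {
    if (v == last) continue;  // no self-loops
    cur.push_back(v);
    enum_rec(cur, std::max(maxlab, v), l, out, k);
    cur.pop_back();
  }
}

static long count_patterns(int l) {
  // a(t+1, k) = a(t, k) * (k - 1) + a(t, k - 1), a(1, 1) = 1
  std::vector<long> a(l + 2, 0); a[1] = 1;
  for (int t = 1; t <= l; ++t) {
    std::vector<long> b(l + 2, 0);
    for (int k = 1; k <= t + 1; ++k)
      b[k] = a[k] * (k - 1) + (k >= 1 ? a[k - 1] : 0);
    a = b;
  }
  long n = 0;
  for (long v : a) n += v;
  return n;
}

// All anonymous walk patterns of length l (edges), lexicographic order.
// [[Rcpp::export]]
List cpp_enumerate_walks(int l) {
  long n = count_patterns(l);
  List out(n);
  int k = 0;
  std::vector<int> cur{1};
  enum_rec(cur, 1, l, out, k);
  return out;
}

struct WalkCtx {
  const std::vector<std::vector<int>>& nbrs;
  const std::unordered_map<uint64_t, int>& index;
  std::vector<int> lab;
  int next_label;
  int l;
  std::vector<double>& vec;
};

static void exact_rec(WalkCtx& c, int u, int depth, uint64_t code, double prob) {
  if (depth == c.l) {
    auto it = c.index.find(code);
    c.vec[it->second] += prob;
    return;
  }
  double p = prob / (double)c.nbrs[u].size();
  for (int v : c.nbrs[u]) {
    bool newly = (c.lab[v] == 0);
    if (newly) c.lab[v] = ++c.next_label;
    exact_rec(c, v, depth + 1, (code << 4) | (uint64_t)c.lab[v], p);
    if (newly) { c.lab[v] = 0; --c.next_label; }
  }
}

static std::vector<std::vector<int>> adj_to_nbrs(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0) nbrs[i].push_back(j);
  return nbrs;
}

static std::unordered_map<uint64_t, int> build_index(const List& patterns) {
  std::unordered_map<uint64_t, int> index;
  index.reserve(patterns.size() * 2);
  for (int i = 0; i < patterns.size(); ++i)
    index[encode_pattern(patterns[i])] = i;
  return index;
}

// Exact anonymous-walk distribution: start node uniform over nodes of
// degree >= 1, each step uniform over neighbors; probability mass of
// every node walk accumulated onto its anonymous pattern.
// [[Rcpp::export]]
NumericVector cpp_exact_embedding(IntegerMatrix A, int l, List patterns) {
  auto nbrs = adj_to_nbrs(A);
  auto index = build_index(patterns);
  std::vector<int> starts;
  for (size_t i = 0; i < nbrs.size(); ++i)
    if (!nbrs[i].empty()) starts.push_back((int)i);
  std::vector<double> vec(patterns.size(), 0.0);
  WalkCtx ctx{nbrs, index, std::vector<int>(A.nrow(), 0), 0, l, vec};
  double p0 = 1.0 / (double)starts.size();
  for (int s : starts) {
    ctx.lab[s] = 1; ctx.next_label = 1;
    exact_rec(ctx, s, 0, 1ULL, p0);
    ctx.lab[s] = 0;
  }
  return NumericVector(vec.begin(), vec.end());
}

// m independent seeded random walks, canonicalized on the fly; returns
// raw pattern counts (R side divides by m). Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_sample_walks(IntegerMatrix A, int l, int m, List patterns) {
  auto nbrs = adj_to_nbrs(A);
  auto index = build_index(patterns);
  std::vector<int> starts;
  for (size_t i = 0; i < nbrs.size(); ++i)
    if (!nbrs[i].empty()) starts.push_back((int)i);
  int n = A.nrow();
  std::vector<double> counts(patterns.size(), 0.0);
  std::vector<int> lab(n, 0), touched;
  touched.reserve(l + 1);
  GetRNGstate();
  for (int w = 0; w < m; ++w) {
    int u = starts[(int)(unif_rand() * starts.size()) % starts.size()];
    lab[u] = 1; touched.push_back(u);
    int next_label = 1;
    uint64_t code = 1ULL;
    for (int step = 0; step < l; ++step) {
      const std::vector<int>& nb = nbrs[u];
      u = nb[(int)(unif_rand() * nb.size()) % nb.size()];
      if (lab[u] == 0) { lab[u] = ++next_label; touched.push_back(u); }
      code = (code << 4) | (uint64_t)lab[u];
    }
    counts[index.find(code)->second] += 1.0;
    for (int t : touched) lab[t] = 0;
    touched.clear();
  }
  PutRNGstate();
  return NumericVector(counts.begin(), counts.end());
}
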